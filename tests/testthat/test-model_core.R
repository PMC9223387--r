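## Data model, I/O round trips, summaries, and biomass-reaction assembly.

rxn_fields_equal <- function(a, b) {
  ka <- sort(names(a$stoichiometry))
  isTRUE(all.equal(a$stoichiometry[ka], b$stoichiometry[ka])) &&
    a$lower_bound == b$lower_bound && a$upper_bound == b$upper_bound &&
    identical(aquaflux:::normalize_gpr(a$gpr),
              aquaflux:::normalize_gpr(b$gpr)) &&
    identical(a$kind, b$kind)
}

models_equal <- function(a, b) {
  identical(names(a$reactions), names(b$reactions)) &&
    all(vapply(names(a$reactions), function(id)
      rxn_fields_equal(a$reactions[[id]], b$reactions[[id]]), TRUE)) &&
    isTRUE(all.equal(a$objective, b$objective)) &&
    setequal(a$genes, b$genes) &&
    identical(a$metabolites$id, b$metabolites$id)
}

test_that("SBML and JSON round trips are fixpoints", {
  m <- toy_default()
  for (ext in c(".xml", ".json")) {
    p1 <- tempfile(fileext = ext); p2 <- tempfile(fileext = ext)
    write_model(m, p1)
    m1 <- read_model(p1)
    expect_true(models_equal(m, m1))
    ## read-write-read fixpoint
    write_model(m1, p2)
    m2 <- read_model(p2)
    expect_true(models_equal(m1, m2))
    expect_equal(fba(m2)$objective_value, fba(m)$objective_value,
                 tolerance = 1e-9)
    unlink(c(p1, p2))
  }
})

test_that("malformed or inconsistent files are rejected with context", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model>", bad)
  expect_error(read_model(bad), "parse error")
  ## a reaction referencing a missing metabolite fails validation
  m <- toy_default()
  p <- tempfile(fileext = ".json")
  write_model(m, p)
  doc <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  doc$reactions[[30]]$metabolites[["ghost_c"]] <- 1
  jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA)
  expect_error(read_model(p), "missing metabolite")
  expect_error(read_model(tempfile()), "no such file")
  unlink(c(bad, p))
})

test_that("model summaries count what the generator constructed", {
  m <- toy_default()
  s <- summarize_model(m)
  cnt <- stats::setNames(s$counts$value, s$counts$quantity)
  expect_equal(cnt[["reactions"]], length(m$reactions))
  expect_equal(cnt[["metabolites"]], nrow(m$metabolites))
  expect_equal(cnt[["genes"]], length(m$genes))
  kinds <- vapply(m$reactions, `[[`, "", "kind")
  expect_equal(cnt[["transport_reactions"]], sum(kinds == "transport"))
  expect_equal(cnt[["boundary_reactions"]],
               sum(kinds %in% c("exchange", "sink_demand")))
  ## unique metabolites collapse compartments: o2 appears in e and m,
  ## amino acids in e and c
  base <- unique(sub("_(e|c|m)$", "", m$metabolites$id))
  expect_equal(cnt[["unique_metabolites"]], length(base))
  ## a metabolite present in three compartments counts once
  mets <- data.frame(id = c("x_e", "x_c", "x_m"), name = "x",
                     compartment = c("e", "c", "m"))
  rxns <- list(list(id = "EX_x_e", name = "x", stoichiometry = c(x_e = -1),
                    lower_bound = -1, upper_bound = 1, gpr = "",
                    kind = "exchange"))
  m3 <- metabolic_model("tiny", c(e = "e", c = "c", m = "m"), mets, rxns)
  expect_equal(summarize_model(m3)$counts$value[
    summarize_model(m3)$counts$quantity == "unique_metabolites"], 1)
})

test_that("summaries are invariant under reaction reordering", {
  m <- toy_default()
  m2 <- m
  set.seed(1)
  m2$reactions <- m2$reactions[sample(length(m2$reactions))]
  s1 <- summarize_model(m)$counts
  s2 <- summarize_model(m2)$counts
  expect_equal(s1$value, s2$value)
  d1 <- summarize_model(m)$degrees
  d2 <- summarize_model(m2)$degrees
  expect_equal(sort(d1$metabolites_per_reaction),
               sort(d2$metabolites_per_reaction))
})

test_that("biomass coefficients follow the mass-fraction arithmetic", {
  ## pure glycine protein: coefficient = 1000 / 75.07 mmol per gDW
  r <- build_biomass_reaction(
    list(macromolecule_fractions = c(protein = 1),
         monomer_fractions = list(protein = c(gly = 1)),
         energy_cost = 0),
    monomer_masses = c(gly = 75.07))
  expect_equal(unname(r$stoichiometry[["gly"]]), -1000 / 75.07,
               tolerance = 1e-12)
  ## two-macromolecule recipe, coefficients computed by hand:
  ## protein 0.6 of which gly 0.5 / ala 0.5 by mass; lipid 0.4
  ## gly: 0.6*0.5/75.07*1000 = 3.996270...; ala: 0.6*0.5/89.09*1000
  ## lipid: 0.4/800*1000 = 0.5
  r2 <- build_biomass_reaction(
    list(macromolecule_fractions = c(protein = 0.6, lipid = 0.4),
         monomer_fractions = list(protein = c(gly = 0.5, ala = 0.5),
                                  lipid = c(lip = 1)),
         energy_cost = 0),
    monomer_masses = c(gly = 75.07, ala = 89.09, lip = 800))
  expect_equal(unname(r2$stoichiometry[["gly"]]), -300 / 75.07,
               tolerance = 1e-12)
  expect_equal(unname(r2$stoichiometry[["ala"]]), -300 / 89.09,
               tolerance = 1e-12)
  expect_equal(unname(r2$stoichiometry[["lip"]]), -0.5, tolerance = 1e-12)
})

test_that("biomass reactions consume exactly 1 g of precursors", {
  set.seed(42)
  for (rep in 1:10) {
    fr <- stats::runif(3); fr <- fr / sum(fr)
    mono_n <- sample(2:5, 3, replace = TRUE)
    monomers <- paste0("m", seq_len(sum(mono_n)))
    masses <- stats::setNames(stats::runif(length(monomers), 60, 600),
                              monomers)
    idx <- split(monomers, rep(1:3, mono_n))
    mono_fr <- lapply(idx, function(ms) {
      w <- stats::runif(length(ms)); stats::setNames(w / sum(w), ms)
    })
    recipe <- list(
      macromolecule_fractions = stats::setNames(fr, c("protein", "x",
                                                      "y")),
      monomer_fractions = stats::setNames(mono_fr, c("protein", "x",
                                                     "y")),
      energy_cost = 30)
    r <- build_biomass_reaction(recipe, masses)
    st <- r$stoichiometry[monomers]
    expect_equal(sum(-st * masses[monomers]) / 1000, 1, tolerance = 1e-6)
    ## the ATP hydrolysis term is mass-neutral and scaled by protein
    expect_equal(unname(r$stoichiometry[["atp_c"]]), -30 * fr[1],
                 tolerance = 1e-9)
  }
})

test_that("invalid recipes fail with informative errors", {
  expect_error(build_biomass_reaction(
    list(macromolecule_fractions = c(protein = 0.7),
         monomer_fractions = list(protein = c(gly = 1))),
    c(gly = 75.07)), "sum to 1")
  expect_error(build_biomass_reaction(
    list(macromolecule_fractions = c(protein = 1),
         monomer_fractions = list(protein = c(gly = 1))),
    c(ala = 89.09)), "gly")
})

test_that("model validation names the offending element", {
  mets <- data.frame(id = c("a_c", "a_c"), name = "a", compartment = "c")
  expect_error(metabolic_model("m", c(c = "cytosol"), mets, list()),
               "duplicated metabolite")
  mets2 <- data.frame(id = "a_c", name = "a", compartment = "zz")
  expect_error(metabolic_model("m", c(c = "cytosol"), mets2, list()),
               "compartment")
  mets3 <- data.frame(id = "a_c", name = "a", compartment = "c")
  rxns <- list(list(id = "R1", name = "r", stoichiometry = c(a_c = -1),
                    lower_bound = 1, upper_bound = -1, gpr = "",
                    kind = "sink_demand"))
  expect_error(metabolic_model("m", c(c = "cytosol"), mets3, rxns),
               "lower_bound")
})
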