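## Synthetic "salmon-like" core model and randomized condition sampling.
## The generator provides ground truth (constructed-essential amino acids,
## known secretion requirements, an oxygen-limited aerobic energy system)
## so every downstream analysis is testable offline.

#' The ten amino acids that are dietarily essential for salmonids
#' @export
ESSENTIAL_AA <- c("arg", "his", "ile", "leu", "lys", "met", "phe", "thr",
                  "trp", "val")

#' Amino acids synthesizable by the organism (non-essential)
#' @export
NONESSENTIAL_AA <- c("ala", "asn", "asp", "cys", "gln", "glu", "gly", "pro",
                     "ser", "tyr")

#' Free amino-acid molar masses in g/mol
#' @export
AA_MOLAR_MASS <- c(
  ala = 89.09, arg = 174.20, asn = 132.12, asp = 133.10, cys = 121.16,
  gln = 146.15, glu = 147.13, gly = 75.07, his = 155.15, ile = 131.17,
  leu = 131.17, lys = 146.19, met = 149.21, phe = 165.19, pro = 115.13,
  ser = 105.09, thr = 119.12, trp = 204.23, tyr = 181.19, val = 117.15)

## whole-protein amino-acid mass percentages (fish-protein-like profile)
PROTEIN_AA_PERCENT <- c(
  ala = 6.82, arg = 7.19, asn = 5.01, asp = 5.01, cys = 0.93, gln = 6.99,
  glu = 6.99, gly = 6.88, his = 2.62, ile = 4.64, leu = 7.91, lys = 8.31,
  met = 3.07, phe = 4.29, pro = 4.45, ser = 4.29, thr = 4.57, trp = 1.13,
  tyr = 3.40, val = 5.48)

WATER_MASS <- 18.02

#' Specification for the synthetic core model
#'
#' @param n_essential_aa number of constructed-essential amino acids
#'   (taken from the salmonid-essential ten; default 10).
#' @param n_nonessential_aa number of synthesizable amino acids (default 8).
#' @param include_urea_route include the ATP-costly arginine-to-urea
#'   disposal route (default TRUE).
#' @param include_anaerobic_route include lactate fermentation
#'   (default TRUE).
#' @param biomass_fractions named mass fractions of 1 gDW for protein,
#'   lipid, carbohydrate, nucleic_acid; must sum to 1.
#' @param energy_cost mmol ATP per g protein synthesized (default 40).
#' @param seed integer seed stored with the generator settings.
#' @return an object of class \code{toy_model_spec}.
#' @export
toy_model_spec <- function(n_essential_aa = 10, n_nonessential_aa = 8,
                           include_urea_route = TRUE,
                           include_anaerobic_route = TRUE,
                           biomass_fractions = c(protein = 0.55,
                                                 lipid = 0.30,
                                                 carbohydrate = 0.10,
                                                 nucleic_acid = 0.05),
                           energy_cost = 40,
                           seed = 1L) {
  if (abs(sum(biomass_fractions) - 1) > 1e-9)
    stop("invalid spec field biomass_fractions: must sum to 1")
  ntot <- n_essential_aa + n_nonessential_aa
  if (ntot > 20 || ntot < 2)
    stop("invalid spec fields n_essential_aa/n_nonessential_aa: ",
         "total must be in [2, 20]")
  if (n_essential_aa < 0 || n_essential_aa > 10)
    stop("invalid spec field n_essential_aa: must be in [0, 10]")
  if (n_nonessential_aa < 0 || n_nonessential_aa > 10)
    stop("invalid spec field n_nonessential_aa: must be in [0, 10]")
  structure(list(n_essential_aa = n_essential_aa,
                 n_nonessential_aa = n_nonessential_aa,
                 include_urea_route = include_urea_route,
                 include_anaerobic_route = include_anaerobic_route,
                 biomass_fractions = biomass_fractions,
                 energy_cost = energy_cost,
                 seed = as.integer(seed)),
            class = "toy_model_spec")
}

#' Generate the synthetic salmon-like core model
#'
#' Builds a compact, flux-consistent three-compartment model (extracellular,
#' cytosol, mitochondrion) with exchanges for oxygen, CO2, ammonia, urea,
#' phosphate, choline, glucose, lactate, and amino acids. Energy comes from
#' glycolysis plus mitochondrial respiration (and optionally lactate
#' fermentation); essential amino acids have no synthesis route while
#' non-essential ones are made from pyruvate and ammonia; ammonia disposal
#' is free while the urea route (arginine catabolism to urea) costs ATP.
#' The biomass reaction is assembled with
#' \code{\link{build_biomass_reaction}} so one unit of biomass flux consumes
#' 1 g of precursors per gDW h.
#'
#' @param spec a \code{\link{toy_model_spec}}.
#' @return a \code{metabolic_model} with objective BIOMASS.
#' @export
generate_toy_model <- function(spec = toy_model_spec()) {
  if (!inherits(spec, "toy_model_spec")) stop("spec must be a toy_model_spec")
  ess <- ESSENTIAL_AA[seq_len(spec$n_essential_aa)]
  non <- NONESSENTIAL_AA[seq_len(spec$n_nonessential_aa)]
  aas <- c(ess, non)

  comp <- c(e = "extracellular", c = "cytosol", m = "mitochondrion")
  masses <- c(AA_MOLAR_MASS,
              glc = 180.16, o2 = 32.00, co2 = 44.01, nh3 = 17.03,
              urea = 60.06, pi = 97.00, chol = 121.18, pyr = 88.06,
              lac = 90.08, atp = 507.18, adp = 427.20,
              lipid = 785.60, ntp = 503.00)

  met <- function(base, cmp) {
    data.frame(id = paste0(base, "_", cmp), name = base, compartment = cmp,
               formula = NA_character_,
               molar_mass = unname(masses[base]))
  }
  e_base <- c("glc", "o2", "co2", "nh3", "urea", "pi", "chol", "lac", aas)
  c_base <- c("glc", "pyr", "lac", "atp", "adp", "pi", "nh3", "urea",
              "chol", "lipid", "ntp", aas)
  m_base <- c("o2", "co2", "pyr", "atp", "adp", "pi")
  mets <- rbind(do.call(rbind, lapply(e_base, met, cmp = "e")),
                do.call(rbind, lapply(c_base, met, cmp = "c")),
                do.call(rbind, lapply(m_base, met, cmp = "m")))

  rxns <- list()
  add <- function(id, stoich, lb = 0, ub = 1000, gpr = "", name = id) {
    rxns[[id]] <<- list(id = id, name = name, stoichiometry = stoich,
                        lower_bound = lb, upper_bound = ub, gpr = gpr,
                        kind = NA_character_)
  }
  ## exchanges: negative flux = import, positive = export
  for (b in e_base)
    add(paste0("EX_", b, "_e"),
        stats::setNames(-1, paste0(b, "_e")), lb = -1000, ub = 1000)
  ## plasma-membrane transports (reversible), gene-associated
  for (b in setdiff(e_base, c("o2", "co2")))
    add(paste0("T_", b),
        stats::setNames(c(-1, 1), paste0(b, c("_e", "_c"))),
        lb = -1000, ub = 1000, gpr = paste0("g_T_", b))
  ## oxygen straight to the mitochondrion; CO2 straight out
  add("T_o2", c(o2_e = -1, o2_m = 1), gpr = "g_T_o2")
  add("T_co2", c(co2_m = -1, co2_e = 1), gpr = "g_T_co2")
  ## inner-membrane carriers
  add("T_pyr_m", c(pyr_c = -1, pyr_m = 1), lb = -1000, gpr = "g_T_pyr_m")
  add("ANT", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
      gpr = "g_ANT", name = "adenine nucleotide translocase")
  add("T_pi_m", c(pi_c = -1, pi_m = 1), gpr = "g_T_pi_m")

  ## energy metabolism
  add("GLYC", c(glc_c = -1, adp_c = -2, pi_c = -2, pyr_c = 2, atp_c = 2),
      gpr = "g_GLYC1 and g_GLYC2", name = "glycolysis (lumped)")
  add("GNG", c(pyr_c = -2, atp_c = -6, glc_c = 1, adp_c = 6, pi_c = 6),
      gpr = "g_GNG", name = "gluconeogenesis (lumped)")
  if (spec$include_anaerobic_route)
    add("FERM", c(pyr_c = -1, lac_c = 1), gpr = "g_FERM",
        name = "lactate fermentation")
  add("RESP", c(pyr_m = -1, o2_m = -2.5, adp_m = -5, pi_m = -5,
                co2_m = 3, atp_m = 5),
      gpr = "(g_RESP1 and g_RESP2) or g_RESP3",
      name = "pyruvate oxidation + oxidative phosphorylation (lumped)")

  ## nitrogen disposal: ammonia leaves freely via T_nh3/EX_nh3_e; the urea
  ## route exists only as ATP-costly arginine catabolism (arginase-like), so
  ## excess non-arginine nitrogen can only leave as ammonia
  ## the ornithine backbone is not tracked, so this route yields no usable
  ## carbon: nitrogen-free carbon salvage cannot run through it
  if (spec$include_urea_route && "arg" %in% ess)
    add("UREA_SYN", c(arg_c = -1, atp_c = -2, urea_c = 1,
                      adp_c = 2, pi_c = 2),
        gpr = "g_UREA", name = "arginine catabolism to urea (ATP-costly)")

  ## essential amino acids are catabolizable (carbon + nitrogen salvage)
  ## but have no synthesis route; arginine carries two nitrogens
  for (a in ess)
    add(paste0("CAT_", a),
        stats::setNames(c(-1, 1, if (a == "arg") 2 else 1),
                        c(paste0(a, "_c"), "pyr_c", "nh3_c")),
        gpr = paste0("g_CAT_", a), name = paste0(a, " catabolism"))
  ## non-essential amino acids are synthesized from pyruvate + ammonia
  for (a in non)
    add(paste0("SYN_", a),
        stats::setNames(c(-1, -1, -2, 1, 2, 2),
                        c("pyr_c", "nh3_c", "atp_c", paste0(a, "_c"),
                          "adp_c", "pi_c")),
        gpr = paste0("g_SYN_", a), name = paste0(a, " synthesis"))

  ## biomass precursors
  add("LIPID_SYN", c(chol_c = -1, glc_c = -0.5, atp_c = -1, lipid_c = 1,
                     adp_c = 1, pi_c = 1),
      gpr = "g_LIPID", name = "phosphatidylcholine-like lipid synthesis")
  ## choline catabolism (betaine-like carbon/nitrogen salvage) so feed
  ## surplus can be burned when secretion of feed nutrients is disabled
  add("CAT_chol", c(chol_c = -1, pyr_c = 1, nh3_c = 1),
      gpr = "g_CAT_chol", name = "choline catabolism")
  add("NTP_SYN", c(glc_c = -0.5, nh3_c = -2, pi_c = -1, atp_c = -2,
                   ntp_c = 1, adp_c = 2),
      gpr = "g_NTP", name = "nucleotide synthesis (lumped)")

  ## biomass reaction from the composition recipe; protein fractions are
  ## renormalized over the amino acids present in this spec
  aa_w <- PROTEIN_AA_PERCENT[aas]
  aa_w <- aa_w / sum(aa_w)
  recipe <- list(
    macromolecule_fractions = spec$biomass_fractions,
    monomer_fractions = list(
      protein = stats::setNames(as.numeric(aa_w), paste0(aas, "_c")),
      lipid = c(lipid_c = 1),
      carbohydrate = c(glc_c = 1),
      nucleic_acid = c(ntp_c = 1)),
    energy_cost = spec$energy_cost)
  monomer_masses <- c(
    stats::setNames(AA_MOLAR_MASS[aas] - WATER_MASS, paste0(aas, "_c")),
    lipid_c = 785.60, glc_c = 162.14, ntp_c = 503.00 - WATER_MASS)
  rxns[["BIOMASS"]] <- build_biomass_reaction(recipe, monomer_masses)

  genes <- unique(unlist(lapply(rxns, function(r) gpr_gene_ids(r$gpr))))
  met_comp <- stats::setNames(mets$compartment, mets$id)
  rxns <- lapply(rxns, function(r) {
    r$kind <- classify_reaction(r$stoichiometry, met_comp, r$id)
    r
  })
  metabolic_model(id = "toy_salmon_core", compartments = comp,
                  metabolites = mets, reactions = rxns, genes = genes,
                  objective = c(BIOMASS = 1))
}

#' Minimal-feed nutrients of a model
#'
#' The nutrients of the minimal feed: essential amino acids plus choline.
#'
#' @param model a \code{metabolic_model}.
#' @return character vector of base metabolite ids.
#' @export
minimal_feed_nutrients <- function(model) {
  base <- base_metabolite_id(model$metabolites$id,
                             names(model$compartments))
  ess <- intersect(ESSENTIAL_AA, base)
  c(ess, intersect("chol", base))
}

## evaluate code with a private RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample one randomized condition
#'
#' Draws feed-nutrient ratios uniformly in [1, 100] for the minimal-feed
#' nutrients and a strictly positive flux-bound sample per direction for
#' every internal/transport reaction, with ln(b) ~ Normal(0, sigma_ln^2).
#' Reversible reactions get independent samples for each direction.
#'
#' @param model a \code{metabolic_model}.
#' @param rng_seed integer seed; the same seed reproduces the sample.
#' @param sigma_ln standard deviation of ln(b) (default 2).
#' @return object of class \code{condition_sample}: list with
#'   \code{feed_ratios} (named numeric), \code{bound_samples} (data.frame
#'   reaction, direction, bound), \code{seed}.
#' @export
sample_condition <- function(model, rng_seed, sigma_ln = 2) {
  if (!is.numeric(sigma_ln) || sigma_ln <= 0)
    stop("sigma_ln must be a positive real")
  nutrients <- minimal_feed_nutrients(model)
  sampled_kinds <- c("internal", "transport")
  ids <- reaction_ids(model, sampled_kinds)
  with_seed(rng_seed, {
    ratios <- stats::setNames(stats::runif(length(nutrients), 1, 100),
                              nutrients)
    rows <- lapply(ids, function(id) {
      r <- model$reactions[[id]]
      dirs <- c(if (r$upper_bound > 0) "forward",
                if (r$lower_bound < 0) "reverse")
      data.frame(reaction = id, direction = dirs,
                 bound = exp(stats::rnorm(length(dirs), 0, sigma_ln)))
    })
    structure(list(feed_ratios = ratios,
                   bound_samples = do.call(rbind, rows),
                   seed = as.integer(rng_seed)),
              class = "condition_sample")
  })
}

#' Sample a batch of conditions from one master seed
#'
#' One master seed spawns independent per-condition child seeds so the whole
#' sweep is reproducible from a single integer.
#'
#' @param model a \code{metabolic_model}.
#' @param n number of conditions.
#' @param master_seed integer.
#' @param sigma_ln standard deviation of ln(b) (default 2).
#' @return list of \code{condition_sample} objects.
#' @export
sample_conditions <- function(model, n, master_seed, sigma_ln = 2) {
  child <- with_seed(master_seed,
                     sample.int(.Machine$integer.max - 1L, n))
  lapply(child, function(s) sample_condition(model, s, sigma_ln))
}

#' Write sampled conditions to CSV
#'
#' Emits two tables: (condition_id, nutrient, ratio) and
#' (condition_id, reaction, direction, bound).
#'
#' @param conditions list of \code{condition_sample}.
#' @param ratios_path,bounds_path output CSV paths.
#' @return invisibly, a list with the two data frames.
#' @export
write_conditions <- function(conditions, ratios_path, bounds_path) {
  rt <- do.call(rbind, lapply(seq_along(conditions), function(i) {
    cs <- conditions[[i]]
    data.frame(condition_id = i, nutrient = names(cs$feed_ratios),
               ratio = unname(cs$feed_ratios))
  }))
  bt <- do.call(rbind, lapply(seq_along(conditions), function(i) {
    cbind(condition_id = i, conditions[[i]]$bound_samples)
  }))
  utils::write.csv(rt, ratios_path, row.names = FALSE)
  utils::write.csv(bt, bounds_path, row.names = FALSE)
  invisible(list(ratios = rt, bounds = bt))
}
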