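## Feed analysis: feed-uptake reaction construction from amino-acid
## composition tables, limiting-amino-acid identification from
## mass-weighted reduced costs, iterative penalized supplementation, and
## feed-efficiency accounting.

#' Load the bundled feed amino-acid composition table
#'
#' Mass percentage of each amino acid relative to total amino-acid mass in
#' three commercial feed ingredients (fish meal, soybean meal, insect
#' meal). Combined entries (Asn/Asp, Gln/Glu) are kept combined; they are
#' split when a \code{\link{feed_composition}} is built.
#'
#' @param path CSV path; defaults to the bundled table.
#' @return data.frame (amino_acid, fish_meal, soybean_meal, insect_meal).
#' @export
read_feed_table <- function(path = system.file("extdata",
                                               "feed_amino_acids.csv",
                                               package = "aquaflux")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a feed composition from a table column
#'
#' Splits combined entries (e.g. "Asn/Asp") with mass divided equally
#' between the members, checks that percentages sum to 100 (within 0.5),
#' and attaches free-amino-acid molar masses.
#'
#' @param feed_name column name in the table ("fish_meal", "soybean_meal",
#'   "insect_meal").
#' @param table composition table from \code{\link{read_feed_table}}.
#' @return object of class \code{feed_composition}: list with \code{name},
#'   \code{mass_percent} (named, lowercase amino-acid ids), and
#'   \code{molar_masses}.
#' @export
feed_composition <- function(feed_name, table = read_feed_table()) {
  if (!feed_name %in% names(table))
    stop("no feed column '", feed_name, "' in table")
  raw_total <- sum(table[[feed_name]])
  if (abs(raw_total - 100) > 0.5)
    stop("feed percentages sum to ", raw_total, ", expected 100 (+/- 0.5)")
  pct <- numeric()
  for (i in seq_len(nrow(table))) {
    keys <- tolower(strsplit(table$amino_acid[i], "/")[[1]])
    for (k in keys) pct[k] <- table[[feed_name]][i] / length(keys)
  }
  unknown <- setdiff(names(pct), names(AA_MOLAR_MASS))
  if (length(unknown)) stop("unknown amino acid key: ", unknown[1])
  structure(list(name = feed_name, mass_percent = pct,
                 molar_masses = AA_MOLAR_MASS[names(pct)]),
            class = "feed_composition")
}

#' Build a feed uptake reaction from a composition
#'
#' The feed reaction supplies extracellular amino acids in the feed's mass
#' proportions: the coefficient of amino acid i is w_i / M_i (normalized
#' mass fraction over molar mass), scaled so one unit of feed flux supplies
#' exactly 1 g of amino acids (coefficients in mmol per g).
#'
#' @param feed a \code{\link{feed_composition}}.
#' @param compartment compartment suffix for the supplied metabolites
#'   (default "e").
#' @return a feed reaction list (kind "feed", id "FEED").
#' @export
build_feed_reaction <- function(feed, compartment = "e") {
  w <- feed$mass_percent / sum(feed$mass_percent)
  coefs <- 1000 * w / feed$molar_masses[names(w)]
  stoich <- stats::setNames(as.numeric(coefs),
                            paste0(names(w), "_", compartment))
  list(id = "FEED", name = paste0("feed uptake (", feed$name, ")"),
       stoichiometry = stoich, lower_bound = 0, upper_bound = 1e6,
       gpr = "", kind = "feed")
}

## Configure a model for feed-limitation analysis: attach the feed
## reaction (restricted to amino acids present in the model), fix growth,
## allow unlimited uptake of glucose, oxygen, phosphate and choline,
## disable amino-acid import except for supplemented ones, and leave
## surplus export open.
feed_limitation_setup <- function(model, feed_reaction, fixed_growth,
                                  supplemented = character()) {
  st <- feed_reaction$stoichiometry
  present <- names(st) %in% model$metabolites$id
  if (!all(present)) {
    st <- st[present]
    if (length(st) == 0) stop("no feed amino acid present in model")
    feed_reaction$stoichiometry <- st
  }
  m2 <- model
  m2$reactions[["FEED"]] <- feed_reaction
  aa_ex <- names(exchange_metabolites(m2))
  aa_base <- base_metabolite_id(exchange_metabolites(m2),
                                names(m2$compartments))
  aa_ex <- aa_ex[aa_base %in% names(AA_MOLAR_MASS)]
  m2 <- set_bounds(m2, aa_ex, lower = 0)
  supp_ex <- paste0("EX_", supplemented, "_e")
  if (length(supplemented)) m2 <- set_bounds(m2, supp_ex, lower = -1000)
  for (ex in intersect(c("EX_glc_e", "EX_o2_e", "EX_pi_e", "EX_chol_e"),
                       names(m2$reactions)))
    m2 <- set_bounds(m2, ex, lower = -1e6)
  m2 <- set_bounds(m2, "BIOMASS", lower = fixed_growth,
                   upper = fixed_growth)
  m2
}

## mass-minimization objective: feed flux is already in g per unit; each
## supplemented exchange contributes -M/1000 * v (v <= 0 on import)
feed_mass_objective <- function(supplemented, penalty_factor = 1) {
  obj <- c(FEED = 1)
  if (length(supplemented)) {
    pen <- -penalty_factor * AA_MOLAR_MASS[supplemented] / 1000
    obj <- c(obj, stats::setNames(as.numeric(pen),
                                  paste0("EX_", supplemented, "_e")))
  }
  obj
}

#' Identify the growth-limiting amino acid in a feed
#'
#' With growth fixed and total consumed mass minimized, multiplies each
#' amino-acid exchange reaction's reduced cost by the amino acid's molar
#' mass and returns the amino acid with the largest negative mass-weighted
#' value (the one whose import would reduce consumed mass the most). Ties
#' are broken lexicographically.
#'
#' @param model a \code{metabolic_model}.
#' @param feed_reaction feed reaction from \code{\link{build_feed_reaction}}.
#' @param fixed_growth growth rate to fix (default 1; arbitrary, as only
#'   relative quantities matter).
#' @param supplemented amino acids already supplemented (their import is
#'   open and mass-penalized in the objective).
#' @param penalty_factor multiplier on the supplement mass penalty
#'   (default 1 = cost parity with feed mass).
#' @return list with \code{amino_acid} (id or NA when none is limiting),
#'   \code{scores} (mass-weighted limiting values, negative = limiting),
#'   \code{solution} (the minimization \code{flux_solution}).
#' @export
limiting_amino_acid <- function(model, feed_reaction, fixed_growth = 1,
                                supplemented = character(),
                                penalty_factor = 1) {
  m2 <- feed_limitation_setup(model, feed_reaction, fixed_growth,
                              supplemented)
  obj <- feed_mass_objective(supplemented, penalty_factor)
  sol <- fba(m2, objective = obj, sense = "min")
  if (sol$status != "optimal")
    stop("feed minimization LP not optimal: ", sol$status)
  ## candidates: amino acids in the model whose import is currently closed
  base <- base_metabolite_id(exchange_metabolites(m2),
                             names(m2$compartments))
  cand_ex <- names(base)[base %in% names(AA_MOLAR_MASS) &
                           !(base %in% supplemented)]
  rc <- sol$reduced_costs[cand_ex]
  ## reduced cost > 0 at the zero import bound means allowing import would
  ## lower consumed mass; the mass-weighted limiting value is its negative
  scores <- stats::setNames(-AA_MOLAR_MASS[base[cand_ex]] * rc, cand_ex)
  limiting <- scores[scores < -VALIDATION_TOL]
  if (length(limiting) == 0)
    return(list(amino_acid = NA_character_, scores = scores,
                solution = sol))
  ## degeneracy guard: a reduced cost at a degenerate vertex can point
  ## along a blocked direction, so confirm each candidate (best first) by
  ## a small unpenalized import and require a real consumed-mass saving
  aa <- base[names(limiting)]
  ord <- order(limiting, aa)
  delta <- 1e-3
  for (k in ord) {
    ex <- names(limiting)[k]
    chk <- fba(set_bounds(m2, ex, lower = -delta), objective = obj,
               sense = "min")
    if (chk$status == "optimal" &&
        sol$objective_value - chk$objective_value >
          1e-8 * max(1, abs(sol$objective_value)))
      return(list(amino_acid = unname(aa[k]), scores = scores,
                  solution = sol))
  }
  list(amino_acid = NA_character_, scores = scores, solution = sol)
}

#' Feed efficiency of a solution
#'
#' Efficiency is fixed growth divided by the total consumed mass flux
#' (feed plus any imported supplement mass); the inverse (mg consumed per
#' gDW produced) is reported as well.
#'
#' @param solution a \code{flux_solution} from the feed minimization.
#' @param fixed_growth the fixed growth rate.
#' @return named numeric: \code{gdw_per_g} and \code{mg_per_gdw}.
#' @export
feed_efficiency <- function(solution, fixed_growth) {
  v <- solution$fluxes
  feed_mass <- if ("FEED" %in% names(v)) v[["FEED"]] else 0
  aa_ex <- grep("^EX_", names(v), value = TRUE)
  base <- sub("^EX_", "", sub("_e$", "", aa_ex))
  aa_ex <- aa_ex[base %in% names(AA_MOLAR_MASS)]
  imp <- pmin(v[aa_ex], 0)
  supp_mass <- sum(-imp * AA_MOLAR_MASS[sub("^EX_", "",
                                            sub("_e$", "", aa_ex))] / 1000)
  total <- feed_mass + supp_mass
  c(gdw_per_g = fixed_growth / total,
    mg_per_gdw = 1000 * total / fixed_growth)
}

#' Iteratively supplement the most limiting amino acid
#'
#' Repeats limiting-amino-acid identification, opens the limiting amino
#' acid's exchange for import with a mass penalty in the objective, and
#' re-solves, until no amino acid is limiting. Feed efficiency is recorded
#' at baseline and after each supplementation step.
#'
#' @param model a \code{metabolic_model}.
#' @param feed a \code{\link{feed_composition}}.
#' @param fixed_growth growth rate to fix (default 1).
#' @param penalty_factor supplement mass penalty multiplier (default 1).
#' @return object of class \code{supplementation_trace}: list with
#'   \code{feed}, \code{baseline_efficiency} (gdw_per_g),
#'   \code{steps} (data.frame step, amino_acid, efficiency_gdw_per_g,
#'   efficiency_mg_per_gdw).
#' @export
supplement_iteratively <- function(model, feed, fixed_growth = 1,
                                   penalty_factor = 1) {
  fr <- build_feed_reaction(feed)
  supplemented <- character()
  base_res <- limiting_amino_acid(model, fr, fixed_growth, supplemented,
                                  penalty_factor)
  eff <- feed_efficiency(base_res$solution, fixed_growth)
  steps <- data.frame(step = integer(), amino_acid = character(),
                      efficiency_gdw_per_g = numeric(),
                      efficiency_mg_per_gdw = numeric())
  res <- base_res
  max_iter <- length(AA_MOLAR_MASS)
  it <- 0
  while (!is.na(res$amino_acid)) {
    it <- it + 1
    if (it > max_iter)
      stop("supplementation did not terminate within ", max_iter,
           " iterations")
    supplemented <- c(supplemented, res$amino_acid)
    res <- limiting_amino_acid(model, fr, fixed_growth, supplemented,
                               penalty_factor)
    e <- feed_efficiency(res$solution, fixed_growth)
    steps <- rbind(steps, data.frame(
      step = it, amino_acid = supplemented[it],
      efficiency_gdw_per_g = e[["gdw_per_g"]],
      efficiency_mg_per_gdw = e[["mg_per_gdw"]]))
  }
  structure(list(feed = feed$name,
                 baseline_efficiency = eff[["gdw_per_g"]],
                 steps = steps),
            class = "supplementation_trace")
}

#' @export
print.supplementation_trace <- function(x, ...) {
  cat("<supplementation_trace>", x$feed, "\n")
  cat(sprintf("  baseline efficiency: %.4f gDW/g\n",
              x$baseline_efficiency))
  if (nrow(x$steps)) {
    for (i in seq_len(nrow(x$steps)))
      cat(sprintf("  step %d: + %s -> %.4f gDW/g\n", x$steps$step[i],
                  x$steps$amino_acid[i],
                  x$steps$efficiency_gdw_per_g[i]))
  } else cat("  no limiting amino acids\n")
  invisible(x)
}
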