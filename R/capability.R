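## Metabolic capability screening: amino-acid essentiality, metabolic tasks,
## and enumeration of minimal growth-supporting uptake/secretion sets.

GROWTH_ZERO_THRESHOLD <- 1e-6  # growth-rate cutoff for "no growth"

#' Nutrient essentiality screen
#'
#' With all listed nutrients open, disables uptake of each one separately
#' and maximizes growth by FBA. A nutrient is essential iff growth falls to
#' (numerically) zero when its uptake alone is disabled.
#'
#' @param model a \code{metabolic_model}; baseline growth with all
#'   nutrients open must be positive.
#' @param nutrients character vector of exchange reaction ids to screen;
#'   defaults to all amino-acid exchanges found in the model.
#' @param threshold growth below this counts as zero (default 1e-6).
#' @return named character vector, nutrient -> "essential"/"non_essential".
#' @export
essentiality_screen <- function(model, nutrients = NULL,
                                threshold = GROWTH_ZERO_THRESHOLD) {
  if (is.null(nutrients)) {
    exm <- exchange_metabolites(model)
    base <- base_metabolite_id(exm, names(model$compartments))
    nutrients <- names(exm)[base %in% c(ESSENTIAL_AA, NONESSENTIAL_AA)]
  }
  missing_n <- setdiff(nutrients, names(model$reactions))
  if (length(missing_n)) stop("unknown exchange reaction: ", missing_n[1])
  base_sol <- fba(model)
  if (base_sol$status != "optimal" ||
      base_sol$objective_value <= threshold)
    stop("essentiality screen undefined: baseline growth is zero")
  out <- vapply(nutrients, function(ex) {
    sol <- fba(set_bounds(model, ex, lower = 0))
    if (sol$status != "optimal" || sol$objective_value <= threshold)
      "essential" else "non_essential"
  }, "")
  out
}

#' Read metabolic task definitions
#'
#' Tab-separated file with columns \code{id}, \code{system},
#' \code{expected} ("feasible"/"infeasible"), \code{uptakes} and
#' \code{secretions} (semicolon-separated \code{metabolite:rate} entries;
#' empty allowed).
#'
#' @param path TSV file path.
#' @return list of task lists.
#' @export
read_tasks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "system", "expected", "uptakes", "secretions")
  if (!all(need %in% names(df)))
    stop("task file must have columns: ", paste(need, collapse = ", "))
  parse_side <- function(s) {
    if (is.na(s) || !nzchar(s)) return(data.frame(metabolite = character(),
                                                  rate = numeric()))
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    data.frame(metabolite = vapply(parts, `[[`, "", 1),
               rate = as.numeric(vapply(parts, `[[`, "", 2)))
  }
  lapply(seq_len(nrow(df)), function(i) {
    list(id = df$id[i], system = df$system[i], expected = df$expected[i],
         required_uptakes = parse_side(df$uptakes[i]),
         required_secretions = parse_side(df$secretions[i]))
  })
}

## find a model metabolite for a task metabolite id; unknown compartments
## are remapped to the cytosol, bare ids resolve extracellular first
map_task_metabolite <- function(model, met_id) {
  ids <- model$metabolites$id
  if (met_id %in% ids) return(met_id)
  base <- base_metabolite_id(met_id, names(model$compartments))
  stripped <- sub("_[a-z0-9]+$", "", met_id)  # foreign compartment suffix
  for (cand_base in unique(c(base, stripped, met_id))) {
    for (cmp in c("e", "c", names(model$compartments))) {
      cand <- paste0(cand_base, "_", cmp)
      if (cand %in% ids) return(cand)
    }
  }
  NA_character_
}

#' Evaluate one metabolic task
#'
#' Closes all regular exchange reactions, opens the task's required uptakes
#' and secretions (adding temporary boundary reactions for metabolites that
#' lack one; metabolites from compartments absent from the model are
#' remapped to the cytosol), and tests feasibility of a steady-state flux.
#' The task passes iff feasibility matches its expectation.
#'
#' @param model a \code{metabolic_model}.
#' @param task a task list (see \code{\link{read_tasks}}).
#' @return list with \code{pass} (logical), \code{observed}
#'   ("feasible"/"infeasible"/"unmappable"), \code{expected}, \code{reason}.
#' @export
evaluate_task <- function(model, task) {
  ups <- task$required_uptakes; secs <- task$required_secretions
  all_mets <- c(ups$metabolite, secs$metabolite)
  mapped <- vapply(all_mets, function(mm) map_task_metabolite(model, mm), "")
  if (anyNA(mapped)) {
    return(list(pass = identical(task$expected, "infeasible") && FALSE,
                observed = "unmappable", expected = task$expected,
                reason = paste0("unmappable: ",
                                all_mets[which(is.na(mapped))[1]])))
  }
  ## close every exchange
  ex <- reaction_ids(model, "exchange")
  m2 <- set_bounds(model, ex, lower = 0, upper = 0)
  open_boundary <- function(m2, met, lb, ub) {
    ## reuse an existing exchange if the metabolite has one, else add a
    ## temporary boundary reaction
    for (ex_id in ex) {
      if (identical(names(m2$reactions[[ex_id]]$stoichiometry), met))
        return(set_bounds(m2, ex_id, lower = lb, upper = ub))
    }
    rid <- paste0("TASK_BND_", met)
    m2$reactions[[rid]] <- list(id = rid, name = rid,
                                stoichiometry = stats::setNames(-1, met),
                                lower_bound = lb, upper_bound = ub,
                                gpr = "", kind = "sink_demand")
    m2
  }
  for (i in seq_len(nrow(ups))) {
    met <- mapped[[ups$metabolite[i]]]
    m2 <- open_boundary(m2, met, lb = -abs(ups$rate[i]), ub = 0)
  }
  for (i in seq_len(nrow(secs))) {
    met <- mapped[[secs$metabolite[i]]]
    m2 <- open_boundary(m2, met, lb = abs(secs$rate[i]), ub = 1e6)
  }
  parts <- model_lp_parts(m2)
  res <- lp_solve(rep(0, length(parts$rxns)), parts$S,
                  rep(0, nrow(parts$S)), rep("=", nrow(parts$S)),
                  parts$lb, parts$ub)
  observed <- if (res$status == "optimal") "feasible" else "infeasible"
  list(pass = identical(observed, task$expected),
       observed = observed, expected = task$expected, reason = "")
}

#' Evaluate a list of tasks
#' @param model a \code{metabolic_model}.
#' @param tasks list of tasks from \code{\link{read_tasks}}.
#' @return data.frame (id, system, expected, observed, pass).
#' @export
evaluate_tasks <- function(model, tasks) {
  rows <- lapply(tasks, function(tk) {
    r <- evaluate_task(model, tk)
    data.frame(id = tk$id, system = tk$system, expected = r$expected,
               observed = r$observed, pass = r$pass)
  })
  do.call(rbind, rows)
}

#' Define a minimal-set enumeration problem
#'
#' @param forced_uptakes base metabolite ids whose uptake is required.
#' @param forced_secretions base metabolite ids whose secretion is required.
#' @param alternatives list of base-metabolite-id sets; at least one member
#'   of each set must be secreted.
#' @param min_growth required growth rate (> 0).
#' @param secretion_min_rate minimum flux for a required secretion
#'   (default 1e-3).
#' @return a \code{minimal_set_problem} list.
#' @export
minimal_set_problem <- function(forced_uptakes = character(),
                                forced_secretions = character(),
                                alternatives = list(),
                                min_growth = 1,
                                secretion_min_rate = 1e-3) {
  if (min_growth <= 0) stop("min_growth must be > 0")
  structure(list(forced_uptakes = forced_uptakes,
                 forced_secretions = forced_secretions,
                 alternatives = alternatives,
                 min_growth = min_growth,
                 secretion_min_rate = secretion_min_rate),
            class = "minimal_set_problem")
}

## map base metabolite ids to their exchange reaction ids
exchange_of_base <- function(model) {
  exm <- exchange_metabolites(model)
  stats::setNames(names(exm),
                  base_metabolite_id(exm, names(model$compartments)))
}

## Build and solve the indicator MILP for uptake or secretion enumeration.
## role = "uptake": candidate j active means exchange flux may go below 0
## (v_j >= -U z_j). role = "secretion": v_j <= U z_j.
enumerate_minimal_sets <- function(model, problem, role, allowed_uptakes,
                                   max_sets) {
  U <- 1000
  eps <- problem$secretion_min_rate
  ex_of <- exchange_of_base(model)
  check_known <- function(x) {
    bad <- setdiff(x, names(ex_of))
    if (length(bad)) stop("no exchange reaction for metabolite: ", bad[1])
  }
  check_known(problem$forced_uptakes)
  check_known(problem$forced_secretions)
  check_known(unlist(problem$alternatives))

  ## base exchange configuration; a user-blocked direction (bound pinned at
  ## 0 in the input model) is never re-opened
  m2 <- model
  all_ex <- unname(ex_of)
  cur <- reaction_bounds(model)
  cur_lb <- stats::setNames(cur$lower_bound, cur$reaction)
  cur_ub <- stats::setNames(cur$upper_bound, cur$reaction)
  open_up <- function(mm, ids) set_bounds(mm, ids,
                                          lower = ifelse(cur_lb[ids] < 0,
                                                         -U, 0))
  if (role == "uptake") {
    ## secretion side open everywhere; uptake only through forced or
    ## candidate (gated) exchanges
    m2 <- set_bounds(m2, all_ex, lower = 0,
                     upper = ifelse(cur_ub[all_ex] > 0, U, 0))
    m2 <- open_up(m2, ex_of[problem$forced_uptakes])
    candidates <- setdiff(names(ex_of), problem$forced_uptakes)
  } else {
    check_known(allowed_uptakes)
    m2 <- set_bounds(m2, all_ex, lower = 0,
                     upper = ifelse(cur_ub[all_ex] > 0, U, 0))
    m2 <- open_up(m2, ex_of[allowed_uptakes])
    ## every secretion is a candidate; forced ones are pre-selected
    candidates <- names(ex_of)
  }
  cand_ex <- ex_of[candidates]
  if (role == "uptake") {
    ## candidate uptake gated by z; allow lb down to -U, gate via rows
    m2 <- open_up(m2, cand_ex)
  }
  parts <- model_lp_parts(m2)
  n <- length(parts$rxns)
  k <- length(cand_ex)
  rxn_pos <- stats::setNames(seq_len(n), parts$rxns)

  ## columns: fluxes then indicators
  nv <- n + k
  rows <- list(); rhs <- c(); dir <- c()
  Srow <- cbind(parts$S, matrix(0, nrow(parts$S), k))
  ## growth requirement
  grow <- numeric(nv)
  grow[rxn_pos[names(model$objective)]] <- model$objective
  rows_extra <- list(list(coefs = grow, dir = ">=",
                          rhs = problem$min_growth))
  ## coupling rows
  for (j in seq_len(k)) {
    cf <- numeric(nv)
    cf[rxn_pos[[cand_ex[j]]]] <- 1
    cf[n + j] <- if (role == "uptake") U else -U
    rows_extra <- c(rows_extra,
                    list(list(coefs = cf,
                              dir = if (role == "uptake") ">=" else "<=",
                              rhs = 0)))
  }
  ## forced secretions must carry flux
  for (b in problem$forced_secretions) {
    cf <- numeric(nv)
    cf[rxn_pos[[ex_of[[b]]]]] <- 1
    rows_extra <- c(rows_extra, list(list(coefs = cf, dir = ">=",
                                          rhs = eps)))
  }
  ## each alternative group: combined secretion above threshold
  for (grp in problem$alternatives) {
    cf <- numeric(nv)
    cf[rxn_pos[ex_of[grp]]] <- 1
    rows_extra <- c(rows_extra, list(list(coefs = cf, dir = ">=",
                                          rhs = eps)))
  }
  A0 <- rbind(Srow, do.call(rbind, lapply(rows_extra, `[[`, "coefs")))
  rhs0 <- c(rep(0, nrow(Srow)), vapply(rows_extra, `[[`, 0, "rhs"))
  dir0 <- c(rep("=", nrow(Srow)), vapply(rows_extra, `[[`, "", "dir"))
  lb0 <- c(parts$lb, rep(0, k))
  ub0 <- c(parts$ub, rep(1, k))
  obj <- c(numeric(n), rep(1, k))

  ## pre-selected indicators for forced secretions in the secretion role
  fixed_one <- integer(0)
  if (role == "secretion") {
    fixed_one <- n + match(problem$forced_secretions, candidates)
    lb0[fixed_one] <- 1
  }

  zcols <- n + seq_len(k)
  cuts_A <- NULL; cuts_rhs <- c()
  found <- list()
  infeasible_flag <- FALSE

  feasible_with <- function(active_bases) {
    ## plain LP feasibility with exactly these candidates active
    lb <- lb0[seq_len(n)]; ub <- ub0[seq_len(n)]
    off <- setdiff(candidates, active_bases)
    if (role == "uptake") {
      lb[rxn_pos[ex_of[off]]] <- pmax(lb[rxn_pos[ex_of[off]]], 0)
    } else {
      ub[rxn_pos[ex_of[off]]] <- pmin(ub[rxn_pos[ex_of[off]]], 0)
    }
    A <- A0[, seq_len(n), drop = FALSE]
    keep <- seq_len(nrow(Srow) + length(rows_extra))
    ## drop coupling rows (they involve z); re-derive from bounds above
    coupl <- nrow(Srow) + 1 + seq_len(k)
    keep <- setdiff(keep, coupl)
    res <- lp_solve(numeric(n), A[keep, , drop = FALSE], rhs0[keep],
                    dir0[keep], lb, ub)
    res$status == "optimal"
  }

  while (length(found) < max_sets) {
    sol <- milp_branch_and_bound(obj, rbind(A0, cuts_A),
                                 c(rhs0, cuts_rhs),
                                 c(dir0, rep("<=", length(cuts_rhs))),
                                 lb0, ub0, int_cols = zcols)
    if (sol$status != "optimal") {
      if (length(found) == 0) infeasible_flag <- TRUE
      break
    }
    active <- candidates[sol$x[zcols] > 0.5]
    ## support-minimality pruning: drop members whose removal stays feasible
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (b in setdiff(active, problem$forced_secretions)) {
        if (feasible_with(setdiff(active, b))) {
          active <- setdiff(active, b); changed <- TRUE; break
        }
      }
    }
    set_members <- sort(unique(c(
      if (role == "uptake") problem$forced_uptakes else character(),
      active)))
    if (!any(vapply(found, identical, TRUE, y = set_members)))
      found <- c(found, list(set_members))
    ## exclusion cut: no superset of the active candidates again
    act_idx <- n + match(intersect(active, candidates), candidates)
    cut <- numeric(nv); cut[act_idx] <- 1
    cuts_A <- rbind(cuts_A, cut)
    cuts_rhs <- c(cuts_rhs, length(act_idx) - 1)
  }
  attr(found, "infeasible") <- infeasible_flag
  found
}

#' Enumerate minimal growth-supporting uptake sets
#'
#' Finds support-minimal sets of exchange metabolites whose uptake supports
#' the required growth, given forced uptakes and secretion requirements.
#' Enumeration uses an indicator-variable MILP (minimize active uptakes,
#' branch and bound) with exclusion cuts, followed by an explicit
#' support-minimality check of each set.
#'
#' @param model a \code{metabolic_model}.
#' @param problem a \code{\link{minimal_set_problem}}.
#' @param max_sets enumeration cap (default 10).
#' @return list of sorted base-metabolite-id sets (each includes the forced
#'   uptakes); attribute \code{infeasible} is TRUE when no set exists.
#' @export
minimal_uptake_sets <- function(model, problem, max_sets = 10) {
  enumerate_minimal_sets(model, problem, "uptake",
                         allowed_uptakes = NULL, max_sets = max_sets)
}

#' Enumerate minimal growth-supporting secretion sets
#'
#' As \code{\link{minimal_uptake_sets}} with roles swapped: uptake is
#' allowed for \code{allowed_uptakes} (typically the union of metabolites
#' found in uptake sets) and minimal sets of active secretions are
#' enumerated.
#'
#' @param model a \code{metabolic_model}.
#' @param problem a \code{\link{minimal_set_problem}}.
#' @param allowed_uptakes base metabolite ids whose uptake is allowed.
#' @param max_sets enumeration cap (default 10).
#' @return list of sorted base-metabolite-id sets.
#' @export
minimal_secretion_sets <- function(model, problem, allowed_uptakes,
                                   max_sets = 10) {
  enumerate_minimal_sets(model, problem, "secretion",
                         allowed_uptakes = allowed_uptakes,
                         max_sets = max_sets)
}

## Depth-first branch and bound over selected integer columns of an LP.
milp_branch_and_bound <- function(obj, A, rhs, dir, lb, ub, int_cols,
                                  int_tol = 1e-6) {
  best <- list(objective = Inf, x = NULL)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > 5000L) break
    rel <- lp_solve(obj, A, rhs, dir, node$lb, node$ub)
    if (rel$status != "optimal") next
    if (rel$objective >= best$objective - 1e-9) next
    zf <- rel$x[int_cols]
    frac <- abs(zf - round(zf))
    if (all(frac <= int_tol)) {
      best <- list(objective = rel$objective, x = rel$x)
      next
    }
    j <- int_cols[which.max(frac)]
    dn <- node; dn$ub[j] <- floor(rel$x[j])
    up <- node; up$lb[j] <- ceiling(rel$x[j])
    ## explore the rounded-up branch first (tends to find feasible fast)
    stack <- c(stack, list(dn), list(up))
  }
  if (is.null(best$x)) list(status = "infeasible")
  else list(status = "optimal", objective = best$objective, x = best$x)
}
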