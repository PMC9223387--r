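## FBA core: model -> LP assembly, flux balance analysis, parsimonious FBA
## (exact L1 minimization via split variables), and the oxygen reference
## point (mu_max, r_max) used by the oxygen-limited growth sweep.

LP_TOL <- 1e-9        # solver feasibility/optimality tolerance
VALIDATION_TOL <- 1e-6  # mass-balance / bound validation tolerance

model_lp_parts <- function(model) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  list(S = S, lb = lb, ub = ub, rxns = colnames(S))
}

new_flux_solution <- function(objective_value, fluxes, reduced_costs,
                              status, tolerance = LP_TOL, duals = NULL) {
  structure(list(objective_value = objective_value, fluxes = fluxes,
                 reduced_costs = reduced_costs, status = status,
                 tolerance = tolerance, duals = duals),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective_value, digits = 8), "\n")
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear flux objective subject to steady state
#' \eqn{S v = 0} and the model's flux bounds. Reduced costs are reported for
#' every reaction as the derivative of the optimal objective with respect to
#' the reaction's flux at its active bound, in the stated optimization
#' sense.
#'
#' @param model a \code{metabolic_model}.
#' @param objective named numeric reaction -> weight; defaults to the
#'   model's objective.
#' @param sense "max" or "min".
#' @param extra_rows optional list of extra linear constraints, each a list
#'   with \code{coefs} (named numeric over reaction ids), \code{dir}
#'   ("=", "<=", ">="), and \code{rhs}.
#' @return a \code{flux_solution}.
#' @export
fba <- function(model, objective = model$objective,
                sense = c("max", "min"), extra_rows = NULL) {
  sense <- match.arg(sense)
  if (length(objective) == 0) stop("objective must be nonempty")
  missing_obj <- setdiff(names(objective), names(model$reactions))
  if (length(missing_obj)) stop("objective reaction not in model: ",
                                missing_obj[1])
  parts <- model_lp_parts(model)
  n <- length(parts$rxns)
  obj <- stats::setNames(numeric(n), parts$rxns)
  obj[names(objective)] <- objective
  A <- parts$S
  rhs <- rep(0, nrow(A))
  dir <- rep("=", nrow(A))
  if (!is.null(extra_rows)) {
    for (row in extra_rows) {
      cf <- stats::setNames(numeric(n), parts$rxns)
      cf[names(row$coefs)] <- row$coefs
      A <- rbind(A, cf)
      rhs <- c(rhs, row$rhs)
      dir <- c(dir, row$dir)
    }
  }
  res <- lp_solve(obj, A, rhs, dir, parts$lb, parts$ub,
                  maximize = (sense == "max"), tol = LP_TOL)
  new_flux_solution(objective_value = res$objective,
                    fluxes = res$x,
                    reduced_costs = res$reduced_costs,
                    status = res$status,
                    duals = res$duals)
}

#' Parsimonious FBA
#'
#' Fixes the growth objective at \code{growth_fraction} of its FBA optimum
#' and minimizes total absolute flux \eqn{\sum |v|} exactly, by splitting
#' every flux into forward and reverse non-negative parts and solving a
#' second LP.
#'
#' @param model a \code{metabolic_model}.
#' @param growth_fraction fraction of the FBA optimum to fix (default 1).
#' @param objective named numeric reaction -> weight; defaults to the
#'   model's objective.
#' @return a \code{flux_solution}; \code{objective_value} is the achieved
#'   growth, with the minimized total absolute flux in \code{sum_abs_flux}
#'   and the first-stage reduced costs retained.
#' @export
pfba <- function(model, growth_fraction = 1, objective = model$objective) {
  if (growth_fraction <= 0 || growth_fraction > 1)
    stop("growth_fraction must be in (0, 1]")
  stage1 <- fba(model, objective, "max")
  if (stage1$status != "optimal")
    return(new_flux_solution(NA_real_, stage1$fluxes, stage1$reduced_costs,
                             stage1$status))
  target <- growth_fraction * stage1$objective_value
  parts <- model_lp_parts(model)
  n <- length(parts$rxns)
  ## split v = v_plus - v_minus with bounds preserving [lb, ub]
  lb_p <- pmax(0, parts$lb); ub_p <- pmax(0, parts$ub)
  lb_m <- pmax(0, -parts$ub); ub_m <- pmax(0, -parts$lb)
  A <- cbind(parts$S, -parts$S)
  colnames(A) <- c(paste0(parts$rxns, "..f"), paste0(parts$rxns, "..r"))
  cf <- stats::setNames(numeric(n), parts$rxns)
  cf[names(objective)] <- objective
  A <- rbind(A, c(cf, -cf))
  rhs <- c(rep(0, nrow(parts$S)), target)
  dir <- rep("=", length(rhs))
  res <- lp_solve(rep(1, 2 * n), A, rhs, dir,
                  c(lb_p, lb_m), c(ub_p, ub_m),
                  maximize = FALSE, tol = LP_TOL)
  if (res$status != "optimal")
    return(new_flux_solution(NA_real_,
                             stats::setNames(rep(NA_real_, n), parts$rxns),
                             stage1$reduced_costs, "infeasible"))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- parts$rxns
  out <- new_flux_solution(objective_value = sum(cf * v),
                           fluxes = v,
                           reduced_costs = stage1$reduced_costs,
                           status = "optimal")
  out$sum_abs_flux <- res$objective
  out
}

#' Oxygen reference point
#'
#' Computes \code{mu_max}, the maximal growth rate with unconstrained
#' oxygen import, and \code{r_max}, the minimal oxygen uptake rate that
#' still supports that maximal growth.
#'
#' @param model a \code{metabolic_model}.
#' @param o2_exchange id of the oxygen exchange reaction
#'   (default "EX_o2_e").
#' @return list with \code{mu_max}, \code{r_max}, and \code{warning_flag}
#'   (TRUE when growth is zero and r_max is defined as 0).
#' @export
oxygen_reference <- function(model, o2_exchange = "EX_o2_e") {
  if (!o2_exchange %in% names(model$reactions))
    stop("no such exchange reaction: ", o2_exchange)
  m2 <- set_bounds(model, o2_exchange, lower = -1e6)
  s1 <- fba(m2)
  if (s1$status != "optimal")
    stop("oxygen_reference: growth FBA not optimal (", s1$status, ")")
  mu_max <- s1$objective_value
  if (mu_max <= VALIDATION_TOL)
    return(list(mu_max = mu_max, r_max = 0, warning_flag = TRUE))
  ## minimize oxygen import magnitude (= maximize the signed flux) at
  ## maximal growth
  grow <- list(coefs = model$objective, dir = ">=",
               rhs = mu_max * (1 - 1e-9))
  s2 <- fba(m2, objective = stats::setNames(1, o2_exchange), sense = "max",
            extra_rows = list(grow))
  if (s2$status != "optimal")
    stop("oxygen_reference: second-stage LP not optimal (", s2$status, ")")
  list(mu_max = mu_max, r_max = max(0, -s2$objective_value),
       warning_flag = FALSE)
}

#' Maximal steady-state mass-balance residual of a solution
#'
#' @param model a \code{metabolic_model}.
#' @param solution a \code{flux_solution}.
#' @return max |S v|.
#' @export
mass_balance_residual <- function(model, solution) {
  S <- stoichiometric_matrix(model)
  max(abs(S %*% solution$fluxes[colnames(S)]))
}
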