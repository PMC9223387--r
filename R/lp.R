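#' Solve a bounded-variable linear program
#'
#' Exact two-phase primal simplex for problems of the form
#' optimize \eqn{c'x} subject to \eqn{A x \{=,\le,\ge\} b} and
#' \eqn{l \le x \le u}. Returns primal values, row duals and per-variable
#' reduced costs, which downstream flux-balance routines use for
#' sensitivity-based nutrient ranking.
#'
#' Reduced costs follow the convention \eqn{d_j = \partial z / \partial x_j}
#' in the *stated* optimization sense: for a maximization the reported
#' \code{reduced_costs} are the derivatives of the maximal objective with
#' respect to moving \eqn{x_j} off its active bound.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense numeric.
#' @param rhs right-hand sides (length m).
#' @param dir character vector of row senses, each one of "=", "<=", ">=".
#' @param lb,ub variable bounds; \code{-Inf}/\code{Inf} allowed.
#' @param maximize logical; default \code{FALSE} (minimize).
#' @param tol numerical tolerance for pivoting/optimality (default 1e-9).
#' @return list with \code{status} ("optimal", "infeasible", "unbounded"),
#'   \code{objective}, \code{x}, \code{duals} (per row), \code{reduced_costs}
#'   (per variable), \code{iterations}, \code{tol}.
#' @export
lp_solve <- function(obj, A, rhs, dir = rep("=", length(rhs)),
                     lb = rep(0, length(obj)), ub = rep(Inf, length(obj)),
                     maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(dir) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) stop("lp_solve: lower bound exceeds upper bound")
  vnames <- colnames(A)
  if (is.null(vnames)) vnames <- paste0("x", seq_len(n))

  ## convert inequality rows to equalities with slack variables
  n_slack <- sum(dir != "=")
  if (n_slack > 0) {
    Sl <- matrix(0, m, n_slack)
    k <- 0
    slb <- sub <- numeric(n_slack)
    for (i in seq_len(m)) {
      if (dir[i] == "=") next
      k <- k + 1
      Sl[i, k] <- if (dir[i] == "<=") 1 else -1
      slb[k] <- 0; sub[k] <- Inf
    }
    A <- cbind(A, Sl)
    obj <- c(obj, rep(0, n_slack))
    lb <- c(lb, slb); ub <- c(ub, sub)
  }
  ntot <- ncol(A)

  cmin <- if (maximize) -obj else obj
  res <- simplex_bounded(cmin, A, rhs, lb, ub, tol)

  out <- list(status = res$status, iterations = res$iterations, tol = tol)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    names(x) <- vnames
    y <- res$y
    d <- res$d[seq_len(n)]
    names(d) <- vnames
    if (maximize) { y <- -y; d <- -d }
    out$objective <- sum(obj[seq_len(n)] * x)
    out$x <- x
    out$duals <- y
    out$reduced_costs <- d
  } else {
    out$objective <- NA_real_
    out$x <- rep(NA_real_, n)
    out$duals <- rep(NA_real_, m)
    out$reduced_costs <- rep(NA_real_, n)
  }
  out
}

## Two-phase bounded-variable revised simplex (dense, minimization).
## Nonbasic variables rest at a finite bound (or at 0 if free); artificial
## variables give the initial basis. Dantzig pricing with a Bland fallback
## guards against cycling on the degenerate vertices that pFBA's split
## formulation produces.
simplex_bounded <- function(cmin, A, b, lb, ub, tol) {
  m <- nrow(A); n <- ncol(A)

  ## initial nonbasic point: finite bound nearest zero, 0 for free vars
  x <- numeric(n)
  at_upper <- logical(n)
  for (j in seq_len(n)) {
    lo <- lb[j]; hi <- ub[j]
    if (is.finite(lo) && is.finite(hi)) {
      if (abs(lo) <= abs(hi)) x[j] <- lo else { x[j] <- hi; at_upper[j] <- TRUE }
    } else if (is.finite(lo)) x[j] <- lo
    else if (is.finite(hi)) { x[j] <- hi; at_upper[j] <- TRUE }
    else x[j] <- 0
  }

  r <- b - as.vector(A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sg, m))
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  at_upper <- c(at_upper, rep(FALSE, m))
  basis <- n + seq_len(m)
  is_basic <- rep(FALSE, n + m); is_basic[basis] <- TRUE

  phase1 <- c(rep(0, n), rep(1, m))
  it_total <- 0

  run_phase <- function(cost, xe, basis, is_basic, at_upper, lbe, ube, phase) {
    nall <- length(cost)
    max_iter <- 200L * (nall + m) + 2000L
    bland_after <- 20L * (nall + m) + 500L
    it <- 0L
    ## recompute basic values exactly from the current basis, shedding the
    ## drift that incremental tableau updates accumulate
    refresh <- function() {
      xnb <- xe
      xnb[basis] <- 0
      rhs_b <- b - as.vector(Aext %*% xnb)
      xe[basis] <<- as.vector(solve(Aext[, basis, drop = FALSE], rhs_b))
    }
    repeat {
      it <- it + 1L
      ## always work from exactly recomputed basic values, so ratio-test
      ## decisions cannot be corrupted by accumulated update drift
      tryCatch(refresh(), error = function(e) NULL)
      if (it > max_iter) return(list(status = "iteration_limit", xe = xe,
                                     basis = basis, is_basic = is_basic,
                                     at_upper = at_upper, it = it, y = NULL))
      B <- Aext[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular", xe = xe, basis = basis,
                                  is_basic = is_basic, at_upper = at_upper,
                                  it = it, y = NULL))
      d <- cost - as.vector(crossprod(Aext, y))
      ## entering candidates (minimization), vectorized
      free_mask <- !is.finite(lbe) & !is.finite(ube)
      cand <- !is_basic & (lbe < ube)
      can_inc <- cand & (free_mask | !at_upper) & (d < -tol)
      can_dec <- cand & (free_mask | at_upper) & (d > tol)
      viol <- can_inc | can_dec
      if (!any(viol)) {
        tryCatch(refresh(), error = function(e) NULL)
        return(list(status = "optimal", xe = xe, basis = basis,
                    is_basic = is_basic, at_upper = at_upper, it = it,
                    y = y, d = d))
      }
      idx <- which(viol)
      q <- if (it > bland_after) idx[1L] else idx[which.max(abs(d[idx]))]
      sg_q <- if (can_inc[q]) 1L else -1L

      w <- as.vector(solve(B, Aext[, q]))
      ## ratio test: basic values change by chg * t as entering moves by
      ## sg_q*t; the exclusion threshold sits just above solve() noise so
      ## that large steps cannot push small-|chg| basics out of bounds
      chg <- -sg_q * w
      ## zero out solve() noise so it cannot be amplified by large steps
      chg[abs(chg) < 1e-11] <- 0
      tvals <- rep(Inf, m); to_up <- logical(m)
      bvals <- xe[basis]
      dec <- chg < -1e-11; inc <- chg > 1e-11
      tvals[dec] <- (bvals[dec] - lbe[basis[dec]]) / (-chg[dec])
      tvals[inc] <- (ube[basis[inc]] - bvals[inc]) / chg[inc]
      to_up[inc] <- TRUE
      tvals[tvals < 0] <- 0
      tmin <- min(tvals)
      span <- ube[q] - lbe[q]
      flip <- is.finite(span) && span < tmin - tol
      if (flip) {
        step <- span
      } else {
        if (!is.finite(tmin))
          return(list(status = "unbounded", xe = xe, basis = basis,
                      is_basic = is_basic, at_upper = at_upper, it = it, y = y))
        step <- tmin
        ## tie-break on smallest variable index (anti-cycling)
        ties <- which(tvals <= tmin + tol)
        leave_pos <- ties[which.min(basis[ties])]
        leave_to_upper <- to_up[leave_pos]
      }
      xe[q] <- xe[q] + sg_q * step
      xe[basis] <- xe[basis] + chg * step
      if (flip) {
        at_upper[q] <- !at_upper[q]
      } else {
        bl <- basis[leave_pos]
        ## snap leaving variable exactly to its bound
        xe[bl] <- if (leave_to_upper) ube[bl] else lbe[bl]
        at_upper[bl] <- leave_to_upper
        is_basic[bl] <- FALSE
        basis[leave_pos] <- q
        is_basic[q] <- TRUE
      }
    }
  }

  ## Phase 1
  p1 <- run_phase(phase1, xe, basis, is_basic, at_upper, lbe, ube, 1L)
  it_total <- it_total + p1$it
  if (p1$status != "optimal")
    return(list(status = "infeasible", iterations = it_total))
  infeas <- sum(p1$xe[n + seq_len(m)])
  if (infeas > 1e-7)
    return(list(status = "infeasible", iterations = it_total))

  ## pin artificials to zero for phase 2
  lbe[n + seq_len(m)] <- 0; ube[n + seq_len(m)] <- 0
  xe <- p1$xe; xe[n + seq_len(m)] <- 0
  basis <- p1$basis; is_basic <- p1$is_basic; at_upper <- p1$at_upper
  ## drive remaining artificials out of the basis so they cannot park
  ## steady-state residual later: pivot in any structural column with a
  ## nonzero entry in the artificial's basis row (degenerate pivot)
  art_pos <- which(basis > n)
  if (length(art_pos)) {
    for (i in art_pos) {
      B <- Aext[, basis, drop = FALSE]
      u <- tryCatch(solve(t(B), diag(m)[, i]), error = function(e) NULL)
      if (is.null(u)) next
      cand_j <- which(!is_basic[seq_len(n)])
      alpha <- as.vector(crossprod(Aext[, cand_j, drop = FALSE], u))
      k <- which(abs(alpha) > 1e-7)
      if (length(k)) {
        j <- cand_j[k[which.max(abs(alpha[k]))]]
        old <- basis[i]
        is_basic[old] <- FALSE
        xe[old] <- 0
        basis[i] <- j
        is_basic[j] <- TRUE
      }
    }
  }
  phase2 <- c(cmin, rep(0, m))
  p2 <- run_phase(phase2, xe, basis, is_basic, at_upper, lbe, ube, 2L)
  it_total <- it_total + p2$it
  if (p2$status == "unbounded")
    return(list(status = "unbounded", iterations = it_total))
  if (p2$status != "optimal")
    return(list(status = "infeasible", iterations = it_total))

  list(status = "optimal",
       x = p2$xe[seq_len(n)],
       y = p2$y,
       d = p2$d[seq_len(n)],
       iterations = it_total)
}
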