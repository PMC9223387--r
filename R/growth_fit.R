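## Growth-versus-oxygen-saturation models: a piecewise-linear saturation
## mapping composed with interpolated metabolic predictions, a logistic
## model with asymptotes -1 and 1, and a Monod model extended with an
## x-intercept. Fitting is by nonlinear least squares.

#' Piecewise-linear mapping from oxygen saturation to relative oxygen uptake
#'
#' r/r_max is 0 up to \code{x0}, rises linearly to 1 at \code{x1}, and is 1
#' beyond: x0 and x1 are the saturations of zero and maximal oxygen uptake.
#'
#' @param x water oxygen saturation (fraction of air saturation; vector ok).
#' @param x0,x1 saturation breakpoints, \code{x1 > x0 >= 0}.
#' @return relative oxygen uptake rate in [0, 1].
#' @export
eval_saturation <- function(x, x0, x1) {
  if (x1 <= x0) stop("x1 must exceed x0")
  pmin(1, pmax(0, (x - x0) / (x1 - x0)))
}

#' Logistic growth model with asymptotes -1 and 1
#'
#' mu/mu_max = 2 / (1 + exp(k (x0 - x))) - 1; zero at \code{x0},
#' approaching 1 as x grows.
#'
#' @param x oxygen saturation.
#' @param x0 saturation of zero growth.
#' @param k logistic growth rate.
#' @return relative growth rate.
#' @export
eval_logistic <- function(x, x0, k) {
  2 / (1 + exp(k * (x0 - x))) - 1
}

#' Monod growth model extended with an x-intercept
#'
#' mu/mu_max = (x - x0) / (Ks + x - x0) for x >= x0, 0 below; Ks + x0 is
#' the saturation at which growth is half-maximal.
#'
#' @param x oxygen saturation.
#' @param x0 saturation of zero growth.
#' @param Ks half-saturation constant.
#' @return relative growth rate.
#' @export
eval_monod <- function(x, x0, Ks) {
  d <- pmax(0, x - x0)
  d / (Ks + d)
}

#' Build the metabolic interpolation function f
#'
#' Linearly interpolates metabolic-model predictions of relative growth as
#' a function of relative oxygen uptake, anchored so that f(0) = 0 and
#' f(1) = 1.
#'
#' @param metabolic_curve data.frame or list with \code{r_rel} and
#'   \code{mu_rel}.
#' @return monotone function mapping r_rel in [0, 1] to mu_rel.
#' @export
metabolic_interpolator <- function(metabolic_curve) {
  r <- c(0, metabolic_curve$r_rel)
  mu <- c(0, metabolic_curve$mu_rel)
  o <- order(r)
  r <- r[o]; mu <- mu[o]
  top <- mu[length(mu)]
  if (top > 0) mu <- mu / top
  f0 <- stats::approxfun(r, mu, rule = 2, ties = mean)
  function(r_rel) f0(pmin(1, pmax(0, r_rel)))
}

#' Fit a growth model to (saturation, relative growth) observations
#'
#' Nonlinear least-squares fit of the metabolic
#' (\code{f(eval_saturation(x))}), logistic, or extended Monod model.
#' Standard errors come from the Jacobian-based covariance at the optimum
#' and R^2 = 1 - SS_res/SS_tot. Starting values are data-driven: x0 is the
#' smallest x with growth above 0.05, x1 the smallest with growth above
#' 0.95, k = 4/(x1 - x0), Ks = (x1 - x0)/2.
#'
#' @param data data.frame with columns \code{x} and \code{mu_rel}
#'   (>= 3 rows).
#' @param form "metabolic", "logistic", or "monod".
#' @param metabolic_curve required for the metabolic form: data.frame with
#'   \code{r_rel}, \code{mu_rel} from a model sweep.
#' @return object of class \code{growth_curve_fit}: list with
#'   \code{model_form}, \code{params}, \code{std_errors},
#'   \code{r_squared}, \code{converged}, \code{diagnostics}, and (metabolic
#'   form) the interpolator \code{f}.
#' @export
fit_growth <- function(data, form = c("metabolic", "logistic", "monod"),
                       metabolic_curve = NULL) {
  form <- match.arg(form)
  if (nrow(data) < 3) stop("need at least 3 observations")
  x <- data$x; y <- data$mu_rel
  o <- order(x)
  x0_start <- if (any(y > 0.05)) min(x[y > 0.05]) else min(x)
  x1_start <- if (any(y > 0.95)) min(x[y > 0.95]) else max(x)
  if (x1_start <= x0_start) x1_start <- x0_start + diff(range(x)) / 4 +
      1e-3
  df <- data.frame(x = x, y = y)
  f <- NULL
  fit <- switch(form,
    metabolic = {
      if (is.null(metabolic_curve))
        stop("metabolic form requires metabolic_curve")
      f <- metabolic_interpolator(metabolic_curve)
      tryCatch(minpack.lm::nlsLM(
        y ~ f(eval_saturation(x, x0, x1)), data = df,
        start = list(x0 = x0_start, x1 = x1_start),
        lower = c(0, 1e-6), control = minpack.lm::nls.lm.control(
          maxiter = 200)),
        error = function(e) e)
    },
    logistic = tryCatch(minpack.lm::nlsLM(
      y ~ eval_logistic(x, x0, k), data = df,
      start = list(x0 = x0_start, k = 4 / (x1_start - x0_start)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e),
    monod = tryCatch(minpack.lm::nlsLM(
      y ~ eval_monod(x, x0, Ks), data = df,
      start = list(x0 = x0_start, Ks = (x1_start - x0_start) / 2),
      lower = c(0, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e))
  if (inherits(fit, "error")) {
    return(structure(list(model_form = form, params = NULL,
                          std_errors = NULL, r_squared = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(fit), f = f),
                     class = "growth_curve_fit"))
  }
  cf <- summary(fit)$coefficients
  params <- stats::setNames(cf[, "Estimate"], rownames(cf))
  ses <- stats::setNames(cf[, "Std. Error"], rownames(cf))
  resid <- stats::resid(fit)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(model_form = form, params = params, std_errors = ses,
                 r_squared = 1 - ss_res / ss_tot, converged = TRUE,
                 diagnostics = "", f = f, fit = fit),
            class = "growth_curve_fit")
}

#' @export
print.growth_curve_fit <- function(x, ...) {
  cat("<growth_curve_fit>", x$model_form, "\n")
  if (!x$converged) {
    cat("  did not converge:", x$diagnostics, "\n")
    return(invisible(x))
  }
  for (p in names(x$params))
    cat(sprintf("  %-3s = %.4f (se %.4f)\n", p, x$params[[p]],
                x$std_errors[[p]]))
  cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  invisible(x)
}
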