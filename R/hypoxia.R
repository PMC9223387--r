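## Randomized oxygen-limited growth analysis: feed construction from sampled
## ratios, per-condition O2 sweep under pFBA, bootstrap confidence bands,
## limiting-reaction detection, flux clustering, and pathway enrichment.

#' Logarithmic oxygen uptake grid
#'
#' \code{n_levels} oxygen uptake rates logarithmically spaced over
#' \code{span_decades} decades up to and including \code{r_max}. The zero
#' endpoint is excluded; the top point equals \code{r_max} so that relative
#' growth reaches 1.
#'
#' @param r_max reference (maximal useful) oxygen uptake rate.
#' @param n_levels number of rates (default 50).
#' @param span_decades decades spanned below r_max (default 3).
#' @return list with \code{o2_rates} (increasing) and \code{r_max}.
#' @export
sweep_grid <- function(r_max, n_levels = 50, span_decades = 3) {
  if (r_max <= 0) stop("r_max must be positive")
  rates <- r_max * 10^seq(-span_decades, 0, length.out = n_levels)
  list(o2_rates = rates, r_max = r_max)
}

#' Apply a sampled condition to a model
#'
#' Adds a feed uptake reaction built from the condition's nutrient ratios
#' (coefficients normalized so one unit of feed flux supplies 1 g of
#' nutrients, with the feed bound set by \code{feed_total_mass}), disables
#' all other uptakes except phosphate (unlimited) and oxygen (left to the
#' caller), disables secretion of feed nutrients, and installs the sampled
#' flux bounds on internal and transport reactions.
#'
#' @param model a \code{metabolic_model}.
#' @param condition a \code{condition_sample}.
#' @param feed_total_mass feed uptake bound in g gDW^-1 h^-1 (default 100).
#' @param o2_exchange oxygen exchange reaction id.
#' @param pi_exchange phosphate exchange reaction id.
#' @return the conditioned \code{metabolic_model} (with reaction "FEED").
#' @export
apply_condition <- function(model, condition, feed_total_mass = 100,
                            o2_exchange = "EX_o2_e",
                            pi_exchange = "EX_pi_e") {
  ratios <- condition$feed_ratios
  mm <- stats::setNames(model$metabolites$molar_mass, model$metabolites$id)
  nut_e <- paste0(names(ratios), "_e")
  if (anyNA(mm[nut_e]))
    stop("feed nutrient lacks molar mass: ",
         nut_e[which(is.na(mm[nut_e]))[1]])
  coefs <- 1000 * ratios / sum(ratios * mm[nut_e])  # mmol per g feed
  feed <- list(id = "FEED", name = "feed uptake",
               stoichiometry = stats::setNames(as.numeric(coefs), nut_e),
               lower_bound = 0, upper_bound = feed_total_mass,
               gpr = "", kind = "feed")
  m2 <- model
  m2$reactions[["FEED"]] <- feed
  ## uptakes: feed only (plus phosphate; oxygen is set by the sweep)
  ex <- reaction_ids(m2, "exchange")
  m2 <- set_bounds(m2, ex, lower = 0)
  m2 <- set_bounds(m2, pi_exchange, lower = -1e6)
  ## no secretion of feed nutrients
  m2 <- set_bounds(m2, paste0("EX_", nut_e), upper = 0)
  ## sampled bounds per direction
  bs <- condition$bound_samples
  for (i in seq_len(nrow(bs))) {
    id <- bs$reaction[i]
    if (bs$direction[i] == "forward")
      m2$reactions[[id]]$upper_bound <- bs$bound[i]
    else
      m2$reactions[[id]]$lower_bound <- -bs$bound[i]
  }
  m2
}

#' Run the oxygen-limited growth sweep
#'
#' For every condition, conditions the model, computes the per-condition
#' oxygen reference (mu_max at unconstrained oxygen and r_max, the minimal
#' oxygen uptake supporting it), then solves pFBA at each relative oxygen
#' level of the grid. Infeasible points are recorded with their status, not
#' dropped.
#'
#' @param model a \code{metabolic_model}.
#' @param conditions list of \code{condition_sample} objects.
#' @param grid a \code{\link{sweep_grid}}; its rates are interpreted
#'   relative to \code{grid$r_max} and rescaled to each condition's own
#'   r_max (default: 20 levels over 3 decades).
#' @param feed_total_mass feed bound in g gDW^-1 h^-1 (default 100).
#' @param o2_exchange oxygen exchange reaction id.
#' @return object of class \code{hypoxia_sweep}: list with \code{points}
#'   (data.frame condition_id, r, r_rel, mu, mu_rel, mu_max, status),
#'   \code{fluxes} (reactions x points matrix of pFBA fluxes),
#'   \code{r_max} (per condition), \code{models} omitted for size.
#' @export
run_sweep <- function(model, conditions, grid = sweep_grid(1, 20),
                      feed_total_mass = 100, o2_exchange = "EX_o2_e") {
  rel_grid <- grid$o2_rates / grid$r_max
  pts <- list(); fx <- list(); rmaxes <- numeric(length(conditions))
  for (ci in seq_along(conditions)) {
    cm <- apply_condition(model, conditions[[ci]], feed_total_mass,
                          o2_exchange)
    oref <- oxygen_reference(cm, o2_exchange)
    rmaxes[ci] <- oref$r_max
    ## FBA is homogeneous in the bounds, so rescale each condition to a
    ## growth scale of 1 before solving: sampled capacities can push
    ## mu_max many orders of magnitude down, where fixed solver
    ## tolerances would dominate the answer
    sc <- if (oref$mu_max > 0) 1 / oref$mu_max else 1
    cms <- scale_model_bounds(cm, sc)
    for (ri in seq_along(rel_grid)) {
      r <- rel_grid[ri] * oref$r_max
      cmr <- set_bounds(cms, o2_exchange, lower = -r * sc)
      sol <- pfba(cmr)
      ok <- identical(sol$status, "optimal")
      mu <- if (ok) sol$objective_value / sc else NA_real_
      pts[[length(pts) + 1]] <- data.frame(
        condition_id = ci, r = r, r_rel = rel_grid[ri], mu = mu,
        mu_rel = if (ok && oref$mu_max > 0) mu / oref$mu_max else NA_real_,
        mu_max = oref$mu_max, status = sol$status)
      fx[[length(fx) + 1]] <- if (ok) sol$fluxes / sc else
        stats::setNames(rep(NA_real_, length(cms$reactions)),
                        names(cms$reactions))
    }
  }
  fmat <- do.call(cbind, fx)
  structure(list(points = do.call(rbind, pts), fluxes = fmat,
                 r_max = rmaxes), class = "hypoxia_sweep")
}

## multiply every finite bound by a positive constant (LP homogeneity)
scale_model_bounds <- function(model, sc) {
  if (sc == 1) return(model)
  for (id in names(model$reactions)) {
    model$reactions[[id]]$lower_bound <- sc *
      model$reactions[[id]]$lower_bound
    model$reactions[[id]]$upper_bound <- sc *
      model$reactions[[id]]$upper_bound
  }
  model
}

#' Correct growth rates for anaerobic (oxygen-independent) growth
#'
#' Subtracts the anaerobic growth rate from every predicted growth rate,
#' floors at zero, and renormalizes relative growth against the corrected
#' maximum, yielding purely aerobic growth curves.
#'
#' @param points the \code{points} data.frame of a sweep.
#' @param anaerobic_mu growth rate at zero oxygen uptake for the same feed.
#' @return the corrected points data.frame.
#' @export
aerobic_correction <- function(points, anaerobic_mu) {
  mu <- pmax(points$mu - anaerobic_mu, 0)
  denom <- pmax(points$mu_max - anaerobic_mu, .Machine$double.eps)
  points$mu <- mu
  points$mu_rel <- mu / denom
  points$mu_max <- denom
  points
}

#' Percentile bootstrap band for per-level means
#'
#' Resamples condition ids with replacement \code{n_boot} times and reports
#' the mean with a percentile confidence band at each level.
#'
#' @param tbl data.frame of per-condition values at each level.
#' @param n_boot bootstrap samples (default 1000).
#' @param level_col,value_col,cond_col column names (defaults "r_rel",
#'   "mu_rel", "condition_id").
#' @param conf confidence level (default 0.95).
#' @return data.frame (level, mean, lower, upper, degenerate).
#' @export
bootstrap_band <- function(tbl, n_boot = 1000, level_col = "r_rel",
                           value_col = "mu_rel", cond_col = "condition_id",
                           conf = 0.95) {
  lv <- tbl[[level_col]]; va <- tbl[[value_col]]; cd <- tbl[[cond_col]]
  keep <- !is.na(va)
  lv <- lv[keep]; va <- va[keep]; cd <- cd[keep]
  alpha <- (1 - conf) / 2
  out <- lapply(sort(unique(lv)), function(l) {
    sel <- lv == l
    vals <- va[sel]; conds <- cd[sel]
    ucond <- unique(conds)
    per_cond <- vapply(ucond, function(u) mean(vals[conds == u]), 0)
    if (length(ucond) < 2) {
      return(data.frame(level = l, mean = mean(per_cond),
                        lower = mean(per_cond), upper = mean(per_cond),
                        degenerate = TRUE))
    }
    boots <- vapply(seq_len(n_boot), function(b) {
      mean(per_cond[sample.int(length(per_cond), replace = TRUE)])
    }, 0)
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    data.frame(level = l, mean = mean(per_cond), lower = qs[1],
               upper = qs[2], degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Detect limiting reactions in a flux solution
#'
#' A reaction is limiting when its predicted flux lies within the detection
#' tolerance of one of its non-zero flux bounds; bounds at zero never flag.
#'
#' @param solution a \code{flux_solution}.
#' @param model the (conditioned) \code{metabolic_model} the solution was
#'   computed on.
#' @param tol detection tolerance (default 1e-6).
#' @return character vector of limiting reaction ids.
#' @export
detect_limiting <- function(solution, model, tol = VALIDATION_TOL) {
  b <- reaction_bounds(model)
  v <- solution$fluxes[b$reaction]
  at_lb <- b$lower_bound != 0 & is.finite(b$lower_bound) &
    abs(v - b$lower_bound) <= tol
  at_ub <- b$upper_bound != 0 & is.finite(b$upper_bound) &
    abs(v - b$upper_bound) <= tol
  b$reaction[at_lb | at_ub]
}

#' Cluster reactions by their normalized flux profiles
#'
#' Takes absolute pFBA fluxes, normalizes each reaction's profile by its
#' maximum within each condition (all-zero profiles map to 0), and applies
#' Ward's minimum variance clustering (Euclidean distance, ward.D2) cut
#' into \code{n_clusters} groups.
#'
#' @param sweep a \code{hypoxia_sweep} (or a list with \code{points} and
#'   \code{fluxes} in the same layout).
#' @param n_clusters number of clusters (default 8).
#' @return named integer vector, reaction -> cluster id; the profile matrix
#'   is attached as attribute \code{"profiles"}.
#' @export
cluster_fluxes <- function(sweep, n_clusters = 8) {
  fm <- abs(sweep$fluxes)
  fm[is.na(fm)] <- 0
  if (nrow(fm) < n_clusters)
    stop("fewer reactions (", nrow(fm), ") than clusters (", n_clusters, ")")
  conds <- sweep$points$condition_id
  prof <- fm
  for (u in unique(conds)) {
    sel <- conds == u
    mx <- apply(fm[, sel, drop = FALSE], 1, max)
    mx[mx == 0] <- 1
    prof[, sel] <- fm[, sel, drop = FALSE] / mx
  }
  hc <- stats::hclust(stats::dist(prof, method = "euclidean"),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  attr(cl, "profiles") <- prof
  attr(cl, "hclust") <- hc
  cl
}

#' Hypergeometric pathway enrichment with BH correction
#'
#' One-sided hypergeometric overrepresentation test of a gene cluster
#' against each pathway, using the model's genes as background, with
#' Benjamini-Hochberg adjustment across pathways. Recall is the fraction of
#' each pathway's genes found in the cluster.
#'
#' @param cluster_genes character vector (subset of background).
#' @param pathway_genes named list of character vectors.
#' @param background character vector of all genes.
#' @return data.frame (pathway, overlap, size, p, p_adjusted, recall).
#' @export
enrich_pathways <- function(cluster_genes, pathway_genes, background) {
  if (length(background) == 0) stop("empty background gene set")
  extra <- setdiff(cluster_genes, background)
  if (length(extra)) stop("cluster gene not in background: ", extra[1])
  N <- length(unique(background))
  n <- length(unique(cluster_genes))
  rows <- lapply(names(pathway_genes), function(pw) {
    genes <- intersect(unique(pathway_genes[[pw]]), background)
    K <- length(genes)
    k <- length(intersect(cluster_genes, genes))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, overlap = k, size = K, p = p,
               recall = if (K > 0) k / K else 0)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[, c("pathway", "overlap", "size", "p", "p_adjusted", "recall")]
}
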