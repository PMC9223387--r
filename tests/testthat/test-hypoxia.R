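## Oxygen-limited growth pipeline: grid, sweep behavior, bootstrap bands,
## limiting-reaction detection, flux clustering, and pathway enrichment.

test_that("the oxygen grid is increasing, positive, and ends at r_max", {
  g <- sweep_grid(5, n_levels = 12)
  expect_length(g$o2_rates, 12)
  expect_true(all(diff(g$o2_rates) > 0))
  expect_true(all(g$o2_rates > 0))
  expect_equal(g$o2_rates[12], 5)
  expect_error(sweep_grid(0), "positive")
})

test_that("relative growth reaches 1 at r_max and is monotone in oxygen", {
  m <- toy_aerobe()
  conds <- sample_conditions(m, 5, master_seed = 31)
  sw <- run_sweep(m, conds, grid = sweep_grid(1, 6))
  pts <- sw$points
  expect_true(all(pts$status == "optimal"))
  top <- pts$mu_rel[pts$r_rel == 1]
  expect_true(all(abs(top - 1) < 1e-6))
  curve <- stats::aggregate(mu_rel ~ r_rel, pts, mean)
  expect_true(all(diff(curve$mu_rel) >= -1e-9))
  ## per-condition monotonicity too (LP relaxation monotonicity)
  for (cid in unique(pts$condition_id)) {
    sub <- pts[pts$condition_id == cid, ]
    sub <- sub[order(sub$r_rel), ]
    expect_true(all(diff(sub$mu_rel) >= -1e-9))
  }
})

test_that("aerobic correction subtracts baseline growth correctly", {
  pts <- data.frame(condition_id = 1, r = 1:4, r_rel = (1:4) / 4,
                    mu = c(1, 2, 3, 4), mu_rel = c(0.25, 0.5, 0.75, 1),
                    mu_max = 4, status = "optimal")
  ## zero anaerobic growth: identity
  expect_equal(aerobic_correction(pts, 0)$mu_rel, pts$mu_rel)
  ## full subtraction: everything collapses to zero
  expect_true(all(aerobic_correction(pts, 4)$mu_rel == 0))
  ## a fermenting model's corrected curve passes through the origin
  m <- toy_default()
  cm <- apply_condition(m, sample_condition(m, 51))
  cm <- set_bounds(cm, "EX_glc_e", lower = -10)
  anaerobic <- fba(set_bounds(cm, "EX_o2_e", lower = 0))$objective_value
  expect_gt(anaerobic, 0)
  oref <- oxygen_reference(cm)
  rr <- c(1e-4, 0.1, 1)
  mus <- vapply(rr, function(f) {
    fba(set_bounds(cm, "EX_o2_e", lower = -f * oref$r_max))$objective_value
  }, 0)
  pts2 <- data.frame(condition_id = 1, r = rr * oref$r_max, r_rel = rr,
                     mu = mus, mu_rel = mus / oref$mu_max,
                     mu_max = oref$mu_max, status = "optimal")
  corr <- aerobic_correction(pts2, anaerobic)
  expect_lt(corr$mu_rel[1], 1e-3)
  expect_equal(corr$mu_rel[3], 1, tolerance = 1e-6)
})

test_that("bootstrap bands behave like percentile bootstrap bands", {
  ## identical conditions give a zero-width band
  tbl <- data.frame(condition_id = rep(1:20, each = 2),
                    r_rel = rep(c(0.5, 1), 20),
                    mu_rel = rep(c(0.4, 0.9), 20))
  bb <- bootstrap_band(tbl, n_boot = 200)
  expect_equal(bb$lower, bb$mean, tolerance = 1e-12)
  expect_equal(bb$upper, bb$mean, tolerance = 1e-12)
  ## half-width tracks the closed-form standard error
  set.seed(99)
  tbl2 <- data.frame(condition_id = 1:100, r_rel = 1,
                     mu_rel = stats::rnorm(100, 0.5, 0.1))
  bb2 <- bootstrap_band(tbl2, n_boot = 1000)
  half <- (bb2$upper - bb2$lower) / 2
  expect_gte(half, 0.015)
  expect_lte(half, 0.025)
  expect_gte(bb2$mean, bb2$lower)
  expect_lte(bb2$mean, bb2$upper)
  ## shifting all values shifts the band endpoints
  tbl3 <- tbl2; tbl3$mu_rel <- tbl3$mu_rel + 1
  set.seed(99)
  bb3 <- bootstrap_band(tbl3, n_boot = 200)
  expect_gt(bb3$lower, bb2$lower)
  expect_gt(bb3$upper, bb2$upper)
  ## single condition: degenerate and flagged
  bb4 <- bootstrap_band(data.frame(condition_id = 1, r_rel = 1,
                                   mu_rel = 0.5), n_boot = 10)
  expect_true(bb4$degenerate)
})

test_that("limiting reactions are exactly those at non-zero bounds", {
  mets <- data.frame(id = c("a_c"), name = "a", compartment = "c")
  rxns <- list(
    list(id = "IN", name = "x", stoichiometry = c(a_c = 1),
         lower_bound = 0, upper_bound = 5, gpr = "", kind = "sink_demand"),
    list(id = "OUT", name = "x", stoichiometry = c(a_c = -1),
         lower_bound = 0, upper_bound = 10, gpr = "",
         kind = "sink_demand"))
  m <- metabolic_model("t", c(c = "cytosol"), mets, rxns)
  sol <- structure(list(fluxes = c(IN = 5, OUT = 5), status = "optimal"),
                   class = "flux_solution")
  expect_identical(detect_limiting(sol, m), "IN")
  sol2 <- structure(list(fluxes = c(IN = 2.5, OUT = 2.5),
                         status = "optimal"), class = "flux_solution")
  expect_length(detect_limiting(sol2, m), 0)
  ## a zero bound never flags
  sol3 <- structure(list(fluxes = c(IN = 0, OUT = 0), status = "optimal"),
                    class = "flux_solution")
  expect_length(detect_limiting(sol3, m), 0)
})

test_that("oxygen is the binding constraint at the lowest oxygen level", {
  m <- toy_aerobe()
  for (seed in c(61, 62)) {
    cm <- apply_condition(m, sample_condition(m, seed))
    oref <- oxygen_reference(cm)
    cmr <- set_bounds(cm, "EX_o2_e", lower = -1e-3 * oref$r_max)
    lim <- detect_limiting(pfba(cmr), cmr)
    expect_true("EX_o2_e" %in% lim)
  }
})

test_that("random bound sampling broadens the set of limiting reactions", {
  m <- toy_aerobe()
  top_limiting <- function(cm) {
    oref <- oxygen_reference(cm)
    cmr <- set_bounds(cm, "EX_o2_e", lower = -oref$r_max)
    detect_limiting(pfba(cmr), cmr)
  }
  default_cond <- sample_condition(m, 71)
  default_cond$bound_samples <- default_cond$bound_samples[0, ]
  base_union <- top_limiting(apply_condition(m, default_cond))
  sampled_union <- character()
  for (seed in 71:78)
    sampled_union <- union(sampled_union,
                           top_limiting(apply_condition(
                             m, sample_condition(m, seed))))
  expect_true(all(setdiff(base_union, "FEED") %in% sampled_union))
  expect_gt(length(sampled_union), length(base_union))
})

test_that("flux clustering recovers planted groups and normalizes to 1", {
  ## two orthogonal profile groups across 8 points in one condition
  fx <- rbind(matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8), 3), 3,
                     byrow = TRUE),
              matrix(rep(c(8, 7, 6, 5, 4, 3, 2, 1), 3), 3,
                     byrow = TRUE))
  rownames(fx) <- paste0("r", 1:6)
  sweep_like <- list(points = data.frame(condition_id = rep(1, 8)),
                     fluxes = fx)
  cl <- cluster_fluxes(sweep_like, 2)
  expect_length(unique(cl[1:3]), 1)
  expect_length(unique(cl[4:6]), 1)
  expect_false(cl[[1]] == cl[[4]])
  ## per-condition max-normalization maps a constant profile to all 1
  fx2 <- rbind(r1 = rep(2, 8), r2 = 1:8, r3 = 8:1, r4 = rep(c(0, 1), 4))
  sweep2 <- list(points = data.frame(condition_id = rep(1, 8)),
                 fluxes = fx2)
  cl2 <- cluster_fluxes(sweep2, 2)
  expect_true(all(attr(cl2, "profiles")["r1", ] == 1))
  ## order invariance (tie-free profiles, so the partition is unique)
  set.seed(17)
  fx3 <- matrix(abs(stats::rnorm(48)), 6, 8,
                dimnames = list(paste0("q", 1:6), NULL))
  sweep3 <- list(points = data.frame(condition_id = rep(1, 8)),
                 fluxes = fx3)
  cl_a <- cluster_fluxes(sweep3, 3)
  perm <- c(4, 2, 6, 1, 3, 5)
  cl_b <- cluster_fluxes(list(points = sweep3$points,
                              fluxes = fx3[perm, ]), 3)
  nm <- rownames(fx3)
  expect_identical(outer(cl_a, cl_a, "==")[nm, nm],
                   outer(cl_b, cl_b, "==")[nm, nm])
  expect_error(cluster_fluxes(sweep2, 9), "fewer reactions")
})

test_that("Ward merges follow the brute-force ESS criterion", {
  set.seed(7)
  X <- matrix(stats::rnorm(24), 6, 4)
  rownames(X) <- paste0("r", 1:6)
  sweep_like <- list(points = data.frame(condition_id = rep(1, 4)),
                     fluxes = abs(X))
  cl <- cluster_fluxes(sweep_like, 2)
  hc <- attr(cl, "hclust")
  prof <- attr(cl, "profiles")
  expect_identical(hclust_merge_sequence(hc),
                   oracle_ward_merge_sequence(prof))
})

test_that("enrichment p-values are exact hypergeometric tails", {
  background <- paste0("g", 1:100)
  pathways <- list(pwA = paste0("g", 1:5), pwB = paste0("g", 3:30),
                   pwC = paste0("g", 90:100))
  cluster <- paste0("g", 1:5)
  res <- enrich_pathways(cluster, pathways, background)
  for (i in seq_len(nrow(res))) {
    K <- res$size[i]; k <- res$overlap[i]
    expect_equal(res$p[i], oracle_hyper_tail(k, K, 100, 5),
                 tolerance = 1e-12)
    expect_equal(res$recall[i], k / K)
  }
  ## the whole background as a cluster is never enriched
  res2 <- enrich_pathways(background, pathways, background)
  expect_true(all(abs(res2$p - 1) < 1e-12))
  ## BH step-up on a known example
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  raw <- c(0.01, 0.02, 0.04)
  expect_equal(sort(enrich_pathways(cluster, pathways,
                                    background)$p_adjusted),
               sort(stats::p.adjust(res$p, "BH")))
  expect_error(enrich_pathways(cluster, pathways, character()),
               "background")
  expect_error(enrich_pathways("not_a_gene", pathways, background),
               "not in background")
})
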