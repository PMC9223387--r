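## Independent oracles used across the suite. These deliberately use
## different algorithms/implementations than the package code they check.

## --- independent LP oracle (SciPy HiGHS via the system python) ----------
## A completely separate LP implementation: the problem is serialized to
## JSON and solved with scipy.optimize.linprog (interior point free,
## dual simplex HiGHS), then read back.
oracle_lp <- function(obj, S, lb, ub, maximize = TRUE,
                      rhs = rep(0, nrow(S))) {
  dir <- tempfile("lp")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  inp <- file.path(dir, "in.json"); outp <- file.path(dir, "out.json")
  jsonlite::write_json(
    list(c = if (maximize) -obj else obj,
         A = apply(unname(as.matrix(S)), 1, as.numeric,
                   simplify = FALSE),
         b = as.numeric(rhs),
         lb = ifelse(is.finite(lb), lb, -1e30),
         ub = ifelse(is.finite(ub), ub, 1e30)),
    inp, digits = NA, auto_unbox = FALSE)
  script <- paste(
    "import json, sys",
    "from scipy.optimize import linprog",
    "d = json.load(open(sys.argv[1]))",
    "bounds = [(None if l <= -1e29 else l, None if u >= 1e29 else u)",
    "          for l, u in zip(d['lb'], d['ub'])]",
    "r = linprog(d['c'], A_eq=d['A'], b_eq=d['b'], bounds=bounds,",
    "            method='highs')",
    "json.dump({'status': int(r.status),",
    "           'fun': None if r.fun is None else float(r.fun),",
    "           'x': None if r.x is None else list(map(float, r.x))},",
    "          open(sys.argv[2], 'w'))", sep = "\n")
  sf <- file.path(dir, "solve.py")
  writeLines(script, sf)
  st <- system2("python", c(sf, inp, outp), stdout = FALSE, stderr = FALSE)
  if (st != 0 || !file.exists(outp)) return(NULL)
  res <- jsonlite::fromJSON(outp)
  if (res$status != 0) return(NULL)
  list(objective = if (maximize) -res$fun else res$fun, x = res$x)
}

## FBA objective of a model via the pracma oracle
oracle_fba_objective <- function(model, maximize = TRUE) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  obj <- stats::setNames(numeric(ncol(S)), colnames(S))
  obj[names(model$objective)] <- model$objective
  oracle_lp(obj, S, lb, ub, maximize = maximize)
}

## minimal total |v| at fixed growth via an independently built split LP
## solved by the pracma oracle
oracle_pfba_sumabs <- function(model, growth) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  n <- ncol(S)
  obj_row <- stats::setNames(numeric(n), colnames(S))
  obj_row[names(model$objective)] <- model$objective
  S2 <- rbind(cbind(S, -S), c(obj_row, -obj_row))
  res <- oracle_lp(rep(1, 2 * n), S2,
                   lb = c(pmax(0, lb), pmax(0, -ub)),
                   ub = c(pmax(0, ub), pmax(0, -lb)),
                   maximize = FALSE, rhs = c(rep(0, nrow(S)), growth))
  if (is.null(res)) NULL else res$objective
}

## random small flux networks with a known-feasible interior
random_lp_instance <- function(seed) {
  set.seed(seed)
  m <- sample(4:10, 1)
  n <- m + sample(3:10, 1)
  S <- matrix(round(rnorm(m * n), 2), m, n)
  x0 <- runif(n, 0.1, 0.5)
  lb <- x0 - runif(n, 0.2, 1)
  ub <- x0 + runif(n, 0.2, 1)
  ## shift rhs into the model via a virtual fixed column: keep S v = b by
  ## solving with bounds only (b = S x0 absorbed through shifted bounds)
  list(S = S, b = as.vector(S %*% x0), lb = lb, ub = ub,
       obj = rnorm(n))
}

## --- brute-force minimal-set oracle -------------------------------------
## All support-minimal candidate subsets (by exhaustive search in order of
## cardinality) for which `feasible(subset)` is TRUE.
oracle_minimal_sets <- function(candidates, feasible, max_card = length(candidates)) {
  found <- list()
  is_superset <- function(s) any(vapply(found, function(f) all(f %in% s),
                                        TRUE))
  for (k in 0:max_card) {
    if (k > length(candidates)) break
    combs <- utils::combn(candidates, k, simplify = FALSE)
    for (s in combs) {
      if (length(found) && is_superset(s)) next
      if (feasible(s)) found <- c(found, list(sort(s)))
    }
  }
  found
}

## --- brute-force Ward (ESS) agglomeration -------------------------------
## Greedy merging minimizing the increase in total within-cluster sum of
## squares, recomputed from the raw profiles at every step.
oracle_ward_merge_sequence <- function(X) {
  ess <- function(rows) {
    if (length(rows) == 1) return(0)
    M <- X[rows, , drop = FALSE]
    sum(sweep(M, 2, colMeans(M))^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  seq_out <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_inc <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        inc <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (inc < best_inc - 1e-12) { best_inc <- inc; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    seq_out[[length(seq_out) + 1]] <- merged
    clusters <- c(clusters[-best], list(merged))
  }
  seq_out
}

## merge sequence (leaf index sets) of an hclust tree
hclust_merge_sequence <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(k) if (k < 0) -k else members[[k]]
    members[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
    out[[i]] <- members[[i]]
  }
  out
}

## --- combinatorial hypergeometric tail ----------------------------------
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

## --- single-supplement perturbation oracle for limiting amino acids -----
## Opens each candidate amino acid's import by a small unpenalized bound
## and picks the amino acid with the strictly largest consumed-mass saving.
oracle_limiting_aa <- function(model, feed_reaction, fixed_growth = 1,
                               supplemented = character(), delta = 1e-3) {
  setup <- aquaflux:::feed_limitation_setup(model, feed_reaction,
                                            fixed_growth, supplemented)
  obj <- aquaflux:::feed_mass_objective(supplemented)
  base <- fba(setup, objective = obj, sense = "min")
  stopifnot(base$status == "optimal")
  exm <- exchange_metabolites(setup)
  base_ids <- sub("_e$", "", exm)
  cand <- names(exm)[base_ids %in% names(AA_MOLAR_MASS) &
                       !(base_ids %in% supplemented)]
  gains <- vapply(cand, function(ex) {
    sol <- fba(set_bounds(setup, ex, lower = -delta), objective = obj,
               sense = "min")
    if (sol$status != "optimal") return(NA_real_)
    base$objective_value - sol$objective_value
  }, 0)
  names(gains) <- base_ids[cand]
  pos <- gains[gains > 1e-9]
  if (length(pos) == 0) return(NA_character_)
  ord <- sort(pos, decreasing = TRUE)
  if (length(ord) > 1 && ord[1] - ord[2] < 1e-9) return("tie")
  names(ord)[1]
}

## random feed compositions over the 20 amino acids
random_feed <- function(seed) {
  set.seed(seed)
  w <- runif(20, 0.2, 3)
  pct <- 100 * w / sum(w)
  structure(list(name = paste0("random_", seed),
                 mass_percent = stats::setNames(pct, names(AA_MOLAR_MASS)),
                 molar_masses = AA_MOLAR_MASS),
            class = "feed_composition")
}

## shared toy fixtures (built once per test run)
toy_default <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- generate_toy_model(toy_model_spec())
    m
  }
})
toy_full_aa <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- generate_toy_model(toy_model_spec(n_nonessential_aa = 10))
    m
  }
})
toy_aerobe <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- generate_toy_model(
        toy_model_spec(include_anaerobic_route = FALSE))
    m
  }
})
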