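## Reaction-content comparison of metabolic models: binary presence
## matrices restricted to shared intracellular compartments, a registry of
## 16 dissimilarity measures x 5 agglomerative linkages, cophenetic
## correlation, and clade-support counting across the measure/method sweep.

#' The registry of 16 supported dissimilarity measures for binary
#' reaction-content profiles
#' @export
DISSIMILARITY_MEASURES <- c("jaccard", "dice", "matching",
                            "rogers_tanimoto", "sokal_sneath",
                            "russell_rao", "yule", "kulsinski",
                            "euclidean", "sqeuclidean", "cityblock",
                            "chebyshev", "canberra", "braycurtis",
                            "cosine", "correlation")

#' The five supported agglomerative linkage methods
#' @export
LINKAGE_METHODS <- c("single", "complete", "average", "weighted", "ward")

#' Binary reaction-content matrix for a set of models
#'
#' Restricts to intracellular metabolic reactions (kind "internal") whose
#' metabolites all live in compartments shared by every model, and records
#' presence/absence of each reaction id per model.
#'
#' @param models named list of \code{metabolic_model} objects sharing a
#'   reaction-identifier namespace.
#' @param compartments compartments to consider; defaults to the
#'   intersection of all models' compartments minus the extracellular one.
#' @return binary matrix (model x reaction), no all-zero columns.
#' @export
reaction_matrix <- function(models, compartments = NULL) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be a named list")
  if (is.null(compartments)) {
    compartments <- Reduce(intersect,
                           lapply(models, function(m)
                             names(m$compartments)))
    compartments <- setdiff(compartments, "e")
  }
  content <- lapply(models, function(m) {
    met_comp <- stats::setNames(m$metabolites$compartment,
                                m$metabolites$id)
    keep <- vapply(m$reactions, function(r) {
      r$kind == "internal" &&
        all(met_comp[names(r$stoichiometry)] %in% compartments)
    }, TRUE)
    names(m$reactions)[keep]
  })
  all_rxns <- sort(unique(unlist(content)))
  mat <- t(vapply(content, function(rx) as.integer(all_rxns %in% rx),
                  integer(length(all_rxns))))
  colnames(mat) <- all_rxns
  rownames(mat) <- names(models)
  mat[, colSums(mat) > 0, drop = FALSE]
}

## pairwise dissimilarity between two binary vectors from the 2x2 counts
binary_dissimilarity <- function(x, y, measure) {
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  n <- a + b + cc + d
  switch(measure,
    jaccard = if (a + b + cc == 0) 0 else (b + cc) / (a + b + cc),
    dice = if (2 * a + b + cc == 0) 0 else (b + cc) / (2 * a + b + cc),
    matching = (b + cc) / n,
    rogers_tanimoto = 2 * (b + cc) / (a + d + 2 * (b + cc)),
    sokal_sneath = if (a + 2 * (b + cc) == 0) 0 else
      2 * (b + cc) / (a + 2 * (b + cc)),
    russell_rao = (n - a) / n,
    yule = if (a * d + b * cc == 0) 0 else
      2 * b * cc / (a * d + b * cc),
    kulsinski = (b + cc - a + n) / (b + cc + n),
    euclidean = sqrt(b + cc),
    sqeuclidean = b + cc,
    cityblock = b + cc,
    chebyshev = as.numeric((b + cc) > 0),
    canberra = b + cc,
    braycurtis = if (2 * a + b + cc == 0) 0 else
      (b + cc) / (2 * a + b + cc),
    cosine = {
      den <- sqrt((a + b) * (a + cc))
      if (den == 0) as.numeric((b + cc) > 0) else 1 - a / den
    },
    correlation = {
      sx <- stats::sd(x); sy <- stats::sd(y)
      if (sx == 0 || sy == 0) as.numeric((b + cc) > 0)
      else 1 - stats::cor(x, y)
    },
    stop("unknown measure '", measure, "'; supported: ",
         paste(DISSIMILARITY_MEASURES, collapse = ", ")))
}

#' Dissimilarity matrix between model reaction contents
#'
#' @param matrix binary reaction matrix from \code{\link{reaction_matrix}}.
#' @param measure one of the 16 supported measures (see
#'   \code{DISSIMILARITY_MEASURES}).
#' @return symmetric \code{dist}-convertible matrix with zero diagonal.
#' @export
reaction_dissimilarity <- function(matrix, measure) {
  if (!measure %in% DISSIMILARITY_MEASURES)
    stop("unknown measure '", measure, "'; supported: ",
         paste(DISSIMILARITY_MEASURES, collapse = ", "))
  nm <- nrow(matrix)
  D <- base::matrix(0, nm, nm, dimnames = list(rownames(matrix),
                                               rownames(matrix)))
  for (i in seq_len(nm - 1)) {
    for (j in (i + 1):nm) {
      D[i, j] <- D[j, i] <- binary_dissimilarity(matrix[i, ],
                                                 matrix[j, ], measure)
    }
  }
  D
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard linkage tree via \code{stats::hclust}; "weighted" maps to
#' McQuitty linkage and "ward" to ward.D2 (squared-distance Ward, the
#' usual Ward criterion on Euclidean input).
#'
#' @param distances symmetric distance matrix or \code{dist}.
#' @param method one of "single", "complete", "average", "weighted",
#'   "ward".
#' @return an \code{hclust} object.
#' @export
agglomerate <- function(distances, method) {
  if (!method %in% LINKAGE_METHODS)
    stop("unknown method '", method, "'; supported: ",
         paste(LINKAGE_METHODS, collapse = ", "))
  hm <- c(single = "single", complete = "complete", average = "average",
          weighted = "mcquitty", ward = "ward.D2")[[method]]
  stats::hclust(stats::as.dist(distances), method = hm)
}

## cophenetic (merge-height) distance matrix computed from the merge tree
cophenetic_from_hclust <- function(hc) {
  n <- length(hc$labels)
  tmat <- base::matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(k) if (k < 0) -k else members[[k]]
    A <- grab(hc$merge[i, 1]); B <- grab(hc$merge[i, 2])
    tmat[A, B] <- hc$height[i]
    tmat[B, A] <- hc$height[i]
    members[[i]] <- c(A, B)
  }
  tmat
}

#' Cophenetic correlation coefficient of a dendrogram
#'
#' Pearson correlation between the strict upper triangles of the input
#' dissimilarities x(i,j) and the dendrogram's cophenetic (merge-height)
#' distances t(i,j), computed from the centered cross-product sums.
#'
#' @param distances the dissimilarity matrix the tree was built from (or
#'   any reference dissimilarity).
#' @param dendrogram an \code{hclust} object over the same leaves.
#' @return list with \code{ccc}, \code{input_distances},
#'   \code{cophenetic_distances}, \code{x_bar}, \code{t_bar}.
#' @export
cophenetic_correlation <- function(distances, dendrogram) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 leaves")
  tmat <- cophenetic_from_hclust(dendrogram)
  tmat <- tmat[rownames(D), colnames(D)]
  iu <- upper.tri(D)
  x <- D[iu]; tt <- tmat[iu]
  x_bar <- mean(x); t_bar <- mean(tt)
  sxx <- sum((x - x_bar)^2); stt <- sum((tt - t_bar)^2)
  if (sxx <= 0 || stt <= 0)
    stop("degenerate variance: cophenetic correlation undefined")
  ccc <- sum((x - x_bar) * (tt - t_bar)) / sqrt(sxx * stt)
  list(ccc = ccc, input_distances = D, cophenetic_distances = tmat,
       x_bar = x_bar, t_bar = t_bar)
}

## leaf sets of every internal node of an hclust tree
tree_clades <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  out <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(k) if (k < 0) hc$labels[-k] else members[[k]]
    members[[i]] <- c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2]))
    out[[i]] <- members[[i]]
  }
  out
}

#' Clade support for a group of models across the measure/method sweep
#'
#' Builds one tree per (measure, method) pair and reports the fraction of
#' trees in which the group's models form a clade (an internal node whose
#' leaf set equals the group exactly; single models and the full set count
#' as trivial clades).
#'
#' @param matrix binary reaction matrix from \code{\link{reaction_matrix}}.
#' @param group character vector of model names.
#' @param measures dissimilarity measures (default: all 16).
#' @param methods linkage methods (default: all 5).
#' @return list with \code{fraction}, \code{n_support}, \code{n_trees},
#'   and a data.frame \code{detail} (measure, method, clade, ccc).
#' @export
clade_support <- function(matrix, group,
                          measures = DISSIMILARITY_MEASURES,
                          methods = LINKAGE_METHODS) {
  stopifnot(all(group %in% rownames(matrix)))
  group <- sort(group)
  rows <- list()
  for (ms in measures) {
    D <- reaction_dissimilarity(matrix, ms)
    for (md in methods) {
      hc <- agglomerate(D, md)
      clades <- c(tree_clades(hc), as.list(rownames(matrix)))
      hit <- any(vapply(clades, function(cl) identical(sort(cl), group),
                        TRUE))
      ccc <- tryCatch(cophenetic_correlation(D, hc)$ccc,
                      error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(measure = ms, method = md,
                                             clade = hit, ccc = ccc)
    }
  }
  detail <- do.call(rbind, rows)
  list(fraction = mean(detail$clade), n_support = sum(detail$clade),
       n_trees = nrow(detail), detail = detail)
}

#' Export an hclust tree in Newick format
#'
#' @param hc an \code{hclust} object.
#' @param digits height precision.
#' @return a Newick string (with branch lengths from merge heights).
#' @export
as_newick <- function(hc, digits = 6) {
  build <- function(k, parent_h) {
    if (k < 0) {
      sprintf("%s:%s", hc$labels[-k], format(parent_h, digits = digits))
    } else {
      h <- hc$height[k]
      sprintf("(%s,%s):%s",
              build(hc$merge[k, 1], h / 2),
              build(hc$merge[k, 2], h / 2),
              format(max(parent_h - h, 0) / 2, digits = digits))
    }
  }
  root <- nrow(hc$merge)
  paste0("(", build(hc$merge[root, 1], hc$height[root] / 2), ",",
         build(hc$merge[root, 2], hc$height[root] / 2), ");")
}
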