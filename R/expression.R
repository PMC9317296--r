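# Expression filtering, z-scoring, k-means clustering, breadth, set algebra.

#' Filter lowly-expressed genes
#'
#' Retains genes whose row sum of FPKM is at least `min_sum` (genes with a
#' sum of FPKM below 3 are excluded by default).
#'
#' @param matrix nonnegative genes x samples FPKM matrix.
#' @param min_sum retention cutoff on the row sum.
#' @return list with `matrix` (retained rows) and `excluded` (gene ids).
#' @export
filter_expressed <- function(matrix, min_sum = 3) {
  if (any(matrix < 0)) stop("expression matrix must be nonnegative")
  keep <- rowSums(matrix) >= min_sum
  if (!any(keep)) warning("no genes pass the expression filter")
  list(matrix = matrix[keep, , drop = FALSE],
       excluded = rownames(matrix)[!keep])
}

#' Z-score rows of an expression matrix
#'
#' Each row is centred and scaled to unit sample standard deviation (n-1
#' denominator). Constant rows become all-zero rows, with a warning.
#'
#' @param matrix numeric matrix.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(matrix) {
  mu <- rowMeans(matrix)
  s <- apply(matrix, 1, sd)
  const <- s == 0 | !is.finite(s)
  if (any(const))
    warning(sum(const), " constant row(s) mapped to zero")
  s[const] <- 1
  z <- (matrix - mu) / s
  z[const, ] <- 0
  z
}

# k-means++ initial centres
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    nd <- rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' K-means clustering of expression profiles
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_init` restarts by
#' total within-cluster sum of squares; deterministic given `seed`.
#'
#' @param zmatrix genes x samples matrix (typically z-scored).
#' @param k number of clusters (>= 2; the stress and tissue analyses use
#'   k = 8 and k = 6 respectively).
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list of class `cluster_assignment`: `cluster` (named integer
#'   vector), `k`, `inertia`, `seed`, `centers`.
#' @export
kmeans_cluster <- function(zmatrix, k, seed = 1L, n_init = 10L,
                           max_iter = 300L) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(zmatrix)) stop("k exceeds the number of genes")
  with_seed(substream_seed(seed, "kmeans"), {
    best <- NULL
    for (i in seq_len(n_init)) {
      ctr <- .kmeanspp_centers(zmatrix, k)
      fit <- suppressWarnings(
        kmeans(zmatrix, centers = ctr, iter.max = max_iter,
               algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    structure(list(cluster = setNames(best$cluster, rownames(zmatrix)),
                   k = k, inertia = best$tot.withinss, seed = seed,
                   centers = best$centers),
              class = "cluster_assignment")
  })
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means assignment: k =", x$k, ", n =", length(x$cluster),
      ", inertia =", format(x$inertia), "\n")
  print(table(x$cluster))
  invisible(x)
}

#' Expression breadth index
#'
#' Replicates of a tissue are first averaged; a gene counts as expressed in
#' a tissue when its mean FPKM is strictly greater than `min_fpkm`. The
#' index is the number of expressing tissues divided by the number of
#' tissues: 0 = silent everywhere, 1 = broadly expressed, low values = high
#' tissue specificity.
#'
#' @param matrix genes x samples FPKM matrix.
#' @param tissues character vector, tissue label per column.
#' @param min_fpkm expression cutoff (strict >; default 1).
#' @return named numeric vector of per-gene breadth in `[0, 1]`.
#' @export
expression_index <- function(matrix, tissues, min_fpkm = 1) {
  stopifnot(length(tissues) == ncol(matrix))
  ut <- unique(tissues)
  if (!length(ut)) stop("no tissues")
  means <- vapply(ut, function(t)
    rowMeans(matrix[, tissues == t, drop = FALSE]),
    numeric(nrow(matrix)))
  if (is.null(dim(means))) means <- matrix(means, nrow = nrow(matrix))
  setNames(rowSums(means > min_fpkm) / length(ut), rownames(matrix))
}

#' Gene sets with high expression per label
#'
#' Maps cluster assignments through a cluster -> label map (e.g. cluster 3
#' -> "heat-induced") and returns the gene set per label.
#'
#' @param assignment a [kmeans_cluster()] result.
#' @param label_map named character vector, cluster id -> label (clusters
#'   missing from the map are ignored).
#' @return named list of gene-id character vectors.
#' @export
high_expression_sets <- function(assignment, label_map) {
  cl <- assignment$cluster
  out <- list()
  for (k in names(label_map)) {
    lab <- label_map[[k]]
    out[[lab]] <- sort(c(out[[lab]], names(cl)[cl == as.integer(k)]))
  }
  out
}

#' Intersect two gene sets (Venn counts)
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return list with `n_intersect`, `n_a_only`, `n_b_only` and the
#'   corresponding membership vectors.
#' @export
intersect_sets <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- sort(intersect(set_a, set_b))
  list(n_intersect = length(both),
       n_a_only = length(setdiff(set_a, set_b)),
       n_b_only = length(setdiff(set_b, set_a)),
       intersect = both,
       a_only = sort(setdiff(set_a, set_b)),
       b_only = sort(setdiff(set_b, set_a)))
}
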