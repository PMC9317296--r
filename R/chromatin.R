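# TSS-anchored multi-mark signal matrices and chromatin-state analysis.
#
# Coordinates are 0-based half-open. A bedGraph interval's value is a read
# count attributed uniformly over the interval, so a bin receives
# value * overlap/width; counts-per-million scales by 1e6 over the track's
# total count. Minus-strand genes are oriented 5'->3' (bin 1 = upstream).

#' Build a TSS-anchored signal matrix from bedGraph tracks
#'
#' Per gene and mark, counts are summed into `2*flank/bin_size` fixed bins
#' over `[TSS - flank, TSS + flank)`; bins falling off the chromosome start
#' are zero. Minus-strand bin order is reversed so every row reads
#' upstream -> downstream.
#'
#' @param tracks named list (one per mark) of bedGraph data.frames
#'   (`chrom`, `start`, `end`, `value`, sorted, non-overlapping).
#' @param genes gene table ([read_gff3()] schema: `gene`, `chrom`, `strand`,
#'   `tss`).
#' @param flank half-window in bp (default 2000).
#' @param bin_size bin width in bp (default 50).
#' @param norm `"cpm"` (counts per million of the track total) or `"raw"`.
#' @return object of class `signal_matrix`: list with `values` (named list
#'   mark -> genes x bins matrix), `genes`, `marks`, `flank`, `bin_size`,
#'   `norm`.
#' @export
tss_signal_matrix <- function(tracks, genes, flank = 2000L, bin_size = 50L,
                              norm = c("cpm", "raw")) {
  norm <- match.arg(norm)
  if ((2L * flank) %% bin_size != 0)
    stop("2*flank must be a multiple of bin_size")
  nb <- as.integer(2L * flank / bin_size)
  ng <- nrow(genes)
  bin_gene <- rep(seq_len(ng), each = nb)
  bin_idx <- rep(seq_len(nb), ng)
  # strand-symmetric anchor: a minus-strand window is [tss+1-flank,
  # tss+1+flank), so mirroring the genome maps windows onto windows exactly
  anchor <- ifelse(genes$strand == "-", genes$tss + 1L, genes$tss)
  bin_start <- anchor[bin_gene] - flank + (bin_idx - 1L) * bin_size
  ok <- bin_start >= 0
  values <- list()
  for (mk in names(tracks)) {
    tr <- tracks[[mk]]
    .check_bedgraph_disjoint(tr)
    m <- matrix(0, ng, nb, dimnames = list(genes$gene, NULL))
    missing_chr <- setdiff(unique(genes$chrom), unique(tr$chrom))
    if (length(missing_chr))
      warning("track ", mk, ": no coverage on ",
              paste(missing_chr, collapse = ", "), "; zeros used")
    if (nrow(tr)) {
      gr_bins <- GenomicRanges::GRanges(
        genes$chrom[bin_gene][ok],
        IRanges::IRanges(start = bin_start[ok] + 1L,
                         width = bin_size))
      gr_tr <- GenomicRanges::GRanges(
        tr$chrom, IRanges::IRanges(start = tr$start + 1L, end = tr$end))
      hits <- GenomicRanges::findOverlaps(gr_bins, gr_tr)
      if (length(hits)) {
        q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
        ovw <- GenomicRanges::width(GenomicRanges::pintersect(
          gr_bins[q], gr_tr[s]))
        contrib <- tr$value[s] * ovw / (tr$end[s] - tr$start[s])
        sums <- tapply(contrib, q, sum)
        flat <- which(ok)[as.integer(names(sums))]
        m[cbind(bin_gene[flat], bin_idx[flat])] <- as.numeric(sums)
      }
    }
    rev_rows <- genes$strand == "-"
    m[rev_rows, ] <- m[rev_rows, nb:1, drop = FALSE]
    if (norm == "cpm") {
      tot <- sum(tr$value)
      m <- if (tot > 0) m * 1e6 / tot else m
    }
    values[[mk]] <- m
  }
  structure(list(values = values, genes = genes$gene, marks = names(tracks),
                 flank = flank, bin_size = bin_size, norm = norm),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", length(x$genes), "genes x", length(x$marks),
      "marks x", 2 * x$flank / x$bin_size, "bins (", x$norm, ")\n")
  invisible(x)
}

#' Flatten a signal matrix to one wide genes x (marks*bins) matrix
#' @param sm a `signal_matrix`.
#' @param log1p apply `log(1+x)` (variance-stabilizing for count data).
#' @return numeric matrix.
#' @export
signal_wide <- function(sm, log1p = FALSE) {
  m <- do.call(cbind, sm$values)
  colnames(m) <- unlist(lapply(sm$marks, function(mk)
    paste0(mk, "_b", seq_len(ncol(sm$values[[mk]])))))
  if (log1p) m <- log1p(m)
  m
}

#' Cluster genes into chromatin states
#'
#' K-means (k-means++ seeding, multiple restarts) on the log(1+x)
#' transformed concatenation of all per-mark bin vectors. When fewer than
#' `k` distinct profiles exist the clustering is degenerate: all genes go to
#' one cluster, with a warning.
#'
#' @param sm a `signal_matrix`.
#' @param k number of sub-clusters (default 8).
#' @param seed integer seed.
#' @param ... passed to [kmeans_cluster()].
#' @return a `cluster_assignment` (see [kmeans_cluster()]).
#' @export
cluster_chromatin <- function(sm, k = 8L, seed = 1L, ...) {
  if (k < 2) stop("k must be >= 2")
  x <- signal_wide(sm, log1p = TRUE)
  if (nrow(unique(x)) < k) {
    warning("fewer than k distinct chromatin profiles; degenerate clustering")
    return(structure(list(cluster = setNames(rep(1L, nrow(x)), rownames(x)),
                          k = k, inertia = 0, seed = seed, centers = NULL,
                          degenerate = TRUE),
                     class = "cluster_assignment"))
  }
  kmeans_cluster(x, k = k, seed = seed, ...)
}

#' Call H3K4me3/H3K27me3 bivalent genes
#'
#' A gene is bivalent when its mean H3K4me3 signal and its mean H3K27me3
#' signal over the central +/- `summary_bp` around the TSS both exceed
#' their thresholds (strictly). Thresholds default to the cohort median per
#' mark; absolute overrides are available for calibrated data.
#'
#' @param sm a `signal_matrix` containing both marks.
#' @param k4_threshold,k27_threshold absolute thresholds, or NULL for the
#'   cohort median.
#' @param summary_bp half-width of the summary window (default 500).
#' @param k4_mark,k27_mark mark names.
#' @return data.frame `gene`, `k4`, `k27`, `bivalent`, with attributes
#'   `fraction`, `k4_threshold`, `k27_threshold`.
#' @export
call_bivalent <- function(sm, k4_threshold = NULL, k27_threshold = NULL,
                          summary_bp = 500L, k4_mark = "H3K4me3",
                          k27_mark = "H3K27me3") {
  if (!all(c(k4_mark, k27_mark) %in% sm$marks))
    stop("signal matrix lacks ", k4_mark, " or ", k27_mark)
  nb <- 2L * sm$flank / sm$bin_size
  lo <- (sm$flank - summary_bp) / sm$bin_size + 1L
  hi <- (sm$flank + summary_bp) / sm$bin_size
  idx <- max(1L, lo):min(nb, hi)
  k4 <- rowMeans(sm$values[[k4_mark]][, idx, drop = FALSE])
  k27 <- rowMeans(sm$values[[k27_mark]][, idx, drop = FALSE])
  if (is.null(k4_threshold)) k4_threshold <- median(k4)
  if (is.null(k27_threshold)) k27_threshold <- median(k27)
  biv <- k4 > k4_threshold & k27 > k27_threshold
  out <- data.frame(gene = sm$genes, k4 = k4, k27 = k27, bivalent = biv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fraction") <- mean(biv)
  attr(out, "k4_threshold") <- k4_threshold
  attr(out, "k27_threshold") <- k27_threshold
  out
}

#' Relate chromatin clusters to expression level and breadth
#'
#' Per-cluster medians of expression and breadth, plus pairwise two-sided
#' Mann-Whitney tests on expression between clusters. Clusters with fewer
#' than 2 genes are excluded from testing and reported.
#'
#' @param states named cluster vector (gene -> cluster id).
#' @param expression named numeric vector of per-gene expression levels.
#' @param breadth named numeric vector of per-gene expression breadth.
#' @return list with `summary` (data.frame cluster, n, median_expression,
#'   median_breadth), `tests` (data.frame cluster_1, cluster_2, U, p) and
#'   `excluded` (clusters too small to test).
#' @export
state_vs_expression <- function(states, expression, breadth = NULL) {
  cl <- sort(unique(states))
  genes_by <- split(names(states), states)
  summary <- data.frame(
    cluster = cl,
    n = lengths(genes_by)[as.character(cl)],
    median_expression = vapply(as.character(cl), function(c)
      median(expression[genes_by[[c]]], na.rm = TRUE), 0),
    median_breadth = if (is.null(breadth)) NA_real_ else
      vapply(as.character(cl), function(c)
        median(breadth[genes_by[[c]]], na.rm = TRUE), 0),
    stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  testable <- cl[summary$n >= 2]
  tests <- NULL
  if (length(testable) >= 2) {
    combs <- combn(as.character(testable), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- expression[genes_by[[combs[1, i]]]]
      b <- expression[genes_by[[combs[2, i]]]]
      mw <- mann_whitney_u(a[is.finite(a)], b[is.finite(b)])
      data.frame(cluster_1 = combs[1, i], cluster_2 = combs[2, i],
                 U = mw$U, p = mw$p, stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, tests = tests,
       excluded = setdiff(cl, testable))
}
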