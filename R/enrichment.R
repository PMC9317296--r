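# Hypergeometric over-representation tests with BH FDR.
#
# Flat annotations: terms are gene sets over a fixed universe, no ontology
# graph propagation. The test is one-sided (over-representation only).

# log-space upper-tail hypergeometric: P(X >= k) for X ~ Hypergeom(N, K, n)
.hyper_upper <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  lp <- lchoose(K, k:hi) + lchoose(N - K, n - (k:hi)) - lchoose(N, n)
  m <- max(lp)
  min(exp(m + log(sum(exp(lp - m)))), 1)
}

#' Hypergeometric enrichment of a query set against annotated terms
#'
#' For each term, tests whether the query set contains more term members
#' than expected under sampling without replacement from the universe:
#' upper-tail p = P(X >= k) with X ~ Hypergeometric(N, K, n), computed by
#' log-space summation. BH-adjusted q-values are added over the tested
#' terms.
#'
#' @param query character vector, the gene set of interest (must be a subset
#'   of `universe`).
#' @param universe character vector, the background gene set.
#' @param annotation data.frame with columns `gene`, `term` and optionally
#'   `label`; genes outside the universe are ignored, empty terms dropped
#'   with a warning.
#' @return data.frame `term`, `label`, `k`, `n`, `K`, `N`, `p`, `q`, sorted
#'   by q then p.
#' @export
hypergeom_enrich <- function(query, universe, annotation) {
  query <- unique(query); universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query genes outside the universe: ",
         paste(head(bad, 5), collapse = ", "))
  ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
  if (!"label" %in% names(ann)) ann$label <- NA_character_
  terms <- split(ann, ann$term)
  empty <- setdiff(unique(annotation$term), names(terms))
  if (length(empty))
    warning(length(empty), " term(s) with no universe member dropped")
  N <- length(universe); n <- length(query)
  out <- do.call(rbind, lapply(names(terms), function(tm) {
    g <- unique(terms[[tm]]$gene)
    k <- length(intersect(query, g))
    data.frame(term = tm, label = terms[[tm]]$label[1],
               k = k, n = n, K = length(g), N = N,
               p = .hyper_upper(k, N, length(g), n),
               stringsAsFactors = FALSE)
  }))
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the original input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Enrichment of gene families within the core set
#'
#' Runs the hypergeometric machinery with the core genes as query and each
#' family as a term, and ranks families by decreasing enrichment
#' (-log10 p).
#'
#' @param calls data.frame from [call_core()] (or any with `gene`,`status`).
#' @param family_map data.frame with columns `gene`, `family`.
#' @return data.frame as [hypergeom_enrich()] plus `neg_log10_p`, sorted by
#'   descending enrichment.
#' @export
family_enrich <- function(calls, family_map) {
  ann <- data.frame(gene = family_map$gene, term = family_map$family,
                    stringsAsFactors = FALSE)
  res <- hypergeom_enrich(calls$gene[calls$status == "core"],
                          calls$gene, ann)
  res$neg_log10_p <- -log10(pmax(res$p, .Machine$double.xmin))
  res[order(-res$neg_log10_p, res$term), , drop = FALSE]
}
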