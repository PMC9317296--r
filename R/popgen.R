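# Per-gene nucleotide diversity and two-population Hudson Fst.
#
# Fst uses Hudson's estimator combined as a ratio of averages over sites
# (Bhatia et al. 2013 recommendation): robust to rare variants and unbiased
# for small samples. Small negative per-gene estimates are retained, not
# clamped; classification uses a strict > 0.25 rule so they land in "low".

#' Per-gene nucleotide diversity (pi)
#'
#' Per site, unbiased expected heterozygosity `2 * ref * alt / (n * (n-1))`
#' with `n = ref + alt`; the gene value is the mean over retained sites.
#' Sites with `n < 2` are dropped with a warning; a gene with no retained
#' site gets `NA`.
#'
#' @param ref,alt nonnegative integer vectors of per-site allele counts for
#'   one population of one gene.
#' @return numeric scalar (mean per-site pi), or NA.
#' @export
nucleotide_diversity <- function(ref, alt) {
  stopifnot(length(ref) == length(alt), all(ref >= 0), all(alt >= 0))
  n <- ref + alt
  keep <- n >= 2
  if (any(!keep)) warning(sum(!keep), " site(s) with n < 2 dropped")
  if (!any(keep)) return(NA_real_)
  mean(2 * ref[keep] * alt[keep] / (n[keep] * (n[keep] - 1)))
}

#' Hudson Fst for one gene between two populations
#'
#' Ratio-of-averages estimator: numerator per site
#' `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`, each averaged over sites before taking the ratio.
#' Returns `NA` (missing, not 0) when the denominator is 0, e.g. for a gene
#' monomorphic in both populations.
#'
#' @param ref1,alt1,ref2,alt2 per-site allele counts of the two populations.
#' @return numeric scalar Fst (can be slightly negative), or NA.
#' @export
hudson_fst <- function(ref1, alt1, ref2, alt2) {
  n1 <- ref1 + alt1; n2 <- ref2 + alt2
  stopifnot(length(n1) == length(n2))
  keep <- n1 >= 2 & n2 >= 2
  if (any(!keep)) warning(sum(!keep), " site(s) with n < 2 dropped")
  if (!any(keep)) return(NA_real_)
  p1 <- (alt1 / n1)[keep]; p2 <- (alt2 / n2)[keep]
  n1 <- n1[keep]; n2 <- n2[keep]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (mean(den) == 0) return(NA_real_)
  mean(num) / mean(den)
}

#' Per-gene popgen statistics from a two-population allele-count table
#'
#' @param counts data.frame with columns `gene`, `site`, `pop1_ref`,
#'   `pop1_alt`, `pop2_ref`, `pop2_alt` (schema written by
#'   [simulate_population()]).
#' @return data.frame `gene`, `pi_pop1`, `pi_pop2`, `fst`.
#' @export
popgen_stats <- function(counts) {
  need <- c("gene", "pop1_ref", "pop1_alt", "pop2_ref", "pop2_alt")
  stopifnot(all(need %in% names(counts)))
  by_gene <- split(counts, counts$gene)
  out <- do.call(rbind, lapply(by_gene, function(d) data.frame(
    gene = d$gene[1],
    pi_pop1 = nucleotide_diversity(d$pop1_ref, d$pop1_alt),
    pi_pop2 = nucleotide_diversity(d$pop2_ref, d$pop2_alt),
    fst = hudson_fst(d$pop1_ref, d$pop1_alt, d$pop2_ref, d$pop2_alt),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Classify genes by population differentiation
#'
#' Strictly-greater rule: `fst > threshold` is "high" differentiation
#' (default 0.25); `NA` Fst values are excluded and counted separately.
#'
#' @param stats data.frame with `gene` and `fst` columns.
#' @param threshold differentiation cutoff.
#' @return data.frame `gene`, `fst`, `class` (high/low; NA rows dropped)
#'   with attributes `n_high` and `n_missing`.
#' @export
classify_differentiation <- function(stats, threshold = 0.25) {
  ok <- !is.na(stats$fst)
  out <- data.frame(gene = stats$gene[ok], fst = stats$fst[ok],
                    class = ifelse(stats$fst[ok] > threshold, "high", "low"),
                    stringsAsFactors = FALSE)
  attr(out, "n_high") <- sum(out$class == "high")
  attr(out, "n_missing") <- sum(!ok)
  attr(out, "threshold") <- threshold
  out
}
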