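# Codon-aware pairwise alignment and NG86 (Nei-Gojobori 1986) Ka/Ks.
#
# Conventions: mutations to stop codons count as nonsynonymous when counting
# sites; multi-hit codon pathways passing through a stop are excluded and
# the remaining shortest pathways weighted equally (all pathways are used in
# the rare case every one is blocked). Ka and Ks use the Jukes-Cantor
# correction; proportions >= 3/4 saturate and are reported missing.

.NTS <- c("A", "C", "G", "T")

# fraction of synonymous single-nt changes per position of one codon
.codon_syn_fraction <- function(codon, aa_of) {
  s <- strsplit(codon, "")[[1]]
  tot <- 0
  for (i in 1:3) {
    nsyn <- 0
    for (n in setdiff(.NTS, s[i])) {
      alt <- s; alt[i] <- n
      altc <- paste(alt, collapse = "")
      if (aa_of[[altc]] != "*" && aa_of[[altc]] == aa_of[[codon]])
        nsyn <- nsyn + 1
    }
    tot <- tot + nsyn / 3
  }
  tot
}

# syn/nonsyn differences between two codons, averaged over equally-weighted
# shortest mutational pathways (stop-free pathways when any exist)
.codon_diff_counts <- function(ca, cb, aa_of) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  walk <- function(cur, allow_stop) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      s <- strsplit(cur, "")[[1]]
      s[p] <- strsplit(cb, "")[[1]][p]
      nxt <- paste(s, collapse = "")
      if (!allow_stop && aa_of[[nxt]] == "*") next
      step <- if (aa_of[[nxt]] == aa_of[[cur]]) c(1, 0) else c(0, 1)
      for (rest in walk(nxt, allow_stop))
        out[[length(out) + 1L]] <- step + rest
    }
    out
  }
  paths <- if (aa_of[[ca]] != "*" && aa_of[[cb]] != "*") walk(ca, FALSE)
           else list()
  if (!length(paths)) paths <- walk(ca, TRUE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

.split_codons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0)
    stop("CDS length ", nchar(x), " is not a multiple of 3")
  n <- nchar(x) / 3
  substring(x, 3 * seq_len(n) - 2, 3 * seq_len(n))
}

#' Codon-aware pairwise alignment of two CDS
#'
#' Translates both sequences, globally aligns the proteins (affine-gap
#' Needleman-Wunsch, BLOSUM62), and back-translates gaps into codon
#' triplets. A terminal stop codon is trimmed; an internal stop is an error
#' with its codon position.
#'
#' @param cds_a,cds_b DNA sequences (character or DNAString), lengths
#'   multiples of 3.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return object of class `codon_alignment`: list with codon vectors `a`
#'   and `b` of equal length (gap codons are `"---"`).
#' @export
codon_align <- function(cds_a, cds_b, gap_opening = 10, gap_extension = 4) {
  ct <- .codon_table()
  aa_of <- setNames(ct$aa, ct$codons)
  prep <- function(x, which) {
    cod <- .split_codons(x)
    aa <- aa_of[cod]
    if (any(is.na(aa)))
      stop("non-ACGT codon in sequence ", which)
    stops <- which(aa == "*")
    if (length(stops) && stops[1] < length(cod))
      stop("internal stop codon in sequence ", which, " at codon ", stops[1])
    if (length(stops)) { cod <- cod[-length(cod)]; aa <- aa[-length(aa)] }
    list(cod = cod, aa = paste(aa, collapse = ""))
  }
  a <- prep(cds_a, "a"); b <- prep(cds_b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$aa), Biostrings::AAString(b$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pc <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  ca <- character(length(pc)); cb <- character(length(sc))
  for (i in seq_along(pc)) {
    if (pc[i] == "-") ca[i] <- "---" else { ia <- ia + 1L; ca[i] <- a$cod[ia] }
    if (sc[i] == "-") cb[i] <- "---" else { ib <- ib + 1L; cb[i] <- b$cod[ib] }
  }
  structure(list(a = ca, b = cb), class = "codon_alignment")
}

#' NG86 Ka/Ks from a codon alignment
#'
#' Nei-Gojobori (1986) counting on ungapped codon columns: synonymous site
#' fractions per codon averaged across the two sequences; observed
#' differences averaged over equally-weighted shortest mutational pathways
#' (stop-free when possible); `ps = Sd/S`, `pn = Nd/N`; Jukes-Cantor
#' correction `K = -(3/4) log(1 - (4/3) p)`. A proportion at or above 3/4
#' saturates the correction: the corresponding rate is `NA` and `saturated`
#' is set.
#'
#' @param alignment a [codon_align()] result (or a list with codon vectors
#'   `a` and `b`).
#' @return data.frame row of class `kaks_result`: `S`, `N`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ka`, `Ks`, `ka_ks` (NA when Ks is 0 or saturated),
#'   `n_codons` (ungapped), `saturated`.
#' @export
ng86_kaks <- function(alignment) {
  ct <- .codon_table()
  aa_of <- setNames(ct$aa, ct$codons)
  keep <- alignment$a != "---" & alignment$b != "---"
  a <- alignment$a[keep]; b <- alignment$b[keep]
  if (!length(a)) stop("no ungapped codon columns")
  syn_cache <- new.env(parent = emptyenv())
  synf <- function(cd) {
    if (is.null(syn_cache[[cd]]))
      syn_cache[[cd]] <- .codon_syn_fraction(cd, aa_of)
    syn_cache[[cd]]
  }
  Sa <- sum(vapply(a, synf, 0)); Sb <- sum(vapply(b, synf, 0))
  S <- (Sa + Sb) / 2
  N <- 3 * length(a) - S
  d <- vapply(seq_along(a), function(i)
    .codon_diff_counts(a[i], b[i], aa_of), c(sd = 0, nd = 0))
  Sd <- sum(d["sd", ]); Nd <- sum(d["nd", ])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps); Ka <- jc(pn)
  out <- data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                    Ka = Ka, Ks = Ks,
                    ka_ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0)
                      Ka / Ks else NA_real_,
                    n_codons = length(a),
                    saturated = is.na(Ka) || is.na(Ks))
  class(out) <- c("kaks_result", class(out))
  out
}

#' Ka/Ks for a table of CDS pairs
#'
#' @param pairs data.frame with `pair`, `gene_a`, `gene_b`.
#' @param cds DNAStringSet holding all member sequences.
#' @return data.frame, one [ng86_kaks()] row per pair plus `pair`.
#' @export
kaks_pairs <- function(pairs, cds) {
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    aln <- codon_align(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    cbind(data.frame(pair = pairs$pair[i], stringsAsFactors = FALSE),
          ng86_kaks(aln))
  }))
  rownames(out) <- NULL
  out
}

#' Classify homeolog triads by core status of their members
#'
#' A triad is `all_core` when all three members are core, otherwise
#' `mixed`. Pairwise (A-B, A-D, B-D) records carry the pair subtype
#' `core_core`, `core_noncore` or `noncore_noncore`. Triads with a member
#' missing from the core calls are skipped with a warning.
#'
#' @param triads data.frame `triad`, `gene_A`, `gene_B`, `gene_D`.
#' @param calls data.frame from [call_core()].
#' @return list with `triads` (adds `status_A/B/D`, `subtype`) and `pairs`
#'   (data.frame `triad`, `pair`, `gene_1`, `gene_2`, `status_1`,
#'   `status_2`, `subtype`).
#' @export
classify_triads <- function(triads, calls) {
  status <- setNames(calls$status, calls$gene)
  members <- c(triads$gene_A, triads$gene_B, triads$gene_D)
  miss <- rowSums(matrix(!(members %in% names(status)),
                         nrow = nrow(triads))) > 0
  if (any(miss))
    warning(sum(miss), " triad(s) skipped: member(s) missing from core calls")
  tr <- triads[!miss, , drop = FALSE]
  tr$status_A <- status[tr$gene_A]
  tr$status_B <- status[tr$gene_B]
  tr$status_D <- status[tr$gene_D]
  tr$subtype <- ifelse(tr$status_A == "core" & tr$status_B == "core" &
                         tr$status_D == "core", "all_core", "mixed")
  pair_def <- list(c("A", "B"), c("A", "D"), c("B", "D"))
  pairs <- do.call(rbind, lapply(pair_def, function(pd) {
    s1 <- tr[[paste0("status_", pd[1])]]
    s2 <- tr[[paste0("status_", pd[2])]]
    data.frame(triad = tr$triad, pair = paste(pd, collapse = "-"),
               gene_1 = tr[[paste0("gene_", pd[1])]],
               gene_2 = tr[[paste0("gene_", pd[2])]],
               status_1 = s1, status_2 = s2,
               subtype = ifelse(s1 == "core" & s2 == "core", "core_core",
                         ifelse(s1 != "core" & s2 != "core",
                                "noncore_noncore", "core_noncore")),
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  list(triads = tr, pairs = pairs)
}

#' Contrast core vs non-core members across homeolog pairs
#'
#' Within `core_noncore` pairs, compares per-gene values (e.g. mean FPKM) of
#' the core members against the non-core members by Mann-Whitney U; within
#' `core_core` pairs the two members form the (expected-null) contrast.
#' Optionally contrasts a per-pair value (e.g. Ka/Ks) between `core_core`
#' and `core_noncore` pairs. Groups with fewer than 2 observations skip the
#' test.
#'
#' @param pairs pair table from [classify_triads()].
#' @param gene_values named numeric vector of per-gene values.
#' @param pair_values optional named numeric vector of per-pair values
#'   (names = pair row key `triad:pair`).
#' @return list of contrasts, each with group medians, `U` and `p`.
#' @export
compare_pair_groups <- function(pairs, gene_values, pair_values = NULL) {
  res <- list()
  contrast <- function(a, b) {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2)
      return(list(median_1 = median(a), median_2 = median(b),
                  U = NA, p = NA, skipped = TRUE))
    mw <- mann_whitney_u(a, b)
    list(median_1 = median(a), median_2 = median(b),
         U = mw$U, p = mw$p, skipped = FALSE)
  }
  cn <- pairs[pairs$subtype == "core_noncore", , drop = FALSE]
  if (nrow(cn)) {
    core_member <- ifelse(cn$status_1 == "core", cn$gene_1, cn$gene_2)
    non_member <- ifelse(cn$status_1 == "core", cn$gene_2, cn$gene_1)
    res$core_vs_noncore <- contrast(gene_values[core_member],
                                    gene_values[non_member])
  }
  cc <- pairs[pairs$subtype == "core_core", , drop = FALSE]
  if (nrow(cc))
    res$core_core_within <- contrast(gene_values[cc$gene_1],
                                     gene_values[cc$gene_2])
  if (!is.null(pair_values)) {
    key <- paste(pairs$triad, pairs$pair, sep = ":")
    res$pair_value_by_subtype <- contrast(
      pair_values[key[pairs$subtype == "core_core"]],
      pair_values[key[pairs$subtype == "core_noncore"]])
  }
  res
}
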