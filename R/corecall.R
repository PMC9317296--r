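# Reference-guided core/dispensable gene classification.
#
# A reference gene is "present" in a variety when its best protein hit
# passes both the similarity and the coverage threshold (defaults 90% / 80%
# of the reference protein length), and "core" when present in at least 80%
# of varieties. Identity and coverage are anchored on the reference length,
# so a truncated variety copy fails coverage even at perfect identity.

.valid_aa <- function(seqs) {
  ok <- !grepl(sprintf("[^%s]", paste(.aa_alphabet(), collapse = "")),
               as.character(seqs))
  ok & Biostrings::width(seqs) > 0
}

.kmer_table <- function(seqs, k) {
  kms <- lapply(as.character(seqs), function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(character(0))
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  })
  data.table::data.table(id = rep(names(seqs), lengths(kms)),
                         kmer = unlist(kms, use.names = FALSE))
}

# identity / coverage for a set of (reference, candidate) pairs, computed
# from one vectorized batch of global alignments. Identity = identical
# aligned residue pairs / reference length; coverage = reference residues
# inside the subject's aligned (non-terminal-gap) region / reference length,
# which is exactly the non-gap width of the clipped pattern view.
.align_pairs <- function(reference, variety, ref_ids, cand_ids,
                         gap_opening, gap_extension) {
  aln <- Biostrings::pairwiseAlignment(
    reference[ref_ids], variety[cand_ids], type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  ref_len <- Biostrings::width(reference)[match(ref_ids, names(reference))]
  pv <- as.character(Biostrings::pattern(aln))
  data.frame(identity = Biostrings::nmatch(aln) / ref_len,
             coverage = nchar(gsub("-", "", pv, fixed = TRUE)) / ref_len)
}

#' Best-hit search of reference proteins against one variety proteome
#'
#' Candidate variety proteins sharing at least `min_shared_kmers` distinct
#' k-mers with the reference protein are globally aligned (affine-gap
#' Needleman-Wunsch, BLOSUM62). Identity is the count of identical aligned
#' residue pairs divided by the reference length; coverage is the fraction
#' of reference residues inside the subject's aligned (non-terminal-gap)
#' region. The candidate maximizing identity wins (ties: higher coverage,
#' then lexicographically smallest id). References without candidates get an
#' absent hit with identity = coverage = 0.
#'
#' @param reference AAStringSet of reference proteins.
#' @param variety AAStringSet of one variety's proteins.
#' @param kmer_len k-mer length for the prefilter.
#' @param min_shared_kmers minimum shared distinct k-mers to align a pair.
#' @param exhaustive if TRUE, skip the prefilter and align all pairs.
#' @param gap_opening,gap_extension affine gap penalties.
#' @return data.frame `ref_gene`, `hit` (NA when absent), `identity`,
#'   `coverage`.
#' @export
best_hit_search <- function(reference, variety, kmer_len = 5L,
                            min_shared_kmers = 3L, exhaustive = FALSE,
                            gap_opening = 10, gap_extension = 4) {
  if (!length(reference) || !length(variety))
    stop("empty proteome")
  okr <- .valid_aa(reference)
  okv <- .valid_aa(variety)
  if (any(!okr)) warning("dropping ", sum(!okr),
                         " invalid/empty reference records")
  if (any(!okv)) warning("dropping ", sum(!okv),
                         " invalid/empty variety records")
  reference <- reference[okr]; variety <- variety[okv]
  ref_ids <- sort(names(reference))
  if (exhaustive) {
    cand <- expand.grid(ref = ref_ids, cand = names(variety),
                        stringsAsFactors = FALSE)
  } else {
    rk <- .kmer_table(reference, kmer_len)
    vk <- .kmer_table(variety, kmer_len)
    data.table::setkey(vk, kmer)
    j <- vk[rk, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
    shared <- j[, list(N = .N), by = list(ref = i.id, cand = id)]
    cand <- as.data.frame(shared[shared$N >= min_shared_kmers,
                                 c("ref", "cand")])
  }
  out <- data.frame(ref_gene = ref_ids, hit = NA_character_,
                    identity = 0, coverage = 0, stringsAsFactors = FALSE)
  if (nrow(cand)) {
    cand <- cand[order(cand$ref, cand$cand), , drop = FALSE]
    stats <- .align_pairs(reference, variety, cand$ref, cand$cand,
                          gap_opening, gap_extension)
    cand$identity <- stats$identity; cand$coverage <- stats$coverage
    best <- do.call(rbind, lapply(split(cand, cand$ref), function(d) {
      d <- d[order(-d$identity, -d$coverage, d$cand), , drop = FALSE]
      d[1, , drop = FALSE]
    }))
    idx <- match(best$ref, out$ref_gene)
    out$hit[idx] <- best$cand
    out$identity[idx] <- best$identity
    out$coverage[idx] <- best$coverage
  }
  rownames(out) <- NULL
  out
}

#' Best-hit search across all variety proteomes
#'
#' @param reference AAStringSet of reference proteins.
#' @param varieties named list of AAStringSet, one per variety.
#' @param ... passed to [best_hit_search()].
#' @return data.frame `ref_gene`, `variety`, `hit`, `identity`, `coverage`
#'   with one row per (reference gene, variety).
#' @export
best_hits_all <- function(reference, varieties, ...) {
  stopifnot(length(names(varieties)) == length(varieties))
  do.call(rbind, lapply(names(varieties), function(v) {
    h <- best_hit_search(reference, varieties[[v]], ...)
    cbind(data.frame(ref_gene = h$ref_gene, variety = v,
                     stringsAsFactors = FALSE),
          h[, c("hit", "identity", "coverage")])
  }))
}

#' Build the gene x variety presence matrix
#'
#' Presence requires identity >= `s` AND coverage >= `c` (inclusive
#' thresholds). Pairs absent from `hits` count as absent.
#'
#' @param hits data.frame from [best_hits_all()].
#' @param s similarity threshold (default 0.90).
#' @param c coverage threshold (default 0.80).
#' @return logical matrix (genes x varieties) of class `presence_matrix`
#'   with thresholds stored in attributes `s` and `c`.
#' @export
build_presence_matrix <- function(hits, s = 0.90, c = 0.80) {
  if (s < 0 || s > 1 || c < 0 || c > 1)
    stop("thresholds s and c must lie in [0, 1]")
  genes <- sort(unique(hits$ref_gene))
  vars <- sort(unique(hits$variety))
  m <- matrix(FALSE, length(genes), length(vars),
              dimnames = list(genes, vars))
  pres <- hits$identity >= s & hits$coverage >= c & !is.na(hits$hit)
  m[cbind(match(hits$ref_gene, genes), match(hits$variety, vars))] <- pres
  structure(m, s = s, c = c, class = c("presence_matrix", class(m)))
}

#' Call core vs dispensable genes from a presence matrix
#'
#' A gene is core when its presence count reaches the smallest integer at or
#' above `t * n_varieties` (literal "at least `t`" reading, so 13 of 16
#' varieties passes at t = 0.80).
#'
#' @param matrix a `presence_matrix` (or plain logical matrix).
#' @param t presence threshold in (0, 1].
#' @return data.frame `gene`, `presence_count`, `status` with attribute
#'   `presence_threshold`.
#' @export
call_core <- function(matrix, t = 0.80) {
  if (t <= 0 || t > 1) stop("presence threshold t must lie in (0, 1]")
  if (ncol(matrix) < 1) stop("need at least one variety column")
  quorum <- ceiling(t * ncol(matrix) - 1e-9)
  cnt <- rowSums(matrix)
  out <- data.frame(gene = rownames(matrix), presence_count = as.integer(cnt),
                    status = ifelse(cnt >= quorum, "core", "dispensable"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "presence_threshold") <- t
  out
}

#' Per-subgenome core-gene counts and fractions
#'
#' @param calls data.frame from [call_core()].
#' @param subgenome_map named character vector gene -> subgenome label.
#' @return data.frame `subgenome`, `n_core`, `fraction` (fractions sum to 1
#'   over assigned core genes); unassigned core genes are reported in the
#'   `n_unassigned` attribute.
#' @export
subgenome_partition <- function(calls, subgenome_map) {
  core <- calls$gene[calls$status == "core"]
  sub <- subgenome_map[core]
  n_un <- sum(is.na(sub))
  tab <- table(sub[!is.na(sub)])
  out <- data.frame(subgenome = names(tab), n_core = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- n_un
  out
}
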