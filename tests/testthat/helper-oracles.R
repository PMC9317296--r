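# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force (full DP, explicit pathway enumeration) rather
# than calling the package's own code paths.

.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Gotoh affine-gap global alignment score; gap of length L costs
# open + L * ext (the Biostrings convention).
gotoh_score <- function(a, b, open = 10, ext = 4, mat = .blosum62) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- mat[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

.gc <- Biostrings::GENETIC_CODE
.sense_codons <- names(.gc)[.gc != "*"]

# NG86 per-codon synonymous site count by direct enumeration
ng86_sites_oracle <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  syn <- 0
  for (i in 1:3) for (n in setdiff(c("A", "C", "G", "T"), s[i])) {
    alt <- s; alt[i] <- n
    altc <- paste(alt, collapse = "")
    if (.gc[[altc]] != "*" && .gc[[altc]] == .gc[[codon]]) syn <- syn + 1 / 3
  }
  c(S = syn, N = 3 - syn)
}

.perms <- list(`1` = list(1L),
               `2` = list(c(1L, 2L), c(2L, 1L)),
               `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                          c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# NG86 pathway counts by explicit enumeration of all orderings of the
# differing positions; pathways through stop codons are dropped (all kept
# when every pathway is blocked)
ng86_paths_oracle <- function(ca, cb) {
  if (ca == cb) return(c(sd = 0, nd = 0))
  da <- strsplit(ca, "")[[1]]; db <- strsplit(cb, "")[[1]]
  pos <- which(da != db)
  enumerate <- function(drop_stops) {
    res <- list()
    for (ord in .perms[[as.character(length(pos))]]) {
      cur <- da; sd <- 0; nd <- 0; valid <- TRUE
      for (p in pos[ord]) {
        nxt <- cur; nxt[p] <- db[p]
        cfrom <- paste(cur, collapse = ""); cto <- paste(nxt, collapse = "")
        if (drop_stops && .gc[[cto]] == "*") { valid <- FALSE; break }
        if (.gc[[cto]] == .gc[[cfrom]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (valid) res[[length(res) + 1L]] <- c(sd, nd)
    }
    res
  }
  paths <- if (.gc[[ca]] != "*" && .gc[[cb]] != "*") enumerate(TRUE)
           else list()
  if (!length(paths)) paths <- enumerate(FALSE)
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

# full NG86 oracle over two aligned gap-free codon vectors
ng86_oracle <- function(codons_a, codons_b) {
  sites_a <- sum(vapply(codons_a, function(c) ng86_sites_oracle(c)["S"], 0))
  sites_b <- sum(vapply(codons_b, function(c) ng86_sites_oracle(c)["S"], 0))
  S <- (sites_a + sites_b) / 2
  d <- vapply(seq_along(codons_a), function(i)
    ng86_paths_oracle(codons_a[i], codons_b[i]), c(sd = 0, nd = 0))
  c(S = S, N = 3 * length(codons_a) - S,
    Sd = sum(d["sd", ]), Nd = sum(d["nd", ]))
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), len, TRUE),
        collapse = "")
}

random_codons <- function(n) sample(.sense_codons, n, TRUE)

# small pan-genome proteome pair for search tests: families of mutated
# copies so real best hits exist
random_proteome_pair <- function(n_genes, len_range = c(60, 100),
                                 divergence = 0.1) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  ref <- character(n_genes)
  var <- character(n_genes)
  for (i in seq_len(n_genes)) {
    L <- sample(len_range[1]:len_range[2], 1)
    s <- sample(aa, L, TRUE)
    ref[i] <- paste(s, collapse = "")
    nmut <- rbinom(1, L, divergence)
    if (nmut > 0) {
      pos <- sample(L, nmut)
      for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
    }
    var[i] <- paste(s, collapse = "")
  }
  list(reference = Biostrings::AAStringSet(setNames(ref,
         sprintf("R%03d", seq_len(n_genes)))),
       variety = Biostrings::AAStringSet(setNames(var,
         sprintf("V%03d", seq_len(n_genes)))))
}

# adjusted Rand index via the independent mclust implementation
ari_oracle <- function(a, b) mclust::adjustedRandIndex(a, b)
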