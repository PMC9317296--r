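test_that("codon alignment handles identity, indels, frame and stop errors", {
  a <- "ATGAAACCCGGG"
  aln <- codon_align(a, a)
  expect_equal(aln$a, aln$b)
  expect_false(any(aln$a == "---"))
  # one inserted codon becomes one 3-nt gap
  b <- "ATGAAATTTCCCGGG"
  aln2 <- codon_align(a, b)
  expect_equal(sum(aln2$a == "---"), 1)
  expect_equal(sum(aln2$b == "---"), 0)
  expect_error(codon_align("ATGA", a), "multiple of 3")
  expect_error(codon_align("ATGTAACCC", a), "internal stop codon.*codon 2")
  # terminal stop is trimmed, not an error
  expect_silent(codon_align("ATGAAATAA", "ATGAAA"))
})

test_that("protein-level alignment score matches the brute-force DP oracle", {
  set.seed(12)
  for (i in 1:8) {
    ca <- random_codons(sample(10:30, 1))
    cb <- ca
    # a few substitutions keep the pair alignable
    idx <- sample(length(cb), 3)
    cb[idx] <- sample(.sense_codons, 3, TRUE)
    pa <- paste(.gc[ca], collapse = ""); pb <- paste(.gc[cb], collapse = "")
    s <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4))
    expect_equal(s, gotoh_score(pa, pb), tolerance = 1e-9)
  }
})

test_that("NG86 counting agrees with explicit pathway enumeration", {
  set.seed(14)
  for (i in 1:40) {
    ca <- random_codons(1); cb <- random_codons(1)
    mine <- pancore:::.codon_diff_counts(ca, cb,
                                         setNames(.gc, names(.gc)))
    orc <- ng86_paths_oracle(ca, cb)
    expect_equal(unname(mine), unname(orc), tolerance = 1e-10,
                 label = paste(ca, cb))
  }
  # whole-alignment agreement on a random gap-free pair
  n <- 40
  ca <- random_codons(n)
  cb <- ca
  idx <- sample(n, 10)
  cb[idx] <- sample(.sense_codons, 10, TRUE)
  kk <- ng86_kaks(list(a = ca, b = cb))
  orc <- ng86_oracle(ca, cb)
  expect_equal(kk$S, unname(orc["S"]), tolerance = 1e-10)
  expect_equal(kk$N, unname(orc["N"]), tolerance = 1e-10)
  expect_equal(kk$Sd, unname(orc["Sd"]), tolerance = 1e-10)
  expect_equal(kk$Nd, unname(orc["Nd"]), tolerance = 1e-10)
})

test_that("NG86 site counts conserve and the estimator is symmetric", {
  set.seed(16)
  ca <- random_codons(30)
  cb <- ca; cb[1:6] <- sample(.sense_codons, 6, TRUE)
  kab <- ng86_kaks(list(a = ca, b = cb))
  kba <- ng86_kaks(list(a = cb, b = ca))
  expect_equal(kab$S + kab$N, 3 * 30, tolerance = 1e-9)
  for (f in c("S", "N", "Sd", "Nd", "Ka", "Ks"))
    expect_equal(kab[[f]], kba[[f]], tolerance = 1e-12)
  # identical sequences: zero rates, undefined ratio
  k0 <- ng86_kaks(list(a = ca, b = ca))
  expect_equal(k0$Ka, 0); expect_equal(k0$Ks, 0)
  expect_true(is.na(k0$ka_ks))
  # saturation flagged missing, not clamped
  far <- ng86_kaks(list(a = rep("TTA", 30), b = rep("CGG", 30)))
  expect_true(far$saturated)
})

test_that("triad subtype classification follows member core status", {
  triads <- data.frame(triad = c("t1", "t2", "t3"),
                       gene_A = c("a1", "a2", "a3"),
                       gene_B = c("b1", "b2", "b3"),
                       gene_D = c("d1", "d2", "d3"))
  calls <- data.frame(
    gene = c("a1", "b1", "d1", "a2", "b2", "d2", "a3", "b3"),
    presence_count = 10,
    status = c("core", "core", "core", "core", "dispensable", "core",
               "core", "core"))
  expect_warning(cl <- classify_triads(triads, calls), "skipped")
  expect_equal(cl$triads$subtype, c("all_core", "mixed"))
  p2 <- cl$pairs[cl$pairs$triad == "t2", ]
  expect_equal(sort(p2$subtype), c("core_core", "core_noncore",
                                   "core_noncore"))
  p1 <- cl$pairs[cl$pairs$triad == "t1", ]
  expect_true(all(p1$subtype == "core_core"))
})

test_that("pair-group contrasts are calibrated under the null and powered under shift", {
  triads <- data.frame(triad = sprintf("t%03d", 1:100),
                       gene_A = sprintf("a%03d", 1:100),
                       gene_B = sprintf("b%03d", 1:100),
                       gene_D = sprintf("d%03d", 1:100))
  calls <- data.frame(gene = c(triads$gene_A, triads$gene_B, triads$gene_D),
                      presence_count = 10,
                      status = rep(c("core", "dispensable", "core"),
                                   each = 100))
  cl <- classify_triads(triads, calls)
  # null: both members drawn from the same distribution
  set.seed(18)
  null_p <- replicate(40, {
    vals <- setNames(rnorm(300), calls$gene)
    compare_pair_groups(cl$pairs, vals)$core_vs_noncore$p
  })
  expect_gte(mean(null_p > 0.01), 0.95)
  # power: core members shifted +2 SD
  vals <- setNames(c(rnorm(100, 2), rnorm(100, 0), rnorm(100, 2)),
                   calls$gene)
  res <- compare_pair_groups(cl$pairs, vals)
  expect_lt(res$core_vs_noncore$p, 1e-4)
  expect_gt(res$core_vs_noncore$median_1, res$core_vs_noncore$median_2)
})
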