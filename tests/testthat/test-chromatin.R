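# two genes on one chromosome, opposite strands, plus hand-made tracks
.toy_genes <- function() {
  data.frame(gene = c("gp", "gm"), chrom = "chr1",
             start = c(5000L, 20000L), end = c(7000L, 22000L),
             strand = c("+", "-"),
             tss = c(5000L, 21999L), subgenome = "A",
             stringsAsFactors = FALSE)
}

test_that("signal matrix geometry, CPM and strand orientation are exact", {
  genes <- .toy_genes()
  # uniform coverage: one interval of constant depth across both windows
  tr <- data.frame(chrom = "chr1", start = 0L, end = 30000L, value = 300)
  sm <- tss_signal_matrix(list(M = tr), genes)
  expect_equal(ncol(sm$values$M), 80)   # 2*2000/50
  expect_true(all(abs(sm$values$M - sm$values$M[1, 1]) < 1e-9))
  # signal strictly upstream of the minus-strand TSS in genome coordinates
  # (to the right of tss) must appear in UPSTREAM (leading) oriented bins
  tr2 <- data.frame(chrom = "chr1", start = 22100L, end = 22150L, value = 50)
  sm2 <- tss_signal_matrix(list(M = tr2), genes, norm = "raw")
  row <- sm2$values$M["gm", ]
  expect_true(all(row[41:80] == 0))
  expect_gt(sum(row[1:40]), 0)
  # same interval for a plus-strand gene would be downstream
  genes_p <- genes; genes_p$strand <- "+"; genes_p$tss <- genes_p$start
  tr3 <- data.frame(chrom = "chr1", start = 20100L, end = 20150L, value = 50)
  sm3 <- tss_signal_matrix(list(M = tr3), genes_p, norm = "raw")
  expect_gt(sum(sm3$values$M["gm", 41:80]), 0)
})

test_that("raw bin sums conserve the track counts overlapping each window", {
  cfg <- sim_config(seed = 27, n_families = 40)
  genes <- simulate_gene_models(sprintf("G%04d", 1:40), cfg)
  sim <- simulate_chromatin(cfg, genes)
  sm <- tss_signal_matrix(sim$tracks, genes, norm = "raw")
  tr <- sim$tracks$H3K4me3
  for (i in c(1, 10, 25)) {
    g <- genes[i, ]
    anchor <- if (g$strand == "-") g$tss + 1 else g$tss
    win <- tr$chrom == g$chrom & tr$start >= anchor - 2000 &
      tr$end <= anchor + 2000
    expect_equal(sum(sm$values$H3K4me3[g$gene, ]), sum(tr$value[win]),
                 tolerance = 1e-9)
  }
})

test_that("mirroring the genome leaves oriented signal rows unchanged", {
  cfg <- sim_config(seed = 29, n_families = 20)
  genes <- simulate_gene_models(sprintf("G%04d", 1:20), cfg)
  sim <- simulate_chromatin(cfg, genes)
  sm <- tss_signal_matrix(sim$tracks, genes, norm = "raw")
  L <- 10000000L
  mgenes <- genes
  mgenes$start <- L - genes$end
  mgenes$end <- L - genes$start
  mgenes$strand <- ifelse(genes$strand == "+", "-", "+")
  mgenes$tss <- ifelse(mgenes$strand == "+", mgenes$start, mgenes$end - 1L)
  mtracks <- lapply(sim$tracks, function(tr) {
    out <- data.frame(chrom = tr$chrom, start = L - tr$end,
                      end = L - tr$start, value = tr$value)
    out[order(out$chrom, out$start), ]
  })
  msm <- tss_signal_matrix(mtracks, mgenes, norm = "raw")
  for (mk in sm$marks)
    expect_equal(msm$values[[mk]], sm$values[[mk]], tolerance = 1e-9)
})

test_that("chromatin clustering recovers planted states and degenerates safely", {
  cfg <- sim_config(seed = 33, n_families = 90,
                    state_fractions = c(active = 0.34, bivalent = 0.33,
                                        polycomb = 0.33, quiescent = 0))
  genes <- simulate_gene_models(sprintf("G%04d", 1:90), cfg)
  sim <- simulate_chromatin(cfg, genes)
  sm <- tss_signal_matrix(sim$tracks, genes)
  cl <- cluster_chromatin(sm, k = 3, seed = 2)
  expect_equal(adjusted_rand_index(cl$cluster, sim$truth[names(cl$cluster)]), 1)
  expect_identical(cl$cluster, cluster_chromatin(sm, k = 3, seed = 2)$cluster)
  # identical profiles: degenerate, reported
  flat <- sm
  for (mk in flat$marks) flat$values[[mk]][] <- 1
  expect_warning(dcl <- cluster_chromatin(flat, k = 2, seed = 1),
                 "degenerate")
  expect_true(all(dcl$cluster == 1))
  expect_error(cluster_chromatin(sm, k = 1), "k must be")
})

test_that("bivalency calling flags the planted co-marked genes", {
  cfg <- sim_config(seed = 35, n_families = 120)
  genes <- simulate_gene_models(sprintf("G%04d", 1:120), cfg)
  sim <- simulate_chromatin(cfg, genes)
  sm <- tss_signal_matrix(sim$tracks, genes, norm = "raw")
  biv <- call_bivalent(sm, k4_threshold = 5, k27_threshold = 5)
  truth_biv <- names(sim$truth)[sim$truth == "bivalent"]
  expect_setequal(biv$gene[biv$bivalent], truth_biv)
  # raising either threshold never adds bivalent genes
  for (thr in list(c(8, 5), c(5, 8), c(12, 12))) {
    b2 <- call_bivalent(sm, k4_threshold = thr[1], k27_threshold = thr[2])
    expect_true(all(b2$gene[b2$bivalent] %in% biv$gene[biv$bivalent]))
  }
  expect_error(call_bivalent(structure(list(marks = "H3K4me3"),
                                       class = "signal_matrix")), "lacks")
})

test_that("state-vs-expression summaries rank planted low-breadth states last", {
  set.seed(6)
  states <- setNames(rep(c("biv", "act"), each = 40),
                     sprintf("g%02d", 1:80))
  expr <- setNames(c(rnorm(40, 2), rnorm(40, 10)), names(states))
  breadth <- setNames(c(runif(40, 0, 0.3), runif(40, 0.7, 1)), names(states))
  sve <- state_vs_expression(states, expr, breadth)
  s <- sve$summary
  expect_equal(s$cluster[which.min(s$median_breadth)], "biv")
  expect_lt(sve$tests$p[1], 1e-6)
  # tiny cluster excluded from testing
  states2 <- c(states, g99 = "solo")
  sve2 <- state_vs_expression(states2, c(expr, g99 = 1), c(breadth, g99 = 1))
  expect_equal(sve2$excluded, "solo")
})

test_that("Mann-Whitney U: exact enumeration, ties, and approximation", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)  # 2/20 arrangements at least as extreme
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2, 2))$p, 1)
  set.seed(8)
  expect_lt(mann_whitney_u(rnorm(100), rnorm(100, 5))$p, 1e-10)
  # exact and approximate p agree closely for small tie-free samples
  for (i in 1:20) {
    a <- sample(seq(0.01, 1, 0.01), sample(3:6, 1))
    b <- sample(seq(1.005, 2, 0.013), sample(3:6, 1))
    pe <- mann_whitney_u(a, b, exact = TRUE)$p
    pa <- mann_whitney_u(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.03)
  }
})
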