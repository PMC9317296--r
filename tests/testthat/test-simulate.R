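test_that("pan-genome generator plants core/dispensable structure and is deterministic", {
  cfg <- sim_config(seed = 11, n_varieties = 4, n_families = 2,
                    core_fraction = 0.5, aa_divergence = 0,
                    trunc_fraction = 0)
  pan <- simulate_pangenome(cfg)
  expect_setequal(pan$truth$status, c("core", "dispensable"))
  core_gene <- pan$truth$gene[pan$truth$status == "core"]
  # zero divergence: the core family is present in all 4 varieties as an
  # identical copy
  copies <- vapply(pan$varieties, function(v) {
    id <- paste0(sub("_.*", "", names(v)[1]), "_", core_gene)
    if (id %in% names(v)) as.character(v[[id]]) else NA_character_
  }, "")
  expect_true(all(!is.na(copies)))
  expect_true(all(copies == as.character(pan$reference[[core_gene]])))
  disp <- pan$truth[pan$truth$status == "dispensable", ]
  expect_true(all(disp$presence_count < 4))

  # same seed, byte-identical FASTA output
  d1 <- tempfile(); d2 <- tempfile()
  simulate_pangenome(cfg, outdir = d1)
  simulate_pangenome(cfg, outdir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  expect_error(sim_config(n_families = 10, core_fraction = 0.55),
               "not an integer")
})

test_that("substitution counts match the binomial expectation", {
  cfg <- sim_config(seed = 5, n_varieties = 4, n_families = 250,
                    core_fraction = 1, aa_divergence = 0.05,
                    protein_length_range = c(200L, 200L), trunc_fraction = 0)
  pan <- simulate_pangenome(cfg)
  refs <- as.character(pan$reference)
  nsub <- unlist(lapply(names(pan$varieties), function(v) {
    copies <- as.character(pan$varieties[[v]])
    genes <- sub("^[^_]*_", "", names(copies))
    mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
           refs[genes], copies)
  }))
  # 1000 copies of length 200 at rate 0.05: mean 10, binomial SD sqrt(9.5)
  expect_lt(abs(mean(nsub) - 10), 3 * sqrt(200 * 0.05 * 0.95 / length(nsub)))
})

test_that("expression generator reproduces templates at zero noise and plants silent genes", {
  cfg <- sim_config(seed = 2, noise_sd = 0, n_genes_expr = 21L)
  ex <- simulate_expression(cfg)
  tpl <- pancore:::.default_templates(cfg$sample_design$group)
  g1 <- rownames(ex$matrix)[1]
  expect_equal(unname(ex$matrix[g1, ]),
               unname(tpl[ex$truth[g1], rep(cfg$sample_design$group,
                                            cfg$sample_design$n_rep)]))
  expect_error(sim_config(noise_sd = -1), "noise_sd")

  # an all-zero template lands under the sum-FPKM filter
  tpl2 <- rbind(tpl, silent = 0)
  ex2 <- simulate_expression(cfg, templates = tpl2)
  flt <- filter_expressed(ex2$matrix, min_sum = 3)
  silent <- names(ex2$truth)[ex2$truth == "silent"]
  expect_setequal(flt$excluded, silent)
})

test_that("chromatin generator respects templates, strand and calibration", {
  cfg <- sim_config(seed = 9, n_families = 60)
  genes <- simulate_gene_models(sprintf("G%04d", 1:60), cfg)
  # a state with Poisson mean 0 for a mark emits no counts at all
  cfg0 <- sim_config(seed = 9, n_families = 60,
                     chromatin_states = list(
                       active = c(H3K4me3 = 20, H3K27me3 = 0),
                       quiet = c(H3K4me3 = 0, H3K27me3 = 0)),
                     state_fractions = c(active = 1, quiet = 0),
                     marks = c("H3K4me3", "H3K27me3"))
  sim0 <- simulate_chromatin(cfg0, genes)
  expect_equal(nrow(sim0$tracks$H3K27me3), 0)
  expect_gt(nrow(sim0$tracks$H3K4me3), 0)
  sim <- simulate_chromatin(cfg, genes)
  # bedGraph coordinates ascend per chromosome even for minus-strand genes
  for (tr in sim$tracks)
    for (ch in unique(tr$chrom)) {
      s <- tr$start[tr$chrom == ch]
      expect_true(all(diff(s) > 0))
    }
  expect_error(
    simulate_chromatin(sim_config(chromatin_states = list(
      bad = c(H3K4me3 = -1))), genes), "negative")
})

test_that("population generator hits planted Fst and is reproducible", {
  cfg <- sim_config(seed = 13, n_chrom_pop = 50, n_sites_popgen = 50)
  ids <- sprintf("G%03d", 1:200)
  pop0 <- simulate_population(cfg, gene_ids = ids, target_fst = rep(0, 200))
  st0 <- popgen_stats(pop0$counts)
  expect_lt(abs(mean(st0$fst, na.rm = TRUE)), 0.02)
  pop0b <- simulate_population(cfg, gene_ids = ids, target_fst = rep(0, 200))
  expect_identical(pop0$counts, pop0b$counts)
  expect_error(simulate_population(sim_config(n_chrom_pop = 1)),
               "at least 2")
  expect_error(simulate_population(cfg, gene_ids = "G1", target_fst = 1),
               "target_fst")
})

test_that("homeolog pair generator plants recoverable divergence", {
  cfg <- sim_config(seed = 4, n_codons = 500L)
  hp <- simulate_homeolog_pairs(cfg, n_pairs = 3)
  kk <- kaks_pairs(hp$pairs, hp$cds)
  expect_true(all(abs(kk$Ks - 0.10) < 0.03))
  expect_true(all(abs(kk$Ka - 0.01) < 0.03))
  # zero divergence
  cfg0 <- sim_config(seed = 4, n_codons = 100L, ka_target = 0, ks_target = 0)
  hp0 <- simulate_homeolog_pairs(cfg0, n_pairs = 1)
  kk0 <- kaks_pairs(hp0$pairs, hp0$cds)
  expect_equal(kk0$Ka, 0)
  expect_equal(kk0$Ks, 0)
  expect_error(simulate_homeolog_pairs(sim_config(ks_target = 5)),
               "saturat")
})

test_that("GRN generator plants motifs only in the hub's targets", {
  cfg <- sim_config(seed = 21, n_tfs = 4, n_targets_grn = 12,
                    n_samples_grn = 30)
  g <- simulate_grn(cfg)
  hits <- motif_scan(g$promoters, cfg$motif)
  hub_targets <- g$truth$target[g$truth$tf == g$hub]
  expect_setequal(hits$gene, hub_targets)
  expect_true(all(hits$strand == "+"))
  m <- merge(hits, g$motif_truth, by = "gene")
  expect_equal(m$offset.x, m$offset.y)
})

test_that("every emitted gene id appears in the truth tables (label conservation)", {
  cfg <- sim_config(seed = 8, n_families = 30)
  pan <- simulate_pangenome(cfg)
  expect_setequal(names(pan$reference), pan$truth$gene)
  for (v in names(pan$varieties))
    expect_true(all(sub("^[^_]*_", "", names(pan$varieties[[v]])) %in%
                      pan$truth$gene))
  ex <- simulate_expression(cfg, gene_ids = pan$truth$gene)
  expect_setequal(rownames(ex$matrix), names(ex$truth))
})
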