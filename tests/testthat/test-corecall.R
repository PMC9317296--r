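aas <- function(x) Biostrings::AAStringSet(x)

test_that("identity and coverage are reference-anchored", {
  ref <- aas(c(g1 = "MKVLINSWYT"))
  # identical copy
  h <- best_hit_search(ref, aas(c(v1 = "MKVLINSWYT")), exhaustive = TRUE)
  expect_equal(h$identity, 1); expect_equal(h$coverage, 1)
  # one substitution in 10 residues
  h <- best_hit_search(ref, aas(c(v1 = "MKVLANSWYT")), exhaustive = TRUE)
  expect_equal(h$identity, 0.9); expect_equal(h$coverage, 1)
  # truncation to the first 7 residues: coverage 0.7 fails c = 0.8
  h <- best_hit_search(ref, aas(c(v1 = "MKVLINS")), exhaustive = TRUE)
  expect_equal(h$coverage, 0.7)
  pm <- build_presence_matrix(
    data.frame(ref_gene = "g1", variety = "V1", hit = "v1",
               identity = h$identity, coverage = h$coverage))
  expect_false(pm["g1", "V1"])
})

test_that("presence thresholds are inclusive and validated", {
  mk <- function(i, c) data.frame(ref_gene = "g", variety = "V", hit = "h",
                                  identity = i, coverage = c)
  expect_true(build_presence_matrix(mk(0.91, 0.85))["g", "V"])
  expect_false(build_presence_matrix(mk(0.91, 0.79))["g", "V"])
  expect_true(build_presence_matrix(mk(0.90, 0.80))["g", "V"])
  expect_error(build_presence_matrix(mk(0.9, 0.8), s = 1.2), "thresholds")
})

test_that("core quorum matches the at-least-80% rule for every count", {
  # oracle: enumerate counts 0..16 against the literal >= t rule
  for (count in 0:16) {
    m <- matrix(seq_len(16) <= count, nrow = 1,
                dimnames = list("g", sprintf("V%02d", 1:16)))
    expected <- if (count / 16 >= 0.80) "core" else "dispensable"
    expect_equal(call_core(m, t = 0.80)$status, expected,
                 label = paste("count", count))
  }
  # presence everywhere is core for any t
  m <- matrix(TRUE, 1, 16, dimnames = list("g", sprintf("V%02d", 1:16)))
  for (t in c(0.2, 0.8, 1)) expect_equal(call_core(m, t)$status, "core")
  expect_error(call_core(m, t = 0), "threshold")
})

test_that("raising thresholds never grows the core set (monotonicity)", {
  set.seed(42)
  pp <- random_proteome_pair(12, divergence = 0.06)
  hits <- best_hits_all(pp$reference, list(V1 = pp$variety, V2 = pp$variety,
                                           V3 = pp$variety))
  core_set <- function(s, c, t)
    with(call_core(build_presence_matrix(hits, s, c), t),
         gene[status == "core"])
  grid_s <- c(0.80, 0.90, 0.98); grid_c <- c(0.6, 0.8, 0.95)
  grid_t <- c(0.5, 0.8, 1.0)
  for (ci in grid_c) for (ti in grid_t) {
    sets <- lapply(grid_s, core_set, c = ci, t = ti)
    for (i in 2:length(sets))
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  for (si in grid_s) for (ti in grid_t) {
    sets <- lapply(grid_c, function(ci) core_set(si, ci, ti))
    for (i in 2:length(sets))
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  for (si in grid_s) for (ci in grid_c) {
    sets <- lapply(grid_t, function(ti) core_set(si, ci, ti))
    for (i in 2:length(sets))
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("prefiltered search equals the exhaustive search", {
  set.seed(7)
  for (rep in 1:3) {
    pp <- random_proteome_pair(10, divergence = 0.08)
    fast <- best_hit_search(pp$reference, pp$variety)
    slow <- best_hit_search(pp$reference, pp$variety, exhaustive = TRUE)
    expect_equal(fast, slow)
  }
})

test_that("alignment engine agrees with an independent affine-gap DP on scores", {
  set.seed(3)
  for (i in 1:10) {
    a <- random_protein(sample(10:30, 1))
    b <- random_protein(sample(10:30, 1))
    s <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4))
    expect_equal(s, gotoh_score(a, b), tolerance = 1e-9)
  }
})

test_that("record order never changes the calls; invalid records are dropped", {
  set.seed(5)
  pp <- random_proteome_pair(8)
  calls1 <- call_core(build_presence_matrix(
    best_hits_all(pp$reference, list(V1 = pp$variety))), t = 0.5)
  perm <- sample(length(pp$reference))
  calls2 <- call_core(build_presence_matrix(
    best_hits_all(pp$reference[perm], list(V1 = pp$variety[rev(seq_len(8))]))),
    t = 0.5)
  expect_equal(calls1, calls2, ignore_attr = TRUE)
  expect_warning(
    best_hit_search(aas(c(ok = "MKVLINSWYT", bad = "MKVXBZ")),
                    aas(c(v = "MKVLINSWYT")), exhaustive = TRUE),
    "invalid")
  expect_error(best_hit_search(aas(character(0)), aas(c(v = "MK"))), "empty")
})

test_that("subgenome partition computes fractions over assigned core genes", {
  calls <- data.frame(gene = sprintf("g%02d", 1:12),
                      presence_count = 10,
                      status = c(rep("core", 10), "dispensable", "core"))
  map <- setNames(c(rep("D", 4), rep("A", 3), rep("B", 3), "A", NA),
                  calls$gene)
  sp <- subgenome_partition(calls, map)
  expect_equal(sp$fraction[match(c("D", "A", "B"), sp$subgenome)],
               c(0.4, 0.3, 0.3))
  expect_equal(sum(sp$fraction), 1)
  expect_equal(attr(sp, "n_unassigned"), 1)
  one <- subgenome_partition(calls[1:3, ], setNames(rep("A", 3), calls$gene[1:3]))
  expect_equal(one$fraction, 1)
})

test_that("planted pan-genome is recovered perfectly below the identity margin", {
  cfg <- sim_config(seed = 31, n_varieties = 6, n_families = 30,
                    core_fraction = 0.5, aa_divergence = 0.03,
                    trunc_fraction = 0)
  pan <- simulate_pangenome(cfg)
  calls <- call_core(build_presence_matrix(
    best_hits_all(pan$reference, pan$varieties)))
  m <- merge(calls, pan$truth, by = "gene")
  expect_true(all(m$status.x == m$status.y))
})
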