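# Synthetic-data generators with planted ground truth.
#
# Every generator draws from a substream seeded by (root seed, stage name),
# so stages are reproducible in isolation and identical configs give
# byte-identical output files.

#' Simulation configuration
#'
#' Bundles the parameters of all synthetic-data generators. Defaults define
#' the standard study conditions: a 16-variety pan-genome, six-tissue
#' expression design, four chromatin states including a bivalent one, a
#' mostly-undifferentiated population with a planted high-Fst subset, slow
#' homeolog divergence, and a sparse TF-target regulatory network.
#'
#' @param seed integer root seed; all stage substreams derive from it.
#' @param n_varieties number of variety proteomes (reference excluded).
#' @param n_families number of gene families (one reference gene each).
#' @param core_fraction fraction of families planted as core (present in all
#'   varieties); `core_fraction * n_families` must be an integer.
#' @param presence_profile optional integer vector (length `n_families`) of
#'   planted per-family carrier counts; overrides the default sampling.
#' @param aa_divergence per-residue substitution probability for variety
#'   copies (uniform over the 19 alternative residues).
#' @param protein_length_range integer pair, reference protein lengths.
#' @param trunc_fraction fraction of dispensable variety copies planted with
#'   a terminal truncation (to exercise the coverage filter).
#' @param trunc_keep fraction of residues kept in a truncated copy.
#' @param sample_design data.frame with columns `group` (tissue or condition
#'   label) and `n_rep` for the expression design.
#' @param n_genes_expr number of genes in a standalone expression simulation.
#' @param cluster_templates numeric matrix (cluster x group) of mean FPKM
#'   templates; `NULL` for an identity-like default.
#' @param noise_sd expression noise standard deviation (FPKM units, >= 0).
#' @param chromatin_states named list of per-mark mean-intensity templates
#'   (counts per 50-bp bin); must include a `bivalent` template with high
#'   H3K4me3 and high H3K27me3.
#' @param state_fractions named numeric vector of planted state frequencies.
#' @param marks histone-mark / open-chromatin track names.
#' @param flank,bin_size chromatin window half-width and bin width (bp).
#' @param n_sites_popgen biallelic sites simulated per gene.
#' @param n_chrom_pop haploid sample size per population.
#' @param fst_high,fst_low,fst_high_fraction planted per-gene Fst targets:
#'   a `fst_high_fraction` share of genes at `fst_high`, the rest at `fst_low`.
#' @param n_codons codons per simulated homeolog CDS.
#' @param ka_target,ks_target planted NG86 divergence per homeolog pair.
#' @param n_tfs,n_targets_grn,n_samples_grn,grn_effect,grn_noise_sd regulatory
#'   network design: each target is driven by one TF with coefficient
#'   `grn_effect` plus `N(0, grn_noise_sd)` noise.
#' @param motif promoter motif (ACGT string) planted in true targets of the
#'   designated hub TF.
#' @param promoter_length promoter sequence length (bp).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_varieties = 16L,
                       n_families = 120L,
                       core_fraction = 0.6,
                       presence_profile = NULL,
                       aa_divergence = 0.03,
                       protein_length_range = c(100L, 200L),
                       trunc_fraction = 0.10,
                       trunc_keep = 0.70,
                       sample_design = data.frame(
                         group = c("leaf", "root", "stem", "spikelet",
                                   "grain", "seedling"),
                         n_rep = 2L),
                       n_genes_expr = 300L,
                       cluster_templates = NULL,
                       noise_sd = 0.3,
                       chromatin_states = list(
                         active    = c(H3K4me3 = 20, H3K27me3 = 0.2,
                                       H3K36me3 = 10, H3K4me1 = 5,
                                       H3K9me2 = 0.2, H3K9ac = 15, DHS = 10),
                         bivalent  = c(H3K4me3 = 15, H3K27me3 = 15,
                                       H3K36me3 = 2, H3K4me1 = 3,
                                       H3K9me2 = 0.2, H3K9ac = 3, DHS = 5),
                         polycomb  = c(H3K4me3 = 0.5, H3K27me3 = 15,
                                       H3K36me3 = 0.5, H3K4me1 = 2,
                                       H3K9me2 = 1, H3K9ac = 0.5, DHS = 1),
                         quiescent = c(H3K4me3 = 0.5, H3K27me3 = 0.5,
                                       H3K36me3 = 0.5, H3K4me1 = 1,
                                       H3K9me2 = 5, H3K9ac = 0.5, DHS = 0.5)),
                       state_fractions = c(active = 0.4, bivalent = 0.2,
                                           polycomb = 0.2, quiescent = 0.2),
                       marks = c("H3K4me3", "H3K27me3", "H3K36me3",
                                 "H3K4me1", "H3K9me2", "H3K9ac", "DHS"),
                       flank = 2000L, bin_size = 50L,
                       n_sites_popgen = 50L, n_chrom_pop = 50L,
                       fst_high = 0.4, fst_low = 0.02,
                       fst_high_fraction = 0.10,
                       n_codons = 500L,
                       ka_target = 0.01, ks_target = 0.10,
                       n_tfs = 10L, n_targets_grn = 40L,
                       n_samples_grn = 200L,
                       grn_effect = 1.0, grn_noise_sd = 0.1,
                       motif = "GCCACGTG",
                       promoter_length = 300L) {
  check_fraction(core_fraction, "core_fraction")
  check_fraction(trunc_fraction, "trunc_fraction")
  check_fraction(aa_divergence, "aa_divergence")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (grn_noise_sd < 0) stop("grn_noise_sd must be >= 0")
  n_core <- core_fraction * n_families
  if (abs(n_core - round(n_core)) > 1e-9)
    stop("core_fraction * n_families = ", n_core,
         " is not an integer number of families")
  for (st in names(chromatin_states))
    if (any(chromatin_states[[st]] < 0))
      stop("negative mark intensity in chromatin state '", st, "'")
  if (grepl("[^ACGT]", motif)) stop("motif must be an ACGT string")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_varieties, "varieties,",
      x$n_families, "families (core fraction", x$core_fraction, ")\n")
  invisible(x)
}

.aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

.variety_ids <- function(n) sprintf("VAR%02d", seq_len(n))

#' Simulate a reference-guided pan-genome
#'
#' Plants `core_fraction * n_families` families in every variety and the
#' rest in fewer than the 80%-presence quorum, so the planted core /
#' dispensable labels coincide with the downstream calling rule. Carrying
#' varieties receive a copy with residue substitutions at rate
#' `aa_divergence`; a planted share of dispensable copies is terminally
#' truncated to `trunc_keep` of the reference length so the coverage filter
#' is exercised independently of the identity filter.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory; if given, writes `reference.faa` and one
#'   `<variety>.faa` per variety.
#' @return list with `reference` (AAStringSet), `varieties` (named list of
#'   AAStringSet), and `truth` (data.frame: `family`, `gene`, `status`,
#'   `presence_count`, `n_truncated`).
#' @export
simulate_pangenome <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_varieties < 2) stop("need at least 2 varieties")
  if (cfg$n_families < 1) stop("need at least 1 family")
  with_seed(substream_seed(cfg$seed, "pangenome"), {
    aa <- .aa_alphabet()
    nf <- cfg$n_families
    n_core <- as.integer(round(cfg$core_fraction * nf))
    status <- rep(c("core", "dispensable"), c(n_core, nf - n_core))
    genes <- sprintf("G%04d", seq_len(nf))
    fams <- sprintf("FAM%04d", seq_len(nf))
    len_pool <- seq(cfg$protein_length_range[1], cfg$protein_length_range[2])
    lens <- len_pool[sample.int(length(len_pool), nf, replace = TRUE)]
    refseq <- vapply(lens, function(L) paste(sample(aa, L, TRUE), collapse = ""),
                     "")
    reference <- Biostrings::AAStringSet(setNames(refseq, genes))
    # planted carrier counts: core = all varieties; dispensable = below the
    # 80% quorum so labels and the >=80% rule agree by construction
    quorum <- as.integer(ceiling(0.8 * cfg$n_varieties))
    if (!is.null(cfg$presence_profile)) {
      presence_n <- as.integer(cfg$presence_profile)
      if (length(presence_n) != nf) stop("presence_profile length mismatch")
    } else {
      presence_n <- ifelse(status == "core", cfg$n_varieties,
                           sample(seq_len(max(quorum - 1L, 1L)), nf, TRUE))
    }
    vids <- .variety_ids(cfg$n_varieties)
    carriers <- lapply(seq_len(nf), function(i)
      sort(sample(vids, presence_n[i])))
    n_trunc <- integer(nf)
    varieties <- setNames(vector("list", cfg$n_varieties), vids)
    for (v in vids) varieties[[v]] <- character(0)
    for (i in seq_len(nf)) {
      s <- strsplit(refseq[i], "")[[1]]
      for (v in carriers[[i]]) {
        copy <- s
        nmut <- rbinom(1, length(s), cfg$aa_divergence)
        if (nmut > 0) {
          pos <- sample(length(s), nmut)
          for (p in pos) copy[p] <- sample(setdiff(aa, copy[p]), 1)
        }
        if (status[i] == "dispensable" && runif(1) < cfg$trunc_fraction) {
          keep <- max(1L, floor(cfg$trunc_keep * length(copy)))
          copy <- copy[seq_len(keep)]
          n_trunc[i] <- n_trunc[i] + 1L
        }
        varieties[[v]][paste0(v, "_", genes[i])] <- paste(copy, collapse = "")
      }
    }
    varieties <- lapply(varieties, Biostrings::AAStringSet)
    truth <- data.frame(family = fams, gene = genes, status = status,
                        presence_count = presence_n, n_truncated = n_trunc,
                        stringsAsFactors = FALSE)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_fasta(reference, file.path(outdir, "reference.faa"))
      for (v in vids)
        write_fasta(varieties[[v]], file.path(outdir, paste0(v, ".faa")))
    }
    list(reference = reference, varieties = varieties, truth = truth)
  })
}

#' Simulate gene models on synthetic chromosomes
#'
#' Lays genes out on one chromosome per subgenome (chr1A/chr1B/chr1D) with
#' spacing wide enough that +/- `flank` promoter windows never overlap, and
#' assigns random strands.
#'
#' @param gene_ids character vector of gene ids.
#' @param cfg a [sim_config()].
#' @param subgenome_probs sampling weights for the A/B/D assignment.
#' @return gene table as returned by [read_gff3()].
#' @export
simulate_gene_models <- function(gene_ids, cfg,
                                 subgenome_probs = c(A = 0.33, B = 0.29,
                                                     D = 0.38)) {
  with_seed(substream_seed(cfg$seed, "gene_models"), {
    n <- length(gene_ids)
    sub <- sample(names(subgenome_probs), n, TRUE, prob = subgenome_probs)
    gene_len <- 2000L
    gap <- 2L * cfg$flank + 1000L
    tab <- data.frame(gene = gene_ids, subgenome = sub,
                      strand = sample(c("+", "-"), n, TRUE),
                      stringsAsFactors = FALSE)
    tab$chrom <- paste0("chr1", tab$subgenome)
    tab$start <- NA_integer_; tab$end <- NA_integer_
    for (ch in unique(tab$chrom)) {
      idx <- which(tab$chrom == ch)
      starts <- cfg$flank + 10L + (seq_along(idx) - 1L) * (gene_len + gap)
      tab$start[idx] <- starts
      tab$end[idx] <- starts + gene_len
    }
    tab$tss <- ifelse(tab$strand == "+", tab$start, tab$end - 1L)
    tab[, c("gene", "chrom", "start", "end", "strand", "tss", "subgenome")]
  })
}

.default_templates <- function(groups, high = 10, low = 1) {
  k <- length(groups)
  tpl <- matrix(low, k, k, dimnames = list(paste0("CL", seq_len(k)), groups))
  diag(tpl) <- high
  tpl
}

#' Simulate an FPKM expression matrix with planted clusters
#'
#' Each gene belongs to one cluster; its FPKM in a sample is the cluster's
#' template mean for that sample's group plus Gaussian noise, floored at 0.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids gene ids to simulate; defaults to `n_genes_expr` new ids.
#' @param templates cluster x group template matrix; default one high-in-own
#'   -tissue cluster per group (see [sim_config()]).
#' @return list with `matrix` (genes x samples), `meta` (sample, group,
#'   replicate), and `truth` (gene -> cluster).
#' @export
simulate_expression <- function(cfg, gene_ids = NULL, templates = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(substream_seed(cfg$seed, "expression"), {
    design <- cfg$sample_design
    if (nrow(design) < 1 || sum(design$n_rep) < 2)
      stop("need at least 2 samples")
    if (is.null(templates)) templates <- cfg$cluster_templates
    if (is.null(templates)) templates <- .default_templates(design$group)
    if (ncol(templates) != nrow(design))
      stop("cluster_templates must have one column per sample group")
    if (is.null(colnames(templates))) colnames(templates) <- design$group
    if (nrow(templates) < 2) stop("need at least 2 cluster templates")
    if (is.null(gene_ids))
      gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes_expr))
    k <- nrow(templates)
    cluster <- rep_len(rownames(templates), length(gene_ids))
    samples <- unlist(lapply(seq_len(nrow(design)), function(i)
      paste0(design$group[i], "_r", seq_len(design$n_rep[i]))))
    group_of <- rep(design$group, design$n_rep)
    mu <- templates[cluster, group_of, drop = FALSE]
    m <- mu + matrix(rnorm(length(mu), 0, cfg$noise_sd), nrow(mu))
    m[m < 0] <- 0
    dimnames(m) <- list(gene_ids, samples)
    list(matrix = m,
         meta = data.frame(sample = samples, group = group_of,
                           replicate = unlist(lapply(design$n_rep, seq_len)),
                           stringsAsFactors = FALSE),
         truth = setNames(cluster, gene_ids))
  })
}

#' Simulate per-mark chromatin tracks around gene TSSs
#'
#' Assigns each gene a chromatin state and emits, per mark, a bedGraph of
#' Poisson counts in `bin_size`-bp bins across the +/- `flank` promoter
#' window, with the Poisson mean given by the state's per-mark template.
#' The `bivalent` template has high H3K4me3 and high H3K27me3.
#'
#' @param cfg a [sim_config()].
#' @param genes gene table ([read_gff3()] schema).
#' @return list with `tracks` (named list of bedGraph data.frames, one per
#'   mark) and `truth` (gene -> state name).
#' @export
simulate_chromatin <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  for (st in names(cfg$chromatin_states))
    if (any(cfg$chromatin_states[[st]] < 0))
      stop("negative mark intensity in state '", st, "'")
  with_seed(substream_seed(cfg$seed, "chromatin"), {
    n <- nrow(genes)
    states <- sample(names(cfg$state_fractions), n, TRUE,
                     prob = cfg$state_fractions)
    nb <- as.integer(2L * cfg$flank / cfg$bin_size)
    tracks <- setNames(vector("list", length(cfg$marks)), cfg$marks)
    # same strand-symmetric window anchor as tss_signal_matrix, so simulated
    # bins land exactly on matrix bins
    anchor <- ifelse(genes$strand == "-", genes$tss + 1L, genes$tss)
    win_start <- anchor - cfg$flank
    for (mk in cfg$marks) {
      mu <- vapply(states, function(s) {
        t <- cfg$chromatin_states[[s]]
        if (mk %in% names(t)) t[[mk]] else 0
      }, 0)
      counts <- matrix(rpois(n * nb, rep(mu, each = nb)), nrow = nb)
      rows <- data.frame(
        chrom = rep(genes$chrom, each = nb),
        start = rep(win_start, each = nb) +
          (seq_len(nb) - 1L) * cfg$bin_size,
        end = rep(win_start, each = nb) + seq_len(nb) * cfg$bin_size,
        value = as.vector(counts), stringsAsFactors = FALSE)
      rows <- rows[rows$start >= 0 & rows$value > 0, , drop = FALSE]
      rows <- rows[order(rows$chrom, rows$start), , drop = FALSE]
      rownames(rows) <- NULL
      tracks[[mk]] <- rows
    }
    list(tracks = tracks, truth = setNames(states, genes$gene))
  })
}

#' Simulate two-population allele counts with planted Fst
#'
#' Balding-Nichols sampling: per site, an ancestral frequency `p` is drawn
#' uniformly on (0.05, 0.95) and each population's frequency is
#' `Beta(p(1-f)/f, (1-p)(1-f)/f)` (equal to `p` when `f = 0`), giving
#' expected Hudson Fst `f`; observed counts are binomial draws of
#' `n_chrom_pop` haploid samples per population.
#'
#' @param cfg a [sim_config()].
#' @param gene_ids gene ids; defaults to `n_families` new ids.
#' @param target_fst per-gene target Fst in `[0, 1)`; defaults to the
#'   `fst_high`/`fst_low` mixture in `cfg`.
#' @return list with `counts` (data.frame: gene, site, pop1_ref, pop1_alt,
#'   pop2_ref, pop2_alt) and `truth` (gene -> target Fst).
#' @export
simulate_population <- function(cfg, gene_ids = NULL, target_fst = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_chrom_pop < 2) stop("need at least 2 samples per population")
  with_seed(substream_seed(cfg$seed, "population"), {
    if (is.null(gene_ids))
      gene_ids <- sprintf("G%04d", seq_len(cfg$n_families))
    ng <- length(gene_ids)
    if (is.null(target_fst)) {
      n_high <- round(cfg$fst_high_fraction * ng)
      target_fst <- rep(cfg$fst_low, ng)
      if (n_high > 0) target_fst[sample(ng, n_high)] <- cfg$fst_high
    }
    if (any(target_fst < 0 | target_fst >= 1))
      stop("target_fst must lie in [0, 1)")
    ns <- cfg$n_sites_popgen
    nchr <- cfg$n_chrom_pop
    rows <- vector("list", ng)
    for (i in seq_len(ng)) {
      f <- target_fst[i]
      p <- runif(ns, 0.05, 0.95)
      if (f == 0) { p1 <- p; p2 <- p } else {
        a <- p * (1 - f) / f; b <- (1 - p) * (1 - f) / f
        p1 <- rbeta(ns, a, b); p2 <- rbeta(ns, a, b)
      }
      alt1 <- rbinom(ns, nchr, p1); alt2 <- rbinom(ns, nchr, p2)
      rows[[i]] <- data.frame(gene = gene_ids[i], site = seq_len(ns),
                              pop1_ref = nchr - alt1, pop1_alt = alt1,
                              pop2_ref = nchr - alt2, pop2_alt = alt2,
                              stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, rows),
         truth = setNames(target_fst, gene_ids))
  })
}

# codon helpers shared with the evolution module
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  list(codons = names(gc), aa = unname(gc), stops = names(gc)[gc == "*"])
}

#' Simulate homeolog CDS pairs with planted Ka/Ks
#'
#' Builds a random stop-free ancestor of `n_codons` codons and a derived
#' copy carrying `Sd` synonymous and `Nd` nonsynonymous single-nucleotide
#' changes in distinct codons, where `Sd`/`Nd` invert the Jukes-Cantor
#' correction on the ancestor's NG86 site counts to hit the
#' (`ka_target`, `ks_target`) pair.
#'
#' @param cfg a [sim_config()].
#' @param pairs optional data.frame `pair`, `gene_a`, `gene_b` naming the
#'   members (e.g. homeolog triad A/B members); default `n_pairs` anonymous
#'   pairs named `<pair>_a` / `<pair>_b`.
#' @param n_pairs number of pairs when `pairs` is NULL.
#' @return list with `cds` (DNAStringSet, two records per pair), `pairs`
#'   (data.frame pair, gene_a, gene_b) and `truth` (data.frame pair,
#'   ka_target, ks_target).
#' @export
simulate_homeolog_pairs <- function(cfg, pairs = NULL, n_pairs = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  ps_target <- 0.75 * (1 - exp(-4 * cfg$ks_target / 3))
  pn_target <- 0.75 * (1 - exp(-4 * cfg$ka_target / 3))
  if (ps_target >= 0.74 || pn_target >= 0.74)
    stop("requested divergence saturates the Jukes-Cantor correction ",
         "(proportion of differences must stay below 0.74)")
  with_seed(substream_seed(cfg$seed, "homeolog"), {
    ct <- .codon_table()
    sense <- setdiff(ct$codons, ct$stops)
    aa_of <- setNames(ct$aa, ct$codons)
    if (is.null(pairs))
      pairs <- data.frame(pair = sprintf("PAIR%02d", seq_len(n_pairs)),
                          gene_a = sprintf("PAIR%02d_a", seq_len(n_pairs)),
                          gene_b = sprintf("PAIR%02d_b", seq_len(n_pairs)),
                          stringsAsFactors = FALSE)
    pair_ids <- pairs$pair
    seqs <- character(0)
    for (j in seq_along(pair_ids)) {
      pid <- pair_ids[j]
      anc <- sample(sense, cfg$n_codons, TRUE)
      sn <- .ng86_sites_seq(anc, aa_of)
      Sd <- round(ps_target * sn$S); Nd <- round(pn_target * sn$N)
      # candidate codons offering a synonymous / nonsynonymous single change
      syn_opts <- lapply(anc, function(cd) .single_changes(cd, aa_of, syn = TRUE))
      non_opts <- lapply(anc, function(cd) .single_changes(cd, aa_of, syn = FALSE))
      can_syn <- which(vapply(syn_opts, length, 1L) > 0)
      can_non <- which(vapply(non_opts, length, 1L) > 0)
      pos_syn <- sample(can_syn, Sd)
      pos_non <- sample(setdiff(can_non, pos_syn), Nd)
      der <- anc
      for (p in pos_syn) der[p] <- sample(syn_opts[[p]], 1)
      for (p in pos_non) der[p] <- sample(non_opts[[p]], 1)
      seqs[pairs$gene_a[j]] <- paste(anc, collapse = "")
      seqs[pairs$gene_b[j]] <- paste(der, collapse = "")
    }
    list(cds = Biostrings::DNAStringSet(seqs),
         pairs = pairs,
         truth = data.frame(pair = pair_ids, ka_target = cfg$ka_target,
                            ks_target = cfg$ks_target,
                            stringsAsFactors = FALSE))
  })
}

# single-nt neighbours of a codon that are synonymous (or non-), stop-free
.single_changes <- function(codon, aa_of, syn) {
  nts <- c("A", "C", "G", "T")
  out <- character(0)
  s <- strsplit(codon, "")[[1]]
  for (i in 1:3) for (n in setdiff(nts, s[i])) {
    alt <- s; alt[i] <- n
    altc <- paste(alt, collapse = "")
    if (aa_of[[altc]] == "*") next
    if ((aa_of[[altc]] == aa_of[[codon]]) == syn) out <- c(out, altc)
  }
  out
}

# NG86 site totals for one codon vector (used by the generator to invert the
# correction; the estimator has its own per-alignment version)
.ng86_sites_seq <- function(codons, aa_of) {
  S <- 0
  for (cd in codons) {
    s <- strsplit(cd, "")[[1]]
    nts <- c("A", "C", "G", "T")
    for (i in 1:3) {
      nsyn <- 0
      for (n in setdiff(nts, s[i])) {
        alt <- s; alt[i] <- n
        altc <- paste(alt, collapse = "")
        if (aa_of[[altc]] != "*" && aa_of[[altc]] == aa_of[[cd]])
          nsyn <- nsyn + 1
      }
      S <- S + nsyn / 3
    }
  }
  list(S = S, N = 3 * length(codons) - S)
}

#' Build homeolog triads from a gene table
#'
#' Groups genes into 1:1:1 triads by drawing one member per subgenome until
#' a subgenome is exhausted.
#'
#' @param genes gene table with `gene` and `subgenome` columns.
#' @param cfg a [sim_config()].
#' @return data.frame `triad`, `gene_A`, `gene_B`, `gene_D`.
#' @export
simulate_triads <- function(genes, cfg) {
  with_seed(substream_seed(cfg$seed, "triads"), {
    by_sub <- split(genes$gene, genes$subgenome)
    if (!all(c("A", "B", "D") %in% names(by_sub)))
      stop("need genes on all three subgenomes")
    nt <- min(lengths(by_sub[c("A", "B", "D")]))
    data.frame(triad = sprintf("TRIAD%03d", seq_len(nt)),
               gene_A = sample(by_sub$A, nt),
               gene_B = sample(by_sub$B, nt),
               gene_D = sample(by_sub$D, nt), stringsAsFactors = FALSE)
  })
}

#' Simulate a TF-target expression matrix, promoters, and true network
#'
#' TF expression is i.i.d. standard normal across samples; each target is a
#' linear combination of its true regulators plus Gaussian noise. Promoters
#' of the true targets of the designated hub TF (the TF with most targets)
#' carry the binding motif at a recorded offset; all other promoters are
#' motif-free on both strands by construction.
#'
#' @param cfg a [sim_config()].
#' @param edges optional data.frame `tf`, `target`, `effect`; default one
#'   regulator per target, round-robin over `n_tfs` TFs.
#' @param tf_ids,target_ids optional gene ids to use for TFs and targets
#'   (e.g. members of the reference gene universe).
#' @return list with `matrix` (genes x samples, TFs first), `tfs`,
#'   `promoters` (DNAStringSet over targets + TFs), `truth` (edge data.frame)
#'   and `motif_truth` (data.frame gene, offset).
#' @export
simulate_grn <- function(cfg, edges = NULL, tf_ids = NULL, target_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_tfs < 2 || cfg$n_samples_grn < 20)
    stop("need >= 2 TFs and >= 20 samples")
  with_seed(substream_seed(cfg$seed, "grn"), {
    tfs <- if (is.null(tf_ids)) sprintf("TF%02d", seq_len(cfg$n_tfs))
           else tf_ids
    targets <- if (is.null(target_ids))
      sprintf("TG%03d", seq_len(cfg$n_targets_grn)) else target_ids
    if (is.null(edges))
      edges <- data.frame(tf = rep_len(tfs, length(targets)),
                          target = targets, effect = cfg$grn_effect,
                          stringsAsFactors = FALSE)
    ns <- cfg$n_samples_grn
    tf_expr <- matrix(rnorm(length(tfs) * ns), length(tfs), ns,
                      dimnames = list(tfs, sprintf("S%03d", seq_len(ns))))
    tg_expr <- matrix(0, length(targets), ns,
                      dimnames = list(targets, colnames(tf_expr)))
    for (i in seq_along(targets)) {
      e <- edges[edges$target == targets[i], , drop = FALSE]
      mu <- if (nrow(e)) colSums(tf_expr[e$tf, , drop = FALSE] * e$effect)
            else rep(0, ns)
      tg_expr[i, ] <- mu + rnorm(ns, 0, cfg$grn_noise_sd)
    }
    # motif planting: hub = TF with most true targets (ties: first id)
    deg <- sort(table(factor(edges$tf, levels = tfs)), decreasing = TRUE)
    hub <- names(deg)[1]
    hub_targets <- edges$target[edges$tf == hub]
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cfg$motif)))
    draw_free <- function() {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), cfg$promoter_length, TRUE),
                   collapse = "")
        if (!grepl(cfg$motif, s, fixed = TRUE) && !grepl(rc, s, fixed = TRUE))
          return(s)
      }
    }
    all_genes <- c(tfs, targets)
    prom <- vapply(all_genes, function(g) draw_free(), "")
    offs <- integer(0)
    count_hits <- function(s)
      sum(gregexpr(cfg$motif, s, fixed = TRUE)[[1]] > 0) +
        sum(gregexpr(rc, s, fixed = TRUE)[[1]] > 0)
    for (g in hub_targets) {
      off <- sample.int(cfg$promoter_length - nchar(cfg$motif), 1)
      repeat {
        # redraw the background until planting creates exactly one forward
        # occurrence (insertion boundaries can spawn spurious matches)
        s <- prom[g]
        substr(s, off + 1, off + nchar(cfg$motif)) <- cfg$motif
        if (count_hits(s) == 1) break
        prom[g] <- draw_free()
      }
      prom[g] <- s
      offs[g] <- off
    }
    list(matrix = rbind(tf_expr, tg_expr), tfs = tfs,
         promoters = Biostrings::DNAStringSet(prom),
         truth = edges, hub = hub,
         motif_truth = data.frame(gene = names(offs), offset = unname(offs),
                                  stringsAsFactors = FALSE))
  })
}

#' Simulate flat functional annotations (GO-like terms and TF families)
#'
#' Random term memberships over the gene universe, plus one planted term and
#' one planted TF family whose members are drawn preferentially from the
#' core set (enrichment ground truth).
#'
#' @param gene_ids gene universe.
#' @param core_genes planted core subset.
#' @param cfg a [sim_config()].
#' @param n_terms number of background GO-like terms.
#' @param n_families number of background TF families.
#' @return list with `go` (data.frame gene, term, label), `family`
#'   (data.frame gene, family), `planted_term`, `planted_family`.
#' @export
simulate_annotation <- function(gene_ids, core_genes, cfg, n_terms = 20L,
                                n_families = 10L) {
  with_seed(substream_seed(cfg$seed, "annotation"), {
    N <- length(gene_ids)
    rows <- list()
    for (i in seq_len(n_terms)) {
      size <- sample(10:min(60, N), 1)
      rows[[i]] <- data.frame(gene = sample(gene_ids, size),
                              term = sprintf("TERM%03d", i),
                              label = sprintf("process %03d", i),
                              stringsAsFactors = FALSE)
    }
    # planted term: drawn mostly from core genes
    size <- min(40L, length(core_genes))
    planted <- data.frame(
      gene = c(sample(core_genes, round(0.9 * size)),
               sample(setdiff(gene_ids, core_genes), size - round(0.9 * size))),
      term = "TERM_CORE", label = "planted core-enriched process",
      stringsAsFactors = FALSE)
    go <- rbind(do.call(rbind, rows), planted)
    fam_genes <- sample(gene_ids, min(N, n_families * 12L))
    fam <- data.frame(gene = fam_genes,
                      family = sprintf("FAM_TF%02d",
                                       rep_len(seq_len(n_families),
                                               length(fam_genes))),
                      stringsAsFactors = FALSE)
    pf_size <- min(15L, length(core_genes))
    fam <- rbind(fam, data.frame(gene = sample(core_genes, pf_size),
                                 family = "FAM_PLANTED",
                                 stringsAsFactors = FALSE))
    fam <- fam[!duplicated(fam$gene), , drop = FALSE]
    list(go = go, family = fam,
         planted_term = "TERM_CORE", planted_family = "FAM_PLANTED")
  })
}
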