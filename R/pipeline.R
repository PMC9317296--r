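# End-to-end orchestration: write a full synthetic input bundle, run every
# analysis stage in dependency order, and join the per-gene report.

#' Write the complete synthetic input bundle for a pipeline run
#'
#' Generates, with planted truth, everything [run_all()] consumes: the
#' reference and variety proteomes, gene models (GFF3), the tissue
#' expression matrix and sample metadata, per-mark chromatin bedGraphs, the
#' two-population allele-count table, homeolog triads with CDS pairs (A-B
#' member per triad), the regulatory-network expression matrix with TF list
#' and promoters, flat GO/TF-family annotations, and a `truth.json`
#' recording every planted label.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created).
#' @return invisibly, the list of in-memory stage outputs (including all
#'   truth tables).
#' @export
simulate_all <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
  pan <- simulate_pangenome(cfg, outdir = outdir)
  genes <- simulate_gene_models(pan$truth$gene, cfg)
  write_gff3(genes, file.path(outdir, "genes.gff3"))

  groups <- cfg$sample_design$group
  templates <- rbind(.default_templates(groups),
                     silent = rep(0, length(groups)))
  expr <- simulate_expression(cfg, gene_ids = genes$gene,
                              templates = templates)
  write_matrix_tsv(round(expr$matrix, 4), file.path(outdir, "expression.tsv"))
  write_tsv(expr$meta, file.path(outdir, "sample_meta.tsv"))

  chrom <- simulate_chromatin(cfg, genes)
  for (mk in names(chrom$tracks))
    write_bedgraph(chrom$tracks[[mk]],
                   file.path(outdir, "tracks", paste0(mk, ".bedGraph")))

  pop <- simulate_population(cfg, gene_ids = genes$gene)
  write_tsv(pop$counts, file.path(outdir, "alleles.tsv"))

  triads <- simulate_triads(genes, cfg)
  write_tsv(triads, file.path(outdir, "triads.tsv"))
  hom <- simulate_homeolog_pairs(
    cfg, pairs = data.frame(pair = triads$triad, gene_a = triads$gene_A,
                            gene_b = triads$gene_B, stringsAsFactors = FALSE))
  write_fasta(hom$cds, file.path(outdir, "cds_pairs.fna"))

  core_truth <- pan$truth$gene[pan$truth$status == "core"]
  tf_ids <- genes$gene[seq_len(cfg$n_tfs)]
  target_ids <- genes$gene[cfg$n_tfs + seq_len(cfg$n_targets_grn)]
  grn <- simulate_grn(cfg, tf_ids = tf_ids, target_ids = target_ids)
  write_matrix_tsv(round(grn$matrix, 6), file.path(outdir, "grn_expression.tsv"))
  writeLines(grn$tfs, file.path(outdir, "tfs.txt"))
  write_fasta(grn$promoters, file.path(outdir, "promoters.fna"))

  ann <- simulate_annotation(genes$gene, core_truth, cfg)
  write_tsv(ann$go, file.path(outdir, "go_annotation.tsv"))
  write_tsv(ann$family, file.path(outdir, "tf_families.tsv"))

  truth <- list(core = pan$truth,
                expression_cluster = as.list(expr$truth),
                chromatin_state = as.list(chrom$truth),
                target_fst = as.list(pop$truth),
                kaks = hom$truth,
                grn_edges = grn$truth, grn_hub = grn$hub,
                motif_offsets = grn$motif_truth,
                planted_term = ann$planted_term,
                planted_family = ann$planted_family)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(pangenome = pan, genes = genes, expression = expr,
                 chromatin = chrom, population = pop, triads = triads,
                 homeolog = hom, grn = grn, annotation = ann))
}

#' Pipeline run configuration
#'
#' Collects input/output paths, stage toggles and every analysis threshold.
#' Defaults are the study's stated parameters: similarity 0.90, coverage
#' 0.80, presence 0.80, Fst cutoff 0.25, sum-FPKM filter 3, FPKM > 1
#' breadth cutoff, k = 8 (stress), k = 6 (tissue), k = 8 (chromatin),
#' 2 kb flank, top 1000 edges, motif GCCACGTG.
#'
#' @param indir input bundle directory (as written by [simulate_all()]).
#' @param outdir output directory.
#' @param seed integer root seed for the seeded stages (k-means, forests).
#' @param stages character vector of enabled stages, any of `"corecall"`,
#'   `"popgen"`, `"expression"`, `"chromatin"`, `"evolution"`,
#'   `"networks"`, `"enrichment"`.
#' @param sim,cov,presence core-calling thresholds.
#' @param fst_threshold differentiation cutoff.
#' @param min_sum,min_fpkm expression filter and breadth cutoffs.
#' @param k_stress,k_tissue,k_chromatin k-means cluster counts.
#' @param flank,bin_size chromatin window geometry (bp).
#' @param top_k GRN edge truncation.
#' @param n_trees trees per GRN target forest.
#' @param min_abs_r co-expression module cut.
#' @param motif promoter motif.
#' @return list of class `run_config`.
#' @export
run_config <- function(indir, outdir, seed = 1L,
                       stages = c("corecall", "popgen", "expression",
                                  "chromatin", "evolution", "networks",
                                  "enrichment"),
                       sim = 0.90, cov = 0.80, presence = 0.80,
                       fst_threshold = 0.25, min_sum = 3, min_fpkm = 1,
                       k_stress = 8L, k_tissue = 6L, k_chromatin = 8L,
                       flank = 2000L, bin_size = 50L, top_k = 1000L,
                       n_trees = 1000L, min_abs_r = 0.7,
                       motif = "GCCACGTG") {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# hash of the analytic parameters (paths excluded, so the same analysis in
# a different directory carries the same provenance tag)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  x <- unclass(config)
  x$indir <- NULL; x$outdir <- NULL
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.stage_log <- function(stage, ...) {
  message(sprintf("[pancore:%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (core calling first,
#' then population genetics, expression, chromatin, homeolog evolution,
#' networks and enrichment) on the input bundle, writes each stage's
#' artifacts into `outdir`, and joins the per-gene report
#' (`gene_report.tsv`). Every written table carries the config hash in a
#' header line; a rerun with the same config and inputs is byte-identical.
#' Disabled stages leave their report columns `NA`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `report` (data.frame, one row per
#'   reference gene), per-stage results, and `config_hash`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  indir <- config$indir
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  hdr <- paste0("config_hash: ", hash)
  on_stage <- function(s) s %in% config$stages
  res <- list(config_hash = hash)

  genes <- read_gff3(file.path(indir, "genes.gff3"))
  report <- data.frame(gene = genes$gene, subgenome = genes$subgenome,
                       stringsAsFactors = FALSE)
  report$core_status <- NA_character_
  report$presence_count <- NA_integer_
  report$fst <- NA_real_; report$fst_class <- NA_character_
  report$pi_pop1 <- NA_real_; report$pi_pop2 <- NA_real_
  report$expr_cluster <- NA_integer_; report$breadth <- NA_real_
  report$chromatin_cluster <- NA_integer_; report$bivalent <- NA
  report$module <- NA_integer_; report$hub_rank <- NA_integer_

  if (on_stage("corecall")) {
    reference <- read_fasta(file.path(indir, "reference.faa"), "AA")
    vfiles <- setdiff(list.files(indir, pattern = "\\.faa$"), "reference.faa")
    varieties <- setNames(
      lapply(vfiles, function(f) read_fasta(file.path(indir, f), "AA")),
      sub("\\.faa$", "", vfiles))
    .stage_log("corecall", length(reference), " reference proteins, ",
               length(varieties), " varieties")
    hits <- best_hits_all(reference, varieties)
    pm <- build_presence_matrix(hits, s = config$sim, c = config$cov)
    calls <- call_core(pm, t = config$presence)
    write_tsv(hits, file.path(outdir, "best_hits.tsv"), hdr)
    write_tsv(data.frame(gene = rownames(pm), 1L * unclass(pm),
                         check.names = FALSE),
              file.path(outdir, "presence_matrix.tsv"), hdr)
    write_tsv(calls, file.path(outdir, "core_calls.tsv"), hdr)
    subp <- subgenome_partition(calls, setNames(genes$subgenome, genes$gene))
    write_tsv(subp, file.path(outdir, "subgenome_partition.tsv"), hdr)
    idx <- match(calls$gene, report$gene)
    report$core_status[idx] <- calls$status
    report$presence_count[idx] <- calls$presence_count
    res$corecall <- list(hits = hits, presence = pm, calls = calls,
                         subgenomes = subp)
    .stage_log("corecall", sum(calls$status == "core"), " core of ",
               nrow(calls), " genes")
  }

  if (on_stage("popgen")) {
    counts <- read_tsv(file.path(indir, "alleles.tsv"))
    stats <- popgen_stats(counts)
    diffc <- classify_differentiation(stats, threshold = config$fst_threshold)
    out <- merge(stats, diffc[, c("gene", "class")], by = "gene",
                 all.x = TRUE, sort = TRUE)
    write_tsv(out, file.path(outdir, "popgen.tsv"), hdr)
    idx <- match(stats$gene, report$gene)
    report$fst[idx] <- stats$fst
    report$pi_pop1[idx] <- stats$pi_pop1
    report$pi_pop2[idx] <- stats$pi_pop2
    report$fst_class[match(diffc$gene, report$gene)] <- diffc$class
    res$popgen <- list(stats = stats, classes = diffc)
    .stage_log("popgen", attr(diffc, "n_high"), " genes with Fst > ",
               config$fst_threshold)
  }

  expressed <- NULL
  if (on_stage("expression")) {
    m <- read_expression_tsv(file.path(indir, "expression.tsv"))
    meta <- read_tsv(file.path(indir, "sample_meta.tsv"))
    flt <- filter_expressed(m, min_sum = config$min_sum)
    .stage_log("expression", length(flt$excluded),
               " genes removed by the sum-FPKM filter")
    z <- suppressWarnings(zscore_rows(flt$matrix))
    cl <- kmeans_cluster(z, k = config$k_tissue, seed = config$seed)
    tissues <- meta$group[match(colnames(m), meta$sample)]
    breadth <- expression_index(flt$matrix, tissues,
                                min_fpkm = config$min_fpkm)
    write_tsv(data.frame(gene = names(cl$cluster),
                         cluster = unname(cl$cluster)),
              file.path(outdir, "expression_clusters.tsv"), hdr)
    write_tsv(data.frame(gene = names(breadth), breadth = unname(breadth)),
              file.path(outdir, "expression_breadth.tsv"), hdr)
    idx <- match(names(cl$cluster), report$gene)
    report$expr_cluster[idx] <- unname(cl$cluster)
    report$breadth[match(names(breadth), report$gene)] <- unname(breadth)
    expressed <- rownames(flt$matrix)
    res$expression <- list(filtered = flt, clusters = cl, breadth = breadth,
                           mean_fpkm = rowMeans(flt$matrix))
  }

  if (on_stage("chromatin")) {
    track_files <- list.files(file.path(indir, "tracks"),
                              pattern = "\\.bedGraph$", full.names = TRUE)
    tracks <- setNames(lapply(track_files, read_bedgraph),
                       sub("\\.bedGraph$", "", basename(track_files)))
    gsel <- if (!is.null(expressed)) genes[genes$gene %in% expressed, ]
            else genes
    sm <- tss_signal_matrix(tracks, gsel, flank = config$flank,
                            bin_size = config$bin_size)
    ccl <- cluster_chromatin(sm, k = config$k_chromatin, seed = config$seed)
    biv <- call_bivalent(sm)
    write_tsv(data.frame(gene = names(ccl$cluster),
                         cluster = unname(ccl$cluster)),
              file.path(outdir, "chromatin_clusters.tsv"), hdr)
    write_tsv(biv, file.path(outdir, "bivalency.tsv"), hdr)
    idx <- match(names(ccl$cluster), report$gene)
    report$chromatin_cluster[idx] <- unname(ccl$cluster)
    report$bivalent[match(biv$gene, report$gene)] <- biv$bivalent
    res$chromatin <- list(matrix = sm, clusters = ccl, bivalency = biv)
    if (!is.null(res$expression)) {
      sve <- state_vs_expression(ccl$cluster,
                                 res$expression$mean_fpkm[names(ccl$cluster)],
                                 res$expression$breadth[names(ccl$cluster)])
      write_tsv(sve$summary, file.path(outdir, "chromatin_summary.tsv"), hdr)
      res$chromatin$state_vs_expression <- sve
    }
    .stage_log("chromatin", round(100 * attr(biv, "fraction"), 1),
               "% bivalent genes")
  }

  if (on_stage("evolution") && on_stage("corecall")) {
    triads <- read_tsv(file.path(indir, "triads.tsv"))
    cds <- read_fasta(file.path(indir, "cds_pairs.fna"), "DNA")
    tcl <- classify_triads(triads, res$corecall$calls)
    kk <- kaks_pairs(data.frame(pair = triads$triad, gene_a = triads$gene_A,
                                gene_b = triads$gene_B,
                                stringsAsFactors = FALSE), cds)
    write_tsv(tcl$triads, file.path(outdir, "triad_subtypes.tsv"), hdr)
    write_tsv(kk, file.path(outdir, "kaks.tsv"), hdr)
    res$evolution <- list(triads = tcl, kaks = kk)
    if (!is.null(res$expression))
      res$evolution$contrasts <- compare_pair_groups(
        tcl$pairs, res$expression$mean_fpkm)
    .stage_log("evolution", sum(tcl$triads$subtype == "all_core"),
               " all-core triads of ", nrow(tcl$triads))
  }

  if (on_stage("networks")) {
    gm <- read_expression_tsv(file.path(indir, "grn_expression.tsv"),
                              nonnegative = FALSE)
    tfs <- readLines(file.path(indir, "tfs.txt"))
    prom <- read_fasta(file.path(indir, "promoters.fna"), "DNA")
    mods <- coexpression_modules(gm, min_abs_r = config$min_abs_r)
    edges <- grn_importance(gm, tfs, n_trees = config$n_trees,
                            seed = config$seed)
    top <- top_edges(edges, K = config$top_k)
    hubs <- find_hubs(top)
    hits <- motif_scan(prom, motif = config$motif)
    write_tsv(mods, file.path(outdir, "modules.tsv"), hdr)
    write_tsv(top, file.path(outdir, "grn_top_edges.tsv"), hdr)
    write_tsv(hubs$regulators, file.path(outdir, "hubs.tsv"), hdr)
    write_tsv(hits, file.path(outdir, "motif_hits.tsv"), hdr)
    report$module[match(mods$gene, report$gene)] <- mods$module
    report$hub_rank[match(hubs$regulators$gene, report$gene)] <-
      hubs$regulators$rank
    res$networks <- list(modules = mods, edges = edges, top = top,
                         hubs = hubs, motif_hits = hits)
    .stage_log("networks", nrow(top), " edges kept; hub ",
               hubs$regulators$gene[1])
  }

  if (on_stage("enrichment") && on_stage("corecall")) {
    go <- read_tsv(file.path(indir, "go_annotation.tsv"))
    fam <- read_tsv(file.path(indir, "tf_families.tsv"))
    calls <- res$corecall$calls
    enr <- hypergeom_enrich(calls$gene[calls$status == "core"],
                            calls$gene, go)
    fenr <- family_enrich(calls, fam)
    write_tsv(enr, file.path(outdir, "go_enrichment.tsv"), hdr)
    write_tsv(fenr, file.path(outdir, "family_enrichment.tsv"), hdr)
    res$enrichment <- list(go = enr, family = fenr)
    .stage_log("enrichment", sum(enr$q < 0.05), " terms at q < 0.05")
  }

  write_tsv(report, file.path(outdir, "gene_report.tsv"), hdr)
  res$report <- report
  invisible(res)
}
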