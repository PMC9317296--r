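# Readers and writers for the pipeline's on-disk formats.
#
# Conventions: genomic coordinates are 0-based half-open internally
# (BED/bedGraph style); GFF3 is 1-based inclusive and converted at this
# boundary. All writers emit deterministic bytes (fixed column order, fixed
# number formatting) so identical runs produce identical files.

#' Read a protein or nucleotide FASTA file
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return a [Biostrings::XStringSet]. Duplicate record ids are an error.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup))
    stop("duplicate FASTA ids in ", path, ": ", paste(dup, collapse = ", "))
  x
}

#' Write sequences to FASTA
#' @param x an XStringSet.
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a minimal gene-model GFF3
#'
#' One `gene` feature per row of `genes`. Input coordinates are 0-based
#' half-open and converted to GFF3's 1-based inclusive on write.
#'
#' @param genes data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, and optionally `subgenome`.
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(all(c("gene", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$end <= genes$start)) stop("gene with end <= start")
  attrs <- paste0("ID=", genes$gene)
  if ("subgenome" %in% names(genes))
    attrs <- paste0(attrs, ";subgenome=", genes$subgenome)
  lines <- c("##gff-version 3",
             paste(genes$chrom, "pancore", "gene",
                   format(genes$start + 1L, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   ".", genes$strand, ".", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-model GFF3 into a gene table
#'
#' @param path GFF3 file with `gene` features carrying `ID` (and optionally
#'   `subgenome`) attributes.
#' @return data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss` (0-based position of the transcription start:
#'   `start` on `+`, `end - 1` on `-`), and `subgenome` (NA when absent).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  if (!length(gr)) stop("no gene features in ", path)
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("gene without explicit strand in ", path)
  sub <- if ("subgenome" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$subgenome) else NA_character_
  data.frame(gene = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start0, end = end0, strand = strand,
             tss = ifelse(strand == "+", start0, end0 - 1L),
             subgenome = sub, stringsAsFactors = FALSE)
}

#' Write a bedGraph track
#'
#' @param track data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and `value`; must be sorted and non-overlapping within chromosome.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(track$end <= track$start)) stop("bedGraph interval with end <= start")
  o <- order(track$chrom, track$start)
  track <- track[o, , drop = FALSE]
  .check_bedgraph_disjoint(track)
  writeLines(paste(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

.check_bedgraph_disjoint <- function(track) {
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)]))
      stop("overlapping bedGraph intervals on ", ch)
  }
  invisible(TRUE)
}

#' Read a bedGraph track
#'
#' Rejects unsorted or overlapping intervals (tracks must be disjoint
#' coverage, as emitted by standard count pipelines).
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @return data.frame `chrom`, `start`, `end`, `value`, coordinate-sorted.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      value = gr$score, stringsAsFactors = FALSE)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  .check_bedgraph_disjoint(track)
  rownames(track) <- NULL
  track
}

#' Read an expression matrix TSV (first column = gene id, header = samples)
#' @param path TSV file.
#' @param nonnegative reject negative entries (TRUE for FPKM matrices;
#'   FALSE for already-standardized matrices).
#' @return numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path, nonnegative = TRUE) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  if (nonnegative && any(m < 0))
    stop("negative expression values in ", path)
  m
}

#' Write a numeric matrix as TSV (first column = gene id)
#' @param m matrix with rownames.
#' @param path output file.
#' @param id_col name for the id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  d <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV with an optional provenance header
#' @param d data.frame.
#' @param path output file.
#' @param header optional character vector of `# `-prefixed header lines.
#' @export
write_tsv <- function(d, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (skipping `#` header lines)
#' @param path TSV file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}
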