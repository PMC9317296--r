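# TF-centered co-expression modules, tree-ensemble regulatory network
# inference, edge truncation, hub detection, and promoter motif scanning.

#' Co-expression modules by correlation-based hierarchical clustering
#'
#' Pairwise Pearson correlation over samples, distance `1 - r`
#' (sign-sensitive: a gene and its negation land in different modules; set
#' `absolute = TRUE` for `1 - |r|`), average-linkage hierarchical
#' clustering cut at height `1 - min_abs_r`. Constant rows have undefined
#' correlation and are removed with a warning.
#'
#' @param matrix genes x samples expression matrix (>= 3 genes, >= 4
#'   samples).
#' @param min_abs_r correlation magnitude defining module co-membership.
#' @param absolute use `1 - |r|` distance.
#' @return data.frame `gene`, `module` (integer ids; singletons are their
#'   own modules), with attribute `cut_height`.
#' @export
coexpression_modules <- function(matrix, min_abs_r = 0.7, absolute = FALSE) {
  if (nrow(matrix) < 3 || ncol(matrix) < 4)
    stop("need >= 3 genes and >= 4 samples")
  s <- apply(matrix, 1, sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warning(sum(const), " constant gene row(s) removed (undefined correlation)")
    matrix <- matrix[!const, , drop = FALSE]
  }
  r <- cor(t(matrix))
  d <- if (absolute) 1 - abs(r) else 1 - r
  hc <- hclust(as.dist(d), method = "average")
  mod <- cutree(hc, h = 1 - min_abs_r)
  out <- data.frame(gene = names(mod), module = as.integer(mod),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cut_height") <- 1 - min_abs_r
  out
}

#' Tree-ensemble regulatory network importance (GENIE3-style)
#'
#' For each target gene, fits a random-forest regression of the target's
#' expression on the candidate regulators' expression (excluding the target
#' itself when it is a regulator); edge weight is each regulator's impurity
#' (variance-reduction) importance, normalized to sum to 1 per target.
#' Negative importances are floored at 0. Each target's forest is seeded
#' from `(seed, target id)`, so results do not depend on target iteration
#' order. Zero-variance targets get all-zero weights with a warning.
#'
#' @param matrix genes x samples expression matrix.
#' @param regulators character vector of regulator (TF) gene ids, a subset
#'   of the rownames.
#' @param n_trees trees per target forest.
#' @param seed integer root seed.
#' @param mtry candidate regulators per split; default `sqrt(#regulators)`.
#' @return data.frame `regulator`, `target`, `weight`, sorted by weight
#'   descending (ties: regulator then target id); class `edge_list`.
#' @export
grn_importance <- function(matrix, regulators, n_trees = 1000L, seed = 1L,
                           mtry = NULL) {
  stopifnot(all(regulators %in% rownames(matrix)))
  targets <- rownames(matrix)
  edges <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    regs <- setdiff(regulators, tg)
    if (!length(regs)) next
    y <- matrix[tg, ]
    if (sd(y) == 0) {
      warning("zero-variance target ", tg, ": all edge weights 0")
      edges[[i]] <- data.frame(regulator = regs, target = tg, weight = 0,
                               stringsAsFactors = FALSE)
      next
    }
    x <- as.data.frame(t(matrix[regs, , drop = FALSE]))
    fit <- ranger::ranger(
      x = x, y = as.numeric(y), num.trees = n_trees,
      mtry = if (is.null(mtry)) max(1L, floor(sqrt(length(regs)))) else mtry,
      importance = "impurity", num.threads = 1L,
      seed = substream_seed(seed, tg))
    imp <- pmax(fit$variable.importance, 0)
    tot <- sum(imp)
    edges[[i]] <- data.frame(regulator = regs, target = tg,
                             weight = if (tot > 0) unname(imp / tot) else
                               rep(0, length(regs)),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, edges)
  out <- out[order(-out$weight, out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_list", class(out))
  out
}

#' Keep the top-K edges by weight
#'
#' Sorted by weight descending with ties broken by (regulator, target)
#' lexicographic order, so the truncation is deterministic.
#'
#' @param edges data.frame `regulator`, `target`, `weight`.
#' @param K number of edges to keep (default 1000).
#' @return the truncated edge data.frame (exactly `min(K, n)` rows), with
#'   attribute `K`.
#' @export
top_edges <- function(edges, K = 1000L) {
  if (K < 1) stop("K must be >= 1")
  o <- order(-edges$weight, edges$regulator, edges$target)
  out <- edges[o[seq_len(min(K, nrow(edges)))], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "K") <- K
  out
}

#' Rank regulators by out-degree (and targets by in-degree)
#'
#' @param edges directed edge data.frame `regulator`, `target`.
#' @return list with `regulators` (data.frame `gene`, `out_degree`, `rank`)
#'   and `targets` (`gene`, `in_degree`, `rank`), descending degree, ties
#'   lexicographic.
#' @export
find_hubs <- function(edges) {
  rank_tab <- function(ids) {
    if (!length(ids))
      return(data.frame(gene = character(0), degree = integer(0),
                        rank = integer(0), stringsAsFactors = FALSE))
    tab <- table(ids)
    d <- data.frame(gene = names(tab), degree = as.integer(tab),
                    stringsAsFactors = FALSE)
    d <- d[order(-d$degree, d$gene), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    rownames(d) <- NULL
    d
  }
  reg <- rank_tab(edges$regulator)
  names(reg)[2] <- "out_degree"
  tg <- rank_tab(edges$target)
  names(tg)[2] <- "in_degree"
  list(regulators = reg, targets = tg)
}

#' Scan promoter sequences for an exact motif
#'
#' Exact substring match of the motif on the forward strand and of its
#' reverse complement for the minus strand; `N` never matches. Offsets are
#' 0-based positions of the match start on the forward sequence.
#'
#' @param promoters DNAStringSet (or named character vector) of ACGTN
#'   sequences.
#' @param motif ACGT string (default `"GCCACGTG"`).
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return data.frame `gene`, `offset`, `strand` (possibly 0 rows).
#' @export
motif_scan <- function(promoters, motif = "GCCACGTG",
                       strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (grepl("[^ACGT]", motif)) stop("motif must be an ACGT string")
  if (!methods::is(promoters, "DNAStringSet"))
    promoters <- Biostrings::DNAStringSet(promoters)
  scan_one <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(pat, promoters, fixed = TRUE)
    st <- Biostrings::startIndex(hits)
    do.call(rbind, lapply(seq_along(st), function(i) {
      if (is.null(st[[i]]) || !length(st[[i]])) return(NULL)
      data.frame(gene = names(promoters)[i], offset = st[[i]] - 1L,
                 strand = strand, stringsAsFactors = FALSE)
    }))
  }
  out <- NULL
  if (strands %in% c("both", "+"))
    out <- rbind(out, scan_one(motif, "+"))
  if (strands %in% c("both", "-")) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    out <- rbind(out, scan_one(rc, "-"))
  }
  if (is.null(out))
    out <- data.frame(gene = character(0), offset = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
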