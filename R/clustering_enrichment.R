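# Drug/gene and drug/tissue matrices, drug-wise min-max normalisation,
# complete-linkage Euclidean hierarchical clustering, and chi-squared
# tissue-origin enrichment.

#' Binary gene x drug membership matrix from screen candidates
#'
#' Entry 1 iff the gene participates in at least one candidate pair for the
#' drug. A gene's appearance count is per candidate pair (a gene paired with
#' two partners for one drug counts twice); genes appearing fewer than
#' `min_appearances` times across all candidate sets are dropped.
#'
#' @param scs_records Screen output; only `candidate` rows are used.
#' @param min_appearances Minimum per-pair appearances to retain a gene,
#'   default 2.
#' @return Binary matrix, genes as rows and drugs as columns (possibly 0x0).
#' @export
build_drug_gene_matrix <- function(scs_records, min_appearances = 2) {
  cand <- scs_records[scs_records$candidate, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(matrix(0L, 0, 0))
  }
  long <- data.frame(
    gene = c(cand$geneA, cand$geneB),
    drug = rep(cand$drug, 2),
    stringsAsFactors = FALSE
  )
  appearances <- table(long$gene)
  keep <- names(appearances)[appearances >= min_appearances]
  long <- long[long$gene %in% keep, , drop = FALSE]
  if (nrow(long) == 0) {
    return(matrix(0L, 0, 0))
  }
  tab <- table(long$gene, long$drug)
  m <- (matrix(as.integer(tab), nrow(tab), ncol(tab),
    dimnames = dimnames(tab)
  ) > 0) * 1L
  m
}

#' Min-max normalise the rows of a matrix to \[0, 1\]
#'
#' Each row is scaled by its own range; a constant row maps to all zeros
#' (logged via `message()`). Idempotent.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with rows in \[0, 1\].
#' @export
minmax_normalize_rows <- function(m) {
  rng <- apply(m, 1, range)
  span <- rng[2, ] - rng[1, ]
  flat <- span == 0
  if (any(flat)) {
    message(sum(flat), " constant row(s) mapped to 0 under min-max normalisation")
  }
  out <- (m - rng[1, ]) / ifelse(flat, 1, span)
  out[flat, ] <- 0
  out
}

#' Drug x tissue matrix of MM cell-line counts
#'
#' Counts, per drug, the tissue origins of its MM cell lines (as supplied in
#' `mm_lines`), over the categories of the chosen tissue descriptor, then
#' optionally min-max normalises each drug row to \[0, 1\].
#'
#' @param mm_lines Data.frame with columns `drug`, `cell_line`: the MM-group
#'   membership per drug (e.g. from candidate pairs' doubly-mutant lines).
#' @param meta Cell-line metadata ([read_cell_line_meta()]).
#' @param descriptor `"tissue1"` (coarse, default) or `"tissue2"` (fine).
#' @param normalize `"drug_wise_minmax"` (default) or `"none"`.
#' @return Numeric matrix, drugs as rows and tissue categories as columns.
#' @export
build_drug_tissue_matrix <- function(mm_lines, meta,
                                     descriptor = c("tissue1", "tissue2"),
                                     normalize = c("drug_wise_minmax", "none")) {
  descriptor <- match.arg(descriptor)
  normalize <- match.arg(normalize)
  stopifnot(all(c("drug", "cell_line") %in% names(mm_lines)))
  tis <- meta[[descriptor]][match(mm_lines$cell_line, meta$cell_line)]
  if (any(is.na(tis))) {
    stop("MM line(s) missing from cell-line metadata", call. = FALSE)
  }
  tissues <- sort(unique(meta[[descriptor]]))
  tab <- table(factor(mm_lines$drug), factor(tis, levels = tissues))
  m <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  if (normalize == "drug_wise_minmax") m <- minmax_normalize_rows(m)
  m
}

#' Complete-linkage Euclidean hierarchical clustering
#'
#' Wraps `stats::hclust(dist(x), method = "complete")`; complete linkage
#' guarantees monotone merge heights. Flat clusters at `k` are cut with
#' `stats::cutree()`.
#'
#' @param m Numeric matrix with at least 2 rows.
#' @param k Optional number of flat clusters to cut.
#' @return List of class `"linkage_result"`: `hclust` (the tree), `order`
#'   (leaf order), `heights`, and `clusters` (named vector, when `k` given).
#' @export
hierarchical_cluster <- function(m, k = NULL) {
  if (is.null(dim(m)) || nrow(m) < 2) {
    stop("clustering needs at least 2 rows", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "complete")
  res <- list(
    hclust = hc,
    order = hc$order,
    labels = hc$labels,
    heights = hc$height,
    clusters = if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  )
  class(res) <- "linkage_result"
  res
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(
    "linkage_result: complete-linkage tree over", length(x$order),
    "rows; merge heights", paste(signif(x$heights, 3), collapse = ", "), "\n"
  )
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' @param linkage A `linkage_result`.
#' @param path Optional file path; when given the Newick string is written.
#' @return The Newick string, invisibly when written to file.
#' @export
export_dendrogram <- function(linkage, path = NULL) {
  stopifnot(inherits(linkage, "linkage_result"))
  phy <- ape::as.phylo(linkage$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Chi-squared tissue-origin enrichment
#'
#' Tests homogeneity of an MM-line tissue histogram against the background
#' histogram of all lines (a tissues x 2 table), using the plain chi-squared
#' statistic (no continuity correction). A warning is raised when any
#' expected cell count falls below 5.
#'
#' @param mm_counts Named integer vector: MM-line count per tissue.
#' @param background Named integer vector over the same tissue categories.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
tissue_enrichment <- function(mm_counts, background) {
  if (!setequal(names(mm_counts), names(background))) {
    stop("mm_counts and background must cover the same tissue categories", call. = FALSE)
  }
  tissues <- names(background)
  tab <- cbind(mm = as.numeric(mm_counts[tissues]), background = as.numeric(background[tissues]))
  rownames(tab) <- tissues
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("chi-squared approximation: expected cell count(s) below 5", call. = FALSE)
  }
  list(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value), table = tab
  )
}
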