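# Damaging-variant classification and the binary gene x cell-line matrix
# that the whole pair screen runs on.

#' Filter configuration for damaging-variant classification
#'
#' Thresholds follow the screen's variant-filter cascade: a missense variant
#' is damaging when its SIFT score is below `sift_cut` (strict, deleterious)
#' and its PolyPhen score is above `polyphen_cut` (strict, probably
#' damaging); `missense_rule = "either"` relaxes the conjunction to a union.
#' Genes damaged in fewer than `min_mutated_lines` distinct cell lines are
#' dropped from the matrix.
#'
#' @param sift_cut SIFT threshold, default 0.05 (damaging iff score < cut).
#' @param polyphen_cut PolyPhen threshold, default 0.908 (damaging iff score > cut).
#' @param min_mutated_lines Minimum distinct damaged cell lines per retained
#'   gene, default 10.
#' @param missense_rule `"both"` (SIFT AND PolyPhen, the default) or `"either"`.
#' @param unknown_class `"warn"` (default) or `"fail"`: behaviour on variant
#'   classification labels outside the closed vocabulary.
#' @return A list with class `"filter_config"`.
#' @export
filter_config <- function(sift_cut = 0.05, polyphen_cut = 0.908,
                          min_mutated_lines = 10,
                          missense_rule = c("both", "either"),
                          unknown_class = c("warn", "fail")) {
  missense_rule <- match.arg(missense_rule)
  unknown_class <- match.arg(unknown_class)
  stopifnot(
    sift_cut > 0, sift_cut < 1,
    polyphen_cut > 0, polyphen_cut < 1,
    min_mutated_lines >= 1
  )
  structure(
    list(
      sift_cut = sift_cut, polyphen_cut = polyphen_cut,
      min_mutated_lines = as.integer(min_mutated_lines),
      missense_rule = missense_rule, unknown_class = unknown_class
    ),
    class = "filter_config"
  )
}

#' Classify coding variants into damaging categories
#'
#' Stop-loss and nonsense variants are loss-of-function (`"LoF"`). Missense
#' variants are `"damaging-missense"` when their scores pass the configured
#' SIFT/PolyPhen rule; a missing score never passes. Everything else is
#' `"none"`.
#'
#' @param variants Coding-variant data.frame (see [read_coding_variants()]).
#' @param cfg A [filter_config()].
#' @return Character vector of categories, one per row:
#'   `"LoF"`, `"damaging-missense"` or `"none"`.
#' @export
classify_variants <- function(variants, cfg = filter_config()) {
  cls <- if (!is.null(variants$class_mapped)) variants$class_mapped else variants$classification
  unknown <- setdiff(unique(cls), variant_classes)
  if (length(unknown) > 0) {
    msg <- paste(
      "unknown variant classification label(s):",
      paste(utils::head(unknown, 10), collapse = ", ")
    )
    if (cfg$unknown_class == "fail") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    cls[cls %in% unknown] <- "other"
  }
  out <- rep("none", length(cls))
  out[cls %in% c("stop-loss", "nonsense")] <- "LoF"
  sift_pass <- !is.na(variants$sift) & variants$sift < cfg$sift_cut
  poly_pass <- !is.na(variants$polyphen) & variants$polyphen > cfg$polyphen_cut
  mis_pass <- if (cfg$missense_rule == "both") sift_pass & poly_pass else sift_pass | poly_pass
  out[cls == "missense" & mis_pass] <- "damaging-missense"
  out
}

#' Classify a single variant or copy-number record
#'
#' Convenience scalar wrapper used in examples and spot checks; copy-number
#' records yield `"CNV-deletion"` only for the homozygous-deletion category.
#'
#' @param v A one-row data.frame: either a coding-variant record or a
#'   copy-number record (recognised by a `category` column).
#' @param cfg A [filter_config()].
#' @return One of `"LoF"`, `"damaging-missense"`, `"CNV-deletion"`, `"none"`.
#' @export
classify_variant <- function(v, cfg = filter_config()) {
  stopifnot(is.data.frame(v), nrow(v) == 1)
  if (!is.null(v$category)) {
    return(if (v$category == "homozygous-deletion") "CNV-deletion" else "none")
  }
  classify_variants(v, cfg)
}

#' Build the binary damaging-mutation matrix
#'
#' Assembles per-(gene, cell line) counts of LoF variants, damaging missense
#' variants and homozygous copy-number deletions, forms the union indicator
#' (`status = 1` iff any category count > 0), and drops genes damaged in
#' fewer than `cfg$min_mutated_lines` *distinct* cell lines (multiple hits
#' in one line count once).
#'
#' @param variants Coding-variant data.frame, or NULL.
#' @param cnvs Copy-number data.frame, or NULL.
#' @param cfg A [filter_config()].
#' @param cell_lines Character vector: the full cell-line universe (columns of
#'   zeros are kept for undamaged lines). Mandatory and non-empty.
#' @return An object of class `"damaging_matrix"`: list with `genes`,
#'   `cell_lines`, binary `status` matrix, and integer count matrices
#'   `lof`, `missense`, `deletion` (genes x cell lines).
#' @export
build_damaging_matrix <- function(variants, cnvs = NULL, cfg = filter_config(),
                                  cell_lines) {
  if (missing(cell_lines) || length(cell_lines) == 0) {
    stop("cell-line universe must be supplied and non-empty", call. = FALSE)
  }
  cell_lines <- as.character(unique(cell_lines))

  hits <- list()
  if (!is.null(variants) && nrow(variants) > 0) {
    cat_v <- classify_variants(variants, cfg)
    keep <- cat_v != "none"
    if (any(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene = variants$gene[keep], cell_line = variants$cell_line[keep],
        category = ifelse(cat_v[keep] == "LoF", "lof", "missense"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    keep <- cnvs$category == "homozygous-deletion"
    if (any(keep)) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene = cnvs$gene[keep], cell_line = cnvs$cell_line[keep],
        category = "deletion", stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (length(hits) > 0) do.call(rbind, hits) else
    data.frame(gene = character(), cell_line = character(), category = character())

  bad_line <- setdiff(unique(hits$cell_line), cell_lines)
  if (length(bad_line) > 0) {
    stop(
      "damaging calls reference cell line(s) outside the universe: ",
      paste(utils::head(bad_line, 5), collapse = ", "),
      call. = FALSE
    )
  }

  genes <- sort(unique(hits$gene))
  dims <- c(length(genes), length(cell_lines))
  dn <- list(genes, cell_lines)
  count_mat <- function(cat) {
    m <- matrix(0L, dims[1], dims[2], dimnames = dn)
    sub <- hits[hits$category == cat, , drop = FALSE]
    if (nrow(sub) > 0) {
      tab <- table(factor(sub$gene, genes), factor(sub$cell_line, cell_lines))
      m <- matrix(as.integer(tab), dims[1], dims[2], dimnames = dn)
    }
    m
  }
  lof <- count_mat("lof")
  mis <- count_mat("missense")
  del <- count_mat("deletion")
  status <- (lof + mis + del > 0L) * 1L

  keep_gene <- rowSums(status) >= cfg$min_mutated_lines
  structure(
    list(
      genes = genes[keep_gene], cell_lines = cell_lines,
      status = status[keep_gene, , drop = FALSE],
      lof = lof[keep_gene, , drop = FALSE],
      missense = mis[keep_gene, , drop = FALSE],
      deletion = del[keep_gene, , drop = FALSE],
      min_mutated_lines = cfg$min_mutated_lines
    ),
    class = "damaging_matrix"
  )
}

#' @export
print.damaging_matrix <- function(x, ...) {
  cat(
    "damaging_matrix:", length(x$genes), "genes x", length(x$cell_lines),
    "cell lines (genes damaged in >=", x$min_mutated_lines, "lines)\n"
  )
  invisible(x)
}

#' Number of unordered gene pairs for n genes
#'
#' Closed form n(n-1)/2; 3804 retained genes give 7,233,306 pairs.
#'
#' @param n_genes Number of genes.
#' @return Pair count (double, to avoid integer overflow).
#' @export
n_gene_pairs <- function(n_genes) {
  n <- as.numeric(n_genes)
  n * (n - 1) / 2
}

#' Enumerate all unordered gene pairs of a damaging matrix
#'
#' Pairs are canonically ordered: lexicographic within a pair and across
#' pairs, deduplicated by construction.
#'
#' @param matrix A `damaging_matrix`, or a character vector of gene names.
#' @return Data.frame with columns `geneA`, `geneB` (geneA < geneB).
#' @export
enumerate_pairs <- function(matrix) {
  genes <- if (inherits(matrix, "damaging_matrix")) matrix$genes else as.character(matrix)
  genes <- sort(unique(genes))
  n <- length(genes)
  if (n < 2) {
    return(data.frame(geneA = character(), geneB = character(), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2)
  data.frame(
    geneA = genes[idx[1, ]], geneB = genes[idx[2, ]],
    stringsAsFactors = FALSE
  )
}

#' Export the per-gene damaging count table
#'
#' One row per gene: distinct damaged lines per category and for the union
#' indicator, mirroring a gene/cell-line mutation count summary.
#'
#' @param matrix A `damaging_matrix`.
#' @param path Optional output path (TSV via [write_results()]).
#' @return The summary data.frame (invisibly written when `path` given).
#' @export
damaging_count_table <- function(matrix, path = NULL) {
  stopifnot(inherits(matrix, "damaging_matrix"))
  out <- data.frame(
    gene = matrix$genes,
    lof_lines = as.integer(rowSums(matrix$lof > 0)),
    missense_lines = as.integer(rowSums(matrix$missense > 0)),
    deletion_lines = as.integer(rowSums(matrix$deletion > 0)),
    any_lines = as.integer(rowSums(matrix$status > 0)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_results(out, path, allow_empty = TRUE)
  out
}
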