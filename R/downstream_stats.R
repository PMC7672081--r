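# Secondary comparisons: per-line mutation-burden summaries of a subgroup
# vs the whole panel, resistance-gene overlap tests, and per-gene expression
# comparison between the combined MM and MW groups.

#' Default resistance-gene list for MAPK-pathway inhibitors
#'
#' Genes whose mutation is commonly associated with resistance to BRAF/MAPK
#' inhibitors; used by [resistance_overlap()]. Anchor amplification, when
#' copy-number data carry it, is consumed as an extra status input, not
#' inferred here.
#'
#' @return Character vector of gene symbols.
#' @export
default_resistance_genes <- function() {
  c(
    "MAP2K1", "MAP2K2", "MAPK1", "MAPK3",
    "PTEN", "RAC1", "CDK4", "AKT1", "NF1", "NRAS"
  )
}

#' Compare per-line mutation burden of a subgroup against the panel
#'
#' For each damaging category (LoF, damaging missense, CNV deletion) the
#' per-cell-line variant counts over `gene_set` (default: all matrix genes)
#' are summarised as mean and SD in the subgroup and in the full population,
#' with a Student's t-test P per category.
#'
#' @param subgroup_lines Character vector of cell lines (subset of `all_lines`).
#' @param all_lines Character vector: the reference population.
#' @param matrix A `damaging_matrix` (per-category counts are used).
#' @param gene_set Optional gene restriction.
#' @return Data.frame: category, subgroup mean/SD, population mean/SD, `p`.
#' @export
compare_mutation_burden <- function(subgroup_lines, all_lines, matrix,
                                    gene_set = NULL) {
  stopifnot(inherits(matrix, "damaging_matrix"))
  if (!all(subgroup_lines %in% all_lines)) {
    stop("subgroup must be a subset of the reference population", call. = FALSE)
  }
  genes <- if (is.null(gene_set)) matrix$genes else intersect(gene_set, matrix$genes)
  if (length(genes) == 0) stop("gene_set shares no genes with the matrix", call. = FALSE)
  cats <- c(LoF = "lof", missense = "missense", deletion = "deletion")
  rows <- lapply(names(cats), function(cn) {
    counts <- colSums(matrix[[cats[[cn]]]][genes, , drop = FALSE])
    sub <- counts[subgroup_lines]
    all <- counts[all_lines]
    p <- if (stats::var(sub) == 0 && stats::var(all) == 0) {
      if (mean(sub) == mean(all)) 1 else NA_real_
    } else if (identical(sort(unname(sub)), sort(unname(all)))) {
      1 # subgroup == population: no difference by construction
    } else {
      stats::t.test(sub, all, var.equal = TRUE)$p.value
    }
    data.frame(
      category = cn,
      subgroup_mean = mean(sub), subgroup_sd = stats::sd(sub),
      population_mean = mean(all), population_sd = stats::sd(all),
      p = p, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Resistance-gene overlap across combined mutation groups
#'
#' Builds per-line/patient resistance status (any damaging call in the
#' resistance gene list, or a supplied status vector) and tests homogeneity
#' of status across the combined groups, plus the focused MMC-vs-MWC 2x2
#' comparison. Empty groups are dropped with a warning.
#'
#' @param labels Named character vector (or `combined_grouping`) of
#'   WWC/WMC/MWC/MMC labels per line/patient.
#' @param resistance_status Named logical vector over the same names.
#' @return List with `overall` (chi-squared across all non-empty groups) and
#'   `mmc_vs_mwc` (2x2 test), each holding `statistic`, `df`, `p_value`,
#'   `table`.
#' @export
resistance_overlap <- function(labels, resistance_status) {
  if (inherits(labels, "combined_grouping")) {
    labels <- stats::setNames(labels$label, labels$cell_line)
  }
  common <- intersect(names(labels), names(resistance_status))
  lab <- labels[common]
  status <- resistance_status[common]
  lev <- intersect(c("WWC", "WMC", "MWC", "MMC"), unique(lab))
  dropped <- setdiff(c("WWC", "WMC", "MWC", "MMC"), lev)
  if (length(dropped) > 0) {
    warning("empty group(s) dropped: ", paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (length(unique(status)) < 2) {
    warning("resistance status is constant; chi-squared tests are degenerate",
      call. = FALSE
    )
  }
  chisq_of <- function(sub_lab, sub_status, levels) {
    tab <- table(factor(sub_lab, levels), factor(sub_status, c(FALSE, TRUE)))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = unname(ht$p.value), table = tab
    )
  }
  overall <- chisq_of(lab, status, lev)
  mmc_vs_mwc <- if (all(c("MMC", "MWC") %in% lev)) {
    keep <- lab %in% c("MMC", "MWC")
    chisq_of(lab[keep], status[keep], c("MWC", "MMC"))
  } else {
    warning("MMC-vs-MWC comparison skipped: a group is empty", call. = FALSE)
    NULL
  }
  list(overall = overall, mmc_vs_mwc = mmc_vs_mwc)
}

#' Resistance status per cell line from the damaging matrix
#'
#' @param matrix A `damaging_matrix`.
#' @param resistance_genes Gene list, default [default_resistance_genes()].
#' @return Named logical vector over the matrix's cell lines.
#' @export
resistance_status_from_matrix <- function(matrix,
                                          resistance_genes = default_resistance_genes()) {
  stopifnot(inherits(matrix, "damaging_matrix"))
  genes <- intersect(resistance_genes, matrix$genes)
  if (length(genes) == 0) {
    return(stats::setNames(rep(FALSE, length(matrix$cell_lines)), matrix$cell_lines))
  }
  stats::setNames(
    colSums(matrix$status[genes, , drop = FALSE]) > 0,
    matrix$cell_lines
  )
}

#' Per-gene expression comparison: combined MM vs MW lines
#'
#' Student's t test per gene of `gene_set` between the MM and MW cell-line
#' groups, with volcano coordinates (mean difference, -log10 P). Genes with
#' fewer than 2 non-missing values in either group are excluded with a
#' warning. Raw P values are reported by default; `adjust = TRUE` adds a
#' BH-adjusted column.
#'
#' @param expression Numeric matrix, genes x cell lines.
#' @param mm_lines,mw_lines Character vectors of cell-line names.
#' @param gene_set Optional gene restriction (default all rows).
#' @param adjust Add BH-adjusted P values, default FALSE.
#' @return Data.frame sorted by P: gene, group means, `difference`
#'   (MM - MW), `p`, `neg_log10_p` (and `q` when `adjust`).
#' @export
expression_mm_vs_mw <- function(expression, mm_lines, mw_lines,
                                gene_set = NULL, adjust = FALSE) {
  stopifnot(length(mm_lines) >= 2, length(mw_lines) >= 2)
  genes <- if (is.null(gene_set)) rownames(expression) else
    intersect(gene_set, rownames(expression))
  rows <- lapply(genes, function(g) {
    mm <- expression[g, mm_lines]
    mw <- expression[g, mw_lines]
    mm <- mm[!is.na(mm)]
    mw <- mw[!is.na(mw)]
    if (length(mm) < 2 || length(mw) < 2) {
      warning("gene ", g, " excluded: too many missing values", call. = FALSE)
      return(NULL)
    }
    p <- if (stats::var(mm) == 0 && stats::var(mw) == 0 && mean(mm) == mean(mw)) {
      1
    } else {
      stats::t.test(mm, mw, var.equal = TRUE)$p.value
    }
    data.frame(
      gene = g, mean_MM = mean(mm), mean_MW = mean(mw),
      difference = mean(mm) - mean(mw), p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(
      gene = character(), mean_MM = numeric(), mean_MW = numeric(),
      difference = numeric(), p = numeric(), neg_log10_p = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  out$neg_log10_p <- -log10(out$p)
  if (adjust) out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
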