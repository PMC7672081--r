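# Combined-partner analysis: pool the screen's partner genes of an anchor
# gene (per drug, or across a drug cluster), reclassify cell lines into
# combined groups (WWC/WMC/MWC/MMC), and test burden effects.

#' Combine SCS partner genes of an anchor gene and regroup cell lines
#'
#' Collects every partner of `anchor` among candidate pairs of the screen
#' output — restricted to one drug (`scope = "drug_specific"`) or unioned
#' across a drug set (`scope = "multidrug"`) — and labels each cell line of
#' the matrix: first letter = anchor status, second letter = whether *any*
#' partner gene carries a damaging mutation. `burden` counts the mutated
#' partner genes per line.
#'
#' @param anchor Anchor gene symbol (e.g. "BRAF").
#' @param scs_records Screen output ([screen_drug()]/[screen_all()]).
#' @param scope `"drug_specific"` or `"multidrug"`.
#' @param matrix A `damaging_matrix`.
#' @param drug Drug identifier (`drug_specific`) or character vector of drugs
#'   forming the cluster (`multidrug`; default: all drugs with a candidate
#'   pair involving the anchor).
#' @return Data.frame (`cell_line`, `label`, `anchor_status`, `burden`) of
#'   class `"combined_grouping"`, with attributes `anchor`, `partner_set`,
#'   `scope`.
#' @export
build_combined_grouping <- function(anchor, scs_records,
                                    scope = c("drug_specific", "multidrug"),
                                    matrix, drug = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(matrix, "damaging_matrix"))
  cand <- scs_records[scs_records$candidate &
    (scs_records$geneA == anchor | scs_records$geneB == anchor), , drop = FALSE]
  if (scope == "drug_specific") {
    if (is.null(drug) || length(drug) != 1) {
      stop("drug_specific scope needs exactly one drug", call. = FALSE)
    }
    cand <- cand[cand$drug == drug, , drop = FALSE]
  } else if (!is.null(drug)) {
    cand <- cand[cand$drug %in% drug, , drop = FALSE]
  }
  partners <- sort(unique(ifelse(cand$geneA == anchor, cand$geneB, cand$geneA)))
  if (length(partners) == 0) {
    stop("no candidate pair involves anchor '", anchor, "' in the given scope",
      call. = FALSE
    )
  }
  stopifnot(anchor %in% matrix$genes, all(partners %in% matrix$genes))
  a <- matrix$status[anchor, ]
  burden <- colSums(matrix$status[partners, , drop = FALSE])
  label <- ifelse(a == 1,
    ifelse(burden > 0, "MMC", "MWC"),
    ifelse(burden > 0, "WMC", "WWC")
  )
  out <- data.frame(
    cell_line = matrix$cell_lines, label = label,
    anchor_status = as.integer(a), burden = as.integer(burden),
    stringsAsFactors = FALSE
  )
  attr(out, "anchor") <- anchor
  attr(out, "partner_set") <- partners
  attr(out, "scope") <- scope
  class(out) <- c("combined_grouping", "data.frame")
  out
}

combined_values <- function(grouping, ic50, drug) {
  y <- ic50_vector(ic50, drug)
  g <- grouping[grouping$cell_line %in% names(y), , drop = FALSE]
  g$ln_ic50 <- as.numeric(y[g$cell_line])
  g
}

#' Compare ln IC50 across the combined groups
#'
#' Reports per-group n and mean, whether MMC has the lowest mean, and the
#' pairwise Student's t-test P of MMC against each of WWC, WMC, MWC.
#' A comparison against a group with fewer than 2 values is skipped with a
#' warning.
#'
#' @param grouping A `combined_grouping`.
#' @param ic50 Averaged dose-response table.
#' @param drug Drug identifier.
#' @return List with `groups` (data.frame of n and mean per label),
#'   `mmc_lowest` (logical), `pairwise_p` (named numeric vector).
#' @export
compare_combined_groups <- function(grouping, ic50, drug) {
  g <- combined_values(grouping, ic50, drug)
  labs <- c("WWC", "WMC", "MWC", "MMC")
  vals <- lapply(labs, function(l) g$ln_ic50[g$label == l])
  names(vals) <- labs
  groups <- data.frame(
    label = labs,
    n = vapply(vals, length, integer(1)),
    mean_ln_ic50 = vapply(vals, function(v) if (length(v) > 0) mean(v) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE
  )
  mmc_lowest <- {
    m <- groups$mean_ln_ic50
    !is.na(m[4]) && all(m[4] < m[1:3], na.rm = TRUE)
  }
  pairwise_p <- vapply(c("WWC", "WMC", "MWC"), function(l) {
    if (length(vals$MMC) < 2 || length(vals[[l]]) < 2) {
      warning("comparison MMC vs ", l, " skipped: group too small", call. = FALSE)
      return(NA_real_)
    }
    stats::t.test(vals$MMC, vals[[l]], var.equal = TRUE)$p.value
  }, numeric(1))
  list(groups = groups, mmc_lowest = mmc_lowest, pairwise_p = pairwise_p)
}

#' Burden analysis: drug response by number of mutated partner genes
#'
#' Stratifies the anchor-mutated cell lines by their partner-mutation burden
#' — either every exact count (`"exact_count"`) or zero / one / two-plus
#' (`"zero_one_twoplus"`, the default) — and compares ln IC50 across strata
#' with pairwise Student's t tests and a one-way ANOVA.
#'
#' @param grouping A `combined_grouping`.
#' @param ic50 Averaged dose-response table.
#' @param drug Drug identifier.
#' @param strata_rule `"zero_one_twoplus"` or `"exact_count"`.
#' @return List with `strata` (data.frame: stratum, n, mean), `pairwise`
#'   (data.frame of stratum pairs and t-test P), `anova_p`.
#' @export
burden_analysis <- function(grouping, ic50, drug,
                            strata_rule = c("zero_one_twoplus", "exact_count")) {
  strata_rule <- match.arg(strata_rule)
  g <- combined_values(grouping, ic50, drug)
  g <- g[g$anchor_status == 1, , drop = FALSE]
  if (nrow(g) == 0) stop("no anchor-mutated cell lines with IC50 for ", drug, call. = FALSE)
  stratum <- if (strata_rule == "zero_one_twoplus") {
    ifelse(g$burden == 0, "MM0", ifelse(g$burden == 1, "MM1", "MM2plus"))
  } else {
    paste0("MM", g$burden)
  }
  lev <- unique(stratum[order(g$burden)])
  stratum <- factor(stratum, levels = lev)
  strata <- data.frame(
    stratum = lev,
    n = as.integer(table(stratum)[lev]),
    mean_ln_ic50 = as.numeric(tapply(g$ln_ic50, stratum, mean)[lev]),
    stringsAsFactors = FALSE
  )
  if (length(lev) < 2) {
    warning("single burden stratum; tests skipped", call. = FALSE)
    return(list(
      strata = strata,
      pairwise = data.frame(
        stratum_a = character(), stratum_b = character(),
        p = numeric(), stringsAsFactors = FALSE
      ),
      anova_p = NA_real_
    ))
  }
  combs <- utils::combn(lev, 2)
  pairwise <- data.frame(
    stratum_a = combs[1, ], stratum_b = combs[2, ],
    p = apply(combs, 2, function(ab) {
      va <- g$ln_ic50[stratum == ab[1]]
      vb <- g$ln_ic50[stratum == ab[2]]
      if (length(va) < 2 || length(vb) < 2) {
        return(NA_real_)
      }
      stats::t.test(va, vb, var.equal = TRUE)$p.value
    }),
    stringsAsFactors = FALSE
  )
  fit <- stats::aov(ln_ic50 ~ stratum, data = data.frame(ln_ic50 = g$ln_ic50, stratum = stratum))
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  list(strata = strata, pairwise = pairwise, anova_p = anova_p)
}
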