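# Frequency summaries of screen hits: per-pair MM frequencies among
# anchor-mutated lines and per-drug mutation frequencies among tested lines.

#' Per-pair and per-drug MM frequency summary
#'
#' Given per-(pair, drug) counts of doubly-mutant (MM) cell lines and
#' per-drug totals, computes the frequencies usually reported for an
#' anchor-gene drug cluster: each pair's MM lines as a percentage of the
#' drug's anchor-mutated lines, and per drug the anchor-mutated percentage
#' of tested lines, the anchor-related MM percentage of anchor-mutated
#' lines, and the all-MM percentage of tested lines.
#'
#' @param counts Data.frame with columns `pair`, `drug`, `mm_lines`.
#' @param totals Data.frame with columns `drug`, `tested_lines`,
#'   `anchor_mutated`, `anchor_related_mm`, `mm_total`.
#' @return List with `per_pair` (counts plus `pct_of_anchor_mutated`) and
#'   `per_drug` (totals plus `anchor_mut_pct`, `anchor_mm_of_anchor_pct`,
#'   `mm_of_tested_pct`), all percentages on the 0-100 scale.
#' @export
mm_frequency_summary <- function(counts, totals) {
  stopifnot(
    all(c("pair", "drug", "mm_lines") %in% names(counts)),
    all(c("drug", "tested_lines", "anchor_mutated", "anchor_related_mm", "mm_total")
    %in% names(totals))
  )
  idx <- match(counts$drug, totals$drug)
  if (any(is.na(idx))) stop("counts reference a drug missing from totals", call. = FALSE)
  per_pair <- counts
  per_pair$pct_of_anchor_mutated <- 100 * counts$mm_lines / totals$anchor_mutated[idx]
  per_drug <- totals
  per_drug$anchor_mut_pct <- 100 * totals$anchor_mutated / totals$tested_lines
  per_drug$anchor_mm_of_anchor_pct <- 100 * totals$anchor_related_mm / totals$anchor_mutated
  per_drug$mm_of_tested_pct <- 100 * totals$mm_total / totals$tested_lines
  list(per_pair = per_pair, per_drug = per_drug)
}

#' Composition percentages of a panel category table
#'
#' @param composition Data.frame with columns `category`, `count`, where one
#'   row has category `"total"`.
#' @return The data.frame with a `pct_of_total` column (total row excluded).
#' @export
panel_composition_pct <- function(composition) {
  stopifnot(all(c("category", "count") %in% names(composition)))
  total <- composition$count[composition$category == "total"]
  if (length(total) != 1) stop("composition needs exactly one 'total' row", call. = FALSE)
  out <- composition[composition$category != "total", , drop = FALSE]
  out$pct_of_total <- 100 * out$count / total
  out
}
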