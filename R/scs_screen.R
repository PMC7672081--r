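# The core synergistic chemo-sensitivity screen: per drug, partition cell
# lines by the mutation status of a gene pair (WW/WM/MW/MM), test MM vs the
# pooled non-MM groups on ln IC50, BH-correct within the drug, and apply the
# synergy filters.

#' Screen configuration
#'
#' @param min_group_size Minimum cell lines per group (all four of WW, WM,
#'   MW, MM), default 5.
#' @param q_threshold Drug-wise FDR level for candidate calls, default 0.05.
#' @param mm_ww_filter Synergy filter relating the MM group's maximum ln IC50
#'   to the WW group's median: `"mm_max_lt_ww_median"` (default; the
#'   sensitivity-consistent direction), `"mm_max_gt_ww_median"` (the literal
#'   opposite direction), or `"off"`.
#' @param t_variant `"pooled"` (Student's two-sample t, default) or `"welch"`.
#' @param require_mm_lower Require mean ln IC50 of MM below the pooled non-MM
#'   mean (drug sensitisation), default TRUE.
#' @param commercial_only Restrict [screen_all()] candidates to commercial
#'   drugs, default TRUE.
#' @return A list with class `"screen_config"`.
#' @export
screen_config <- function(min_group_size = 5, q_threshold = 0.05,
                          mm_ww_filter = c("mm_max_lt_ww_median", "mm_max_gt_ww_median", "off"),
                          t_variant = c("pooled", "welch"),
                          require_mm_lower = TRUE, commercial_only = TRUE) {
  mm_ww_filter <- match.arg(mm_ww_filter)
  t_variant <- match.arg(t_variant)
  stopifnot(min_group_size >= 2, q_threshold > 0, q_threshold < 1)
  structure(
    list(
      min_group_size = as.integer(min_group_size), q_threshold = q_threshold,
      mm_ww_filter = mm_ww_filter, t_variant = t_variant,
      require_mm_lower = isTRUE(require_mm_lower),
      commercial_only = isTRUE(commercial_only)
    ),
    class = "screen_config"
  )
}

#' Average replicate IC50 measurements
#'
#' Collapses a dose-response record table to one natural-log IC50 value per
#' (drug, cell line): the arithmetic mean (on the ln scale) of the available
#' sources. Triplicate or deeper replication is unusual for these panels and
#' is reported via a warning.
#'
#' @param records Dose-response data.frame (see [read_dose_response()]).
#' @return Data.frame with columns `drug`, `cell_line`, `ln_ic50`,
#'   `n_sources`.
#' @export
average_replicates <- function(records) {
  stopifnot(all(c("drug", "cell_line", "ln_ic50") %in% names(records)))
  key <- interaction(records$drug, records$cell_line, drop = TRUE, sep = "\r")
  mean_by <- tapply(records$ln_ic50, key, mean)
  n_by <- tapply(records$ln_ic50, key, length)
  parts <- strsplit(names(mean_by), "\r", fixed = TRUE)
  out <- data.frame(
    drug = vapply(parts, `[`, "", 1),
    cell_line = vapply(parts, `[`, "", 2),
    ln_ic50 = as.numeric(mean_by),
    n_sources = as.integer(n_by),
    stringsAsFactors = FALSE
  )
  if (any(out$n_sources >= 3)) {
    warning(
      sum(out$n_sources >= 3),
      " (drug, cell line) pair(s) measured three or more times; all sources averaged",
      call. = FALSE
    )
  }
  out[order(out$drug, out$cell_line), , drop = FALSE]
}

ic50_vector <- function(ic50, drug) {
  sub <- ic50[ic50$drug == drug, , drop = FALSE]
  if (nrow(sub) == 0) stop("drug not present in IC50 table: ", drug, call. = FALSE)
  stats::setNames(sub$ln_ic50, sub$cell_line)
}

#' Assign cell lines to WW/WM/MW/MM groups for one gene pair and drug
#'
#' Only cell lines with an IC50 value for the drug are labelled. The first
#' letter is the status of `geneA`, the second of `geneB` (M = damaging
#' mutation, W = wild-type).
#'
#' @param pair Character vector `c(geneA, geneB)` (both in the matrix).
#' @param matrix A `damaging_matrix`.
#' @param ic50 Averaged dose-response table ([average_replicates()]).
#' @param drug Drug identifier.
#' @return A data.frame (`cell_line`, `ln_ic50`, `group`) with attribute
#'   `sizes` = named counts of the four groups; class `"pair_grouping"`.
#' @export
assign_groups <- function(pair, matrix, ic50, drug) {
  stopifnot(inherits(matrix, "damaging_matrix"), length(pair) == 2)
  missing_gene <- setdiff(pair, matrix$genes)
  if (length(missing_gene) > 0) {
    stop("gene(s) not in damaging matrix: ", paste(missing_gene, collapse = ", "),
      call. = FALSE
    )
  }
  y <- ic50_vector(ic50, drug)
  lines <- intersect(names(y), matrix$cell_lines)
  sa <- matrix$status[pair[1], lines]
  sb <- matrix$status[pair[2], lines]
  group <- ifelse(sa == 1,
    ifelse(sb == 1, "MM", "MW"),
    ifelse(sb == 1, "WM", "WW")
  )
  out <- data.frame(
    cell_line = lines, ln_ic50 = as.numeric(y[lines]), group = group,
    stringsAsFactors = FALSE
  )
  attr(out, "pair") <- pair
  attr(out, "drug") <- drug
  attr(out, "sizes") <- vapply(
    c(WW = "WW", WM = "WM", MW = "MW", MM = "MM"),
    function(g) sum(group == g), integer(1)
  )
  class(out) <- c("pair_grouping", "data.frame")
  out
}

#' Model P value: MM vs pooled non-MM t test on ln IC50
#'
#' The model P value is the two-sided P of a two-sample t test (pooled
#' variance by default) comparing the MM group against the union of WW, WM
#' and MW.
#'
#' @param grouping A `pair_grouping` from [assign_groups()].
#' @param cfg A [screen_config()].
#' @return List with `model_p`, `t`, `mean_MM`, `mean_nonMM`, `n_MM`,
#'   `n_nonMM`.
#' @export
model_p <- function(grouping, cfg = screen_config()) {
  mm <- grouping$ln_ic50[grouping$group == "MM"]
  non <- grouping$ln_ic50[grouping$group != "MM"]
  if (length(mm) < 2 || length(non) < 2) {
    stop("model_p needs at least two values in MM and in pooled non-MM", call. = FALSE)
  }
  if (stats::var(mm) == 0 && stats::var(non) == 0) {
    if (mean(mm) == mean(non)) {
      stop("degenerate test: zero variance in both samples", call. = FALSE)
    }
    stop("degenerate test: zero variance in both samples (means differ)", call. = FALSE)
  }
  ht <- stats::t.test(mm, non, var.equal = (cfg$t_variant == "pooled"))
  list(
    model_p = unname(ht$p.value), t = unname(ht$statistic),
    mean_MM = mean(mm), mean_nonMM = mean(non),
    n_MM = length(mm), n_nonMM = length(non)
  )
}

#' Benjamini-Hochberg adjustment of one drug's model P values
#'
#' Standard step-up: q_(i) = min over j >= i of p_(j) * m / j, clipped at 1,
#' returned in the original order.
#'
#' @param p_values Numeric vector of P values in \[0, 1\].
#' @return Numeric vector of Q values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

# Vectorised per-drug screen core. Computes, for every pair of matrix genes,
# the four group sizes and the pooled t of MM vs non-MM from cross-products,
# avoiding a per-pair pass over the cell lines.
screen_core <- function(status, y) {
  n <- length(y)
  S <- t(status) # lines x genes, binary
  storage.mode(S) <- "double"
  nA <- colSums(S)
  nMM <- crossprod(S) # genes x genes: lines mutated in both
  sumy <- sum(y)
  ssy <- sum(y^2)
  Sy <- S * y
  sMM <- crossprod(S, Sy) # sum of y over MM lines
  ssMM <- crossprod(S, S * y^2) # sum of y^2 over MM lines

  list(
    n = n, nA = nA, nMM = nMM, sMM = sMM, ssMM = ssMM,
    sumy = sumy, ssy = ssy
  )
}

pooled_t_p <- function(n1, s1, ss1, n2, s2, ss2, welch = FALSE) {
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- (ss1 - n1 * m1^2) / (n1 - 1)
  v2 <- (ss2 - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0) # guard tiny negative round-off
  v2 <- pmax(v2, 0)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = p, m1 = m1, m2 = m2)
}

#' Screen every gene pair of the damaging matrix against one drug
#'
#' For each unordered pair of retained genes the cell lines with an IC50 for
#' the drug are partitioned into WW/WM/MW/MM; pairs whose four groups all
#' reach `cfg$min_group_size` form the tested batch. Within that batch the
#' model P (MM vs pooled non-MM t test) is BH-adjusted to a Q value, and a
#' pair is a candidate when it additionally passes the direction flag
#' (MM mean lower) and the MM-max/WW-median filter.
#'
#' @param drug Drug identifier (must be present in `ic50`).
#' @param matrix A `damaging_matrix`.
#' @param ic50 Averaged dose-response table.
#' @param cfg A [screen_config()].
#' @param pairs Optional data.frame (`geneA`, `geneB`) restricting the pairs
#'   screened; default all pairs from [enumerate_pairs()].
#' @return Data.frame of SCS records, one row per pair: group sizes, group
#'   means, `model_p`, `q`, the four filter flags and `candidate`.
#' @export
screen_drug <- function(drug, matrix, ic50, cfg = screen_config(), pairs = NULL) {
  stopifnot(inherits(matrix, "damaging_matrix"))
  y_full <- ic50_vector(ic50, drug)
  lines <- intersect(names(y_full), matrix$cell_lines)
  y <- as.numeric(y_full[lines])
  status <- matrix$status[, lines, drop = FALSE]

  if (is.null(pairs)) pairs <- enumerate_pairs(matrix)
  if (nrow(pairs) == 0) {
    return(empty_scs_records())
  }
  gi <- match(pairs$geneA, matrix$genes)
  gj <- match(pairs$geneB, matrix$genes)
  if (any(is.na(gi) | is.na(gj))) stop("pair references gene outside the matrix", call. = FALSE)

  core <- screen_core(status, y)
  idx <- cbind(gi, gj)
  n_mm <- core$nMM[idx]
  n_a <- core$nA[gi]
  n_b <- core$nA[gj]
  n_mw <- n_a - n_mm
  n_wm <- n_b - n_mm
  n_ww <- core$n - n_a - n_b + n_mm

  s_mm <- core$sMM[idx]
  ss_mm <- core$ssMM[idx]
  n_non <- core$n - n_mm
  s_non <- core$sumy - s_mm
  ss_non <- core$ssy - ss_mm

  passed_size <- n_mm >= cfg$min_group_size & n_mw >= cfg$min_group_size &
    n_wm >= cfg$min_group_size & n_ww >= cfg$min_group_size

  model_p <- rep(NA_real_, nrow(pairs))
  mean_mm <- ifelse(n_mm > 0, s_mm / n_mm, NA_real_)
  mean_non <- ifelse(n_non > 0, s_non / n_non, NA_real_)
  if (any(passed_size)) {
    tp <- pooled_t_p(
      n_mm[passed_size], s_mm[passed_size], ss_mm[passed_size],
      n_non[passed_size], s_non[passed_size], ss_non[passed_size],
      welch = (cfg$t_variant == "welch")
    )
    model_p[passed_size] <- tp$p
  }
  degenerate <- passed_size & !is.finite(model_p)
  if (any(degenerate)) {
    warning(
      sum(degenerate), " pair(s) with a degenerate (zero-variance) test excluded",
      call. = FALSE
    )
    passed_size[degenerate] <- FALSE
    model_p[degenerate] <- NA_real_
  }

  passed_direction <- if (cfg$require_mm_lower) {
    !is.na(mean_mm) & !is.na(mean_non) & mean_mm < mean_non
  } else {
    rep(TRUE, nrow(pairs))
  }

  # MM-max / WW-median filter: per-pair group extrema are not cross-product
  # expressible, so loop over the (few) size-passing pairs only.
  passed_mm_ww <- rep(NA, nrow(pairs))
  if (cfg$mm_ww_filter == "off") {
    passed_mm_ww <- rep(TRUE, nrow(pairs))
  } else if (any(passed_size)) {
    for (k in which(passed_size)) {
      a <- status[gi[k], ] == 1
      b <- status[gj[k], ] == 1
      mm_vals <- y[a & b]
      ww_vals <- y[!a & !b]
      passed_mm_ww[k] <- if (cfg$mm_ww_filter == "mm_max_lt_ww_median") {
        max(mm_vals) < stats::median(ww_vals)
      } else {
        max(mm_vals) > stats::median(ww_vals)
      }
    }
  }

  q <- rep(NA_real_, nrow(pairs))
  q[passed_size] <- bh_adjust(model_p[passed_size])
  passed_q <- !is.na(q) & q < cfg$q_threshold
  candidate <- passed_size & passed_direction & (passed_mm_ww %in% TRUE) & passed_q

  data.frame(
    drug = drug, geneA = pairs$geneA, geneB = pairs$geneB,
    n_WW = as.integer(n_ww), n_WM = as.integer(n_wm),
    n_MW = as.integer(n_mw), n_MM = as.integer(n_mm),
    mean_MM = mean_mm, mean_nonMM = mean_non,
    model_p = model_p, q = q,
    passed_size = passed_size, passed_direction = passed_direction,
    passed_mm_ww = passed_mm_ww, passed_q = passed_q,
    candidate = candidate,
    stringsAsFactors = FALSE
  )
}

empty_scs_records <- function() {
  data.frame(
    drug = character(), geneA = character(), geneB = character(),
    n_WW = integer(), n_WM = integer(), n_MW = integer(), n_MM = integer(),
    mean_MM = numeric(), mean_nonMM = numeric(),
    model_p = numeric(), q = numeric(),
    passed_size = logical(), passed_direction = logical(),
    passed_mm_ww = logical(), passed_q = logical(), candidate = logical(),
    stringsAsFactors = FALSE
  )
}

#' Screen all drugs of a panel
#'
#' Concatenates [screen_drug()] over every drug in `drugs` that has IC50
#' data; with `cfg$commercial_only` the candidate flag is switched off for
#' non-commercial drugs (their records remain for inspection). Summary
#' counts are reported via `message()`.
#'
#' @param matrix A `damaging_matrix`.
#' @param ic50 Averaged dose-response table.
#' @param drugs Drug metadata data.frame (see [read_drug_meta()]), or a
#'   character vector of drug identifiers (all treated as commercial).
#' @param cfg A [screen_config()].
#' @param pairs Optional pair restriction, as in [screen_drug()].
#' @return Row-bound SCS record table with attribute `summary` (candidate
#'   sets, distinct genes, drugs with at least one candidate).
#' @export
screen_all <- function(matrix, ic50, drugs, cfg = screen_config(), pairs = NULL) {
  if (is.character(drugs)) {
    drugs <- data.frame(
      drug = drugs, name = drugs, target_class = NA_character_,
      commercial = TRUE, stringsAsFactors = FALSE
    )
  }
  present <- drugs$drug[drugs$drug %in% unique(ic50$drug)]
  res <- lapply(present, function(d) screen_drug(d, matrix, ic50, cfg, pairs))
  out <- if (length(res) > 0) do.call(rbind, res) else empty_scs_records()
  if (cfg$commercial_only && nrow(out) > 0) {
    comm <- drugs$drug[drugs$commercial %in% TRUE]
    out$candidate <- out$candidate & out$drug %in% comm
  }
  cand <- out[out$candidate, , drop = FALSE]
  summ <- list(
    n_sets = nrow(cand),
    n_genes = length(unique(c(cand$geneA, cand$geneB))),
    n_drugs = length(unique(cand$drug))
  )
  message(
    "screen: ", summ$n_sets, " candidate set(s), ", summ$n_genes,
    " gene(s), ", summ$n_drugs, " drug(s) with >= 1 candidate"
  )
  attr(out, "summary") <- summ
  out
}
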