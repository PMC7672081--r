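# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately naive re-implementations (per-pair loops, explicit formulas)
# kept independent of the package's vectorised paths.

# Build a damaging_matrix directly from a binary status matrix (rows =
# genes, cols = cell lines); all damaging calls are booked as LoF.
toy_matrix <- function(status) {
  storage.mode(status) <- "integer"
  structure(
    list(
      genes = rownames(status), cell_lines = colnames(status),
      status = status, lof = status,
      missense = matrix(0L, nrow(status), ncol(status), dimnames = dimnames(status)),
      deletion = matrix(0L, nrow(status), ncol(status), dimnames = dimnames(status)),
      min_mutated_lines = 1L
    ),
    class = "damaging_matrix"
  )
}

# Averaged dose-response table from named ln-IC50 vectors, one per drug.
toy_ic50 <- function(...) {
  vs <- list(...)
  do.call(rbind, lapply(names(vs), function(d) {
    data.frame(
      drug = d, cell_line = names(vs[[d]]), ln_ic50 = as.numeric(vs[[d]]),
      n_sources = 1L, stringsAsFactors = FALSE
    )
  }))
}

# Brute-force BH step-up: q_(i) = min_{j>=i} p_(j) * m / j, clipped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    q[o[i]] <- running
  }
  q
}

# Naive re-implementation of the per-drug screen: per-pair loop, explicit
# grouping, stats::t.test, brute-force BH over the size-passing batch.
brute_screen <- function(drug, matrix, ic50, cfg = scscreen::screen_config()) {
  sub <- ic50[ic50$drug == drug, ]
  y <- stats::setNames(sub$ln_ic50, sub$cell_line)
  lines <- intersect(names(y), matrix$cell_lines)
  pairs <- scscreen::enumerate_pairs(matrix)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    a <- matrix$status[pairs$geneA[k], lines] == 1
    b <- matrix$status[pairs$geneB[k], lines] == 1
    grp <- ifelse(a & b, "MM", ifelse(a, "MW", ifelse(b, "WM", "WW")))
    sizes <- sapply(c("WW", "WM", "MW", "MM"), function(g) sum(grp == g))
    passed_size <- all(sizes >= cfg$min_group_size)
    mm <- y[lines][grp == "MM"]
    non <- y[lines][grp != "MM"]
    ww <- y[lines][grp == "WW"]
    p <- if (passed_size) {
      stats::t.test(mm, non, var.equal = (cfg$t_variant == "pooled"))$p.value
    } else {
      NA_real_
    }
    data.frame(
      geneA = pairs$geneA[k], geneB = pairs$geneB[k],
      n_WW = sizes[["WW"]], n_WM = sizes[["WM"]],
      n_MW = sizes[["MW"]], n_MM = sizes[["MM"]],
      passed_size = passed_size, model_p = p,
      passed_direction = length(mm) > 0 && mean(mm) < mean(non),
      passed_mm_ww = if (passed_size) max(mm) < stats::median(ww) else NA,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  out$q[out$passed_size] <- bh_brute(out$model_p[out$passed_size])
  out$candidate <- out$passed_size & out$passed_direction &
    (out$passed_mm_ww %in% TRUE) & !is.na(out$q) & out$q < cfg$q_threshold
  out
}

# A small deterministic two-drug, five-gene panel with one strong planted
# pair for drug DA, used by the oracle-equivalence tests.
toy_panel <- function(seed = 42, n_lines = 60) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  genes <- paste0("g", 1:5)
  status <- matrix(rbinom(5 * n_lines, 1, 0.25), 5, n_lines, dimnames = list(genes, lines))
  mm <- sample(lines, 7)
  status["g1", mm] <- 1L
  status["g2", mm] <- 1L
  status["g2", setdiff(lines[status["g1", ] == 1 & status["g2", ] == 1], mm)] <- 0L
  mat <- toy_matrix(status)
  base <- rnorm(n_lines, 2, 0.6)
  ya <- base
  ya[colnames(status) %in% mm] <- ya[colnames(status) %in% mm] - 2.5
  yb <- rnorm(n_lines, 2, 0.6)
  ic50 <- toy_ic50(DA = stats::setNames(ya, lines), DB = stats::setNames(yb, lines))
  list(matrix = mat, ic50 = ic50, planted_mm = mm)
}

# all permutations of 1..n, tiny n only
combinat_perms <- function(n) {
  if (n == 1) {
    return(matrix(1, 1, 1))
  }
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

write_tsv_tmp <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  path
}
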