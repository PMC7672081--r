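test_that("replicate averaging takes the arithmetic mean on the ln scale", {
  rec <- data.frame(
    drug = c("D1", "D1", "D1"), cell_line = c("L1", "L2", "L2"),
    ln_ic50 = c(2.3, 1.0, 3.0), source = c("S1", "S1", "S2"),
    stringsAsFactors = FALSE
  )
  avg <- average_replicates(rec)
  expect_equal(avg$ln_ic50[avg$cell_line == "L1"], 2.3)
  expect_equal(avg$ln_ic50[avg$cell_line == "L2"], 2.0)
  rec3 <- rbind(rec, data.frame(
    drug = "D1", cell_line = "L2", ln_ic50 = 5.0,
    source = "S3", stringsAsFactors = FALSE
  ))
  expect_warning(avg3 <- average_replicates(rec3), "three or more")
  expect_equal(avg3$ln_ic50[avg3$cell_line == "L2"], 3.0)
})

test_that("group assignment uses only lines with an IC50 for the drug", {
  status <- rbind(
    A = c(L1 = 1L, L2 = 1L, L3 = 0L, L4 = 0L, L5 = 1L),
    B = c(L1 = 1L, L2 = 0L, L3 = 1L, L4 = 0L, L5 = 1L)
  )
  mat <- toy_matrix(status)
  ic50 <- toy_ic50(D1 = c(L1 = 1, L2 = 2, L3 = 3, L4 = 4)) # no L5
  g <- assign_groups(c("A", "B"), mat, ic50, "D1")
  expect_equal(
    stats::setNames(g$group, g$cell_line),
    c(L1 = "MM", L2 = "MW", L3 = "WM", L4 = "WW")
  )
  expect_false("L5" %in% g$cell_line)
  expect_equal(attr(g, "sizes"), c(WW = 1L, WM = 1L, MW = 1L, MM = 1L))
  expect_error(assign_groups(c("A", "Z"), mat, ic50, "D1"), "not in damaging matrix")
  expect_error(assign_groups(c("A", "B"), mat, ic50, "D9"), "not present")
})

test_that("model P equals the closed-form pooled t-test result", {
  status <- rbind(
    A = c(L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 0, L6 = 0, L7 = 0, L8 = 0),
    B = c(L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 0, L6 = 0, L7 = 0, L8 = 0)
  )
  mat <- toy_matrix(status)
  # MM = {0,0,1,1}, non-MM = {2,2,3,3}: pooled variance 1/3,
  # t = (0.5 - 2.5) / sqrt((1/3) * (1/4 + 1/4)) = -2 * sqrt(6), df = 6
  ic50 <- toy_ic50(D1 = c(L1 = 0, L2 = 0, L3 = 1, L4 = 1, L5 = 2, L6 = 2, L7 = 3, L8 = 3))
  g <- assign_groups(c("A", "B"), mat, ic50, "D1")
  res <- model_p(g)
  expect_equal(res$t, -2 * sqrt(6), tolerance = 1e-12)
  expect_equal(res$model_p, 2 * stats::pt(-2 * sqrt(6), df = 6), tolerance = 1e-12)
  expect_equal(res$mean_MM, 0.5)
  expect_equal(res$mean_nonMM, 2.5)
})

test_that("identical samples give p = 1 and constant data a degenerate-test error", {
  status <- rbind(
    A = c(L1 = 1, L2 = 1, L3 = 1, L4 = 0, L5 = 0, L6 = 0),
    B = c(L1 = 1, L2 = 1, L3 = 1, L4 = 0, L5 = 0, L6 = 0)
  )
  mat <- toy_matrix(status)
  same <- toy_ic50(D1 = c(L1 = 1, L2 = 2, L3 = 3, L4 = 1, L5 = 2, L6 = 3))
  g <- assign_groups(c("A", "B"), mat, same, "D1")
  res <- model_p(g)
  expect_equal(res$t, 0)
  expect_equal(res$model_p, 1)
  flat <- toy_ic50(D1 = c(L1 = 2, L2 = 2, L3 = 2, L4 = 2, L5 = 2, L6 = 2))
  gf <- assign_groups(c("A", "B"), mat, flat, "D1")
  expect_error(model_p(gf), "degenerate")
})

test_that("BH adjustment matches the brute-force step-up for all permutations of small vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  base_sets <- list(
    c(0.001, 0.011, 0.02, 0.1, 0.5, 0.9),
    c(0.04, 0.04, 0.05, 0.2, 0.9),
    c(0.5, 0.5, 0.5)
  )
  for (ps in base_sets) {
    perms <- combinat_perms(length(ps))
    for (i in seq_len(nrow(perms))) {
      p <- ps[perms[i, ]]
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  }
  # contract: q bounded by 1 and at least p (step-up never shrinks the max rank)
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q <= 1))
  expect_true(all(q >= p - 1e-12))
})

test_that("screen_drug equals the brute-force re-computation pair-for-pair", {
  tp <- toy_panel(seed = 42)
  for (d in c("DA", "DB")) {
    mine <- screen_drug(d, tp$matrix, tp$ic50)
    ref <- brute_screen(d, tp$matrix, tp$ic50)
    expect_equal(mine$geneA, ref$geneA)
    expect_equal(mine$n_MM, unname(ref$n_MM))
    expect_equal(mine$n_WW, unname(ref$n_WW))
    expect_equal(mine$passed_size, unname(ref$passed_size))
    expect_equal(mine$model_p, ref$model_p, tolerance = 1e-10)
    expect_equal(mine$q, ref$q, tolerance = 1e-10)
    expect_equal(mine$passed_direction, ref$passed_direction)
    expect_equal(mine$passed_mm_ww, ref$passed_mm_ww)
    expect_equal(mine$candidate, ref$candidate)
  }
})

test_that("a strongly planted pair is recovered as the top candidate", {
  tp <- toy_panel(seed = 7)
  res <- screen_drug("DA", tp$matrix, tp$ic50)
  cand <- res[res$candidate, ]
  expect_gt(nrow(cand), 0)
  top <- cand[which.min(cand$q), ]
  expect_equal(c(top$geneA, top$geneB), c("g1", "g2"))
})

test_that("undersized groups are excluded from the BH batch", {
  status <- rbind(
    A = c(L1 = 1, L2 = 1, L3 = 1, L4 = 0, L5 = 0, L6 = 0, L7 = 0, L8 = 1, L9 = 0, L10 = 0),
    B = c(L1 = 1, L2 = 1, L3 = 1, L4 = 1, L5 = 1, L6 = 0, L7 = 0, L8 = 0, L9 = 0, L10 = 0)
  )
  mat <- toy_matrix(status)
  set.seed(2)
  ic50 <- toy_ic50(D1 = stats::setNames(rnorm(10), sprintf("L%d", 1:10)))
  res <- screen_drug("D1", mat, ic50) # n_MM = 3 < 5
  expect_false(res$passed_size)
  expect_true(is.na(res$model_p))
  expect_true(is.na(res$q))
  expect_false(res$candidate)
})

test_that("shuffling cell-line order changes no statistic", {
  tp <- toy_panel(seed = 11)
  res1 <- screen_drug("DA", tp$matrix, tp$ic50)
  set.seed(99)
  perm <- sample(ncol(tp$matrix$status))
  mat2 <- toy_matrix(tp$matrix$status[, perm])
  ic2 <- tp$ic50[sample(nrow(tp$ic50)), ]
  res2 <- screen_drug("DA", mat2, ic2)
  expect_equal(res1$model_p, res2$model_p, tolerance = 1e-12)
  expect_equal(res1$q, res2$q, tolerance = 1e-12)
  expect_equal(res1$candidate, res2$candidate)
})

test_that("screen_all concatenates drugs, reports the summary and honours commercial_only", {
  tp <- toy_panel(seed = 13)
  drugs <- data.frame(
    drug = c("DA", "DB"), name = c("a", "b"), target_class = "x",
    commercial = c(FALSE, TRUE), stringsAsFactors = FALSE
  )
  res <- suppressMessages(screen_all(tp$matrix, tp$ic50, drugs))
  expect_false(any(res$candidate[res$drug == "DA"])) # non-commercial masked
  res_all <- suppressMessages(screen_all(
    tp$matrix, tp$ic50, drugs,
    screen_config(commercial_only = FALSE)
  ))
  expect_true(any(res_all$candidate[res_all$drug == "DA"]))
  summ <- attr(res_all, "summary")
  expect_true(all(c("n_sets", "n_genes", "n_drugs") %in% names(summ)))
  expect_equal(summ$n_sets, sum(res_all$candidate))
})

test_that("the literal mm_ww filter direction and the off switch are selectable", {
  tp <- toy_panel(seed = 21)
  lt <- screen_drug("DA", tp$matrix, tp$ic50, screen_config(mm_ww_filter = "mm_max_lt_ww_median"))
  gt <- screen_drug("DA", tp$matrix, tp$ic50, screen_config(mm_ww_filter = "mm_max_gt_ww_median"))
  off <- screen_drug("DA", tp$matrix, tp$ic50, screen_config(mm_ww_filter = "off"))
  tested <- lt$passed_size
  expect_equal(lt$passed_mm_ww[tested], !gt$passed_mm_ww[tested])
  expect_true(all(off$passed_mm_ww))
})
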