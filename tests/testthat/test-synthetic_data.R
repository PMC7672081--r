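test_that("the same seed reproduces the panel exactly and different seeds differ", {
  cfg <- panel_config(n_cell_lines = 50, n_genes = 12, seed = 101)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a, b)
  c <- generate_panel(panel_config(n_cell_lines = 50, n_genes = 12, seed = 102))
  expect_false(identical(a$dose_response$ln_ic50, c$dose_response$ln_ic50))
})

test_that("generated files pass data_io validation unmodified and round-trip the truth", {
  cfg <- panel_config(
    n_cell_lines = 80, n_genes = 15,
    planted_pairs = data.frame(
      drug = "D1", geneA = "G001", geneB = "G002",
      delta = -2, n_mm = 8
    ),
    seed = 103
  )
  pan <- generate_panel(cfg)
  dir <- withr::local_tempdir()
  paths <- write_panel(pan, dir)
  tabs <- suppressMessages(read_tables(paths))
  mat <- build_damaging_matrix(
    tabs$coding_variants, tabs$copy_number,
    filter_config(min_mutated_lines = 1), tabs$cell_line_meta$cell_line
  )
  # pipeline-recovered status equals the truth manifest
  expect_identical(
    mat$status[rownames(pan$truth$status)[rownames(pan$truth$status) %in% mat$genes], ],
    pan$truth$status[rownames(pan$truth$status) %in% mat$genes, ]
  )
  # planted pair realised with exactly the requested number of MM lines
  expect_equal(pan$truth$planted_pairs$n_mm_realised, 8L)
  expect_equal(sum(pan$truth$status["G001", ] & pan$truth$status["G002", ]), 8)
})

test_that("a null panel yields (almost) no candidates and a planted shift is found", {
  drugs <- data.frame(
    drug = "D1", name = "d", target_class = "x", commercial = TRUE,
    baseline_mean = 2.5, baseline_sd = 0.5, stringsAsFactors = FALSE
  )
  null_cfg <- panel_config(
    n_cell_lines = 150, n_genes = 15, drugs = drugs,
    replicate_fraction = 0, seed = 104
  )
  pan0 <- generate_panel(null_cfg)
  mat0 <- build_damaging_matrix(
    pan0$coding_variants, pan0$copy_number,
    filter_config(min_mutated_lines = 10), pan0$cell_line_meta$cell_line
  )
  res0 <- screen_drug("D1", mat0, average_replicates(pan0$dose_response))
  expect_lte(sum(res0$candidate), 1) # global null: false candidates rare
  planted_cfg <- panel_config(
    n_cell_lines = 150, n_genes = 15, drugs = drugs,
    planted_pairs = data.frame(
      drug = "D1", geneA = "G001", geneB = "G002",
      delta = -2, n_mm = 10
    ),
    replicate_fraction = 0, seed = 105
  )
  pan1 <- generate_panel(planted_cfg)
  mat1 <- build_damaging_matrix(
    pan1$coding_variants, pan1$copy_number,
    filter_config(min_mutated_lines = 10), pan1$cell_line_meta$cell_line
  )
  res1 <- screen_drug("D1", mat1, average_replicates(pan1$dose_response))
  hit <- res1[res1$geneA == "G001" & res1$geneB == "G002", ]
  expect_true(hit$candidate)
})

test_that("the same pair planted for several drugs keeps one shared MM set", {
  drugs <- data.frame(
    drug = c("D1", "D2"), name = c("a", "b"), target_class = "x",
    commercial = TRUE, baseline_mean = 2.5, baseline_sd = 0.5,
    stringsAsFactors = FALSE
  )
  cfg <- panel_config(
    n_cell_lines = 120, n_genes = 10, drugs = drugs,
    planted_pairs = data.frame(
      drug = c("D1", "D2"), geneA = "G001", geneB = "G002",
      delta = -2, n_mm = 10
    ),
    replicate_fraction = 0, seed = 110
  )
  pan <- generate_panel(cfg)
  mm <- pan$truth$planted_mm_lines
  expect_identical(mm[[1]], mm[[2]])
  expect_equal(length(mm[[1]]), 10)
  # both drugs' screens see the pair
  mat <- build_damaging_matrix(
    pan$coding_variants, pan$copy_number,
    filter_config(min_mutated_lines = 10), pan$cell_line_meta$cell_line
  )
  ic50 <- average_replicates(pan$dose_response)
  for (d in c("D1", "D2")) {
    res <- screen_drug(d, mat, ic50)
    hit <- res[res$geneA == "G001" & res$geneB == "G002", ]
    expect_true(hit$candidate)
    expect_equal(hit$n_MM, 10L)
  }
})

test_that("plants referencing unknown genes or drugs are config errors", {
  drugs <- data.frame(
    drug = "D1", name = "d", target_class = "x", commercial = TRUE,
    baseline_mean = 2.5, baseline_sd = 0.5, stringsAsFactors = FALSE
  )
  expect_error(
    panel_config(
      n_cell_lines = 20, n_genes = 5, drugs = drugs,
      planted_pairs = data.frame(
        drug = "D9", geneA = "G001", geneB = "G002", delta = -1
      ),
      seed = 1
    ),
    "unknown drug"
  )
  cfg <- panel_config(
    n_cell_lines = 20, n_genes = 5, drugs = drugs,
    planted_pairs = data.frame(
      drug = "D1", geneA = "G001", geneB = "G999", delta = -1
    ),
    seed = 1
  )
  expect_error(generate_panel(cfg), "unknown gene")
})

test_that("cohort generation is deterministic, hits exact group counts and the censoring target", {
  cc <- cohort_config(seed = 106)
  a <- generate_cohort(cc)
  b <- generate_cohort(cc)
  expect_identical(a, b)
  counts <- table(factor(a$truth$labels, c("WWC", "WMC", "MWC", "MMC")))
  expect_equal(as.integer(counts), c(30L, 22L, 2L, 11L))
  # expected censoring fraction at the solved rate matches the target
  cr <- a$truth$censoring_rate_used
  haz <- a$truth$hazards
  expect_equal(mean(cr / (cr + haz)), 0.2, tolerance = 1e-6)
})

test_that("null cohorts give uniform-ish log-rank p values over seeds", {
  ps <- vapply(1:30, function(s) {
    cc <- cohort_config(
      n_patients = 120,
      group_proportions = c(WWC = 0.5, WMC = 0, MWC = 0, MMC = 0.5),
      hazard_ratios = c(WWC = 1, WMC = 1, MWC = 1, MMC = 1),
      censoring_rate = 0.2, seed = 200 + s
    )
    coh <- generate_cohort(cc)
    ct <- classify_patients(coh$maf, coh$clinical, "BRAF", c("GPR112", "NBEA", "TTN"))
    km_logrank(ct, "MMC", "WWC")$logrank_p
  }, numeric(1))
  # under the null, p values should not pile up at the low end
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 1e-4)
})

test_that("cohort text files read back through data_io", {
  cc <- cohort_config(seed = 107)
  coh <- generate_cohort(cc)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  maf <- read_maf(paths$maf)
  clin <- read_clinical(paths$clinical)
  expect_equal(sort(unique(maf$patient)), sort(unique(coh$maf$patient)))
  expect_equal(nrow(clin), cc$n_patients)
  ct <- classify_patients(maf, clin, "BRAF", c("GPR112", "NBEA", "TTN"))
  expect_identical(unname(coh$truth$labels[ct$patient]), ct$label)
})
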