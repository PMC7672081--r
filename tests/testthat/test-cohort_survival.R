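toy_clinical <- function(patients, os = NULL, event = NULL) {
  n <- length(patients)
  data.frame(
    patient = patients,
    age = 60, sex = "female", cancer_type = "SKCM",
    drugs = I(as.list(rep("dabrafenib", n))),
    os_months = if (is.null(os)) rep(12, n) else os,
    event = if (is.null(event)) rep(TRUE, n) else event,
    stringsAsFactors = FALSE
  )
}

test_that("patients classify by anchor/partner damaging status with Silent rows inert", {
  maf <- data.frame(
    patient = c("P1", "P1", "P2", "P3", "P4"),
    gene = c("BRAF", "NBEA", "BRAF", "BRAF", "NBEA"),
    variant_classification = c(
      "Missense_Mutation", "Nonsense_Mutation", # P1: anchor + partner -> MMC
      "Silent", # P2: only Silent -> WWC
      "Splice_Site", # P3: anchor only -> MWC
      "Translation_Start_Site" # P4: partner only -> WMC
    ),
    stringsAsFactors = FALSE
  )
  ct <- classify_patients(maf, toy_clinical(c("P1", "P2", "P3", "P4")),
    anchor = "BRAF", partner_set = c("NBEA", "GPR112")
  )
  expect_equal(
    stats::setNames(ct$label, ct$patient),
    c(P1 = "MMC", P2 = "WWC", P3 = "MWC", P4 = "WMC")
  )
  expect_equal(ct$burden[ct$patient == "P1"], 1L)
})

test_that("the drug filter keeps only exposed patients and inclusion needs both tables", {
  maf <- data.frame(
    patient = c("P1", "P2"), gene = "BRAF",
    variant_classification = "Missense_Mutation", stringsAsFactors = FALSE
  )
  clin <- toy_clinical(c("P1", "P2", "P3"))
  clin$drugs <- I(list("dabrafenib", "aspirin", "dabrafenib"))
  ct <- classify_patients(maf, clin, "BRAF", "NBEA",
    drug_filter = c("Dabrafenib", "trametinib")
  )
  # P2 dropped (drug), P3 dropped (no mutation data)
  expect_identical(ct$patient, "P1")
})

test_that("a 65-patient cohort with planted 30/22/2/11 proportions classifies to those sizes", {
  cc <- cohort_config(seed = 17)
  coh <- generate_cohort(cc)
  ct <- classify_patients(coh$maf, coh$clinical, "BRAF", c("GPR112", "NBEA", "TTN"),
    drug_filter = cc$inhibitors
  )
  counts <- table(factor(ct$label, c("WWC", "WMC", "MWC", "MMC")))
  expect_equal(as.integer(counts), c(30L, 22L, 2L, 11L))
  expect_identical(
    unname(coh$truth$labels[ct$patient]),
    ct$label
  )
})

test_that("identical groups give log-rank statistic 0 and p = 1", {
  clin <- toy_clinical(sprintf("P%d", 1:8),
    os = rep(c(2, 4, 6, 8), 2),
    event = rep(TRUE, 8)
  )
  maf <- data.frame(
    patient = sprintf("P%d", 1:8),
    gene = c(rep("BRAF", 4), rep("FILLER", 4)),
    variant_classification = c(rep("Missense_Mutation", 4), rep("Silent", 4)),
    stringsAsFactors = FALSE
  )
  ct <- classify_patients(maf, clin, "BRAF", "NBEA")
  res <- km_logrank(ct, "MWC", "WWC")
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-10)
  expect_equal(res$logrank_p, 1, tolerance = 1e-10)
})

test_that("the KM median without censoring equals the sample median", {
  expect_equal(km_curve(c(2, 4, 6, 8))$median_os, 5) # curve sits at 0.5: average of 4 and 6
  expect_equal(km_curve(c(1, 2, 3))$median_os, 2)
  set.seed(3)
  x <- rexp(101, 0.1)
  expect_equal(km_curve(x)$median_os, stats::median(x), tolerance = 1e-9)
  # KM curve is non-increasing and starts at 1
  fit <- km_curve(c(2, 4, 6, 8))$fit
  expect_true(all(diff(fit$surv) <= 0))
  expect_equal(max(fit$surv), 0.75) # first drop from 1 at the first event
})

test_that("a planted hazard ratio is recovered by KM/log-rank and Cox", {
  cc <- cohort_config(
    n_patients = 1000,
    group_proportions = c(WWC = 0.5, WMC = 0, MWC = 0, MMC = 0.5),
    hazard_ratios = c(WWC = 1, WMC = 1, MWC = 1, MMC = 0.44),
    censoring_rate = 0.2, seed = 23
  )
  coh <- generate_cohort(cc)
  ct <- classify_patients(coh$maf, coh$clinical, "BRAF", c("GPR112", "NBEA", "TTN"))
  res <- km_logrank(ct, "MMC", "WWC")
  expect_gt(res$hr, 0.33)
  expect_lt(res$hr, 0.59)
  expect_lt(res$logrank_p, 0.01)
  expect_gt(res$median_os[["MMC"]], res$median_os[["WWC"]])
  # censoring close to the 20% target
  expect_lt(abs(mean(!ct$event) - 0.2), 0.05)
})

test_that("Cox models fit univariate and multivariate factors with WWC reference", {
  cc <- cohort_config(
    n_patients = 400,
    group_proportions = c(WWC = 0.4, WMC = 0.2, MWC = 0.1, MMC = 0.3),
    hazard_ratios = c(WWC = 1, WMC = 1, MWC = 1, MMC = 0.5),
    censoring_rate = 0.2, seed = 31
  )
  coh <- generate_cohort(cc)
  ct <- classify_patients(coh$maf, coh$clinical, "BRAF", c("GPR112", "NBEA", "TTN"))
  res <- cox_models(ct)
  expect_true(all(res$univariate$hr > 0))
  mm_row <- res$multivariate[res$multivariate$term == "groupMMC", ]
  expect_equal(nrow(mm_row), 1)
  expect_lt(mm_row$p, 0.01)
  # planted HR within the multivariate CI
  expect_gt(0.5, mm_row$ci_lower)
  expect_lt(0.5, mm_row$ci_upper)
})

test_that("a hazard-independent covariate estimates HR near 1 and zero events error", {
  cc <- cohort_config(
    n_patients = 1000,
    group_proportions = c(WWC = 0.5, WMC = 0.5, MWC = 0, MMC = 0),
    hazard_ratios = c(WWC = 1, WMC = 1, MWC = 1, MMC = 1),
    censoring_rate = 0.1, seed = 37
  )
  coh <- generate_cohort(cc)
  ct <- classify_patients(coh$maf, coh$clinical, "BRAF", c("GPR112", "NBEA", "TTN"))
  res <- cox_models(ct)
  wm <- res$univariate[res$univariate$term == "groupWMC", ]
  expect_gt(wm$hr, 0.85)
  expect_lt(wm$hr, 1.18)
  ct0 <- ct
  ct0$event <- FALSE
  expect_error(cox_models(ct0), "no events")
})

test_that("complete separation is flagged rather than silently reported", {
  # all events in one group at early times, none in the other: monotone likelihood
  clin <- toy_clinical(sprintf("P%d", 1:20),
    os = c(seq(1, 10, length.out = 10), seq(100, 110, length.out = 10)),
    event = c(rep(TRUE, 10), rep(FALSE, 9), TRUE)
  )
  maf <- data.frame(
    patient = sprintf("P%d", 1:20),
    gene = c(rep("BRAF", 10), rep("FILLER", 10)),
    variant_classification = c(rep("Missense_Mutation", 10), rep("Silent", 10)),
    stringsAsFactors = FALSE
  )
  ct <- classify_patients(maf, clin, "BRAF", "NBEA")
  res <- cox_models(ct, covariates = character(0))
  expect_gt(length(res$flags), 0)
})
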