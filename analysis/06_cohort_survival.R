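#!/usr/bin/env Rscript
# Cohort validation: simulate a 65-patient inhibitor-treated cohort with the
# anchor/partner group structure and a protective hazard for the doubly
# mutated group, classify patients from the MAF-like file, and compare
# survival (KM medians, log-rank, univariate + multivariate Cox).

source("analysis/00_config.R")

partners <- c("GPR112", "NBEA", "TTN")
cc <- cohort_config(
  n_patients = 65,
  hazard_ratios = c(WWC = 1, WMC = 1, MWC = 1, MMC = 0.44),
  seed = study_seed
)
coh <- generate_cohort(cc)
paths <- write_cohort(coh, cohort_dir)

maf <- read_maf(paths$maf)
clin <- read_clinical(paths$clinical)
ct <- classify_patients(maf, clin, "BRAF", partners, drug_filter = cc$inhibitors)
cat("cohort groups:\n")
print(table(factor(ct$label, c("WWC", "WMC", "MWC", "MMC"))))

km <- km_logrank(ct, "MMC", "WWC")
cat(
  "\nMMC vs WWC: median OS", signif(km$median_os[["MMC"]], 4), "vs",
  signif(km$median_os[["WWC"]], 4), "months; HR =", signif(km$hr, 3),
  "[", signif(km$hr_ci[["lower"]], 3), ",", signif(km$hr_ci[["upper"]], 3), "],",
  "log-rank p =", signif(km$logrank_p, 3), "\n"
)

cox <- cox_models(ct)
cat("\nmultivariate Cox:\n")
print(cox$multivariate, row.names = FALSE, digits = 3)
if (length(cox$flags) > 0) {
  cat("fitter flags:", paste(cox$flags, collapse = "; "), "\n")
}
write_results(cox$multivariate, "results/cox_multivariate.tsv")
write_results(
  data.frame(
    group = names(km$median_os), median_os = as.numeric(km$median_os),
    stringsAsFactors = FALSE
  ),
  "results/km_medians.tsv"
)
cat("\n(at n = 65 the pairwise HR is noisy; the planted 0.44 sits inside the CI)\n")
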