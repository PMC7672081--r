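#!/usr/bin/env Rscript
# Combined-partner analysis around the anchor gene: pool its screen partners
# per drug and across the MAPK-class drugs, compare the combined groups
# (WWC/WMC/MWC/MMC) on ln IC50, and test the burden effect.

source("analysis/00_config.R")

tabs <- study_tables()
mat <- study_matrix(tabs)
ic50 <- average_replicates(tabs$dose_response)
records <- read_results("results/scs_records.tsv")
anchor <- "G001"
mapk_drugs <- tabs$drug_meta$drug[tabs$drug_meta$target_class == "MAPK"]

gm <- build_combined_grouping(anchor, records, "multidrug", mat, drug = mapk_drugs)
cat(
  "multidrug partner set of", anchor, ":",
  paste(attr(gm, "partner_set"), collapse = ", "), "\n\n"
)

rows <- list()
for (d in mapk_drugs) {
  cmp <- compare_combined_groups(gm, ic50, d)
  cat(d, ": MMC lowest =", cmp$mmc_lowest, "; MMC-vs-MWC p =",
    signif(cmp$pairwise_p[["MWC"]], 3), "\n",
    sep = " "
  )
  rows[[d]] <- data.frame(
    drug = d, scope = "multidrug",
    mmc_lowest = cmp$mmc_lowest,
    p_vs_wwc = cmp$pairwise_p[["WWC"]],
    p_vs_wmc = cmp$pairwise_p[["WMC"]],
    p_vs_mwc = cmp$pairwise_p[["MWC"]],
    stringsAsFactors = FALSE
  )
}
write_results(do.call(rbind, rows), "results/combined_group_comparison.tsv")

cat("\nburden effect (zero / one / two-plus mutated partners):\n")
burden_rows <- list()
for (d in mapk_drugs) {
  res <- burden_analysis(gm, ic50, d, strata_rule = "zero_one_twoplus")
  cat(
    d, ": stratum means",
    paste(signif(res$strata$mean_ln_ic50, 3), collapse = " > "),
    "; ANOVA p =", signif(res$anova_p, 3), "\n"
  )
  burden_rows[[d]] <- cbind(drug = d, res$strata, anova_p = res$anova_p)
}
write_results(do.call(rbind, burden_rows), "results/burden_strata.tsv")
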