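#!/usr/bin/env Rscript
# Build the binary damaging-mutation matrix from the simulated panel:
# LoF + damaging-missense (SIFT < 0.05 AND PolyPhen > 0.908) + homozygous
# deletions, genes kept when damaged in >= 10 distinct lines.

source("analysis/00_config.R")

tabs <- study_tables()
mat <- study_matrix(tabs)
print(mat)

tab <- damaging_count_table(mat, "results/damaging_count_table.tsv")
cat(
  "retained", length(mat$genes), "of", 30, "genes ->",
  format(n_gene_pairs(length(mat$genes)), big.mark = ","), "gene pairs\n"
)
cat(
  "per-line damaging calls: LoF", sum(mat$lof), "; missense", sum(mat$missense),
  "; deletion", sum(mat$deletion), "\n"
)
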