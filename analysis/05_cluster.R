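#!/usr/bin/env Rscript
# Clustering of the screen output: binary gene x drug membership (genes
# appearing >= 2 times), drug x tissue MM-line counts with drug-wise min-max
# scaling, complete-linkage Euclidean dendrograms, and chi-squared tissue
# enrichment of the anchor's MM lines against the panel background.

source("analysis/00_config.R")

tabs <- study_tables()
mat <- study_matrix(tabs)
records <- read_results("results/scs_records.tsv")
cand <- records[records$candidate, ]

dg <- build_drug_gene_matrix(records)
cat("drug/gene matrix:", nrow(dg), "genes x", ncol(dg), "drugs\n")
write_results(cbind(gene = rownames(dg), as.data.frame(dg)), "results/drug_gene_matrix.tsv")
if (ncol(dg) >= 2) {
  link <- hierarchical_cluster(t(dg))
  export_dendrogram(link, "results/drug_gene_dendrogram.nwk")
  cat("drug dendrogram leaf order:", paste(link$labels[link$order], collapse = ", "), "\n")
}

# MM lines per candidate pair feed the drug/tissue matrix
mm_lines <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
  both <- mat$status[cand$geneA[k], ] == 1 & mat$status[cand$geneB[k], ] == 1
  data.frame(
    drug = cand$drug[k], cell_line = mat$cell_lines[both],
    stringsAsFactors = FALSE
  )
}))
mm_lines <- unique(mm_lines)
dt <- build_drug_tissue_matrix(mm_lines, tabs$cell_line_meta, "tissue1")
write_results(cbind(drug = rownames(dt), as.data.frame(dt)), "results/drug_tissue_matrix.tsv")
if (nrow(dt) >= 2) {
  link_t <- hierarchical_cluster(dt)
  export_dendrogram(link_t, "results/drug_tissue_dendrogram.nwk")
}

# tissue enrichment of the anchor's MM lines vs the whole panel
anchor_mm <- unique(mm_lines$cell_line[mm_lines$drug %in%
  tabs$drug_meta$drug[tabs$drug_meta$target_class == "MAPK"]])
mm_hist <- table(factor(
  tabs$cell_line_meta$tissue1[match(anchor_mm, tabs$cell_line_meta$cell_line)],
  levels = sort(unique(tabs$cell_line_meta$tissue1))
))
bg_hist <- table(factor(tabs$cell_line_meta$tissue1,
  levels = sort(unique(tabs$cell_line_meta$tissue1))
))
enr <- tissue_enrichment(c(mm_hist), c(bg_hist))
cat(
  "tissue enrichment of", length(anchor_mm), "MM lines: chi-squared =",
  signif(enr$statistic, 4), ", df =", enr$df, ", p =", signif(enr$p_value, 3), "\n"
)
cat("(the generator draws tissues independently of mutations, so p should be unremarkable)\n")
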