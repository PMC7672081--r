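# Shared configuration for the worked synthetic study driven by the
# numbered analysis scripts. Every script sources this file, so the panel,
# the planted truths and all paths are defined once.

library(scscreen)

study_seed <- 42
panel_dir <- "results/panel"
cohort_dir <- "results/cohort"

study_drugs <- data.frame(
  drug = c("DAB", "TRA", "REF", "NC1"),
  name = c("dabrafenib_like", "trametinib_like", "refametinib_like", "probe_compound"),
  target_class = c("MAPK", "MAPK", "MAPK", "other"),
  commercial = c(TRUE, TRUE, TRUE, FALSE),
  baseline_mean = 2.5, baseline_sd = 0.6,
  stringsAsFactors = FALSE
)

# Anchor gene G001 with partners G002-G004 across the three MAPK-class
# drugs (shared-partner structure that drug/gene clustering should find),
# plus one non-anchor pair on the non-commercial probe.
study_planted_pairs <- data.frame(
  drug = c("DAB", "DAB", "TRA", "TRA", "REF", "NC1"),
  geneA = c("G001", "G001", "G001", "G001", "G001", "G005"),
  geneB = c("G002", "G003", "G002", "G004", "G003", "G006"),
  delta = -2, n_mm = 12,
  stringsAsFactors = FALSE
)

study_panel_config <- function() {
  panel_config(
    n_cell_lines = 300, n_genes = 30, damaging_prob = 0.12,
    drugs = study_drugs,
    planted_pairs = study_planted_pairs,
    planted_combined = list(
      anchor = "G001", partners = c("G002", "G003", "G004"),
      delta = -0.5, drugs = c("DAB", "TRA", "REF")
    ),
    seed = study_seed
  )
}

# Rebuild the damaging matrix from the panel files written by script 01.
study_matrix <- function(tabs) {
  build_damaging_matrix(
    tabs$coding_variants, tabs$copy_number,
    filter_config(min_mutated_lines = 10),
    cell_lines = tabs$cell_line_meta$cell_line
  )
}

study_tables <- function() {
  suppressMessages(read_tables(list(
    coding_variants = file.path(panel_dir, "coding_variants.tsv"),
    copy_number = file.path(panel_dir, "copy_number.tsv"),
    dose_response = file.path(panel_dir, "dose_response.tsv"),
    drug_meta = file.path(panel_dir, "drug_meta.tsv"),
    cell_line_meta = file.path(panel_dir, "cell_line_meta.tsv")
  )))
}
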