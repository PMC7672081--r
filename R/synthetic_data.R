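# Synthetic panel and cohort generators with known planted structure, so
# every pipeline stage is testable without external downloads. Defaults
# emulate the shape of a large drug-sensitivity panel at desk scale:
# sparse Bernoulli damaging indicators, Normal ln-IC50 baselines, planted
# MM-group shifts, tissue labels, and exponential survival with planted
# hazard ratios.

#' Configuration for the synthetic cell-line panel generator
#'
#' @param n_cell_lines Number of cell lines, default 150.
#' @param n_genes Number of genes, default 40.
#' @param damaging_prob Per-gene probability that a given cell line carries a
#'   damaging mutation; scalar or per-gene vector. Default 0.12.
#' @param drugs Data.frame with columns `drug`, `name`, `target_class`,
#'   `commercial`, `baseline_mean`, `baseline_sd` (ln-IC50 scale, ln uM).
#'   Default: two commercial drugs, baseline N(2.5, 1).
#' @param planted_pairs Data.frame (`drug`, `geneA`, `geneB`, `delta`,
#'   optional `n_mm`) of MM-group ln-IC50 shifts. When `n_mm` is given the
#'   generator fixes exactly that many doubly-mutant lines for the pair (and
#'   removes accidental co-mutations elsewhere), so group-size preconditions
#'   hold deterministically.
#' @param planted_combined Optional list(`anchor`, `partners`, `delta`,
#'   `drugs`): an additive ln-IC50 shift of `delta` per mutated partner gene,
#'   applied to anchor-mutated lines for the listed drugs.
#' @param tissue1_levels,tissue2_levels Tissue label pools (coarse and fine).
#' @param replicate_fraction Fraction of (drug, line) measurements duplicated
#'   at a second source, default 0.05.
#' @param noise_variants Mean number of non-damaging decoy variant rows per
#'   cell line, default 2.
#' @param seed Mandatory integer seed.
#' @return List of class `"panel_config"`.
#' @export
panel_config <- function(n_cell_lines = 150, n_genes = 40, damaging_prob = 0.12,
                         drugs = NULL, planted_pairs = NULL,
                         planted_combined = NULL,
                         tissue1_levels = c("skin", "large_intestine", "lung", "breast", "blood"),
                         tissue2_levels = c(
                           "melanoma", "colorectal_carcinoma", "NSCLC",
                           "breast_carcinoma", "AML", "SCLC"
                         ),
                         replicate_fraction = 0.05, noise_variants = 2,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(drugs)) {
    drugs <- data.frame(
      drug = c("D1", "D2"), name = c("drugone", "drugtwo"),
      target_class = c("MAPK", "PI3K"), commercial = c(TRUE, TRUE),
      baseline_mean = c(2.5, 2.5), baseline_sd = c(1, 1),
      stringsAsFactors = FALSE
    )
  }
  p <- damaging_prob
  if (length(p) == 1) p <- rep(p, n_genes)
  stopifnot(
    length(p) == n_genes, all(p >= 0 & p <= 1),
    replicate_fraction >= 0, replicate_fraction <= 1
  )
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("drug", "geneA", "geneB", "delta") %in% names(planted_pairs)))
    stopifnot(all(is.finite(planted_pairs$delta)))
    if (!all(planted_pairs$drug %in% drugs$drug)) {
      stop("planted pair references unknown drug", call. = FALSE)
    }
  }
  structure(
    list(
      n_cell_lines = n_cell_lines, n_genes = n_genes, damaging_prob = p,
      drugs = drugs, planted_pairs = planted_pairs,
      planted_combined = planted_combined,
      tissue1_levels = tissue1_levels, tissue2_levels = tissue2_levels,
      replicate_fraction = replicate_fraction, noise_variants = noise_variants,
      seed = as.integer(seed)
    ),
    class = "panel_config"
  )
}

gene_names <- function(n) sprintf("G%03d", seq_len(n))
line_names <- function(n) sprintf("CL%04d", seq_len(n))

#' Generate a synthetic cell-line panel
#'
#' Draws a binary damaging-status matrix (Bernoulli per gene), applies the
#' planted-pair and planted-combined adjustments, and emits the raw record
#' tables the pipeline consumes: coding variants (with SIFT/PolyPhen scores
#' guaranteeing the intended damaging call, plus non-damaging decoys),
#' copy-number calls, replicate-bearing dose-response records, drug
#' metadata, and cell-line metadata. The truth manifest records the status
#' matrix and every planted effect.
#'
#' @param cfg A [panel_config()].
#' @return List: `coding_variants`, `copy_number`, `dose_response`,
#'   `drug_meta`, `cell_line_meta` (data.frames), and `truth` (list with
#'   `status`, `planted_pairs`, `planted_combined`).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  set.seed(cfg$seed)
  genes <- gene_names(cfg$n_genes)
  lines <- line_names(cfg$n_cell_lines)
  pp <- cfg$planted_pairs
  extra_genes <- character()
  if (!is.null(pp)) extra_genes <- c(extra_genes, pp$geneA, pp$geneB)
  if (!is.null(cfg$planted_combined)) {
    extra_genes <- c(extra_genes, cfg$planted_combined$anchor, cfg$planted_combined$partners)
  }
  unknown <- setdiff(extra_genes, genes)
  if (length(unknown) > 0) {
    stop("planted effect references unknown gene(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  status <- matrix(
    stats::rbinom(cfg$n_genes * cfg$n_cell_lines, 1, rep(cfg$damaging_prob, cfg$n_cell_lines)),
    nrow = cfg$n_genes, ncol = cfg$n_cell_lines, dimnames = list(genes, lines)
  )

  planted_mm <- list()
  if (!is.null(pp)) {
    # Force each unique gene pair once (the same pair may be planted for
    # several drugs); the realised MM sets are resolved only after all
    # forcing, so later plants cannot undo earlier ones.
    pair_key <- paste(pmin(pp$geneA, pp$geneB), pmax(pp$geneA, pp$geneB))
    if (!is.null(pp$n_mm)) {
      for (key in unique(pair_key[!is.na(pp$n_mm)])) {
        rows <- which(pair_key == key & !is.na(pp$n_mm))
        a <- pp$geneA[rows[1]]
        b <- pp$geneB[rows[1]]
        mm <- sample(lines, max(pp$n_mm[rows]))
        status[a, mm] <- 1L
        status[b, mm] <- 1L
        stray <- setdiff(lines[status[a, ] == 1 & status[b, ] == 1], mm)
        status[b, stray] <- 0L
      }
    }
    for (k in seq_len(nrow(pp))) {
      planted_mm[[k]] <- lines[status[pp$geneA[k], ] == 1 & status[pp$geneB[k], ] == 1]
    }
  }

  # Coding variants / CNV records realising the status matrix. Category per
  # damaged (gene, line): LoF, damaging missense, or homozygous deletion.
  hit_idx <- which(status == 1, arr.ind = TRUE)
  n_hit <- nrow(hit_idx)
  category <- sample(c("lof", "missense", "deletion"), n_hit,
    replace = TRUE, prob = c(0.35, 0.45, 0.20)
  )
  hit_gene <- genes[hit_idx[, 1]]
  hit_line <- lines[hit_idx[, 2]]

  lof_class <- sample(c("nonsense", "stop-loss"), sum(category == "lof"),
    replace = TRUE, prob = c(0.8, 0.2)
  )
  cv <- data.frame(
    gene = hit_gene[category == "lof"], cell_line = hit_line[category == "lof"],
    classification = lof_class, sift = NA_real_, polyphen = NA_real_,
    stringsAsFactors = FALSE
  )
  n_mis <- sum(category == "missense")
  cv <- rbind(cv, data.frame(
    gene = hit_gene[category == "missense"], cell_line = hit_line[category == "missense"],
    classification = "missense",
    sift = stats::runif(n_mis, 0, 0.04),
    polyphen = stats::runif(n_mis, 0.92, 1),
    stringsAsFactors = FALSE
  ))
  # Non-damaging decoys: benign missense and unclassified labels.
  n_noise <- stats::rpois(1, cfg$noise_variants * cfg$n_cell_lines)
  if (n_noise > 0) {
    noise_class <- sample(c("missense", "other"), n_noise, replace = TRUE)
    cv <- rbind(cv, data.frame(
      gene = sample(genes, n_noise, replace = TRUE),
      cell_line = sample(lines, n_noise, replace = TRUE),
      classification = noise_class,
      sift = ifelse(noise_class == "missense", stats::runif(n_noise, 0.3, 1), NA_real_),
      polyphen = ifelse(noise_class == "missense", stats::runif(n_noise, 0, 0.5), NA_real_),
      stringsAsFactors = FALSE
    ))
  }
  cv <- cv[order(cv$gene, cv$cell_line, cv$classification), , drop = FALSE]
  rownames(cv) <- NULL

  cnv <- data.frame(
    gene = hit_gene[category == "deletion"], cell_line = hit_line[category == "deletion"],
    category = "homozygous-deletion", stringsAsFactors = FALSE
  )
  n_cnv_noise <- stats::rpois(1, 0.5 * cfg$n_cell_lines)
  if (n_cnv_noise > 0) {
    cnv <- rbind(cnv, data.frame(
      gene = sample(genes, n_cnv_noise, replace = TRUE),
      cell_line = sample(lines, n_cnv_noise, replace = TRUE),
      category = "neutral", stringsAsFactors = FALSE
    ))
  }
  cnv <- unique(cnv[order(cnv$gene, cnv$cell_line), , drop = FALSE])
  rownames(cnv) <- NULL

  # Dose response: Normal baseline per drug plus planted shifts.
  dr <- list()
  for (d in seq_len(nrow(cfg$drugs))) {
    drug <- cfg$drugs$drug[d]
    mu <- rep(cfg$drugs$baseline_mean[d], cfg$n_cell_lines)
    names(mu) <- lines
    if (!is.null(pp)) {
      for (k in which(pp$drug == drug)) {
        mu[planted_mm[[k]]] <- mu[planted_mm[[k]]] + pp$delta[k]
      }
    }
    pc <- cfg$planted_combined
    if (!is.null(pc) && drug %in% pc$drugs) {
      anchor_on <- status[pc$anchor, ] == 1
      burden <- colSums(status[pc$partners, , drop = FALSE])
      mu <- mu + ifelse(anchor_on, burden * pc$delta, 0)
    }
    y <- stats::rnorm(cfg$n_cell_lines, mu, cfg$drugs$baseline_sd[d])
    dr[[d]] <- data.frame(
      drug = drug, cell_line = lines, ln_ic50 = y, source = "S1",
      stringsAsFactors = FALSE
    )
    n_rep <- round(cfg$replicate_fraction * cfg$n_cell_lines)
    if (n_rep > 0) {
      rep_lines <- sample(lines, n_rep)
      dr[[length(dr) + 1L]] <- data.frame(
        drug = drug, cell_line = rep_lines,
        ln_ic50 = stats::rnorm(n_rep, mu[rep_lines], cfg$drugs$baseline_sd[d]),
        source = "S2", stringsAsFactors = FALSE
      )
    }
  }
  dose_response <- do.call(rbind, dr)
  rownames(dose_response) <- NULL

  meta <- data.frame(
    cell_line = lines,
    tissue1 = sample(cfg$tissue1_levels, cfg$n_cell_lines, replace = TRUE),
    tissue2 = sample(cfg$tissue2_levels, cfg$n_cell_lines, replace = TRUE),
    stringsAsFactors = FALSE
  )

  truth_pairs <- if (is.null(pp)) NULL else {
    cbind(pp, n_mm_realised = vapply(planted_mm, length, integer(1)))
  }
  list(
    coding_variants = cv, copy_number = cnv, dose_response = dose_response,
    drug_meta = cfg$drugs[, c("drug", "name", "target_class", "commercial")],
    cell_line_meta = meta,
    truth = list(
      status = status, planted_pairs = truth_pairs,
      planted_mm_lines = planted_mm, planted_combined = cfg$planted_combined
    )
  )
}

#' Write a generated panel to a directory of delimited text files
#'
#' Files use the default schema column names, so [read_tables()] reads them
#' back without configuration.
#'
#' @param panel Output of [generate_panel()].
#' @param dir Output directory (created if absent).
#' @return Named list of file paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c("coding_variants", "copy_number", "dose_response", "drug_meta", "cell_line_meta")
  paths <- lapply(tabs, function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- panel[[nm]]
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    p
  })
  names(paths) <- tabs
  invisible(paths)
}

#' Configuration for the synthetic patient-cohort generator
#'
#' @param n_patients Number of patients, default 65.
#' @param group_proportions Named proportions over WWC/WMC/MWC/MMC (summing
#'   to 1); realised as exact counts by largest remainder. Default
#'   30/22/2/11 out of 65.
#' @param baseline_hazard Events per month in the WWC group, default 0.025.
#' @param hazard_ratios Named per-group hazard ratios relative to WWC.
#' @param censoring_rate Target expected fraction censored, default 0.2;
#'   achieved by independent exponential censoring whose rate is solved
#'   numerically.
#' @param anchor,partners Gene symbols used in the emitted mutation records.
#' @param inhibitors Drug names assigned to patients (one each, cycled).
#' @param age_mean,age_sd,melanoma_prob Clinical covariate distributions.
#' @param seed Mandatory integer seed.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 65,
                          group_proportions = c(
                            WWC = 30 / 65, WMC = 22 / 65,
                            MWC = 2 / 65, MMC = 11 / 65
                          ),
                          baseline_hazard = 0.025,
                          hazard_ratios = c(WWC = 1, WMC = 1, MWC = 1, MMC = 0.44),
                          censoring_rate = 0.2,
                          anchor = "BRAF",
                          partners = c("GPR112", "NBEA", "TTN"),
                          inhibitors = c(
                            "dabrafenib", "sorafenib", "trametinib",
                            "vemurafenib", "selumetinib"
                          ),
                          age_mean = 60, age_sd = 10, melanoma_prob = 0.5,
                          seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(
    abs(sum(group_proportions) - 1) < 1e-8,
    all(group_proportions >= 0),
    baseline_hazard > 0, all(hazard_ratios > 0),
    censoring_rate >= 0, censoring_rate < 1
  )
  structure(
    list(
      n_patients = n_patients, group_proportions = group_proportions,
      baseline_hazard = baseline_hazard, hazard_ratios = hazard_ratios,
      censoring_rate = censoring_rate, anchor = anchor, partners = partners,
      inhibitors = inhibitors, age_mean = age_mean, age_sd = age_sd,
      melanoma_prob = melanoma_prob, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

largest_remainder_counts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic patient cohort with planted survival structure
#'
#' Assigns patients to the four combined mutation groups at exact
#' largest-remainder counts, draws exponential survival times with
#' group-specific hazards, censors with an independent exponential time
#' whose rate is solved so the expected censoring fraction matches the
#' target, and emits MAF-like mutation records that make
#' [classify_patients()] reproduce the planted labels exactly (every patient
#' carries at least one MAF row; wild-type status is encoded with Silent
#' rows).
#'
#' @param cfg A [cohort_config()].
#' @return List: `maf`, `clinical` (data.frames) and `truth` (labels,
#'   hazards, censoring rate used).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  groups <- c("WWC", "WMC", "MWC", "MMC")
  counts <- largest_remainder_counts(cfg$group_proportions[groups], cfg$n_patients)
  label <- rep(groups, counts)
  label <- sample(label) # shuffle patient order
  patients <- sprintf("P%04d", seq_len(cfg$n_patients))

  hazards <- cfg$baseline_hazard * cfg$hazard_ratios[label]
  t_event <- stats::rexp(cfg$n_patients, rate = hazards)
  if (cfg$censoring_rate > 0) {
    target <- cfg$censoring_rate
    f <- function(cr) mean(cr / (cr + hazards)) - target
    cr <- stats::uniroot(f, c(1e-10, 1e6), tol = 1e-12)$root
    t_cens <- stats::rexp(cfg$n_patients, rate = cr)
  } else {
    cr <- 0
    t_cens <- rep(Inf, cfg$n_patients)
  }
  os <- pmin(t_event, t_cens)
  event <- t_event <= t_cens

  dmg_class <- function(n) {
    sample(maf_damaging_classes, n,
      replace = TRUE,
      prob = c(0.7, 0.15, 0.1, 0.05)
    )
  }
  # Every patient appears in the MAF (wild-type status encoded via Silent
  # filler rows); anchor/partner damaging rows realise the planted labels.
  anchor_mut <- label %in% c("MWC", "MMC")
  anchor_silent <- !anchor_mut & stats::runif(cfg$n_patients) < 0.5
  partner_mut <- label %in% c("WMC", "MMC")
  k_partner <- ifelse(partner_mut, sample(length(cfg$partners), cfg$n_patients, replace = TRUE), 0L)
  partner_pat <- rep(patients, k_partner)
  partner_gene <- unlist(lapply(k_partner[k_partner > 0], function(k) sample(cfg$partners, k)))
  maf <- rbind(
    data.frame(
      patient = patients, gene = "FILLER1",
      variant_classification = "Silent", stringsAsFactors = FALSE
    ),
    data.frame(
      patient = patients[anchor_mut], gene = rep(cfg$anchor, sum(anchor_mut)),
      variant_classification = dmg_class(sum(anchor_mut)), stringsAsFactors = FALSE
    ),
    data.frame(
      patient = patients[anchor_silent], gene = rep(cfg$anchor, sum(anchor_silent)),
      variant_classification = rep("Silent", sum(anchor_silent)), stringsAsFactors = FALSE
    ),
    data.frame(
      patient = partner_pat, gene = partner_gene,
      variant_classification = dmg_class(length(partner_pat)), stringsAsFactors = FALSE
    )
  )
  maf <- maf[order(maf$patient, maf$gene), , drop = FALSE]
  rownames(maf) <- NULL

  clinical <- data.frame(
    patient = patients,
    age = round(stats::rnorm(cfg$n_patients, cfg$age_mean, cfg$age_sd), 1),
    sex = sample(c("male", "female"), cfg$n_patients, replace = TRUE),
    cancer_type = ifelse(stats::runif(cfg$n_patients) < cfg$melanoma_prob, "SKCM", "COAD"),
    stringsAsFactors = FALSE
  )
  clinical$drugs <- as.list(cfg$inhibitors[(seq_len(cfg$n_patients) - 1) %% length(cfg$inhibitors) + 1])
  clinical$os_months <- os
  clinical$event <- event

  list(
    maf = maf, clinical = clinical,
    truth = list(
      labels = stats::setNames(label, patients),
      hazards = stats::setNames(unname(hazards), patients),
      censoring_rate_used = cr
    )
  )
}

#' Write a generated cohort to MAF-like and clinical text files
#'
#' The MAF file uses the standard minimum columns (Hugo_Symbol,
#' Tumor_Sample_Barcode, Variant_Classification); the clinical file joins
#' the drug list with `;`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory.
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maf_path <- file.path(dir, "cohort_mutations.maf.tsv")
  maf_out <- data.frame(
    Hugo_Symbol = cohort$maf$gene,
    Tumor_Sample_Barcode = cohort$maf$patient,
    Variant_Classification = cohort$maf$variant_classification,
    stringsAsFactors = FALSE
  )
  utils::write.table(maf_out, maf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  clin_path <- file.path(dir, "cohort_clinical.tsv")
  clin <- cohort$clinical
  clin$drugs <- vapply(clin$drugs, paste, "", collapse = ";")
  utils::write.table(clin, clin_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(maf = maf_path, clinical = clin_path))
}
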