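#' @keywords internal
"_PACKAGE"

# ---- schema configuration -------------------------------------------------

#' Default column-name mappings for the flat-file readers
#'
#' Each element maps the logical field names used throughout the package to
#' the column names found in a particular file. Override any entry (or the
#' delimiter) via the `schema_config` argument of [read_tables()] and the
#' individual readers, so GDSC-style exports with different headers can be
#' read without editing code.
#'
#' @return A named list of named character vectors, one per table kind.
#' @export
default_schema <- function() {
  list(
    delim = "\t",
    coding_variants = c(
      gene = "gene", cell_line = "cell_line",
      classification = "classification", sift = "sift", polyphen = "polyphen"
    ),
    copy_number = c(gene = "gene", cell_line = "cell_line", category = "category"),
    dose_response = c(
      drug = "drug", cell_line = "cell_line",
      ln_ic50 = "ln_ic50", source = "source"
    ),
    drug_meta = c(
      drug = "drug", name = "name",
      target_class = "target_class", commercial = "commercial"
    ),
    cell_line_meta = c(cell_line = "cell_line", tissue1 = "tissue1", tissue2 = "tissue2"),
    maf = c(
      patient = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
      variant_classification = "Variant_Classification"
    ),
    clinical = c(
      patient = "patient", age = "age", sex = "sex", cancer_type = "cancer_type",
      drugs = "drugs", os_months = "os_months", event = "event"
    )
  )
}

# Closed vocabulary for cell-line coding variants. "other" carries any label
# not mapped onto the first three; the damaging classifier never promotes it.
variant_classes <- c("stop-loss", "nonsense", "missense", "other")

merge_schema <- function(schema_config = NULL) {
  schema <- default_schema()
  if (is.null(schema_config)) {
    return(schema)
  }
  stopifnot(is.list(schema_config))
  for (nm in names(schema_config)) {
    if (nm == "delim") {
      schema$delim <- schema_config$delim
    } else if (nm %in% names(schema)) {
      upd <- schema_config[[nm]]
      schema[[nm]][names(upd)] <- upd
    } else {
      stop("unknown schema table: ", nm, call. = FALSE)
    }
  }
  schema
}

read_mapped <- function(path, mapping, delim, required = names(mapping)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path,
    sep = delim, header = TRUE, stringsAsFactors = FALSE,
    check.names = FALSE, na.strings = c("NA", "")
  )
  missing_cols <- setdiff(unname(mapping[required]), names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "schema error in '", basename(path), "': missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  present <- mapping[mapping %in% names(raw)]
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)
  out
}

assert_unique <- function(df, key_cols, what) {
  key <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    offenders <- utils::head(unique(key[dup]), 5)
    stop(
      "validation error: duplicate ", what, " key(s): ",
      paste(gsub("\r", " / ", offenders), collapse = "; "),
      call. = FALSE
    )
  }
  invisible(df)
}

# ---- individual readers ---------------------------------------------------

#' Read an annotated coding-variant table
#'
#' Expects one row per variant call with a gene symbol, cell-line identifier,
#' a variant classification, and SIFT/PolyPhen scores for missense variants.
#' Labels outside the closed vocabulary (`stop-loss`, `nonsense`, `missense`)
#' are kept verbatim and mapped to `"other"` in a `class_mapped` column;
#' unknown labels are reported once per label. Missing SIFT/PolyPhen scores
#' stay `NA` — a missing score can never satisfy a damaging-score threshold.
#'
#' @param path File path.
#' @param schema_config Optional overrides of [default_schema()].
#' @param class_mapping Named character vector mapping raw labels onto the
#'   closed vocabulary, e.g. `c("Nonsense_Mutation" = "nonsense")`.
#' @return A data.frame of validated coding-variant records.
#' @export
read_coding_variants <- function(path, schema_config = NULL, class_mapping = NULL) {
  schema <- merge_schema(schema_config)
  df <- read_mapped(path, schema$coding_variants, schema$delim,
    required = c("gene", "cell_line", "classification")
  )
  if (is.null(df$sift)) df$sift <- NA_real_
  if (is.null(df$polyphen)) df$polyphen <- NA_real_
  df$sift <- as.numeric(df$sift)
  df$polyphen <- as.numeric(df$polyphen)
  bad <- stats::na.omit(c(df$sift, df$polyphen))
  if (any(bad < 0 | bad > 1)) {
    stop("validation error: SIFT/PolyPhen scores must lie in [0, 1]", call. = FALSE)
  }
  raw_class <- as.character(df$classification)
  mapped <- raw_class
  if (!is.null(class_mapping)) {
    hit <- raw_class %in% names(class_mapping)
    mapped[hit] <- unname(class_mapping[raw_class[hit]])
  }
  unknown <- setdiff(unique(mapped), variant_classes)
  if (length(unknown) > 0) {
    message(
      "coding variants: ", length(unknown), " unmapped classification label(s) ",
      "treated as 'other': ", paste(utils::head(unknown, 10), collapse = ", ")
    )
    mapped[mapped %in% unknown] <- "other"
  }
  df$class_mapped <- mapped
  df
}

#' Read a gene-level copy-number call table
#'
#' Only the `homozygous-deletion` category can later yield a damaging call;
#' every other category is retained but inert.
#'
#' @inheritParams read_coding_variants
#' @return A data.frame of copy-number records.
#' @export
read_copy_number <- function(path, schema_config = NULL) {
  schema <- merge_schema(schema_config)
  read_mapped(path, schema$copy_number, schema$delim)
}

#' Read per-drug per-cell-line natural-log IC50 measurements
#'
#' Values are natural-log IC50 in ln(uM). The (drug, cell_line, source)
#' triple must be unique; replicates from different measurement sites carry
#' distinct `source` labels and are averaged later by [average_replicates()].
#'
#' @inheritParams read_coding_variants
#' @return A data.frame of dose-response records.
#' @export
read_dose_response <- function(path, schema_config = NULL) {
  schema <- merge_schema(schema_config)
  df <- read_mapped(path, schema$dose_response, schema$delim)
  df$ln_ic50 <- as.numeric(df$ln_ic50)
  if (any(!is.finite(df$ln_ic50))) {
    stop("validation error: non-finite ln_ic50 values", call. = FALSE)
  }
  assert_unique(df, c("drug", "cell_line", "source"), "(drug, cell_line, source)")
  df
}

#' Read drug metadata (target class and commercial availability)
#' @inheritParams read_coding_variants
#' @return A data.frame with one row per drug.
#' @export
read_drug_meta <- function(path, schema_config = NULL) {
  schema <- merge_schema(schema_config)
  df <- read_mapped(path, schema$drug_meta, schema$delim)
  df$commercial <- as.logical(df$commercial)
  assert_unique(df, "drug", "drug")
  df
}

#' Read cell-line metadata with two tissue descriptors
#'
#' `tissue1` is the coarse anatomical origin; `tissue2` the finer
#' pathological classification.
#'
#' @inheritParams read_coding_variants
#' @return A data.frame with one row per cell line.
#' @export
read_cell_line_meta <- function(path, schema_config = NULL) {
  schema <- merge_schema(schema_config)
  df <- read_mapped(path, schema$cell_line_meta, schema$delim)
  assert_unique(df, "cell_line", "cell_line")
  df
}

#' Read a MAF-like somatic mutation table for a patient cohort
#'
#' Minimum columns: Hugo_Symbol, Tumor_Sample_Barcode, Variant_Classification.
#' All rows are parsed; classification into damaging vs not happens in
#' [classify_patients()], so Silent and other rows survive parsing.
#'
#' @inheritParams read_coding_variants
#' @return A data.frame of cohort variant records.
#' @export
read_maf <- function(path, schema_config = NULL) {
  schema <- merge_schema(schema_config)
  read_mapped(path, schema$maf, schema$delim)
}

#' Read a clinical table with survival outcome and drug exposure
#'
#' `drugs` is a `;`-separated list of drug names per patient; it is split
#' into a list-column. Overall survival must be non-negative.
#'
#' @inheritParams read_coding_variants
#' @return A data.frame of clinical records with a `drugs` list-column.
#' @export
read_clinical <- function(path, schema_config = NULL) {
  schema <- merge_schema(schema_config)
  df <- read_mapped(path, schema$clinical, schema$delim)
  assert_unique(df, "patient", "patient")
  df$age <- as.numeric(df$age)
  df$os_months <- as.numeric(df$os_months)
  df$event <- as.logical(df$event)
  if (any(df$os_months < 0, na.rm = TRUE)) {
    stop("validation error: negative os_months", call. = FALSE)
  }
  df$drugs <- strsplit(ifelse(is.na(df$drugs), "", as.character(df$drugs)), ";",
    fixed = TRUE
  )
  df
}

#' Read every table of a study in one call
#'
#' `paths` is a named list with any subset of `coding_variants`,
#' `copy_number`, `dose_response`, `drug_meta`, `cell_line_meta`, `maf`,
#' `clinical`; each present entry is read with its dedicated reader and
#' validated. Row counts are reported via `message()`.
#'
#' @param paths Named list of file paths.
#' @param schema_config Optional overrides of [default_schema()].
#' @param class_mapping Passed to [read_coding_variants()].
#' @return Named list of validated data.frames.
#' @export
read_tables <- function(paths, schema_config = NULL, class_mapping = NULL) {
  readers <- list(
    coding_variants = function(p) read_coding_variants(p, schema_config, class_mapping),
    copy_number = function(p) read_copy_number(p, schema_config),
    dose_response = function(p) read_dose_response(p, schema_config),
    drug_meta = function(p) read_drug_meta(p, schema_config),
    cell_line_meta = function(p) read_cell_line_meta(p, schema_config),
    maf = function(p) read_maf(p, schema_config),
    clinical = function(p) read_clinical(p, schema_config)
  )
  unknown <- setdiff(names(paths), names(readers))
  if (length(unknown) > 0) {
    stop("unknown table kind(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- lapply(names(paths), function(nm) {
    tab <- readers[[nm]](paths[[nm]])
    message(nm, ": ", nrow(tab), " rows")
    tab
  })
  names(out) <- names(paths)
  out
}

# ---- writing --------------------------------------------------------------

#' Write a pipeline result table to a delimited text file
#'
#' Serialisation is schema-faithful: column classes are recorded in a `#types:`
#' header comment so [read_results()] restores integer/double/logical/character
#' columns exactly rather than re-inferring them. List-columns are not
#' supported.
#'
#' @param records A data.frame. Empty tables are refused unless
#'   `allow_empty = TRUE` (then a typed header-only file is written).
#' @param path Output path.
#' @param delim Field delimiter (tab by default).
#' @param allow_empty Permit writing a zero-row table.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, delim = "\t", allow_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0 && !allow_empty) {
    stop("refusing to write an empty table (set allow_empty = TRUE)", call. = FALSE)
  }
  if (any(vapply(records, is.list, logical(1)))) {
    stop("list-columns cannot be serialised", call. = FALSE)
  }
  types <- vapply(records, function(col) class(col)[1], character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#types: ", paste(types, collapse = ",")), con)
  utils::write.table(records, con,
    sep = delim, quote = FALSE,
    row.names = FALSE, col.names = TRUE, na = "NA"
  )
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @return The original data.frame, classes restored.
#' @export
read_results <- function(path, delim = "\t") {
  first <- readLines(path, n = 1)
  types <- NULL
  skip <- 0
  if (startsWith(first, "#types: ")) {
    types <- strsplit(sub("^#types: ", "", first), ",", fixed = TRUE)[[1]]
    skip <- 1
  }
  df <- utils::read.delim(path,
    sep = delim, header = TRUE, skip = skip,
    stringsAsFactors = FALSE, check.names = FALSE,
    colClasses = if (is.null(types)) NA else types,
    na.strings = "NA"
  )
  df
}
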