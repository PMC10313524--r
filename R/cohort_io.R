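# Subject tables: reading, writing, evaluability filtering, and the small
# derived biomarker quantities (5hmC percent, cellularity-normalized 2-HG).

#' Column schema for subject cohort tables
#'
#' One row per enrolled subject.  Numeric cells left empty in the CSV are
#' read as missing (`NA`), never as zero.  Lesion measurements live in a
#' separate long table (see [read_lesion_table()]).
#'
#' @return A named character vector mapping column name to type
#'   (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @export
cohort_schema <- function() {
  c(
    subject_id = "character",
    cohort = "integer",
    arm = "character",
    treated_presurgery = "logical",
    missed_doses_2wk = "integer",
    midh1_confirmed = "logical",
    tissue_sufficient = "logical",
    dosing_correct = "logical",
    tumor_2hg = "numeric",
    cellularity = "numeric",
    c_5hmc = "numeric",
    c_5mc = "numeric",
    c_c = "numeric",
    ki67_pct = "numeric",
    cd3_density = "numeric",
    cd8_density = "numeric"
  )
}

#' Read a subject cohort table
#'
#' Reads a UTF-8, "."-decimal CSV with one row per subject and the columns
#' of [cohort_schema()].  Validates the mandatory columns, coerces types,
#' and checks the basic domain invariants (nonnegative 2-HG, cellularity in
#' (0, 1], untreated subjects not flagged as treated before surgery).
#'
#' @param path Path to a CSV file.
#' @return A tibble of subject records.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cohort table not found: ", path), class = "hg_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("cohort table is missing mandatory column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "hg_schema_error"
    )
  }
  out <- coerce_schema(raw[names(schema)], schema, path)
  validate_cohort(out)
  out
}

coerce_schema <- function(df, schema, path) {
  for (col in names(schema)) {
    x <- df[[col]]
    df[[col]] <- switch(
      schema[[col]],
      character = x,
      numeric = parse_numeric_col(x, col, path),
      integer = as.integer(parse_numeric_col(x, col, path)),
      logical = parse_logical_col(x, col)
    )
  }
  tibble::as_tibble(df)
}

parse_numeric_col <- function(x, col, path) {
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(
      paste0("non-numeric value in column '", col, "' at data row ", bad[1],
             " of ", path, ": '", x[bad[1]], "'"),
      class = "hg_parse_error"
    )
  }
  out
}

parse_logical_col <- function(x, col) {
  x <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  out
}

validate_cohort <- function(df) {
  if (any(df$tumor_2hg < 0, na.rm = TRUE)) {
    abort("tumor_2hg must be nonnegative", class = "hg_domain_error")
  }
  bad_cell <- !is.na(df$cellularity) & (df$cellularity <= 0 | df$cellularity > 1)
  if (any(bad_cell)) {
    abort("cellularity must lie in (0, 1]", class = "hg_domain_error")
  }
  bad_arm <- !df$arm %in% ALL_ARMS
  if (any(bad_arm)) {
    abort(paste0("unknown arm label: ", df$arm[which(bad_arm)[1]]),
          class = "hg_domain_error")
  }
  untreated_flagged <- df$arm == "UNTREATED" & !is.na(df$treated_presurgery) &
    df$treated_presurgery
  if (any(untreated_flagged)) {
    abort("untreated subjects cannot be flagged treated_presurgery",
          class = "hg_domain_error")
  }
  invisible(df)
}

#' Write a subject cohort table
#'
#' Inverse of [read_cohort_table()]: `read_cohort_table(write_cohort_table(x, p))`
#' reproduces `x` field for field.  Missing numerics are written as empty
#' cells.
#'
#' @param records Tibble of subject records (columns of [cohort_schema()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  records <- tibble::as_tibble(records)[names(cohort_schema())]
  readr::write_csv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read/write external-control 2-HG tables
#'
#' External controls are previously banked tumor samples with a known IDH
#' status and a measured tumor 2-HG concentration; they share the cohort
#' CSV conventions but carry no trial fields.
#'
#' @param path CSV path with columns `sample_id`, `idh_status`
#'   (`WT`/`mIDH1`) and `tumor_2hg`.
#' @return A tibble of external-control records.
#' @export
read_external_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("external-control table not found: ", path), class = "hg_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("sample_id", "idh_status", "tumor_2hg")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("external-control table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hg_schema_error")
  }
  out <- tibble::tibble(
    sample_id = raw$sample_id,
    idh_status = raw$idh_status,
    tumor_2hg = parse_numeric_col(raw$tumor_2hg, "tumor_2hg", path)
  )
  if (!all(out$idh_status %in% c("WT", "mIDH1"))) {
    abort("idh_status must be WT or mIDH1", class = "hg_domain_error")
  }
  if (any(out$tumor_2hg < 0, na.rm = TRUE)) {
    abort("tumor_2hg must be nonnegative", class = "hg_domain_error")
  }
  out
}

#' @rdname read_external_table
#' @param records Tibble of external-control records.
#' @export
write_external_table <- function(records, path) {
  readr::write_csv(records[c("sample_id", "idh_status", "tumor_2hg")],
                   path, na = "", progress = FALSE)
  invisible(path)
}

#' Evaluability filter for the tissue analysis set
#'
#' Applies the trial's evaluability rules.  A treated subject is excluded
#' if tissue was insufficient, the IDH1 mutation was not confirmed in the
#' resected tissue, pre-surgery dosing was incorrect, or two or more doses
#' were missed in the two weeks before surgery.  Untreated subjects can be
#' excluded only for the tissue and confirmation reasons.  When several
#' reasons apply, the first in the fixed precedence order
#' tissue > confirmation > dosing > missed doses is recorded.
#'
#' @param records Tibble of subject records.
#' @return A list with `included` (tibble of retained records) and
#'   `exclusions` (tibble of `subject_id`, `reason`).
#' @export
eligibility_filter <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(list(
      included = records,
      exclusions = tibble::tibble(subject_id = character(), reason = character())
    ))
  }
  treated <- records$arm != "UNTREATED"
  reason <- rep(NA_character_, nrow(records))
  hit <- function(flag) is.na(reason) & flag
  reason[hit(!records$tissue_sufficient)] <- "INSUFFICIENT_TISSUE"
  reason[hit(!records$midh1_confirmed)] <- "MIDH1_NOT_CONFIRMED"
  reason[hit(treated & !records$dosing_correct)] <- "INCORRECT_DOSING"
  reason[hit(treated & records$missed_doses_2wk >= 2)] <- "MISSED_DOSES"
  excluded <- !is.na(reason)
  list(
    included = records[!excluded, , drop = FALSE],
    exclusions = tibble::tibble(
      subject_id = records$subject_id[excluded],
      reason = reason[excluded]
    )
  )
}

#' Percent 5-hydroxymethylcytosine relative to unmodified cytosine
#'
#' DNA hydroxymethylation readout: the 5hmC nucleoside count as a percent
#' of the unmodified cytosine count.  The denominator is the unmodified C
#' signal; pass a different denominator explicitly if a total-cytosine
#' convention is preferred.
#'
#' @param c_5hmc Nonnegative 5hmC count (vectorised).
#' @param c_c Positive unmodified cytosine count.
#' @return Percent values, `100 * c_5hmc / c_c`.
#' @export
compute_5hmc_percent <- function(c_5hmc, c_c) {
  if (any(c_c <= 0, na.rm = TRUE)) {
    abort("cytosine denominator must be positive", class = "hg_domain_error")
  }
  if (any(c_5hmc < 0, na.rm = TRUE)) {
    abort("5hmC count must be nonnegative", class = "hg_domain_error")
  }
  100 * c_5hmc / c_c
}

#' Cellularity-normalized tumor 2-HG
#'
#' Divides the bulk tumor 2-HG concentration by the tumor-cell fraction of
#' the specimen, expressing 2-HG per unit tumor-cell content.  Because
#' cellularity is at most 1 the normalized value is never below the bulk
#' value.
#'
#' @param tumor_2hg Nonnegative 2-HG concentration, ug/g (vectorised).
#' @param cellularity Tumor-cell fraction in (0, 1].
#' @return Normalized 2-HG, same units per unit tumor-cell fraction.
#' @export
normalize_2hg <- function(tumor_2hg, cellularity) {
  if (any(cellularity <= 0 | cellularity > 1, na.rm = TRUE)) {
    abort("cellularity must lie in (0, 1]", class = "hg_domain_error")
  }
  if (any(tumor_2hg < 0, na.rm = TRUE)) {
    abort("tumor_2hg must be nonnegative", class = "hg_domain_error")
  }
  tumor_2hg / cellularity
}

#' Read/write long lesion-measurement tables
#'
#' Lesion series are stored long: one row per subject visit with the day
#' (baseline at day 0) and the sum of products of perpendicular lesion
#' diameters (SPD, cm^2).  `no_residual` marks subjects whose resection
#' left no measurable disease (baseline SPD 0).
#'
#' @param path CSV path with columns `subject_id`, `day`, `spd`.
#' @return A tibble sorted by subject and day.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("lesion table not found: ", path), class = "hg_io_error")
  }
  out <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    day = readr::col_double(),
    spd = readr::col_double()
  ), progress = FALSE)
  if (any(out$spd < 0, na.rm = TRUE)) {
    abort("spd must be nonnegative", class = "hg_domain_error")
  }
  dplyr::arrange(out, .data$subject_id, .data$day)
}

#' @rdname read_lesion_table
#' @param records Tibble with `subject_id`, `day`, `spd`.
#' @export
write_lesion_table <- function(records, path) {
  readr::write_csv(records[c("subject_id", "day", "spd")], path,
                   na = "", progress = FALSE)
  invisible(path)
}
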