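#' Admission-record data model and I/O
#'
#' One hospital discharge record is one row of a tibble with the columns
#' below. Diagnoses are stored wide: up to 16 three-character ICD-10 codes in
#' `diag_01`..`diag_16` (principal diagnosis in `diag_01`) with matching
#' point-of-admission flags `poa_01`..`poa_16` (1 = present at admission).
#' Empty strings / `NA` mark unused diagnosis slots.
#'
#' Mandatory columns: `record_id`, `patient_id`, `sex` (`male`/`female`),
#' `age` (integer years), `ethnic_group` (`han`/`minority`),
#' `admission_date`, `discharge_date` (ISO-8601 dates), `los` (whole days),
#' `hospital_id`, `hospital_level`, `hospital_affiliation`,
#' `hospital_address_code`, `patient_address_code`, `admission_status`
#' (1 danger, 2 urgent, 3 general), `admission_source` (1..4), `job` (1..13),
#' `marital_status` (1..4), plus the 32 diagnosis columns. An optional
#' logical `died` column supports the alive-during-period criterion.
#'
#' @name admission-records
NULL

N_DIAG <- 16L

diag_cols <- function() sprintf("diag_%02d", seq_len(N_DIAG))
poa_cols <- function() sprintf("poa_%02d", seq_len(N_DIAG))

mandatory_cols <- function() {
  c(
    "record_id", "patient_id", "sex", "age", "ethnic_group",
    "admission_date", "discharge_date", "los",
    "hospital_id", "hospital_level", "hospital_affiliation",
    "hospital_address_code", "patient_address_code",
    "admission_status", "admission_source", "job", "marital_status",
    diag_cols(), poa_cols()
  )
}

#' Create a chronic-disease catalog
#'
#' The catalog is the set of three-character ICD-10 codes considered chronic;
#' membership is exact string match. The study-defining catalog is an external
#' input, so it is always user-supplied (the synthetic generator ships its
#' own).
#'
#' @param codes Character vector of codes matching `^[A-Z][0-9]{2}$`.
#' @param source_label Free-text provenance label.
#' @return A character vector of unique codes with class `chronic_catalog`.
#' @export
#' @examples
#' chronic_catalog(c("I10", "E11", "N18"), "toy")
chronic_catalog <- function(codes, source_label = "user-supplied") {
  codes <- unique(as.character(codes))
  if (length(codes) == 0) abort("a chronic-disease catalog must be non-empty")
  bad <- codes[!is_icd3(codes)]
  if (length(bad) > 0) {
    abort(paste0("malformed catalog codes: ", paste(head(bad, 5), collapse = ", ")))
  }
  structure(codes, source_label = source_label, class = c("chronic_catalog", "character"))
}

#' Read admission records from a delimited file
#'
#' Reads the CSV dialect described in [admission-records]: UTF-8, header row,
#' ISO-8601 dates, diagnosis columns `diag_01..diag_16` with PoA flag columns
#' `poa_01..poa_16` (0/1), empty string = missing. Structural problems
#' (missing mandatory columns, unparseable dates, malformed diagnosis codes)
#' raise errors naming the offending column or rows; a negative stored LOS or
#' an LOS disagreeing with the date difference is kept but reported, so the
#' inclusion filter can count it.
#'
#' @param path Path to a CSV file.
#' @return A tibble of admission records, one row per admission, in file
#'   order. Attribute `issues` holds a tibble of non-fatal row-level issues.
#' @seealso [write_admissions()]
#' @export
read_admissions <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0,
    col_types = readr::cols(.default = "c"), progress = FALSE))
  missing <- setdiff(mandatory_cols(), hdr)
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")))
  }
  spec <- readr::cols(
    .default = readr::col_integer(),
    record_id = readr::col_character(),
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    ethnic_group = readr::col_character(),
    hospital_id = readr::col_character(),
    admission_date = readr::col_character(),
    discharge_date = readr::col_character()
  )
  for (dc in diag_cols()) spec$cols[[dc]] <- readr::col_character()
  x <- readr::read_csv(path, col_types = spec, na = c("", "NA"), progress = FALSE)

  adm <- lubridate::ymd(x$admission_date, quiet = TRUE)
  dis <- lubridate::ymd(x$discharge_date, quiet = TRUE)
  bad_date <- which((is.na(adm) & !is.na(x$admission_date)) |
    (is.na(dis) & !is.na(x$discharge_date)))
  if (length(bad_date) > 0) {
    abort(paste0(
      "unparseable date(s) in row(s): ",
      paste(head(bad_date, 10), collapse = ", ")
    ))
  }
  x$admission_date <- adm
  x$discharge_date <- dis

  dmat <- as.matrix(x[diag_cols()])
  bad_code_rows <- which(apply(dmat, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) > 0 && any(!is_icd3(r))
  }))
  if (length(bad_code_rows) > 0) {
    abort(paste0(
      "malformed diagnosis code(s) in row(s): ",
      paste(head(bad_code_rows, 10), collapse = ", ")
    ))
  }
  no_diag <- which(rowSums(!is.na(dmat)) == 0)
  if (length(no_diag) > 0) {
    abort(paste0(
      "record(s) without any diagnosis in row(s): ",
      paste(head(no_diag, 10), collapse = ", ")
    ))
  }

  issues <- tibble(row = integer(), issue = character())
  los_mismatch <- which(!is.na(x$los) & !is.na(adm) & !is.na(dis) &
    x$los != as.integer(dis - adm))
  if (length(los_mismatch) > 0) {
    issues <- bind_rows(issues, tibble(row = los_mismatch, issue = "los_date_mismatch"))
  }
  neg <- which(!is.na(x$los) & x$los < 0)
  if (length(neg) > 0) {
    issues <- bind_rows(issues, tibble(row = neg, issue = "negative_los"))
  }
  if (nrow(issues) > 0) {
    warn(paste0(nrow(issues), " record(s) with LOS issues; see attr(x, 'issues')"))
  }
  attr(x, "issues") <- issues
  x
}

#' Write admission records to a delimited file
#'
#' Inverse of [read_admissions()]: `read_admissions(write_admissions(x, p))`
#' reproduces `x` field for field.
#'
#' @param records Admission-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(records, path) {
  out <- records
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$discharge_date <- format(out$discharge_date, "%Y-%m-%d")
  ord <- c(intersect(mandatory_cols(), names(out)), setdiff(names(out), mandatory_cols()))
  readr::write_csv(out[, ord], path, na = "", progress = FALSE)
  invisible(path)
}

#' Per-admission diagnosis sets
#'
#' @param records Admission-record tibble.
#' @param poa_only Keep only diagnoses flagged present at admission.
#' @param catalog Optional [chronic_catalog()]; restricts to chronic codes.
#' @return A list (one element per row) of character vectors of codes.
#' @export
diagnosis_sets <- function(records, poa_only = FALSE, catalog = NULL) {
  dmat <- as.matrix(records[diag_cols()])
  pmat <- as.matrix(records[poa_cols()])
  keep_codes <- if (is.null(catalog)) NULL else as.character(catalog)
  lapply(seq_len(nrow(records)), function(i) {
    codes <- dmat[i, ]
    flags <- pmat[i, ]
    ok <- !is.na(codes)
    if (poa_only) ok <- ok & !is.na(flags) & flags == 1
    codes <- unique(codes[ok])
    if (!is.null(keep_codes)) codes <- codes[codes %in% keep_codes]
    codes
  })
}

#' Length-of-stay outlier cutoff by nearest-rank quantile
#'
#' @param records Admission-record tibble with valid `los`.
#' @param q Quantile in (0, 1); default 0.99 (the conventional tail trim for
#'   administrative LOS data).
#' @return Integer day count: the nearest-rank `q`-quantile of `los`.
#' @export
#' @examples
#' r <- tibble::tibble(los = 1:100)
#' compute_los_cutoff(r, 0.99) # 99
compute_los_cutoff <- function(records, q = 0.99) {
  los <- records$los[!is.na(records$los)]
  if (length(los) == 0) abort("no LOS values to compute a cutoff from")
  as.integer(nearest_rank_quantile(los, q))
}

#' Apply the cohort inclusion criteria
#'
#' Filters admission records, in order: (1a) LOS present and non-negative,
#' (1b) admission date inside `date_range`, (2) patient alive (optional
#' `died` column), (3) age at least `min_age`, (4) LOS at most the outlier
#' cutoff (supplied, or the nearest-rank `los_quantile` of the records
#' surviving 1-3), (5) at least one catalog chronic disease flagged at the
#' point of admission. The order only affects which criterion a doubly
#' excluded record is attributed to, not the kept set.
#'
#' @param records Admission-record tibble.
#' @param catalog [chronic_catalog()] of chronic codes.
#' @param min_age Minimum age in years (default 65).
#' @param los_quantile Outlier quantile for the LOS cutoff (default 0.99).
#' @param date_range Length-2 vector of dates (or `NULL` for no date filter).
#' @param los_cutoff Optional fixed cutoff in days, overriding the quantile.
#' @param require_chronic_poa Enforce criterion 5 (default `TRUE`).
#' @return A list of class `inclusion_result`: `records` (kept rows),
#'   `tally` (tibble criterion/removed, in application order), `cutoff`
#'   (days). `nrow(records) + sum(tally$removed)` equals the input row count.
#' @export
apply_inclusion_criteria <- function(records, catalog,
                                     min_age = 65L,
                                     los_quantile = 0.99,
                                     date_range = NULL,
                                     los_cutoff = NULL,
                                     require_chronic_poa = TRUE) {
  x <- records
  tally <- c()

  drop_step <- function(x, keep, name) {
    tally[[name]] <<- sum(!keep)
    x[keep, , drop = FALSE]
  }

  x <- drop_step(x, !is.na(x$los) & x$los >= 0, "los_missing")
  if (!is.null(date_range)) {
    dr <- as.Date(date_range)
    stopifnot(length(dr) == 2, dr[1] <= dr[2])
    x <- drop_step(x, x$admission_date >= dr[1] & x$admission_date <= dr[2], "date_out_of_range")
  } else {
    tally[["date_out_of_range"]] <- 0L
  }
  alive <- if ("died" %in% names(x)) !isTRUE_vec(x$died) else rep(TRUE, nrow(x))
  x <- drop_step(x, alive, "not_alive")
  x <- drop_step(x, !is.na(x$age) & x$age >= min_age, "age_below_min")

  cutoff <- if (is.null(los_cutoff)) {
    if (nrow(x) > 0) compute_los_cutoff(x, los_quantile) else NA_integer_
  } else {
    as.integer(los_cutoff)
  }
  x <- drop_step(x, is.na(cutoff) | x$los <= cutoff, "los_above_cutoff")

  if (require_chronic_poa) {
    sets <- diagnosis_sets(x, poa_only = TRUE, catalog = catalog)
    x <- drop_step(x, lengths(sets) > 0, "no_chronic_poa")
  } else {
    tally[["no_chronic_poa"]] <- 0L
  }

  structure(
    list(
      records = as_tibble(x),
      tally = tibble(criterion = names(tally), removed = as.integer(unlist(tally))),
      cutoff = cutoff
    ),
    class = "inclusion_result"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' @export
print.inclusion_result <- function(x, ...) {
  cat("<inclusion_result>\n")
  cat("  kept records:", nrow(x$records), "\n")
  cat("  LOS cutoff:", x$cutoff, "days\n")
  for (i in seq_len(nrow(x$tally))) {
    cat(sprintf("  removed by %-18s %d\n", x$tally$criterion[i], x$tally$removed[i]))
  }
  invisible(x)
}
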