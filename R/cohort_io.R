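# Canonical column order for cohort tables. Doses in Gy; PRO-CTCAE dry-mouth
# scores 0 (none) to 4 (very severe). Missing values are NA, never a sentinel
# number: 0 Gy is a legal dose.
COHORT_COLS <- c("patient_id", "cohort", "dose_gland", "dose_duct_total",
                 "dose_duct_ig", "proctcae_6mo", "proctcae_12mo")

PAIR_COLS <- c("patient_id", "structure", "mda", "dose_ref", "dose_est",
               "dose_diff")

#' Construct a validated cohort table
#'
#' A cohort table holds one row per patient: bilateral parotid gland mean
#' dose, total and intraglandular parotid duct mean doses (Gy), and
#' PRO-CTCAE dry-mouth scores at 6 and 12 months post-RT. Doses must be
#' finite and non-negative; scores, when present, must lie in 0--4.
#'
#' @param x data.frame with columns `patient_id`, `cohort` (one of
#'   `"PDS"`, `"PGS"`, `"SYNTH"`), `dose_gland`, `dose_duct_total`,
#'   `dose_duct_ig`, `proctcae_6mo`, `proctcae_12mo`. Missing doses/scores
#'   are `NA`.
#' @param provenance character tag recording where the table came from.
#' @return a `cohort_table` (a data.frame).
#' @export
as_cohort <- function(x, provenance = "unspecified") {
  x <- as.data.frame(x)
  missing_cols <- setdiff(COHORT_COLS, names(x))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- x[COHORT_COLS]
  x$patient_id <- as.character(x$patient_id)
  x$cohort <- as.character(x$cohort)
  for (col in c("dose_gland", "dose_duct_total", "dose_duct_ig"))
    x[[col]] <- as.numeric(x[[col]])
  for (col in c("proctcae_6mo", "proctcae_12mo"))
    x[[col]] <- as.integer(x[[col]])
  validate_cohort(x)
  rownames(x) <- NULL
  structure(x, provenance = provenance,
            class = c("cohort_table", "data.frame"))
}

validate_cohort <- function(x) {
  dup <- x$patient_id[duplicated(x$patient_id)]
  if (length(dup))
    stop("duplicate patient_id: ", paste(unique(dup), collapse = ", "))
  bad_cohort <- !x$cohort %in% c("PDS", "PGS", "SYNTH")
  if (any(bad_cohort))
    stop("unknown cohort label in row(s) ",
         paste(which(bad_cohort), collapse = ", "),
         " (expected PDS, PGS or SYNTH)")
  for (col in c("dose_gland", "dose_duct_total", "dose_duct_ig")) {
    v <- x[[col]]
    bad <- !is.na(v) & (!is.finite(v) | v < 0)
    if (any(bad))
      stop("column ", col, ": dose must be finite and >= 0 Gy in row(s) ",
           paste(which(bad), collapse = ", "))
  }
  for (col in c("proctcae_6mo", "proctcae_12mo")) {
    v <- x[[col]]
    bad <- !is.na(v) & !v %in% 0:4
    if (any(bad))
      stop("column ", col, ": PRO-CTCAE score must be in 0..4 in row(s) ",
           paste(which(bad), collapse = ", "))
  }
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' The expected dialect is comma-separated UTF-8 with a header row and "."
#' as decimal separator. Empty cells are missing values and stay missing;
#' nothing is imputed. Columns may be renamed through `schema`.
#'
#' @param path path to a CSV file.
#' @param schema optional column mapping: either a named character vector
#'   `c(internal_name = "file_column", ...)` or the path to a YAML/JSON file
#'   holding such a mapping. Internal names are
#'   `patient_id, cohort, dose_gland, dose_duct_total, dose_duct_ig,
#'   proctcae_6mo, proctcae_12mo`.
#' @return a `cohort_table`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  raw <- apply_schema(raw, schema)
  missing_cols <- setdiff(COHORT_COLS, names(raw))
  if (length(missing_cols))
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(patient_id = trimws(raw$patient_id),
                    cohort = trimws(raw$cohort),
                    stringsAsFactors = FALSE)
  for (col in c("dose_gland", "dose_duct_total", "dose_duct_ig",
                "proctcae_6mo", "proctcae_12mo"))
    out[[col]] <- parse_numeric_column(raw[[col]], col)
  as_cohort(out, provenance = path)
}

apply_schema <- function(raw, schema) {
  if (is.null(schema)) return(raw)
  if (is.character(schema) && is.null(names(schema)) && length(schema) == 1)
    schema <- read_schema(schema)
  if (is.null(names(schema)) || any(!nzchar(names(schema))))
    stop("schema must be a named mapping internal_name -> file column")
  absent <- setdiff(unname(unlist(schema)), names(raw))
  if (length(absent))
    stop("schema refers to column(s) absent from the file: ",
         paste(absent, collapse = ", "))
  for (internal in names(schema))
    names(raw)[names(raw) == schema[[internal]]] <- internal
  raw
}

#' Read a column mapping from a YAML or JSON config file
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file containing a flat
#'   mapping from internal column names to file column names.
#' @return named character vector usable as the `schema` argument of
#'   [read_cohort()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path)
  m <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(m)
}

parse_numeric_column <- function(v, col) {
  if (is.null(v)) stop("missing column: ", col)
  v <- trimws(v)
  v[v == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(v))
  bad <- is.na(out) & !is.na(v)
  if (any(bad))
    stop("column ", col, ": cannot parse value '", v[which(bad)[1]],
         "' as a number in row ", which(bad)[1])
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: missing values become empty cells, and finite
#' decimal values round-trip bit-exactly.
#'
#' @param cohort a `cohort_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Construct a validated table of dose-validation pairs
#'
#' Each row pairs a reference (MRI sialography based) and surrogate
#' (atlas based) mean duct dose for one patient and structure, optionally
#' with the mean distance to agreement (mm) between the two contours.
#' `dose_diff` follows the reference-minus-surrogate sign convention and
#' must agree with `dose_ref - dose_est` up to the rounding of the source
#' values.
#'
#' @param x data.frame with columns `patient_id`, `structure` (`"total"` or
#'   `"ig"`), `mda`, `dose_ref`, `dose_est`, `dose_diff`.
#' @param rounding_tol largest tolerated |dose_diff - (dose_ref - dose_est)|;
#'   the default allows each printed value to be rounded to 0.1 Gy.
#' @return a `validation_pairs` data.frame.
#' @export
as_validation_pairs <- function(x, rounding_tol = 0.151) {
  x <- as.data.frame(x)
  missing_cols <- setdiff(PAIR_COLS, names(x))
  if (length(missing_cols))
    stop("validation pairs missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- x[PAIR_COLS]
  x$patient_id <- as.character(x$patient_id)
  x$structure <- as.character(x$structure)
  if (any(!x$structure %in% c("total", "ig")))
    stop("structure must be 'total' or 'ig'")
  for (col in c("mda", "dose_ref", "dose_est", "dose_diff"))
    x[[col]] <- as.numeric(x[[col]])
  if (any(!is.na(x$mda) & x$mda < 0)) stop("mda must be >= 0 mm")
  resid <- abs(x$dose_diff - (x$dose_ref - x$dose_est))
  bad <- !is.na(resid) & resid > rounding_tol
  if (any(bad))
    stop("dose_diff inconsistent with dose_ref - dose_est in row(s) ",
         paste(which(bad), collapse = ", "))
  rownames(x) <- NULL
  structure(x, class = c("validation_pairs", "data.frame"))
}

#' Read validation pairs from CSV
#'
#' @inheritParams read_cohort
#' @return a `validation_pairs` data.frame.
#' @export
read_validation_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(PAIR_COLS, names(raw))
  if (length(missing_cols))
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  out <- data.frame(patient_id = trimws(raw$patient_id),
                    structure = trimws(raw$structure),
                    stringsAsFactors = FALSE)
  for (col in c("mda", "dose_ref", "dose_est", "dose_diff"))
    out[[col]] <- parse_numeric_column(raw[[col]], col)
  as_validation_pairs(out)
}

#' Load a bundled published-table fixture
#'
#' The package ships the published summary tables of the parotid duct
#' sparing study as plain-text fixtures:
#' \describe{
#'   \item{`"table4"`}{the 14-patient atlas-segmentation validation set:
#'     per-patient mean distance to agreement and reference vs atlas-based
#'     mean duct doses, for the total and intraglandular ducts, as a
#'     `validation_pairs` data.frame (28 rows).}
#'   \item{`"table2"`}{xerostomia rate table for the intraglandular duct
#'     constraint (14 Gy): toxic/total counts per dose group and timepoint
#'     plus each group's mean bilateral parotid gland dose.}
#'   \item{`"table3"`}{as `"table2"`, for the total duct constraint (12 Gy).}
#'   \item{`"table1_counts"`}{categorical patient-characteristic counts of
#'     the duct-sparing vs gland-sparing cohorts (T stage, N stage,
#'     prescription), as a list of contingency matrices.}
#' }
#'
#' @param name one of `"table2"`, `"table3"`, `"table4"`, `"table1_counts"`.
#' @return see Details; the published values exactly as printed.
#' @export
load_fixture <- function(name) {
  name <- match.arg(name, c("table2", "table3", "table4", "table1_counts"))
  extdata <- function(f) system.file("extdata", f, package = "ductdose",
                                     mustWork = TRUE)
  if (name == "table4")
    return(read_validation_pairs(extdata("table4_duct_validation.csv")))
  if (name == "table1_counts") {
    raw <- jsonlite::read_json(extdata("table1_counts.json"),
                               simplifyVector = TRUE)
    return(lapply(raw, function(m) {
      cm <- m$counts
      if (!is.matrix(cm))
        cm <- matrix(unlist(cm), nrow = length(m$rows), byrow = TRUE)
      storage.mode(cm) <- "integer"
      dimnames(cm) <- list(m$rows, m$cols)
      cm
    }))
  }
  raw <- jsonlite::read_json(extdata(paste0(name, "_rates.json")),
                             simplifyVector = TRUE)
  groups <- as.data.frame(raw$groups)
  groups$rate <- groups$n_toxic / groups$n_total
  structure(list(structure = raw$structure,
                 cutpoint = raw$cutpoint_gy,
                 mean_gland_dose = unlist(raw$mean_gland_dose),
                 groups = groups),
            class = "rate_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance")))
  print(as.data.frame(x), ...)
  invisible(x)
}
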