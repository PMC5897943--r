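# Patient cohort container, validation, and delimited-file I/O.

.responses <- c("responder", "non_responder")
.datasets  <- c("discovery", "validation")

#' Required cohort columns
#' @noRd
.required_cols <- function() {
  c("study_id", "dataset", "clinical_response", "PDL1",
    ism_molecules(), "DC_index")
}

#' Construct a patient cohort
#'
#' A cohort is a data frame with one row per patient, carrying the patient's
#' predicted percent-change expression profile (PD-L1, the 14
#' immunosuppressive molecules, the dendritic-cell infiltration index and
#' optionally the 9 chemokines) plus identifying and clinical metadata.
#' `pd_cohort()` validates the frame and stamps the `pd_cohort` class on it;
#' the object remains an ordinary data frame.
#'
#' Reference columns `predicted_response_ref` and `match_ref`, when present,
#' hold previously published predictions. They are metadata used only as a
#' validation oracle and are never consumed by [classify_cohort()].
#'
#' @param x Data frame with columns `study_id`, `dataset` (`discovery` or
#'   `validation`), `clinical_response` (`responder` or `non_responder`),
#'   `PDL1`, the 14 columns named by [ism_molecules()], `DC_index`, and
#'   optionally the 9 columns named by [dc_chemokines()].
#' @param name Optional cohort label.
#' @return The validated data frame with class `pd_cohort`.
#' @export
pd_cohort <- function(x, name = NULL) {
  x <- as.data.frame(x, check.names = FALSE)
  names(x) <- canonical_molecule(names(x))
  validate_cohort(x)
  class(x) <- unique(c("pd_cohort", class(x)))
  attr(x, "cohort_name") <- name
  x
}

#' Validate cohort invariants
#'
#' Checks the schema and value invariants of a cohort data frame: required
#' columns present, numeric profile columns numeric and non-missing, factor
#' fields within their enums, non-empty unique study identifiers, and — when
#' chemokine columns are present — all nine of them.
#'
#' @param x Data frame to check.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_cohort <- function(x) {
  missing <- setdiff(.required_cols(), names(x))
  if (length(missing) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(x$study_id) | is.na(x$study_id))) {
    stop("study_id must be non-empty for every record", call. = FALSE)
  }
  dup <- x$study_id[duplicated(x$study_id)]
  if (length(dup) > 0) {
    stop("duplicate study_id value(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(x$dataset %in% .datasets)) {
    stop("dataset must be one of: ", paste(.datasets, collapse = ", "),
         call. = FALSE)
  }
  if (!all(x$clinical_response %in% .responses)) {
    stop("clinical_response must be one of: ",
         paste(.responses, collapse = ", "), call. = FALSE)
  }
  chemo_present <- intersect(dc_chemokines(), names(x))
  if (length(chemo_present) > 0 &&
      length(chemo_present) < length(dc_chemokines())) {
    stop("partial chemokine panel: missing ",
         paste(setdiff(dc_chemokines(), chemo_present), collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("PDL1", ism_molecules(), "DC_index", chemo_present)
  for (col in num_cols) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- if (is.numeric(v)) which(is.na(v))[1] else 1L
      stop("column ", col, " must be numeric and complete (see row ", bad,
           ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Parse a numeric column tolerant of Unicode minus (U+2212), thin/no-break
# spaces, and stray blanks; errors name the offending row and column.
.parse_pct <- function(v, col) {
  if (is.numeric(v)) return(v)
  cleaned <- gsub("−", "-", as.character(v))
  cleaned <- gsub("[  [:space:]]", "", cleaned)
  out <- suppressWarnings(as.numeric(cleaned))
  bad <- which(is.na(out) & nzchar(cleaned))
  if (length(bad) > 0) {
    stop("unparseable numeric value in column ", col, ", row ", bad[1],
         ": '", v[bad[1]], "'", call. = FALSE)
  }
  out
}

#' Read a patient cohort from a delimited file
#'
#' Reads a CSV or TSV cohort table, normalizes molecule column names to
#' canonical spelling (e.g. `CX3CL` -> `CX3CL1`), parses numeric cells
#' including negative values written with a Unicode minus sign, and
#' validates all cohort invariants.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @param name Optional cohort label; defaults to the file name.
#' @return A [pd_cohort] data frame.
#' @export
#' @examples
#' path <- system.file("extdata", "table1_cohort.csv", package = "pd1tree")
#' cohort <- read_cohort(path)
#' nrow(cohort)
read_cohort <- function(path, dialect = c("csv", "tsv"), name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  names(raw) <- canonical_molecule(names(raw))
  missing <- setdiff(.required_cols(), names(raw))
  if (length(missing) > 0) {
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c("PDL1", ism_molecules(), "DC_index",
                          dc_chemokines()), names(raw))
  for (col in num_cols) raw[[col]] <- .parse_pct(raw[[col]], col)
  pd_cohort(raw, name = if (is.null(name)) basename(path) else name)
}

#' Write a cohort to a delimited file
#'
#' Numeric values are written at full double precision so that
#' `read_cohort(write_cohort(x, f), ...)` reproduces `x` exactly.
#'
#' @param cohort A [pd_cohort] data frame.
#' @param path Destination path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_cohort(cohort)
  sep <- if (dialect == "csv") "," else "\t"
  out <- as.data.frame(cohort, check.names = FALSE)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                           scientific = FALSE)
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write cohort to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  }
  invisible(path)
}

#' The published 29-patient NSCLC cohort
#'
#' Returns the packaged cohort of 29 stage IV NSCLC patients treated with
#' pembrolizumab (13 discovery, 16 validation), with each patient's simulated
#' percent-change expression of PD-L1 and the 14 immunosuppressive molecules,
#' the dendritic-cell infiltration index, the recorded clinical response, and
#' — as reference metadata — the originally published predicted response and
#' match flag. The reference columns serve as the package's validation
#' oracle and are never used by the classifier.
#'
#' @return A [pd_cohort] with 29 rows.
#' @export
#' @examples
#' cohort <- table1_cohort()
#' table(cohort$dataset, cohort$clinical_response)
table1_cohort <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "pd1tree")
  read_cohort(path, "csv", name = "table1")
}

#' Chemokine profile of patient SA97V5
#'
#' The one patient whose individual chemokine percent changes were published
#' alongside the summarized infiltration index: a named vector over the nine
#' canonical chemokines. Useful as a worked example for
#' [dc_infiltration_index()].
#'
#' @return Named numeric vector of length 9.
#' @export
#' @examples
#' dc_infiltration_index(sa97v5_chemokines())
sa97v5_chemokines <- function() {
  path <- system.file("extdata", "sa97v5_chemokines.csv", package = "pd1tree")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$pct, tab$chemokine)[dc_chemokines()]
}

#' @export
print.pd_cohort <- function(x, ...) {
  nm <- attr(x, "cohort_name")
  cat("<pd_cohort", if (!is.null(nm)) paste0("'", nm, "'"), ">",
      nrow(x), "patients (",
      sum(x$dataset == "discovery"), "discovery,",
      sum(x$dataset == "validation"), "validation )\n")
  print(as.data.frame(utils::head(x, 6))[
    , c("study_id", "dataset", "clinical_response", "PDL1", "DC_index")])
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}
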