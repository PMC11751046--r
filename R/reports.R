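#' Canonical spontaneous-report set
#'
#' An `srs_reports` object is a data.frame with one row per spontaneous
#' adverse-drug-reaction (ADR) report and list-columns holding the per-report
#' term sets. It is the common currency of the package: ingestion,
#' standardization and filtering produce it, and both signal detectors consume
#' it.
#'
#' Columns:
#' \describe{
#'   \item{report_id}{character, opaque report identifier}
#'   \item{year}{integer reporting year (NA allowed)}
#'   \item{age}{numeric age in years (NA = missing)}
#'   \item{sex}{one of `"male"`, `"female"`, `"unknown"`}
#'   \item{reporter_category}{free-text reporting-unit category}
#'   \item{diseases}{list of character vectors (deduplicated)}
#'   \item{drugs}{list of character vectors (set semantics, deduplicated)}
#'   \item{aes}{list of character vectors of adverse-event preferred terms}
#'   \item{ae_categories}{list of character vectors parallel to `aes`,
#'     carrying a system-organ-class style grouping (NA where unknown)}
#'   \item{causality}{one of `"certain"`, `"probable"`, `"possible"`,
#'     `"unlikely"`, `"pending"`}
#' }
#'
#' @param report_id character vector of identifiers.
#' @param drugs,aes,diseases lists of character vectors (a single vector is
#'   recycled into a one-report list).
#' @param year,age,sex,reporter_category,causality per-report scalars,
#'   recycled to the number of reports.
#' @param ae_categories optional list of character vectors parallel to `aes`.
#' @return An object of class `srs_reports` (also a data.frame).
#' @examples
#' r <- srs_reports(
#'   report_id = c("a", "b"),
#'   drugs = list(c("Aspirin", "Ticagrelor"), "Nifedipine"),
#'   aes = list("Epistaxis", c("Flushing", "Headache"))
#' )
#' nrow(r)
#' @export
srs_reports <- function(report_id, drugs, aes,
                        diseases = NULL, year = NA_integer_, age = NA_real_,
                        sex = "unknown", reporter_category = NA_character_,
                        causality = "possible", ae_categories = NULL) {
  n <- length(report_id)
  as_set_list <- function(x, nm) {
    if (is.null(x)) return(rep(list(character(0)), n))
    if (!is.list(x)) x <- list(x)
    if (length(x) == 1L && n > 1L) x <- rep(x, n)
    if (length(x) != n) stop(sprintf("'%s' must have one entry per report", nm))
    lapply(x, function(v) unique(trimws(as.character(v[!is.na(v) & nzchar(trimws(v))]))))
  }
  drugs <- as_set_list(drugs, "drugs")
  aes_raw <- if (is.null(aes)) rep(list(character(0)), n) else {
    if (!is.list(aes)) aes <- list(aes)
    if (length(aes) == 1L && n > 1L) aes <- rep(aes, n)
    aes
  }
  if (length(aes_raw) != n) stop("'aes' must have one entry per report")
  if (is.null(ae_categories)) {
    ae_categories <- lapply(aes_raw, function(v) rep(NA_character_, length(v)))
  }
  # dedupe AEs while keeping their category tags aligned
  cleaned <- Map(function(a, cat) {
    a <- trimws(as.character(a))
    keep <- !is.na(a) & nzchar(a)
    a <- a[keep]
    cat <- rep_len(as.character(cat), length(keep))[keep]
    first <- !duplicated(a)
    list(ae = a[first], cat = cat[first])
  }, aes_raw, ae_categories)
  sex <- rep_len(as.character(sex), n)
  sex[is.na(sex) | !sex %in% SEX_LEVELS] <- "unknown"
  causality <- rep_len(as.character(causality), n)
  bad <- !causality %in% CAUSALITY_LEVELS
  if (any(bad)) {
    stop("invalid causality grade(s): ",
         paste(unique(causality[bad]), collapse = ", "))
  }
  out <- data.frame(report_id = as.character(report_id), stringsAsFactors = FALSE)
  out$year <- rep_len(as.integer(year), n)
  out$age <- rep_len(as.numeric(age), n)
  out$sex <- sex
  out$reporter_category <- rep_len(as.character(reporter_category), n)
  out$diseases <- as_set_list(diseases, "diseases")
  out$drugs <- drugs
  out$aes <- lapply(cleaned, `[[`, "ae")
  out$ae_categories <- lapply(cleaned, `[[`, "cat")
  out$causality <- causality
  class(out) <- c("srs_reports", "data.frame")
  out
}

#' @export
print.srs_reports <- function(x, ...) {
  cat(sprintf("<srs_reports> %d reports, %d distinct drugs, %d distinct AE terms\n",
              nrow(x), length(unique(unlist(x$drugs))),
              length(unique(unlist(x$aes)))))
  invisible(x)
}

#' Subset a report set
#'
#' `[` keeps the `srs_reports` class when whole rows are selected.
#' @param x an `srs_reports` object.
#' @param i row index.
#' @param ... further arguments to the data.frame method.
#' @export
#' @keywords internal
`[.srs_reports` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("drugs", "aes") %in% names(out))) {
    class(out) <- c("srs_reports", "data.frame")
  }
  out
}

#' Read spontaneous reports from a delimited text file
#'
#' Reads one report per row from a CSV/TSV file whose list-valued cells
#' (diseases, drugs, adverse events) pack several terms into one cell using an
#' intra-cell delimiter. Column names are resolved through a schema map, so
#' the reader is agnostic to the source system's header language.
#'
#' Missing age or sex are mapped to `NA` / `"unknown"` and retained; dropping
#' incomplete reports is the job of [apply_filters()], not the reader.
#'
#' @param path path to a delimited text file with a header row.
#' @param schema named character vector mapping canonical field names
#'   (`report_id`, `year`, `age`, `sex`, `reporter_category`, `diseases`,
#'   `drugs`, `aes`, `causality`) to column names in the file. Fields absent
#'   from the schema fall back to the canonical name itself; `report_id`,
#'   `drugs`, `aes` and `causality` must be resolvable.
#' @param sep field delimiter of the file (default `","`).
#' @param list_sep intra-cell delimiter separating terms inside a list cell
#'   (default `";"`; the source export format is site-specific).
#' @return An [srs_reports] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,drugs,aes,causality",
#'              "r1,Aspirin;Ticagrelor,Epistaxis,probable"), f)
#' read_reports(f, schema = c(report_id = "id"))
#' @export
read_reports <- function(path, schema = character(), sep = ",", list_sep = ";") {
  if (!file.exists(path)) stop("cannot read report file: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  resolve <- function(field, required = FALSE) {
    col <- if (field %in% names(schema)) unname(schema[[field]]) else field
    if (!col %in% names(raw)) {
      if (required) stop(sprintf("schema error: required column '%s' (field '%s') not found",
                                 col, field))
      return(NULL)
    }
    raw[[col]]
  }
  split_cell <- function(x) {
    lapply(x, function(cell) {
      if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
      unique(trimws(strsplit(cell, list_sep, fixed = TRUE)[[1]]))
    })
  }
  id <- resolve("report_id", required = TRUE)
  drugs <- split_cell(resolve("drugs", required = TRUE))
  aes <- split_cell(resolve("aes", required = TRUE))
  causality <- tolower(trimws(resolve("causality", required = TRUE)))
  if (any(!causality %in% CAUSALITY_LEVELS)) {
    stop("unrecognized causality grade(s): ",
         paste(unique(causality[!causality %in% CAUSALITY_LEVELS]), collapse = ", "))
  }
  year_col <- resolve("year")
  age_col <- resolve("age")
  sex_col <- resolve("sex")
  norm_sex <- function(x) {
    if (is.null(x)) return("unknown")
    x <- tolower(trimws(x))
    x[x %in% c("m", "male")] <- "male"
    x[x %in% c("f", "female")] <- "female"
    x[!x %in% c("male", "female")] <- "unknown"
    x
  }
  dis_col <- resolve("diseases")
  srs_reports(
    report_id = id,
    drugs = drugs,
    aes = aes,
    diseases = if (is.null(dis_col)) NULL else split_cell(dis_col),
    year = if (is.null(year_col)) NA_integer_ else suppressWarnings(as.integer(year_col)),
    age = if (is.null(age_col)) NA_real_ else suppressWarnings(as.numeric(age_col)),
    sex = norm_sex(sex_col),
    reporter_category = resolve("reporter_category") %||% NA_character_,
    causality = causality
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trusted fast constructor: terms already clean, deduplicated and validated
# (used by the synthetic generator, where the catalogs guarantee this)
new_srs_reports <- function(report_id, year, age, sex, reporter_category,
                            diseases, drugs, aes, ae_categories, causality) {
  out <- data.frame(report_id = report_id, stringsAsFactors = FALSE)
  out$year <- year
  out$age <- age
  out$sex <- sex
  out$reporter_category <- reporter_category
  out$diseases <- diseases
  out$drugs <- drugs
  out$aes <- aes
  out$ae_categories <- ae_categories
  out$causality <- causality
  class(out) <- c("srs_reports", "data.frame")
  out
}
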