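#' Cohort inclusion filter specification
#'
#' Encodes the inclusion/exclusion criteria applied to a spontaneous-report
#' database before signal mining: reporting-year window, a disease term set
#' defining the cohort (a report qualifies if it carries at least one of the
#' terms), the admissible causality grades, and which missing-field rules
#' exclude a report.
#'
#' Defaults mirror a common surveillance setup: years 2014-2022, causality
#' restricted to certain/probable/possible, reports lacking drug or AE
#' information dropped, and demographics allowed to be missing (incomplete
#' demographics are excluded from the relevant strata later, not here).
#'
#' @param year_min,year_max inclusive reporting-year window.
#' @param required_disease_terms character vector; `NULL` disables the
#'   disease criterion (the qualifying diagnosis list is deployment-specific
#'   and must be user-supplied).
#' @param allowed_causality subset of
#'   `c("certain","probable","possible","unlikely","pending")`; must be
#'   non-empty.
#' @param drop_missing subset of `c("drug","ae","demographics")`; which
#'   missingness conditions exclude a report. `"demographics"` requires both
#'   non-missing age and known sex.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(year_min = 2014L, year_max = 2022L,
                        required_disease_terms = NULL,
                        allowed_causality = c("certain", "probable", "possible"),
                        drop_missing = c("drug", "ae")) {
  if (length(allowed_causality) == 0) {
    stop("configuration error: allowed_causality must be non-empty")
  }
  allowed_causality <- match.arg(allowed_causality, CAUSALITY_LEVELS,
                                 several.ok = TRUE)
  if (length(drop_missing)) {
    drop_missing <- match.arg(drop_missing, c("drug", "ae", "demographics"),
                              several.ok = TRUE)
  } else {
    drop_missing <- character(0)
  }
  year_min <- as.integer(year_min); year_max <- as.integer(year_max)
  if (year_min > year_max) stop("year_min must not exceed year_max")
  structure(list(
    year_min = year_min, year_max = year_max,
    required_disease_terms = required_disease_terms,
    allowed_causality = allowed_causality,
    drop_missing = drop_missing
  ), class = "filter_spec")
}

#' Apply inclusion filters to a report set
#'
#' Criteria are applied in a fixed order — year, disease, causality,
#' missingness — so the removal log is deterministic and each excluded report
#' is attributed to exactly one criterion (the first it violates). A report
#' with `NA` year fails the year criterion.
#'
#' @param reports an [srs_reports] object (ideally already standardized).
#' @param spec a [filter_spec].
#' @param verbose log per-criterion removal counts.
#' @return A list with `reports` (the retained [srs_reports]) and `log`, a
#'   data.frame with columns `criterion`, `removed`, `remaining` (one row per
#'   criterion in application order).
#' @export
apply_filters <- function(reports, spec = filter_spec(), verbose = TRUE) {
  stopifnot(inherits(reports, "srs_reports"), inherits(spec, "filter_spec"))
  steps <- list(
    year = function(r) !is.na(r$year) & r$year >= spec$year_min & r$year <= spec$year_max,
    disease = function(r) {
      if (is.null(spec$required_disease_terms)) return(rep(TRUE, nrow(r)))
      vapply(r$diseases, function(d) any(d %in% spec$required_disease_terms), logical(1))
    },
    causality = function(r) r$causality %in% spec$allowed_causality,
    missingness = function(r) {
      keep <- rep(TRUE, nrow(r))
      if ("drug" %in% spec$drop_missing) {
        keep <- keep & lengths(r$drugs) > 0
      }
      if ("ae" %in% spec$drop_missing) {
        keep <- keep & lengths(r$aes) > 0
      }
      if ("demographics" %in% spec$drop_missing) {
        keep <- keep & !is.na(r$age) & r$sex != "unknown"
      }
      keep
    }
  )
  log <- data.frame(criterion = names(steps), removed = 0L, remaining = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(steps)) {
    keep <- steps[[i]](reports)
    log$removed[i] <- sum(!keep)
    reports <- reports[keep, , drop = FALSE]
    log$remaining[i] <- nrow(reports)
    if (verbose && log$removed[i] > 0) {
      message(sprintf("filter [%s]: removed %d, %d remaining",
                      log$criterion[i], log$removed[i], log$remaining[i]))
    }
  }
  rownames(reports) <- NULL
  list(reports = reports, log = log)
}

#' Subset reports to an analysis stratum
#'
#' Strata are defined by sex and/or an age predicate. Reports with unknown
#' sex are excluded from both sex strata; reports with missing age from both
#' age strata; the overall stratum keeps everything. Age 60 belongs to the
#' "60 and above" stratum.
#'
#' @param label stratum name (used in outputs).
#' @param sex `NULL`, `"male"` or `"female"`.
#' @param age `NULL`, `"<60"` or `">=60"`.
#' @return A `stratum_spec` object.
#' @export
stratum_spec <- function(label, sex = NULL, age = NULL) {
  if (!is.null(sex)) sex <- match.arg(sex, c("male", "female"))
  if (!is.null(age)) age <- match.arg(age, c("<60", ">=60"))
  structure(list(label = label, sex = sex, age = age), class = "stratum_spec")
}

#' The five standard analysis strata
#'
#' Overall, male, female, under 60, and 60-and-above.
#' @return A named list of [stratum_spec] objects.
#' @export
standard_strata <- function() {
  list(
    overall = stratum_spec("overall"),
    male = stratum_spec("male", sex = "male"),
    female = stratum_spec("female", sex = "female"),
    age_lt60 = stratum_spec("age_lt60", age = "<60"),
    age_ge60 = stratum_spec("age_ge60", age = ">=60")
  )
}

#' @rdname stratum_spec
#' @param reports an [srs_reports] object.
#' @param stratum a [stratum_spec].
#' @export
subset_stratum <- function(reports, stratum) {
  stopifnot(inherits(reports, "srs_reports"), inherits(stratum, "stratum_spec"))
  keep <- rep(TRUE, nrow(reports))
  if (!is.null(stratum$sex)) keep <- keep & reports$sex == stratum$sex
  if (!is.null(stratum$age)) {
    keep <- keep & !is.na(reports$age) &
      (if (stratum$age == "<60") reports$age < 60 else reports$age >= 60)
  }
  out <- reports[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
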