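#' Term dictionary for drug- and AE-name standardization
#'
#' Spontaneous reports carry hand-entered drug names and adverse-event
#' descriptions. Real deployments standardize drugs against a regulatory
#' product registry and AEs against MedDRA preferred terms; neither vocabulary
#' can be shipped, so dictionaries are plain user-supplied lookup tables:
#' raw term, standard term, and (for AEs) an optional category playing the
#' role of a system-organ class.
#'
#' Raw terms are normalized before lookup — lowercase, trimmed, internal
#' whitespace collapsed — so that "Aspirin ", "aspirin" and "ASPIRIN" all hit
#' the same entry. Keys must be unique after normalization.
#'
#' @param raw character vector of raw terms (lookup keys).
#' @param standard character vector of standard replacement terms.
#' @param category optional character vector of term categories (e.g. a
#'   system-organ-class analogue for AEs).
#' @param unmapped one of `"keep_raw"` (pass unmapped terms through
#'   unchanged), `"drop"` (remove them), `"error"` (fail listing them).
#' @return A `term_dictionary` object.
#' @seealso [standardize_reports()], [read_term_dictionary()]
#' @export
term_dictionary <- function(raw, standard, category = NULL,
                            unmapped = c("keep_raw", "drop", "error")) {
  unmapped <- match.arg(unmapped)
  key <- normalize_term(raw)
  if (anyDuplicated(key)) {
    stop("duplicate dictionary keys after normalization: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  if (length(standard) != length(key)) stop("raw and standard must have equal length")
  if (!is.null(category) && length(category) != length(key)) {
    stop("category must match the number of entries")
  }
  structure(list(
    standard = stats::setNames(as.character(standard), key),
    category = if (is.null(category)) NULL else stats::setNames(as.character(category), key),
    unmapped = unmapped
  ), class = "term_dictionary")
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary> %d entries, unmapped policy '%s'%s\n",
              length(x$standard), x$unmapped,
              if (is.null(x$category)) "" else ", with categories"))
  invisible(x)
}

#' Read a term dictionary from a delimited file
#'
#' Expects two or three columns: raw term, standard term, optional category.
#' A header row is assumed.
#'
#' @inheritParams term_dictionary
#' @param path path to the delimited file.
#' @param sep field delimiter.
#' @return A [term_dictionary].
#' @export
read_term_dictionary <- function(path, sep = ",",
                                 unmapped = c("keep_raw", "drop", "error")) {
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(tab) < 2) stop("dictionary file needs at least two columns (raw, standard)")
  term_dictionary(tab[[1]], tab[[2]],
                  category = if (ncol(tab) >= 3) tab[[3]] else NULL,
                  unmapped = match.arg(unmapped))
}

normalize_term <- function(x) {
  gsub("\\s+", " ", trimws(tolower(as.character(x))))
}

lookup_terms <- function(terms, dict, what) {
  key <- normalize_term(terms)
  hit <- key %in% names(dict$standard)
  out <- terms
  out[hit] <- unname(dict$standard[key[hit]])
  cat_out <- rep(NA_character_, length(terms))
  if (!is.null(dict$category)) cat_out[hit] <- unname(dict$category[key[hit]])
  list(term = out, category = cat_out, unmapped = terms[!hit])
}

#' Standardize drug and AE terms across a report set
#'
#' Replaces every drug and adverse-event term by its standard form from the
#' supplied dictionaries; AE terms additionally pick up the dictionary's
#' category tag (a system-organ-class analogue). Unmapped terms are handled
#' according to each dictionary's `unmapped` policy. The operation is
#' deterministic and acts report-wise, so report order is irrelevant.
#'
#' @param reports an [srs_reports] object.
#' @param drug_dict,ae_dict [term_dictionary] objects; `NULL` leaves the
#'   corresponding terms untouched.
#' @param verbose log a per-dictionary count of unmapped terms (each distinct
#'   term reported once).
#' @return The standardized [srs_reports]; terms mapping onto the same
#'   standard name collapse to one (set semantics).
#' @export
standardize_reports <- function(reports, drug_dict = NULL, ae_dict = NULL,
                                verbose = TRUE) {
  stopifnot(inherits(reports, "srs_reports"))
  unmapped_drugs <- character(0)
  unmapped_aes <- character(0)
  if (!is.null(drug_dict)) {
    stopifnot(inherits(drug_dict, "term_dictionary"))
    mapped <- lapply(reports$drugs, function(d) {
      res <- lookup_terms(d, drug_dict, "drug")
      unmapped_drugs <<- c(unmapped_drugs, res$unmapped)
      term <- res$term
      if (drug_dict$unmapped == "drop") term <- term[!term %in% res$unmapped]
      unique(term)
    })
    if (drug_dict$unmapped == "error" && length(unmapped_drugs)) {
      stop("unmapped drug terms: ", paste(sort(unique(unmapped_drugs)), collapse = ", "))
    }
    reports$drugs <- mapped
  }
  if (!is.null(ae_dict)) {
    stopifnot(inherits(ae_dict, "term_dictionary"))
    mapped <- Map(function(a, old_cat) {
      res <- lookup_terms(a, ae_dict, "ae")
      unmapped_aes <<- c(unmapped_aes, res$unmapped)
      term <- res$term
      cat_new <- ifelse(is.na(res$category), old_cat, res$category)
      if (ae_dict$unmapped == "drop") {
        keep <- !term %in% res$unmapped
        term <- term[keep]; cat_new <- cat_new[keep]
      }
      first <- !duplicated(term)
      list(ae = term[first], cat = cat_new[first])
    }, reports$aes, reports$ae_categories)
    if (ae_dict$unmapped == "error" && length(unmapped_aes)) {
      stop("unmapped AE terms: ", paste(sort(unique(unmapped_aes)), collapse = ", "))
    }
    reports$aes <- lapply(mapped, `[[`, "ae")
    reports$ae_categories <- lapply(mapped, `[[`, "cat")
  }
  if (verbose) {
    if (length(unmapped_drugs)) {
      message(sprintf("standardize: %d distinct drug term(s) unmapped (%s policy)",
                      length(unique(unmapped_drugs)),
                      drug_dict$unmapped))
    }
    if (length(unmapped_aes)) {
      message(sprintf("standardize: %d distinct AE term(s) unmapped (%s policy)",
                      length(unique(unmapped_aes)),
                      ae_dict$unmapped))
    }
  }
  reports
}
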