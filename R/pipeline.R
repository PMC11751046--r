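#' Two-detector DDI signal detection on one analysis stratum
#'
#' Runs the full screen on a (possibly stratified) report set:
#' candidate (drug1, drug2, AE) triples are enumerated at `min_n111`, one 4x2
#' contingency table is built per triple, and both detectors are evaluated on
#' that same table — so the two detectors always agree on `n111`. The rule
#' detector applies the lift/conviction/count thresholds and (optionally)
#' redundancy pruning against single-drug rules; the Omega detector requires
#' `omega025 > 0`. A triple is a signal only if it passes both.
#'
#' No multiple-testing adjustment is applied; the Omega lower bound and the
#' two-detector intersection are the conservatism mechanisms.
#'
#' @param reports an [srs_reports] object (already filtered/standardized).
#' @param thresholds a [rule_thresholds] object; its `min_n111` also drives
#'   candidate enumeration.
#' @param omega_model expectation model for `E111`, see
#'   [expected_count_e111()].
#' @param stratum optional [stratum_spec]; `NULL` means the set as given.
#' @param prune_redundant apply [remove_redundant_rules()] to the rule
#'   detector (default `TRUE`).
#' @return A `ddi_signals` object: list with
#'   \describe{
#'     \item{signals}{data.frame of intersection signals sorted by `omega025`
#'       descending, with both detectors' metrics.}
#'     \item{rules}{full per-candidate rule metrics with `rule_pass`,
#'       `redundant`, `removal_reason`.}
#'     \item{omega}{full per-candidate Omega results.}
#'     \item{candidates, n_reports, stratum, thresholds, omega_model}{run
#'       metadata.}
#'   }
#' @examples
#' r <- example_reports()
#' detect_signals(r, rule_thresholds(min_n111 = 1))
#' @export
detect_signals <- function(reports, thresholds = rule_thresholds(),
                           omega_model = c("noren_excess", "independence"),
                           stratum = NULL, prune_redundant = TRUE) {
  stopifnot(inherits(reports, "srs_reports"))
  omega_model <- match.arg(omega_model)
  label <- "overall"
  if (!is.null(stratum)) {
    reports <- subset_stratum(reports, stratum)
    label <- stratum$label
  }
  if (nrow(reports) == 0) {
    warning("empty stratum '", label, "': no reports to analyse")
    empty <- data.frame()
    return(structure(list(signals = empty, rules = empty, omega = empty,
                          candidates = empty, n_reports = 0L, stratum = label,
                          thresholds = thresholds, omega_model = omega_model),
                     class = "ddi_signals"))
  }
  candidates <- enumerate_candidates(reports, min_n111 = thresholds$min_n111)
  idx <- report_index(reports)
  if (nrow(candidates)) {
    metrics <- lapply(seq_len(nrow(candidates)), function(i) {
      tab <- as_ddi_table(cells_from_index(idx, candidates$drug1[i],
                                           candidates$drug2[i],
                                           candidates$ae[i]))
      m <- rule_metrics(tab)
      m$e111 <- expected_count_e111(tab, omega_model)
      m
    })
    metrics <- do.call(rbind, metrics)
    rules <- cbind(candidates[, c("drug1", "drug2", "ae")],
                   metrics[, c("n111", "support", "support_pair", "support_ae",
                               "confidence", "lift", "conviction")])
    rules <- apply_rule_thresholds(rules, thresholds)
    if (prune_redundant) {
      rules <- remove_redundant_rules(rules, reports)
      rules$rule_pass <- rules$rule_pass & !rules$redundant
    } else {
      rules$redundant <- FALSE
      rules$removal_reason <- NA_character_
    }
    omega <- cbind(candidates[, c("drug1", "drug2", "ae")],
                   data.frame(n111 = metrics$n111, e111 = metrics$e111))
    omega$omega <- omega_statistic(omega$n111, omega$e111)
    omega$omega025 <- suppressMessages(omega_lower_bound(omega$omega, omega$n111))
    omega$model <- omega_model
    omega$omega_signal <- !is.na(omega$omega025) & omega$omega025 > 0
    omega <- omega[order(-omega$omega025, omega$drug1, omega$drug2, omega$ae), ]
    rownames(omega) <- NULL
    both <- merge(rules[rules$rule_pass, , drop = FALSE],
                  omega[omega$omega_signal,
                        c("drug1", "drug2", "ae", "e111", "omega", "omega025")],
                  by = c("drug1", "drug2", "ae"))
    both <- both[order(-both$omega025, both$drug1, both$drug2, both$ae), ,
                 drop = FALSE]
    rownames(both) <- NULL
  } else {
    rules <- cbind(candidates, data.frame(rule_pass = logical(0)))
    omega <- cbind(candidates, data.frame(omega_signal = logical(0)))
    both <- candidates
  }
  structure(list(signals = both, rules = rules, omega = omega,
                 candidates = candidates, n_reports = nrow(reports),
                 stratum = label, thresholds = thresholds,
                 omega_model = omega_model),
            class = "ddi_signals")
}

#' @export
print.ddi_signals <- function(x, ...) {
  cat(sprintf("<ddi_signals> stratum '%s': %d reports, %d candidates, %d rule signals, %d omega signals, %d joint signals\n",
              x$stratum, x$n_reports, nrow(x$candidates),
              if (nrow(x$rules)) sum(x$rules$rule_pass) else 0L,
              if (nrow(x$omega)) sum(x$omega$omega_signal) else 0L,
              nrow(x$signals)))
  if (nrow(x$signals)) print(format_signal_table(x))
  invisible(x)
}

#' Stratified signal detection
#'
#' Runs [detect_signals()] independently on the five standard strata:
#' overall, male, female, under 60, 60 and above. Candidate sets and
#' contingency tables are recomputed within each stratum, so a
#' stratum-specific effect diluted in the pooled data can still surface in
#' its stratum. Unknown-sex reports are excluded from both sex strata only;
#' missing-age reports from both age strata only.
#'
#' @inheritParams detect_signals
#' @param strata list of [stratum_spec] objects (default [standard_strata()]).
#' @return Named list of `ddi_signals`, one per stratum.
#' @export
stratified_signals <- function(reports, thresholds = rule_thresholds(),
                               omega_model = c("noren_excess", "independence"),
                               strata = standard_strata(),
                               prune_redundant = TRUE) {
  omega_model <- match.arg(omega_model)
  out <- lapply(strata, function(s) {
    detect_signals(reports, thresholds = thresholds, omega_model = omega_model,
                   stratum = s, prune_redundant = prune_redundant)
  })
  names(out) <- vapply(strata, `[[`, character(1), "label")
  out
}

#' Human-readable signal table
#'
#' Formats joint signals in the conventional layout of published DDI signal
#' tables: combination, ADR, n111, Omega lower bound, lift, conviction,
#' confidence, rounded to 2 decimals (internal values keep full precision).
#'
#' @param x a `ddi_signals` object.
#' @return A data.frame ready for printing/export.
#' @export
format_signal_table <- function(x) {
  stopifnot(inherits(x, "ddi_signals"))
  s <- x$signals
  if (!nrow(s)) {
    return(data.frame(combination = character(0), adr = character(0),
                      n111 = integer(0), omega025 = numeric(0),
                      lift = numeric(0), conviction = numeric(0),
                      confidence = numeric(0)))
  }
  data.frame(
    combination = paste(s$drug1, "and", s$drug2),
    adr = s$ae,
    n111 = s$n111,
    omega025 = round(s$omega025, 2),
    lift = round(s$lift, 2),
    conviction = round(s$conviction, 2),
    confidence = round(s$confidence, 2),
    stringsAsFactors = FALSE
  )
}

#' Descriptive summary of a report database
#'
#' Summaries in the shape conventional for spontaneous-report studies. The
#' descriptive counting unit is the drug-AE *combination*: one AE occurrence
#' on one report, tagged with that report's full drug set. (Signal inference
#' elsewhere counts reports, not combinations.)
#'
#' @param reports an [srs_reports] object.
#' @param top_n rows to keep in the frequency tables.
#' @return A list:
#'   \describe{
#'     \item{n_reports, n_combinations}{totals.}
#'     \item{drug_freq}{combinations involving each drug, with percentage of
#'       all combinations.}
#'     \item{ae_freq}{combinations per AE term with its category.}
#'     \item{pair_ae_freq}{co-occurrence counts for drug pair x AE (reports
#'       with >= 2 drugs).}
#'     \item{drug_count_breakdown}{combinations involving 1, 2, >= 3 drugs.}
#'     \item{sex_breakdown, age_breakdown}{report counts by demographics
#'       (age split at 60; 60 belongs to the upper group).}
#'   }
#' @export
descriptive_summary <- function(reports, top_n = 10L) {
  stopifnot(inherits(reports, "srs_reports"))
  n_drugs_per_report <- lengths(reports$drugs)
  n_aes_per_report <- lengths(reports$aes)
  n_comb <- sum(n_aes_per_report)

  # drug frequency: combinations whose report lists the drug
  drug_freq <- data.table::data.table(
    drug = unlist(rep(reports$drugs, times = n_aes_per_report), use.names = FALSE)
  )[, .(frequency = .N), by = drug]
  data.table::setorderv(drug_freq, c("frequency", "drug"), order = c(-1L, 1L))
  drug_freq[, percentage := round(100 * frequency / n_comb, 2)]

  ae_cat <- data.table::data.table(
    ae = unlist(reports$aes, use.names = FALSE),
    category = unlist(reports$ae_categories, use.names = FALSE)
  )
  ae_freq <- ae_cat[, .(frequency = .N,
                        category = category[which(!is.na(category))[1]]),
                    by = ae]
  data.table::setorderv(ae_freq, c("frequency", "ae"), order = c(-1L, 1L))
  ae_freq[, percentage := round(100 * frequency / n_comb, 2)]

  pair_ae <- enumerate_candidates(reports, min_n111 = 1L)
  names(pair_ae)[names(pair_ae) == "n111"] <- "frequency"

  k <- rep(n_drugs_per_report, times = n_aes_per_report)
  drug_count_breakdown <- data.frame(
    drugs_involved = c("1", "2", ">=3"),
    combinations = c(sum(k == 1), sum(k == 2), sum(k >= 3))
  )
  drug_count_breakdown$percentage <-
    round(100 * drug_count_breakdown$combinations / max(n_comb, 1L), 1)

  sex_breakdown <- as.data.frame(table(sex = reports$sex),
                                 stringsAsFactors = FALSE)
  names(sex_breakdown)[2] <- "reports"
  age_grp <- ifelse(is.na(reports$age), "unknown",
                    ifelse(reports$age >= 60, ">=60", "<60"))
  age_breakdown <- as.data.frame(table(age_group = age_grp),
                                 stringsAsFactors = FALSE)
  names(age_breakdown)[2] <- "reports"

  list(
    n_reports = nrow(reports),
    n_combinations = n_comb,
    drug_freq = utils::head(as.data.frame(drug_freq), top_n),
    ae_freq = utils::head(as.data.frame(ae_freq)[, c("ae", "frequency",
                                                     "percentage", "category")],
                          top_n),
    pair_ae_freq = utils::head(pair_ae, top_n),
    drug_count_breakdown = drug_count_breakdown,
    sex_breakdown = sex_breakdown,
    age_breakdown = age_breakdown
  )
}

#' Small built-in example report set
#'
#' Thirty hand-written reports with one strong drug-pair/AE association,
#' used in documentation examples and as an end-to-end oracle fixture.
#' @return An [srs_reports] object.
#' @export
example_reports <- function() {
  pair_reports <- srs_reports(
    report_id = sprintf("pair%02d", 1:6),
    drugs = rep(list(c("Amlodipine", "Atorvastatin")), 6),
    aes = c(rep(list("Jaundice"), 4), list("Headache"), list("Rash")),
    year = 2018L, age = c(70, 55, 61, 48, 66, 72),
    sex = c("male", "female", "male", "female", "male", "female")
  )
  single_reports <- srs_reports(
    report_id = sprintf("sgl%02d", 1:18),
    drugs = rep(list("Amlodipine", "Atorvastatin", "Nifedipine"), each = 6),
    aes = rep(list("Rash", "Headache", "Flushing"), times = 6),
    year = 2019L, age = rep(c(45, 76, 59), 6),
    sex = rep(c("male", "female"), 9)
  )
  other_reports <- srs_reports(
    report_id = sprintf("oth%02d", 1:6),
    drugs = rep(list(c("Aspirin", "Clopidogrel")), 6),
    aes = list("Rash", "Headache", "Flushing", "Rash", "Headache", "Flushing"),
    year = 2020L, age = rep(c(63, 50), 3),
    sex = rep(c("female", "male"), 3)
  )
  out <- rbind(pair_reports, single_reports, other_reports)
  class(out) <- c("srs_reports", "data.frame")
  out
}
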