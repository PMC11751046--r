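#' Association-rule metrics for a drug-pair rule
#'
#' For the rule drug1 & drug2 -> AE, computed over an analysis set of `T`
#' reports (the grand total of the contingency table):
#' \deqn{support = n_{111}/T}
#' \deqn{confidence = support / support_{pair}}
#' \deqn{lift = confidence / support_{AE}}
#' \deqn{conviction = (1 - support_{AE}) / (1 - confidence)}
#' where `support_pair` is the fraction of reports listing both drugs and
#' `support_ae` the fraction listing the AE.
#'
#' Degenerate cases never raise: `support_pair = 0` gives `NA` confidence
#' (no rule to evaluate); `support_ae = 0` gives `NA` lift (the AE never
#' occurs, impossible for enumerated candidates but guarded); `confidence = 1`
#' with `support_ae < 1` gives `conviction = Inf`, which passes any finite
#' threshold.
#'
#' @param table a `ddi_table` from [build_contingency()] or [ddi_table()].
#' @return A one-row data.frame: `n111`, `support`, `support_pair`,
#'   `support_ae`, `confidence`, `lift`, `conviction`.
#' @examples
#' tab <- ddi_table(12, 16, 5, 500, 4, 400, 2, 5000)
#' rule_metrics(tab)
#' @export
rule_metrics <- function(table) {
  stopifnot(inherits(table, "ddi_table"))
  total <- table[["nppp"]]
  if (total <= 0) stop("empty analysis set: contingency total is zero")
  support <- table[["n111"]] / total
  support_pair <- table[["n11p"]] / total
  support_ae <- table[["npp1"]] / total
  confidence <- if (support_pair > 0) support / support_pair else NA_real_
  lift <- if (!is.na(confidence) && support_ae > 0) confidence / support_ae else NA_real_
  conviction <- conviction_from_marginals(confidence, support_ae)
  data.frame(n111 = as.integer(table[["n111"]]), support = support,
             support_pair = support_pair, support_ae = support_ae,
             confidence = confidence, lift = lift, conviction = conviction)
}

conviction_from_marginals <- function(confidence, support_ae) {
  if (is.na(confidence) || is.na(support_ae)) return(NA_real_)
  if (confidence >= 1) {
    if (support_ae < 1) return(Inf)
    return(NA_real_)  # confidence = support_ae = 1: 0/0, undefined
  }
  (1 - support_ae) / (1 - confidence)
}

#' Conviction recovered from printed confidence and lift
#'
#' Published signal tables typically print confidence, lift and conviction
#' but not the AE's marginal support. Since lift = confidence / support_AE,
#' the marginal is recoverable as confidence/lift, and conviction follows as
#' (1 - confidence/lift) / (1 - confidence). This makes printed rows
#' internally checkable without the source database.
#'
#' @param confidence rule confidence in (0, 1].
#' @param lift rule lift (> 0).
#' @return Conviction (vectorized; `Inf` where confidence = 1).
#' @examples
#' conviction_from_confidence_lift(0.43, 1116.69)  # ~1.75
#' @export
conviction_from_confidence_lift <- function(confidence, lift) {
  stopifnot(all(lift > 0), all(confidence >= 0), all(confidence <= 1))
  support_ae <- confidence / lift
  ifelse(confidence < 1, (1 - support_ae) / (1 - confidence),
         ifelse(support_ae < 1, Inf, NA_real_))
}

#' Detection thresholds for association rules
#'
#' The screening criteria are strict `lift > min_lift`, strict
#' `conviction > min_conviction`, and inclusive `n111 >= min_n111`; the
#' conventional values are lift > 1, conviction > 1, N >= 3.
#'
#' @param min_lift exclusive lift threshold (default 1).
#' @param min_conviction exclusive conviction threshold (default 1).
#' @param min_n111 inclusive co-report count threshold (default 3).
#' @return A `rule_thresholds` object.
#' @export
rule_thresholds <- function(min_lift = 1, min_conviction = 1, min_n111 = 3L) {
  stopifnot(min_lift > 0, min_conviction > 0, min_n111 >= 1)
  structure(list(min_lift = min_lift, min_conviction = min_conviction,
                 min_n111 = as.integer(min_n111)),
            class = "rule_thresholds")
}

#' Apply rule thresholds to computed metrics
#'
#' @param metrics a data.frame containing at least `n111`, `lift`,
#'   `conviction` (typically the candidate table with [rule_metrics()]
#'   columns bound on).
#' @param thresholds a [rule_thresholds] object.
#' @return `metrics` with a logical column `rule_pass`; rows with `NA` lift
#'   or conviction never pass.
#' @export
apply_rule_thresholds <- function(metrics, thresholds = rule_thresholds()) {
  stopifnot(inherits(thresholds, "rule_thresholds"))
  pass <- !is.na(metrics$lift) & !is.na(metrics$conviction) &
    metrics$lift > thresholds$min_lift &
    metrics$conviction > thresholds$min_conviction &
    metrics$n111 >= thresholds$min_n111
  metrics$rule_pass <- pass
  metrics
}

#' Confidence of single-drug rules drug -> AE
#'
#' For every (drug, AE) combination present in the report set, the fraction
#' of reports listing the drug that also list the AE. Used to prune pair
#' rules explainable by one constituent drug alone.
#'
#' @param reports an [srs_reports] object.
#' @return A data.frame `drug`, `ae`, `n_drug`, `n_drug_ae`, `confidence`.
#' @export
single_drug_confidence <- function(reports) {
  stopifnot(inherits(reports, "srs_reports"))
  n <- nrow(reports)
  dt_drug <- data.table::data.table(
    rid = rep.int(seq_len(n), lengths(reports$drugs)),
    drug = unlist(reports$drugs, use.names = FALSE)
  )
  dt_ae <- data.table::data.table(
    rid = rep.int(seq_len(n), lengths(reports$aes)),
    ae = unlist(reports$aes, use.names = FALSE)
  )
  if (!nrow(dt_drug) || !nrow(dt_ae)) {
    return(data.frame(drug = character(0), ae = character(0),
                      n_drug = integer(0), n_drug_ae = integer(0),
                      confidence = numeric(0)))
  }
  per_drug <- dt_drug[, .(n_drug = .N), by = drug]
  joint <- merge(dt_drug, dt_ae, by = "rid", allow.cartesian = TRUE)
  joint <- joint[, .(n_drug_ae = .N), by = .(drug, ae)]
  out <- merge(joint, per_drug, by = "drug")
  out[, confidence := n_drug_ae / n_drug]
  data.table::setorderv(out, c("drug", "ae"))
  as.data.frame(out[, .(drug, ae, n_drug, n_drug_ae, confidence)])
}

#' Remove redundant pair rules
#'
#' A pair rule (drug1, drug2) -> AE is redundant when either constituent
#' single-drug rule for the same AE achieves confidence greater than or equal
#' to the pair rule's confidence: the pair adds no predictive value over one
#' drug alone, so the apparent association is attributed to that drug. Pairs
#' are already in canonical order, so duplicate orderings cannot occur.
#' Every removal is annotated with the dominating drug for audit.
#'
#' @param rules a data.frame of passing rules with columns `drug1`, `drug2`,
#'   `ae`, `confidence`.
#' @param single either the output of [single_drug_confidence()] or an
#'   [srs_reports] object from which it is computed (use the same report set
#'   that produced the rules).
#' @return `rules` with columns `redundant` (logical) and `removal_reason`
#'   (`NA` for retained rules).
#' @export
remove_redundant_rules <- function(rules, single) {
  if (inherits(single, "srs_reports")) single <- single_drug_confidence(single)
  if (!nrow(rules)) {
    rules$redundant <- logical(0)
    rules$removal_reason <- character(0)
    return(rules)
  }
  key <- function(d, a) paste(d, a, sep = "\r")
  conf_lookup <- stats::setNames(single$confidence, key(single$drug, single$ae))
  conf1 <- conf_lookup[key(rules$drug1, rules$ae)]
  conf2 <- conf_lookup[key(rules$drug2, rules$ae)]
  conf1[is.na(conf1)] <- 0
  conf2[is.na(conf2)] <- 0
  dom1 <- conf1 >= rules$confidence
  dom2 <- conf2 >= rules$confidence
  rules$redundant <- dom1 | dom2
  rules$removal_reason <- ifelse(
    dom1 & dom2, paste0("dominated by ", rules$drug1, " and ", rules$drug2),
    ifelse(dom1, paste0("dominated by ", rules$drug1),
           ifelse(dom2, paste0("dominated by ", rules$drug2), NA_character_)))
  rules
}
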