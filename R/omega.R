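#' Expected both-drug target-AE count under no interaction
#'
#' `E111` is the number of reports listing both drugs and the target AE that
#' would be expected if the two drugs did not interact. Two models:
#'
#' \describe{
#'   \item{`"noren_excess"` (default)}{The excess-risk no-interaction model
#'     used with the shrinkage measure in DDI surveillance. With observed AE
#'     risks in the three unexposed-to-both rows,
#'     `f101 = n101/n10+` (only drug1), `f011 = n011/n01+` (only drug2),
#'     `f001 = n001/n00+` (neither), the projected risk `g111` among
#'     both-exposed reports solves
#'     \deqn{1/(1-g_{111}) = 1/(1-f_{101}) + 1/(1-f_{011}) - 1/(1-f_{001})}
#'     and `E111 = n11+ * g111`. `g111` is clamped into the unit interval; if any of the
#'     three stratum margins is zero the independence value is substituted.}
#'   \item{`"independence"`}{`E111 = n11+ * (n++1 / n+++)`: both-exposed
#'     reports carry the AE at the overall marginal rate.}
#' }
#'
#' The excess-risk model is the more conservative of the two for interaction
#' detection when each single drug already elevates the AE risk, because the
#' single-drug excesses are absorbed into the expectation.
#'
#' @param table a `ddi_table`.
#' @param model `"noren_excess"` or `"independence"`.
#' @return The non-negative expected count (scalar).
#' @examples
#' # f101 = f011 = 0.5, f001 = 0: 1/(1-g) = 2 + 2 - 1 = 3, g = 2/3
#' tab <- ddi_table(0, 30, 10, 10, 10, 10, 0, 40)
#' expected_count_e111(tab)  # 30 * 2/3 = 20
#' @export
expected_count_e111 <- function(table, model = c("noren_excess", "independence")) {
  stopifnot(inherits(table, "ddi_table"))
  model <- match.arg(model)
  if (table[["nppp"]] <= 0) stop("empty analysis set: all margins are zero")
  n11p <- table[["n11p"]]
  e_indep <- n11p * table[["npp1"]] / table[["nppp"]]
  if (model == "independence") return(e_indep)
  n10p <- table[["n10p"]]; n01p <- table[["n01p"]]; n00p <- table[["n00p"]]
  if (n10p == 0 || n01p == 0 || n00p == 0) return(e_indep)
  f101 <- table[["n101"]] / n10p
  f011 <- table[["n011"]] / n01p
  f001 <- table[["n001"]] / n00p
  if (f101 >= 1 || f011 >= 1) return(n11p)  # projected risk saturates at 1
  h <- 1 / (1 - f101) + 1 / (1 - f011) - 1 / (1 - f001)
  g111 <- 1 - 1 / h
  g111 <- min(max(g111, 0), 1)
  n11p * g111
}

#' Omega shrinkage statistic
#'
#' The shrinkage-regularized log ratio of observed to expected both-drug
#' target-AE report counts:
#' \deqn{\Omega = \log_2 \frac{n_{111} + 0.5}{E_{111} + 0.5}}
#' The +0.5 terms pull the statistic toward zero when counts are small, which
#' is what makes the measure conservative for rare combinations.
#'
#' @param n111 observed count (non-negative).
#' @param e111 expected count under no interaction (non-negative).
#' @return Omega (vectorized).
#' @examples
#' omega_statistic(0, 0)        # exactly 0
#' omega_statistic(7, 0.4375)   # (7.5)/(0.9375) = 8, so exactly 3
#' @export
omega_statistic <- function(n111, e111) {
  if (any(n111 < 0) || any(e111 < 0)) stop("counts must be non-negative")
  log2((n111 + 0.5) / (e111 + 0.5))
}

# 97.5% standard-normal quantile, frozen for bit-reproducibility
Z_975 <- 1.959964

#' Lower 2.5% credibility bound of Omega
#'
#' \deqn{\Omega_{0.025} = \Omega - \frac{\phi(0.975)}{\ln 2 \cdot \sqrt{n_{111}}}}
#' with the normal quantile fixed at 1.959964. The 1/sqrt(n111) standard
#' error on the log2 scale makes the bound demanding at small counts; a
#' signal is flagged when the bound is strictly positive. Undefined at
#' `n111 = 0` (returns `NA`, never a signal).
#'
#' @param omega the Omega statistic.
#' @param n111 observed count; must be >= 1 for a defined bound.
#' @return The lower bound (vectorized; `NA` where `n111 = 0`).
#' @export
omega_lower_bound <- function(omega, n111) {
  out <- rep(NA_real_, length(omega))
  ok <- n111 >= 1
  out[ok] <- omega[ok] - Z_975 / (log(2) * sqrt(n111[ok]))
  if (any(!ok)) message("omega_lower_bound: undefined at n111 = 0; no signal")
  out
}

#' Scan candidate triples with the Omega shrinkage measure
#'
#' Builds the 4x2 contingency table for every candidate and computes `E111`,
#' Omega and its lower bound. A triple is an Omega signal when
#' `omega025 > 0` (strict).
#'
#' @param reports an [srs_reports] object.
#' @param candidates a data.frame from [enumerate_candidates()].
#' @param model expectation model, see [expected_count_e111()].
#' @return A data.frame with the triple columns plus `n111`, `e111`, `omega`,
#'   `omega025`, `model`, `omega_signal`, sorted by `omega025` descending
#'   (higher bound = stronger association).
#' @export
scan_omega <- function(reports, candidates,
                       model = c("noren_excess", "independence")) {
  model <- match.arg(model)
  if (!nrow(candidates)) {
    return(cbind(candidates[, c("drug1", "drug2", "ae")],
                 data.frame(n111 = integer(0), e111 = numeric(0),
                            omega = numeric(0), omega025 = numeric(0),
                            model = character(0), omega_signal = logical(0))))
  }
  idx <- report_index(reports)
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    tab <- as_ddi_table(cells_from_index(idx, candidates$drug1[i],
                                         candidates$drug2[i], candidates$ae[i]))
    e111 <- expected_count_e111(tab, model)
    n111 <- tab[["n111"]]
    om <- omega_statistic(n111, e111)
    c(n111 = n111, e111 = e111, omega = om)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- cbind(candidates[, c("drug1", "drug2", "ae")], res)
  out$n111 <- as.integer(out$n111)
  out$omega025 <- suppressMessages(omega_lower_bound(out$omega, out$n111))
  out$model <- model
  out$omega_signal <- !is.na(out$omega025) & out$omega025 > 0
  out <- out[order(-out$omega025, out$drug1, out$drug2, out$ae), , drop = FALSE]
  rownames(out) <- NULL
  out
}
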