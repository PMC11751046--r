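# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain loops and nested filters over individual reports,
# and numeric root-finding where the package uses closed-form algebra.

oracle_cells <- function(reports, d1, d2, ae) {
  cells <- c(n111 = 0, n110 = 0, n101 = 0, n100 = 0,
             n011 = 0, n010 = 0, n001 = 0, n000 = 0)
  for (i in seq_len(nrow(reports))) {
    has1 <- d1 %in% reports$drugs[[i]]
    has2 <- d2 %in% reports$drugs[[i]]
    has_ae <- ae %in% reports$aes[[i]]
    row <- if (has1 && has2) "11" else if (has1) "10" else if (has2) "01" else "00"
    cell <- paste0("n", row, if (has_ae) "1" else "0")
    cells[cell] <- cells[cell] + 1
  }
  cells
}

oracle_rule_metrics <- function(cells) {
  n <- sum(cells)
  n111 <- cells[["n111"]]
  pair <- cells[["n111"]] + cells[["n110"]]
  ae_total <- cells[["n111"]] + cells[["n101"]] + cells[["n011"]] + cells[["n001"]]
  support <- n111 / n
  confidence <- if (pair > 0) n111 / pair else NA_real_
  support_ae <- ae_total / n
  lift <- if (!is.na(confidence) && support_ae > 0) confidence / support_ae else NA_real_
  conviction <- if (is.na(confidence)) NA_real_
    else if (confidence < 1) (1 - support_ae) / (1 - confidence)
    else if (support_ae < 1) Inf else NA_real_
  list(support = support, confidence = confidence, support_ae = support_ae,
       lift = lift, conviction = conviction)
}

# solves the defining no-interaction equation numerically instead of
# inverting it algebraically
oracle_e111 <- function(cells, model = "noren_excess") {
  n11p <- cells[["n111"]] + cells[["n110"]]
  n10p <- cells[["n101"]] + cells[["n100"]]
  n01p <- cells[["n011"]] + cells[["n010"]]
  n00p <- cells[["n001"]] + cells[["n000"]]
  ae_total <- cells[["n111"]] + cells[["n101"]] + cells[["n011"]] + cells[["n001"]]
  n <- sum(cells)
  e_indep <- n11p * ae_total / n
  if (model == "independence") return(e_indep)
  if (n10p == 0 || n01p == 0 || n00p == 0) return(e_indep)
  f101 <- cells[["n101"]] / n10p
  f011 <- cells[["n011"]] / n01p
  f001 <- cells[["n001"]] / n00p
  if (f101 >= 1 || f011 >= 1) return(n11p)
  rhs <- 1 / (1 - f101) + 1 / (1 - f011) - 1 / (1 - f001)
  if (rhs <= 1) return(0)  # solution g <= 0, clamped
  g <- stats::uniroot(function(g) 1 / (1 - g) - rhs,
                      lower = 0, upper = 1 - 1e-12, tol = 1e-14)$root
  n11p * g
}

oracle_omega <- function(n111, e111) {
  log(( n111 + 0.5) / (e111 + 0.5)) / log(2)
}

oracle_omega025 <- function(n111, e111) {
  # 1.959964 is a fixed parameter of the method, not a computed quantity
  oracle_omega(n111, e111) - 1.959964 / (log(2) * sqrt(n111))
}

# brute-force candidate enumeration: double loop over reports x pairs x AEs
oracle_candidates <- function(reports, min_n111 = 1L) {
  counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(reports))) {
    drugs <- sort(reports$drugs[[i]])
    if (length(drugs) < 2) next
    for (a in seq_along(drugs)) for (b in seq_along(drugs)) {
      if (a >= b) next
      for (ae in reports$aes[[i]]) {
        key <- paste(drugs[a], drugs[b], ae, sep = "\r")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  n <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- n >= min_n111
  parts <- strsplit(keys[keep], "\r", fixed = TRUE)
  data.frame(drug1 = vapply(parts, `[`, "", 1),
             drug2 = vapply(parts, `[`, "", 2),
             ae = vapply(parts, `[`, "", 3),
             n111 = unname(n[keep]), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random report sets for property tests
random_reports <- function(n, seed, n_drugs = 6, n_aes = 4) {
  set.seed(seed)
  drugs <- LETTERS[seq_len(n_drugs)]
  aes <- paste0("AE", seq_len(n_aes))
  srs_reports(
    report_id = sprintf("r%04d", seq_len(n)),
    drugs = lapply(seq_len(n), function(i) {
      sample(drugs, size = sample(1:3, 1))
    }),
    aes = lapply(seq_len(n), function(i) {
      sample(aes, size = sample(1:2, 1))
    }),
    year = sample(2014:2022, n, replace = TRUE),
    age = sample(20:95, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    causality = sample(c("certain", "probable", "possible"), n, replace = TRUE)
  )
}
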