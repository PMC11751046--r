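test_that("conviction is recoverable from printed confidence and lift", {
  # strongest published-style row: confidence 0.43, lift 1116.69 -> 1.75
  expect_equal(round(conviction_from_confidence_lift(0.43, 1116.69), 2), 1.75)
  # vectorized, and exact at confidence = 1
  expect_identical(conviction_from_confidence_lift(1, 2), Inf)
})

test_that("rule_metrics matches the frequency-counting oracle", {
  for (seed in c(61, 62)) {
    r <- random_reports(100, seed = seed)
    cand <- enumerate_candidates(r, min_n111 = 1)
    for (i in seq_len(min(nrow(cand), 20))) {
      tab <- build_contingency(r, cand$drug1[i], cand$drug2[i], cand$ae[i])
      got <- rule_metrics(tab)
      want <- oracle_rule_metrics(oracle_cells(r, cand$drug1[i],
                                               cand$drug2[i], cand$ae[i]))
      expect_equal(got$support, want$support, tolerance = 1e-12)
      expect_equal(got$confidence, want$confidence, tolerance = 1e-12)
      expect_equal(got$lift, want$lift, tolerance = 1e-12)
      expect_equal(got$conviction, want$conviction, tolerance = 1e-12)
    }
  }
})

test_that("exact independence gives lift = conviction = 1", {
  # confidence = 2/10 = support_ae = 20/100 by construction
  tab <- ddi_table(2, 8, 3, 12, 5, 20, 10, 40)
  m <- rule_metrics(tab)
  expect_equal(m$confidence, m$support_ae)
  expect_equal(m$lift, 1)
  expect_equal(m$conviction, 1)
})

test_that("degenerate denominators give sentinels, not errors", {
  m <- rule_metrics(ddi_table(0, 0, 1, 9, 1, 9, 5, 75))  # no pair exposure
  expect_true(is.na(m$confidence))
  m2 <- rule_metrics(ddi_table(5, 0, 0, 10, 0, 10, 0, 75))  # confidence = 1
  expect_identical(m2$conviction, Inf)
  expect_error(rule_metrics(ddi_table(0, 0, 0, 0, 0, 0, 0, 0)), "empty")
})

test_that("conviction identity holds to floating tolerance on random tables", {
  set.seed(71)
  for (i in 1:50) {
    cells <- rpois(8, lambda = c(5, 20, 10, 200, 10, 200, 30, 2000))
    cells[2] <- cells[2] + 1  # keep confidence < 1
    tab <- do.call(ddi_table, as.list(cells))
    m <- rule_metrics(tab)
    expect_lt(abs(m$conviction * (1 - m$confidence) + m$support_ae - 1), 1e-9)
  }
})

test_that("metrics increase strictly in n111 with exposure margins fixed", {
  base <- c(n111 = 3, n110 = 27, n101 = 4, n100 = 96,
            n011 = 5, n010 = 95, n001 = 20, n000 = 1980)
  grow <- function(k) {
    cells <- base; cells["n111"] <- cells["n111"] + k; cells["n110"] <- cells["n110"] - k
    rule_metrics(do.call(ddi_table, as.list(cells)))
  }
  ms <- lapply(0:10, grow)
  for (col in c("support", "confidence", "lift", "conviction")) {
    vals <- vapply(ms, `[[`, numeric(1), col)
    expect_true(all(diff(vals) > 0), info = col)
  }
})

test_that("thresholds: strict lift/conviction, inclusive n111", {
  th <- rule_thresholds()
  mk <- function(n111, lift, conviction) {
    data.frame(n111 = n111, lift = lift, conviction = conviction)
  }
  expect_false(apply_rule_thresholds(mk(5, 1.0, 2), th)$rule_pass)   # lift == 1
  expect_false(apply_rule_thresholds(mk(5, 2, 1.0), th)$rule_pass)   # conviction == 1
  expect_false(apply_rule_thresholds(mk(2, 2, 1.5), th)$rule_pass)   # n111 < 3
  expect_true(apply_rule_thresholds(mk(3, 2, 1.5), th)$rule_pass)    # boundary n111
  expect_false(apply_rule_thresholds(mk(3, NA, 1.5), th)$rule_pass)  # NA never passes

  # batch of 20 rows with hand-labelled outcomes
  set.seed(81)
  batch <- mk(n111 = sample(1:6, 20, TRUE),
              lift = round(runif(20, 0.5, 3), 2),
              conviction = round(runif(20, 0.8, 2), 2))
  labels <- with(batch, n111 >= 3 & lift > 1 & conviction > 1)
  expect_equal(apply_rule_thresholds(batch, th)$rule_pass, labels)
})

test_that("redundancy: pair rules dominated by a single drug are removed", {
  rules <- data.frame(drug1 = c("A", "A"), drug2 = c("B", "C"),
                      ae = "X", confidence = c(0.10, 0.40))
  single <- data.frame(drug = c("A", "B", "C"), ae = "X",
                       n_drug = 100, n_drug_ae = c(12, 5, 5),
                       confidence = c(0.12, 0.05, 0.05))
  out <- remove_redundant_rules(rules, single)
  expect_equal(out$redundant, c(TRUE, FALSE))
  expect_match(out$removal_reason[1], "dominated by A")
  expect_true(is.na(out$removal_reason[2]))
})

test_that("single_drug_confidence counts reports, and redundancy suppresses a
           spurious pair while keeping a genuine interaction", {
  # drug S alone causes the AE; T merely co-occurs with S. Pair (S,T) adds
  # nothing over S. Pair (G1,G2) is a genuine interaction: AE only when both.
  spurious <- srs_reports(
    sprintf("s%02d", 1:12),
    drugs = c(rep(list(c("S", "T")), 6), rep(list("S"), 6)),
    aes = c(rep(list("X"), 4), list("Y"), list("Y"),
            rep(list("X"), 4), list("Y"), list("Y"))
  )
  genuine <- srs_reports(
    sprintf("g%02d", 1:18),
    drugs = c(rep(list(c("G1", "G2")), 6), rep(list("G1"), 6), rep(list("G2"), 6)),
    aes = c(rep(list("Z"), 5), list("Y"), rep(list("Y"), 12))
  )
  background <- srs_reports(sprintf("b%02d", 1:30),
                            drugs = rep(list("N"), 30), aes = rep(list("Y"), 30))
  r <- bind_reports(spurious, genuine, background)
  sdc <- single_drug_confidence(r)
  expect_equal(sdc$confidence[sdc$drug == "S" & sdc$ae == "X"], 8 / 12)
  det <- detect_signals(r, rule_thresholds(min_n111 = 3))
  key <- paste(det$signals$drug1, det$signals$drug2, det$signals$ae)
  expect_true("G1 G2 Z" %in% key)
  expect_false("S T X" %in% key)
  st <- det$rules[det$rules$drug1 == "S" & det$rules$ae == "X", ]
  expect_true(st$redundant)
})
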