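test_that("generation is byte-identical under the same seed, differs across seeds", {
  cfg <- synth_config(n_reports = 500, seed = 171)
  g1 <- generate_reports(cfg)
  g2 <- generate_reports(cfg)
  expect_identical(g1$reports, g2$reports)
  cfg2 <- synth_config(n_reports = 500, seed = 172)
  expect_false(identical(generate_reports(cfg2)$reports, g1$reports))
  # the generator restores the caller's RNG state
  set.seed(1); before <- .Random.seed
  invisible(generate_reports(cfg))
  expect_identical(.Random.seed, before)
})

test_that("seed is mandatory and every report has a drug and an AE", {
  expect_error(synth_config(n_reports = 10), "seed")
  gen <- generate_reports(synth_config(n_reports = 400, seed = 181))
  expect_true(all(lengths(gen$reports$drugs) >= 1))
  expect_true(all(lengths(gen$reports$aes) >= 1))
  expect_true(all(gen$reports$causality %in%
                    c("certain", "probable", "possible", "unlikely", "pending")))
})

test_that("empirical frequencies match the conditional closed form at n = 50,000", {
  lambda <- 20
  cfg <- synth_config(
    n_reports = 50000,
    injected_effects = data.frame(drug1 = "Amlodipine", drug2 = "Atorvastatin",
                                  ae = "Jaundice", lambda = lambda),
    copair_boost = data.frame(drug1 = "Amlodipine", drug2 = "Atorvastatin",
                              odds_multiplier = 3),
    seed = 191
  )
  gen <- generate_reports(cfg)
  r <- gen$reports
  truth <- gen$truth
  expect_false(truth$approximate)

  # realized contingency cells within 3 SD (binomial, SD ~ sqrt(expectation))
  tab <- build_contingency(r, "Amlodipine", "Atorvastatin", "Jaundice")
  for (cell in c("n111", "n110", "n101", "n011")) {
    e <- truth[[paste0("e_", cell)]]
    expect_lt(abs(tab[[cell]] - e), 3 * sqrt(e) + 1e-9)
  }
  expect_lt(abs(tab[["n11p"]] - truth$e_n11p), 3 * sqrt(truth$e_n11p))

  # drug exposure marginals: configured prob inflated by 1/P(>=1 drug),
  # with the boost folded into the focal drugs' marginals
  cat_d <- cfg$drug_catalog
  p_none <- prod(1 - cat_d$prob)
  for (d in c("Nifedipine", "Aspirin", "Vitamin C")) {
    p <- cat_d$prob[cat_d$drug == d]
    expected <- 50000 * p / (1 - p_none)
    got <- sum(vapply(r$drugs, function(x) d %in% x, logical(1)))
    expect_lt(abs(got - expected), 3 * sqrt(expected))
  }
})

test_that("a lambda = 1 effect is a true null: both-exposed AE rate matches baseline", {
  cfg <- synth_config(
    n_reports = 20000,
    injected_effects = data.frame(drug1 = "Aspirin", drug2 = "Nifedipine",
                                  ae = "Headache", lambda = 1),
    copair_boost = data.frame(drug1 = "Aspirin", drug2 = "Nifedipine",
                              odds_multiplier = 8),
    seed = 201
  )
  gen <- generate_reports(cfg)
  tab <- build_contingency(gen$reports, "Aspirin", "Nifedipine", "Headache")
  # conditional AE share should agree between the both-row and the truth's
  # closed form (which equals the no-effect share, lambda being 1)
  share_both <- tab[["n111"]] / tab[["n11p"]]
  share_expected <- gen$truth$e_n111 / gen$truth$e_n11p
  se <- sqrt(share_expected * (1 - share_expected) / tab[["n11p"]])
  expect_lt(abs(share_both - share_expected), 3 * se)
})

test_that("ground truth echoes injected effects and is derivable from config alone", {
  cfg <- synth_config(
    n_reports = 1000,
    injected_effects = data.frame(
      drug1 = c("Atorvastatin", "Aspirin"), drug2 = c("Amlodipine", "Ticagrelor"),
      ae = c("Jaundice", "Epistaxis"), lambda = c(20, 10)),
    seed = 211
  )
  truth <- ground_truth(cfg)
  expect_equal(nrow(truth), 2)
  # pairs canonicalized at config construction
  expect_equal(truth$drug1, c("Amlodipine", "Aspirin"))
  expect_true(all(truth$e_n111 >= 0))
  # cells of each triple sum to (nearly) n_reports; both rows carry every report
  sums <- rowSums(truth[, paste0("e_n", c("111", "110", "101", "100",
                                          "011", "010", "001", "000"))])
  expect_equal(sums, rep(1000, 2), tolerance = 1e-6)
  # no generation happened: derivable from config alone
  expect_identical(truth, generate_reports(cfg)$truth)
})

test_that("recovery experiment: replicates are seed-isolated and reproducible", {
  cfg <- synth_config(
    n_reports = 4000,
    injected_effects = data.frame(drug1 = "Amlodipine", drug2 = "Atorvastatin",
                                  ae = "Jaundice", lambda = 50),
    copair_boost = data.frame(drug1 = "Amlodipine", drug2 = "Atorvastatin",
                              odds_multiplier = 3),
    seed = 1
  )
  r1 <- recovery_experiment(cfg, n_replicates = 2, base_seed = 300)
  r2 <- recovery_experiment(cfg, n_replicates = 2, base_seed = 300)
  expect_identical(r1, r2)
  expect_equal(r1$replicates$seed, c(301, 302))
  # intersection can never fire more often than either detector
  expect_lte(r1$summary$joint_sensitivity, r1$summary$rule_sensitivity)
  expect_lte(r1$summary$joint_sensitivity, r1$summary$omega_sensitivity)
})

test_that("a strong injected interaction is recovered at moderate scale", {
  cfg <- synth_config(
    n_reports = 8000,
    injected_effects = data.frame(drug1 = "Amlodipine", drug2 = "Atorvastatin",
                                  ae = "Jaundice", lambda = 50),
    copair_boost = data.frame(drug1 = "Amlodipine", drug2 = "Atorvastatin",
                              odds_multiplier = 3),
    seed = 1
  )
  rec <- recovery_experiment(cfg, n_replicates = 5, base_seed = 400)
  expect_gte(rec$summary$joint_sensitivity, 0.6)
})

test_that("a single-drug effect does not masquerade as an interaction", {
  # drug A alone elevates the AE; the pair (A, B) has lambda = 1
  cfg <- synth_config(
    n_reports = 20000,
    single_drug_effects = data.frame(drug = "Aspirin",
                                     ae = "Gastrointestinal haemorrhage",
                                     multiplier = 15),
    injected_effects = data.frame(drug1 = "Aspirin", drug2 = "Clopidogrel",
                                  ae = "Gastrointestinal haemorrhage",
                                  lambda = 1),
    copair_boost = data.frame(drug1 = "Aspirin", drug2 = "Clopidogrel",
                              odds_multiplier = 10),
    seed = 221
  )
  rec <- recovery_experiment(cfg, n_replicates = 5, base_seed = 500)
  # redundancy pruning and/or the excess-risk expectation suppress the pair
  expect_lte(rec$summary$joint_sensitivity, 0.2)
})
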