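test_that("read_reports splits, trims and deduplicates list cells", {
  f <- withr_local_csv(c(
    "report_id,year,age,sex,drugs,aes,causality",
    "r1,2020,70,M,Aspirin;Ticagrelor,Epistaxis,probable",
    "r2,2019,55,F,Aspirin;Aspirin,Rash; Headache,possible",
    "r3,2021,61,M,Nifedipine, ,certain",
    "r4,2018,NA,x,Amlodipine;Atorvastatin,Jaundice,possible",
    "r5,2022,80,F, Aspirin ,Rash,unlikely"
  ))
  r <- read_reports(f)
  expect_s3_class(r, "srs_reports")
  expect_equal(nrow(r), 5)
  expect_setequal(r$drugs[[1]], c("Aspirin", "Ticagrelor"))
  expect_equal(r$drugs[[2]], "Aspirin")            # duplicate collapsed
  expect_setequal(r$aes[[2]], c("Rash", "Headache"))
  expect_length(r$aes[[3]], 0)                     # empty AE cell kept for now
  expect_equal(r$sex[4], "unknown")
  expect_true(is.na(r$age[4]))
  expect_equal(r$drugs[[5]], "Aspirin")            # whitespace trimmed
})

test_that("read_reports resolves columns via schema and errors clearly", {
  f <- withr_local_csv(c("ID,Drug list,ADEs,Grade",
                         "x1,A;B,Rash,possible"))
  r <- read_reports(f, schema = c(report_id = "ID", drugs = "Drug list",
                                  aes = "ADEs", causality = "Grade"))
  expect_equal(r$report_id, "x1")
  expect_error(read_reports(f, schema = c(report_id = "ID", drugs = "nope",
                                          aes = "ADEs", causality = "Grade")),
               "nope")
  expect_error(read_reports(tempfile()), "cannot read")
})

test_that("standardization normalizes case/whitespace and applies policies", {
  r <- srs_reports(c("a", "b"),
                   drugs = list(c("aspirin ", "UnknownDrug"), "ASPIRIN"),
                   aes = list("nose bleed", "rash"))
  dd <- term_dictionary("aspirin", "Aspirin")
  ad <- term_dictionary(c("nose bleed", "rash"), c("Epistaxis", "Rash"),
                        category = c("Respiratory", "Skin"))
  out <- suppressMessages(standardize_reports(r, dd, ad))
  expect_setequal(out$drugs[[1]], c("Aspirin", "UnknownDrug"))  # keep_raw
  expect_equal(out$drugs[[2]], "Aspirin")
  expect_equal(out$aes[[1]], "Epistaxis")
  expect_equal(out$ae_categories[[1]], "Respiratory")

  dd_drop <- term_dictionary("aspirin", "Aspirin", unmapped = "drop")
  out2 <- suppressMessages(standardize_reports(r, dd_drop))
  expect_equal(out2$drugs[[1]], "Aspirin")

  dd_err <- term_dictionary("aspirin", "Aspirin", unmapped = "error")
  expect_error(suppressMessages(standardize_reports(r, dd_err)), "UnknownDrug")
})

test_that("standardization collapses synonyms and is order-independent", {
  r <- srs_reports("a", drugs = list(c("aspirin", "acetylsalicylic acid")),
                   aes = list("rash"))
  dd <- term_dictionary(c("aspirin", "acetylsalicylic acid"),
                        c("Aspirin", "Aspirin"))
  out <- standardize_reports(r, dd, verbose = FALSE)
  expect_equal(out$drugs[[1]], "Aspirin")

  r10 <- random_reports(10, seed = 3)
  dd2 <- term_dictionary(c("a", "b"), c("Astd", "Bstd"))
  fwd <- standardize_reports(r10, dd2, verbose = FALSE)
  rev <- standardize_reports(r10[10:1, ], dd2, verbose = FALSE)
  expect_equal(fwd$drugs, rev$drugs[10:1])
})

test_that("term_dictionary rejects duplicate keys after normalization", {
  expect_error(term_dictionary(c("Aspirin", "aspirin "), c("A", "B")),
               "duplicate")
})

test_that("inclusion filters: per-criterion log matches a hand count", {
  # 10 reports with known violations, in a fixed order:
  #  y1 year 2013 (year), y2 year 2023 (year),
  #  d1 no qualifying disease (disease),
  #  c1 unlikely, c2 pending (causality),
  #  m1 no drugs, m2 no AEs (missingness),
  #  k1..k3 clean
  mk <- function(id, year = 2018, dis = "Hypertension", caus = "possible",
                 drugs = "Aspirin", aes = "Rash") {
    srs_reports(id, drugs = list(drugs), aes = list(aes), diseases = list(dis),
                year = year, causality = caus)
  }
  r <- do.call(rbind, list(
    mk("y1", year = 2013), mk("y2", year = 2023),
    mk("d1", dis = "Influenza"),
    mk("c1", caus = "unlikely"), mk("c2", caus = "pending"),
    mk("m1", drugs = character(0)), mk("m2", aes = character(0)),
    mk("k1"), mk("k2"), mk("k3")
  ))
  class(r) <- c("srs_reports", "data.frame")
  spec <- filter_spec(2014, 2022, required_disease_terms = "Hypertension")
  res <- apply_filters(r, spec, verbose = FALSE)
  expect_equal(res$log$removed, c(2L, 1L, 2L, 2L))
  expect_equal(res$log$criterion, c("year", "disease", "causality", "missingness"))
  expect_equal(nrow(res$reports), 3)
  expect_setequal(res$reports$report_id, c("k1", "k2", "k3"))
  # retained + removed partitions the input
  expect_equal(nrow(res$reports) + sum(res$log$removed), nrow(r))
})

test_that("filtering is idempotent and boundary years are inclusive", {
  r <- random_reports(40, seed = 9)
  spec <- filter_spec(2015, 2020)
  once <- apply_filters(r, spec, verbose = FALSE)
  twice <- apply_filters(once$reports, spec, verbose = FALSE)
  expect_equal(twice$reports, once$reports)
  expect_equal(sum(twice$log$removed), 0)
  expect_true(all(once$reports$year >= 2015 & once$reports$year <= 2020))

  edge <- srs_reports(c("lo", "hi", "out"), drugs = list("A"), aes = list("X"),
                      year = c(2015L, 2020L, 2014L))
  kept <- apply_filters(edge, spec, verbose = FALSE)$reports
  expect_setequal(kept$report_id, c("lo", "hi"))
})

test_that("filter_spec validates its configuration", {
  expect_error(filter_spec(allowed_causality = character(0)), "non-empty")
  expect_error(filter_spec(year_min = 2022, year_max = 2014), "year_min")
})

test_that("the shipped example CSV round-trips through ingest + dictionaries", {
  path <- system.file("extdata", "example_reports.csv", package = "srsddi")
  dd <- read_term_dictionary(system.file("extdata", "drug_dictionary.csv",
                                         package = "srsddi"))
  ad <- read_term_dictionary(system.file("extdata", "ae_dictionary.csv",
                                         package = "srsddi"))
  r <- read_reports(path, schema = c(report_id = "id",
                                     reporter_category = "unit"))
  expect_equal(nrow(r), 10)
  std <- standardize_reports(r, dd, ad, verbose = FALSE)
  expect_setequal(std$drugs[[7]], c("Aspirin", "Clopidogrel"))
  res <- apply_filters(std, filter_spec(2014, 2022), verbose = FALSE)
  # excluded: R0006 (2013), R0008 (unlikely, also duplicate drug), R0010 (no AE)
  expect_setequal(res$reports$report_id,
                  paste0("R000", c(1, 2, 3, 4, 5, 7, 9)))
})
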