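#' Default drug catalog for the synthetic generator
#'
#' Heavy-tailed marginal exposure probabilities loosely emulating a
#' provincial cardio-/cerebrovascular ADR database: one dominant
#' antihypertensive (~9% of reports), a tail of common co-medications, and
#' several antithrombotic/statin agents that make interesting pairs.
#' Probabilities are pre-conditioning (see [generate_reports()]).
#' @return data.frame with columns `drug`, `prob`.
#' @export
default_drug_catalog <- function() {
  data.frame(
    drug = c("Nifedipine", "Isosorbide mononitrate", "Xiangdan", "Aspirin",
             "Shenmai", "Levofloxacin", "Xuesaitong", "Salvia miltiorrhiza",
             "Amlodipine", "Atorvastatin", "Clopidogrel", "Ticagrelor",
             "Vitamin B6", "Vitamin C", "Captopril", "Felodipine", "Irbesartan"),
    prob = c(0.09, 0.05, 0.04, 0.04, 0.03, 0.025, 0.02, 0.02,
             0.05, 0.04, 0.03, 0.02, 0.015, 0.02, 0.02, 0.015, 0.015),
    stringsAsFactors = FALSE
  )
}

#' Default adverse-event catalog for the synthetic generator
#'
#' Per-report baseline probabilities (pre-conditioning) with a realistic
#' heavy tail: frequent non-specific events (pruritus, headache, rash) and
#' rare events (jaundice, haemorrhages) that only become visible through
#' drug effects. Categories play the role of system-organ classes.
#' @return data.frame with columns `ae`, `baseline`, `category`.
#' @export
default_ae_catalog <- function() {
  data.frame(
    ae = c("Pruritus", "Headache", "Rash", "Nausea", "Dizziness",
           "Hypersensitivity", "Palpitations", "Chest discomfort", "Flushing",
           "Vomiting", "Cough", "Erythema", "Chills", "Epistaxis",
           "Skin reaction", "Gastrointestinal haemorrhage", "Jaundice",
           "Haematochezia", "Haemorrhage", "Upper gastrointestinal haemorrhage",
           "Petechiae"),
    baseline = c(0.10, 0.09, 0.08, 0.07, 0.06, 0.05, 0.05, 0.04, 0.04,
                 0.035, 0.03, 0.01, 0.005, 0.004, 0.004, 0.003, 0.002,
                 0.002, 0.002, 0.002, 0.002),
    category = c("Skin", "Nervous system", "Skin", "Gastrointestinal",
                 "Nervous system", "Immune system", "Cardiac", "Cardiac",
                 "General", "Gastrointestinal", "Respiratory", "Skin",
                 "General", "Respiratory", "Skin", "Gastrointestinal",
                 "Hepatobiliary", "Gastrointestinal", "Vascular",
                 "Gastrointestinal", "Skin"),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Describes a complete simulated reporting world: drug exposure
#' probabilities, optional co-prescription boosts, per-report AE baseline
#' probabilities, injected pair-specific interaction effects (the ground
#' truth a detection pipeline should recover), optional single-drug effects,
#' demographics, causality mix and reporting years. The seed is mandatory;
#' generation is fully reproducible from the config alone.
#'
#' @param n_reports number of reports to generate.
#' @param drug_catalog data.frame `drug`, `prob` (independent Bernoulli
#'   exposure per drug, before conditioning on >= 1 drug).
#' @param ae_catalog data.frame `ae`, `baseline`, `category` (per-report AE
#'   probability before drug effects and conditioning on >= 1 AE).
#' @param copair_boost optional data.frame `drug1`, `drug2`,
#'   `odds_multiplier`: when `drug1` is drawn, `drug2`'s odds are multiplied
#'   by this factor (models preferential co-prescription).
#' @param injected_effects optional data.frame `drug1`, `drug2`, `ae`,
#'   `lambda`: reports exposed to both drugs have the AE probability
#'   multiplied by `lambda` (capped at 1). `lambda = 1` is an explicit null.
#' @param single_drug_effects optional data.frame `drug`, `ae`, `multiplier`.
#' @param sex_probs named probabilities for `male`, `female`, `unknown`.
#' @param age_mean,age_sd,age_range normal age model, truncated by rounding
#'   into `age_range` (defaults give roughly a 60/40 split around age 60).
#' @param age_missing_prob probability that age is missing.
#' @param causality_probs named probabilities over the five grades.
#' @param year_range inclusive reporting-year window (uniform).
#' @param seed integer RNG seed (required).
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_reports,
                         drug_catalog = default_drug_catalog(),
                         ae_catalog = default_ae_catalog(),
                         copair_boost = NULL,
                         injected_effects = NULL,
                         single_drug_effects = NULL,
                         sex_probs = c(male = 0.47, female = 0.527, unknown = 0.003),
                         age_mean = 65, age_sd = 15, age_range = c(18, 100),
                         age_missing_prob = 0.001,
                         causality_probs = c(certain = 0.05, probable = 0.35,
                                             possible = 0.55, unlikely = 0.03,
                                             pending = 0.02),
                         year_range = c(2014L, 2022L),
                         seed) {
  if (missing(seed)) stop("seed is mandatory: no silent nondeterminism")
  stopifnot(n_reports >= 1,
            all(drug_catalog$prob >= 0 & drug_catalog$prob <= 1),
            all(ae_catalog$baseline >= 0 & ae_catalog$baseline <= 1),
            !anyDuplicated(drug_catalog$drug), !anyDuplicated(ae_catalog$ae),
            abs(sum(sex_probs) - 1) < 1e-8,
            abs(sum(causality_probs) - 1) < 1e-8)
  canon_pair <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    swap <- df$drug1 > df$drug2
    tmp <- df$drug1[swap]; df$drug1[swap] <- df$drug2[swap]; df$drug2[swap] <- tmp
    df
  }
  injected_effects <- canon_pair(injected_effects)
  if (!is.null(injected_effects)) {
    stopifnot(all(c("drug1", "drug2", "ae", "lambda") %in% names(injected_effects)),
              all(injected_effects$lambda >= 0),
              all(injected_effects$drug1 %in% drug_catalog$drug),
              all(injected_effects$drug2 %in% drug_catalog$drug),
              all(injected_effects$ae %in% ae_catalog$ae))
  }
  if (!is.null(copair_boost)) {
    stopifnot(all(c("drug1", "drug2", "odds_multiplier") %in% names(copair_boost)),
              all(copair_boost$odds_multiplier > 0))
  }
  if (!is.null(single_drug_effects)) {
    stopifnot(all(c("drug", "ae", "multiplier") %in% names(single_drug_effects)),
              all(single_drug_effects$multiplier >= 0))
  }
  structure(list(
    n_reports = as.integer(n_reports), drug_catalog = drug_catalog,
    ae_catalog = ae_catalog, copair_boost = copair_boost,
    injected_effects = injected_effects,
    single_drug_effects = single_drug_effects,
    sex_probs = sex_probs[SEX_LEVELS], age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, age_missing_prob = age_missing_prob,
    causality_probs = causality_probs[CAUSALITY_LEVELS],
    year_range = as.integer(year_range), seed = as.integer(seed)
  ), class = "synth_config")
}

# draw the n x D drug exposure matrix (independent Bernoulli + copair boosts)
draw_drug_matrix <- function(n, config) {
  cat <- config$drug_catalog
  m <- matrix(runif(n * nrow(cat)) < rep(cat$prob, each = n), nrow = n,
              dimnames = list(NULL, cat$drug))
  if (!is.null(config$copair_boost)) {
    for (i in seq_len(nrow(config$copair_boost))) {
      b <- config$copair_boost[i, ]
      p2 <- cat$prob[match(b$drug2, cat$drug)]
      if (is.na(p2)) next
      odds <- b$odds_multiplier * p2 / (1 - p2)
      p2_boost <- odds / (1 + odds)
      rows <- which(m[, b$drug1])
      if (length(rows)) m[rows, b$drug2] <- runif(length(rows)) < p2_boost
    }
  }
  m
}

# per-report AE probability matrix given the drug exposure matrix
ae_prob_matrix <- function(drug_m, config) {
  n <- nrow(drug_m)
  cat <- config$ae_catalog
  p <- matrix(rep(cat$baseline, each = n), nrow = n,
              dimnames = list(NULL, cat$ae))
  sde <- config$single_drug_effects
  if (!is.null(sde)) {
    for (i in seq_len(nrow(sde))) {
      rows <- drug_m[, sde$drug[i]]
      p[rows, sde$ae[i]] <- p[rows, sde$ae[i]] * sde$multiplier[i]
    }
  }
  inj <- config$injected_effects
  if (!is.null(inj)) {
    for (i in seq_len(nrow(inj))) {
      rows <- drug_m[, inj$drug1[i]] & drug_m[, inj$drug2[i]]
      p[rows, inj$ae[i]] <- p[rows, inj$ae[i]] * inj$lambda[i]
    }
  }
  pmin(p, 1)
}

#' Generate a synthetic spontaneous-report database
#'
#' Sampling scheme, per report: (1) drug exposures are independent Bernoulli
#' draws from the catalog probabilities, with optional co-prescription odds
#' boosts applied to `drug2` when `drug1` was drawn; reports with no drug are
#' redrawn (a spontaneous report always names a suspect drug). (2) Each AE is
#' drawn with probability baseline x applicable single-drug multipliers x
#' lambda when both drugs of an injected effect are present, capped at 1;
#' reports with no AE have their AE draws repeated (a report always carries
#' an event). (3) Demographics, year and causality are sampled
#' independently.
#'
#' The zero-truncation in (1) and (2) means empirical frequencies exceed the
#' configured pre-conditioning probabilities by a factor ~ 1/P(at least one);
#' [ground_truth()] returns the exact post-conditioning expectations, which
#' is what tests should compare against.
#'
#' @param config a [synth_config].
#' @return A list: `reports` (an [srs_reports]) and `truth` (see
#'   [ground_truth()]).
#' @examples
#' cfg <- synth_config(n_reports = 200, seed = 1)
#' gen <- generate_reports(cfg)
#' gen$reports
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  n <- config$n_reports

  drug_m <- draw_drug_matrix(n, config)
  for (iter in 1:1000) {
    empty <- which(rowSums(drug_m) == 0L)
    if (!length(empty)) break
    drug_m[empty, ] <- draw_drug_matrix(length(empty), config)
  }
  if (any(rowSums(drug_m) == 0L)) stop("drug regeneration failed to converge")

  p_ae <- ae_prob_matrix(drug_m, config)
  ae_m <- matrix(runif(length(p_ae)) < p_ae, nrow = n)
  for (iter in 1:1000) {
    empty <- which(rowSums(ae_m) == 0L)
    if (!length(empty)) break
    sub <- p_ae[empty, , drop = FALSE]
    ae_m[empty, ] <- runif(length(sub)) < sub
  }
  if (any(rowSums(ae_m) == 0L)) stop("AE regeneration failed to converge")
  colnames(ae_m) <- colnames(p_ae)

  ae_cats <- stats::setNames(config$ae_catalog$category, config$ae_catalog$ae)
  # every row has >= 1 hit, so split() covers all report ids in order
  hits_to_list <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    o <- order(idx[, 1L])
    unname(split(colnames(m)[idx[o, 2L]], idx[o, 1L]))
  }
  drugs_list <- hits_to_list(drug_m)
  aes_list <- hits_to_list(ae_m)

  sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = config$sex_probs)
  age <- round(pmin(pmax(rnorm(n, config$age_mean, config$age_sd),
                         config$age_range[1]), config$age_range[2]))
  age[runif(n) < config$age_missing_prob] <- NA_real_
  year <- sample(seq(config$year_range[1], config$year_range[2]), n,
                 replace = TRUE)
  causality <- sample(CAUSALITY_LEVELS, n, replace = TRUE,
                      prob = config$causality_probs)

  reports <- new_srs_reports(
    report_id = sprintf("SYN%07d", seq_len(n)),
    year = year, age = age, sex = sex,
    reporter_category = rep("synthetic", n),
    diseases = rep(list(character(0)), n),
    drugs = drugs_list, aes = aes_list,
    ae_categories = lapply(aes_list, function(a) unname(ae_cats[a])),
    causality = causality
  )
  list(reports = reports, truth = ground_truth(config))
}

#' Exact expected contingency cells for the injected effects
#'
#' For every injected (drug1, drug2, AE, lambda) effect, computes the
#' expected value of each cell of its 4x2 contingency table under the
#' generator's own sampling scheme, including the conditioning on at least
#' one drug and at least one AE per report. The calculation is exact when
#' co-prescription boosts and risk effects involve only the focal pair (the
#' regime used by the test-bench configurations); effects attached to other
#' drugs are ignored in the expectation and noted in `approximate`.
#'
#' @param config a [synth_config].
#' @return A data.frame, one row per injected effect: the triple, `lambda`,
#'   the eight expected cells (`e_n111` ... `e_n000`), the expected
#'   both-exposure count `e_n11p`, and `approximate`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  inj <- config$injected_effects
  if (is.null(inj) || !nrow(inj)) {
    return(data.frame(drug1 = character(0), drug2 = character(0),
                      ae = character(0), lambda = numeric(0)))
  }
  cat_d <- config$drug_catalog
  cat_a <- config$ae_catalog
  p_all <- stats::setNames(cat_d$prob, cat_d$drug)
  p_none_all <- prod(1 - cat_d$prob)

  out <- lapply(seq_len(nrow(inj)), function(i) {
    d1 <- inj$drug1[i]; d2 <- inj$drug2[i]; ae <- inj$ae[i]
    lam <- inj$lambda[i]
    p1 <- p_all[[d1]]; p2 <- p_all[[d2]]
    p2_given_1 <- p2
    approximate <- FALSE
    if (!is.null(config$copair_boost)) {
      hit <- (config$copair_boost$drug1 == d1 & config$copair_boost$drug2 == d2)
      if (any(hit)) {
        m <- config$copair_boost$odds_multiplier[which(hit)[1]]
        odds <- m * p2 / (1 - p2)
        p2_given_1 <- odds / (1 + odds)
      }
      if (nrow(config$copair_boost) > sum(hit)) approximate <- TRUE
    }
    # the four rows partition {>= 1 drug}: both / only1 / only2 carry a focal
    # drug; the "neither" row requires at least one non-focal drug
    p_others_none <- p_none_all / ((1 - p1) * (1 - p2))
    p_row <- c(both = p1 * p2_given_1,
               only1 = p1 * (1 - p2_given_1),
               only2 = (1 - p1) * p2,
               neither = (1 - p1) * (1 - p2) * (1 - p_others_none))
    p_row <- p_row / sum(p_row)

    # per-row AE probability vectors
    base <- stats::setNames(cat_a$baseline, cat_a$ae)
    mult_for <- function(drug_present1, drug_present2) {
      q <- base
      sde <- config$single_drug_effects
      if (!is.null(sde)) {
        for (j in seq_len(nrow(sde))) {
          if ((sde$drug[j] == d1 && drug_present1) ||
              (sde$drug[j] == d2 && drug_present2)) {
            q[sde$ae[j]] <- q[sde$ae[j]] * sde$multiplier[j]
          } else if (!sde$drug[j] %in% c(d1, d2)) {
            approximate <<- TRUE
          }
        }
      }
      other_inj <- inj[-i, , drop = FALSE]
      if (nrow(other_inj)) {
        both_focal <- drug_present1 && drug_present2
        for (j in seq_len(nrow(other_inj))) {
          if (other_inj$drug1[j] == d1 && other_inj$drug2[j] == d2) {
            if (both_focal) q[other_inj$ae[j]] <- q[other_inj$ae[j]] * other_inj$lambda[j]
          } else {
            approximate <<- TRUE
          }
        }
      }
      if (drug_present1 && drug_present2) q[ae] <- q[ae] * lam
      pmin(q, 1)
    }
    rows_q <- list(both = mult_for(TRUE, TRUE), only1 = mult_for(TRUE, FALSE),
                   only2 = mult_for(FALSE, TRUE), neither = mult_for(FALSE, FALSE))
    cells <- numeric(8)
    names(cells) <- c("e_n111", "e_n110", "e_n101", "e_n100",
                      "e_n011", "e_n010", "e_n001", "e_n000")
    row_keys <- c("both", "only1", "only2", "neither")
    for (r in 1:4) {
      q <- rows_q[[row_keys[r]]]
      p_any_ae <- 1 - prod(1 - q)
      p_target <- q[[ae]] / p_any_ae  # P(target AE | >= 1 AE)
      n_row <- config$n_reports * p_row[[row_keys[r]]]
      cells[2 * r - 1] <- n_row * p_target
      cells[2 * r] <- n_row * (1 - p_target)
    }
    data.frame(drug1 = d1, drug2 = d2, ae = ae, lambda = lam,
               t(cells), e_n11p = cells[1] + cells[2],
               approximate = approximate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery experiment
#'
#' Generates `n_replicates` independent databases from `config` (replicate
#' `r` uses seed `base_seed + r`, so each is individually reproducible), runs
#' [detect_signals()] on each, and records for every injected effect whether
#' the rule detector, the Omega detector and their intersection fired, plus
#' the number of false joint signals (joint signals not matching any injected
#' triple). For an explicit null config (all `lambda = 1`), the "sensitivity"
#' columns are false-positive rates on the focal triples.
#'
#' @param config a [synth_config] with at least one injected effect (possibly
#'   a null with `lambda = 1`).
#' @param thresholds a [rule_thresholds].
#' @param omega_model expectation model for `E111`.
#' @param n_replicates number of replicates.
#' @param base_seed integer; replicate seeds are `base_seed + 1..n_replicates`.
#' @param prune_redundant passed to [detect_signals()].
#' @return A list: `replicates` (one row per replicate x injected effect with
#'   logical `rule_fired`, `omega_fired`, `joint_fired` and integer
#'   `false_signals`) and `summary` (per-effect detection proportions and the
#'   mean false-signal count).
#' @export
recovery_experiment <- function(config, thresholds = rule_thresholds(),
                                omega_model = c("noren_excess", "independence"),
                                n_replicates = 20L, base_seed = 1L,
                                prune_redundant = TRUE) {
  stopifnot(inherits(config, "synth_config"),
            !is.null(config$injected_effects),
            nrow(config$injected_effects) >= 1)
  omega_model <- match.arg(omega_model)
  inj <- config$injected_effects
  inj_key <- paste(inj$drug1, inj$drug2, inj$ae, sep = "\r")
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + r)
    gen <- generate_reports(cfg)
    det <- detect_signals(gen$reports, thresholds = thresholds,
                          omega_model = omega_model,
                          prune_redundant = prune_redundant)
    sig_key <- if (nrow(det$signals))
      paste(det$signals$drug1, det$signals$drug2, det$signals$ae, sep = "\r")
    else character(0)
    rule_key <- if (nrow(det$rules))
      with(det$rules[det$rules$rule_pass, , drop = FALSE],
           paste(drug1, drug2, ae, sep = "\r")) else character(0)
    omega_key <- if (nrow(det$omega))
      with(det$omega[det$omega$omega_signal, , drop = FALSE],
           paste(drug1, drug2, ae, sep = "\r")) else character(0)
    rows[[r]] <- data.frame(
      replicate = r, seed = cfg$seed,
      drug1 = inj$drug1, drug2 = inj$drug2, ae = inj$ae, lambda = inj$lambda,
      rule_fired = inj_key %in% rule_key,
      omega_fired = inj_key %in% omega_key,
      joint_fired = inj_key %in% sig_key,
      false_signals = sum(!sig_key %in% inj_key),
      stringsAsFactors = FALSE
    )
  }
  reps <- do.call(rbind, rows)
  dt <- data.table::as.data.table(reps)
  summary <- dt[, .(
    rule_sensitivity = mean(rule_fired),
    omega_sensitivity = mean(omega_fired),
    joint_sensitivity = mean(joint_fired),
    mean_false_signals = mean(false_signals)
  ), by = .(drug1, drug2, ae, lambda)]
  list(replicates = reps, summary = as.data.frame(summary))
}
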