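#' The seven antihypertensive drug classes on the prescription menu
#'
#' Calcium channel blockers, thiazide diuretics, angiotensin-II receptor
#' blockers, ACE inhibitors, beta-blockers, loop diuretics and
#' mineralocorticoid-receptor antagonists, in the canonical menu order used
#' throughout the package.
#'
#' @return Character vector of length 7.
#' @export
bp_drug_classes <- function() {
  c("CCB", "Thiazide", "ARB", "ACEi", "BetaBlocker", "LoopDiuretic", "MRA")
}

#' Default per-class treatment-effect matrix
#'
#' One row per drug class giving the base shift in next-period mean systolic
#' blood pressure (mmHg, negative = lowering) plus interaction coefficients on
#' patient covariates. The interactions encode guideline-flavored heterogeneity:
#' renin-angiotensin drugs (ACEi/ARB) work best in diabetic and non-Black
#' patients, CCB/thiazide respond best in Black patients, beta-blockers gain in
#' systolic heart failure. `age10` multiplies (age - 60)/10.
#'
#' @return A tibble with columns `drug_class`, `base`, `diabetes`, `black`,
#'   `smoker`, `age10`, `systolic_hf`.
#' @export
default_effect_matrix <- function() {
  tibble::tribble(
    ~drug_class,    ~base, ~diabetes, ~black, ~smoker, ~age10, ~systolic_hf,
    "CCB",           -8.0,       0.0,   -3.0,     0.0,   -0.3,          0.0,
    "Thiazide",      -7.0,       0.0,   -2.5,     0.0,    0.0,          0.0,
    "ARB",           -7.0,      -3.0,    2.0,     0.0,    0.0,          0.0,
    "ACEi",          -7.5,      -3.5,    2.5,     0.0,    0.0,          0.0,
    "BetaBlocker",   -5.0,       0.0,    1.0,    -1.0,    0.0,         -3.0,
    "LoopDiuretic",  -4.0,       0.0,    0.0,     0.0,   -0.5,         -2.0,
    "MRA",           -5.0,       0.0,   -2.0,     0.0,    0.0,          0.0
  )
}

default_rule_trigger_fractions <- function() {
  c(low_pulse = 0.08, potassium_high = 0.08, potassium_very_high = 0.03,
    creatinine_high = 0.05, diabetes = 0.30, systolic_hf = 0.05)
}

#' Configuration for the synthetic longitudinal EHR generator
#'
#' @param n_patients Number of patients (>= 1).
#' @param horizon_days Observation horizon in days; the number of 90-day review
#'   periods is `floor(horizon_days / visit_period)`.
#' @param visit_period Length of a review period in days (default 90).
#' @param drug_classes Ordered drug-class labels; must match `effect_matrix`.
#' @param effect_matrix Per-class base SBP effect plus covariate-interaction
#'   coefficients (mmHg); see [default_effect_matrix()].
#' @param noise_sd Process noise on next-period mean SBP, mmHg; measurement
#'   noise is half of it. 0 gives a fully deterministic trajectory.
#' @param outlier_fraction Fraction of SBP measurements corrupted at generation
#'   time by entry-error style shifts (in `[0, 1)`).
#' @param outlier_magnitude Magnitude of those shifts in mmHg.
#' @param missing_fraction Fraction of measurement rows dropped completely at
#'   random (the anchor first-SBP record of each patient is always retained).
#' @param combo_fraction Probability that a (re)chosen regimen is a two-class
#'   combination rather than a monotherapy.
#' @param rule_trigger_fractions Named per-rule fractions of patients whose
#'   labs/diagnoses trigger the clinical rules (low pulse, elevated potassium,
#'   elevated creatinine, diabetes, systolic heart failure).
#' @param rho First-order autoregressive weight of the SBP drift toward each
#'   patient's setpoint.
#' @param seed Integer seed; identical configs generate identical cohorts.
#'
#' @return An object of class `bp_generator_config`.
#' @export
generator_config <- function(n_patients,
                             horizon_days = 720,
                             visit_period = 90,
                             drug_classes = bp_drug_classes(),
                             effect_matrix = default_effect_matrix(),
                             noise_sd = 5,
                             outlier_fraction = 0,
                             outlier_magnitude = 50,
                             missing_fraction = 0.05,
                             combo_fraction = 0.15,
                             rule_trigger_fractions = default_rule_trigger_fractions(),
                             rho = 0.7,
                             seed = 1L) {
  chk_frac <- function(x, nm) {
    if (!is.numeric(x) || any(x < 0) || any(x >= 1)) {
      abort(paste0("`", nm, "` must lie in [0, 1)."), class = "bp_config_error")
    }
  }
  if (!is.numeric(n_patients) || n_patients < 1) {
    abort("`n_patients` must be >= 1.", class = "bp_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0.", class = "bp_config_error")
  }
  chk_frac(outlier_fraction, "outlier_fraction")
  chk_frac(missing_fraction, "missing_fraction")
  chk_frac(combo_fraction, "combo_fraction")
  chk_frac(rule_trigger_fractions, "rule_trigger_fractions")
  if (!setequal(effect_matrix$drug_class, drug_classes) ||
      nrow(effect_matrix) != length(drug_classes)) {
    abort("`effect_matrix` must have exactly one row per entry of `drug_classes`.",
          class = "bp_config_error")
  }
  if (rho < 0 || rho > 1) {
    abort("`rho` must lie in [0, 1].", class = "bp_config_error")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), horizon_days = horizon_days,
      visit_period = visit_period, drug_classes = drug_classes,
      effect_matrix = effect_matrix, noise_sd = noise_sd,
      outlier_fraction = outlier_fraction, outlier_magnitude = outlier_magnitude,
      missing_fraction = missing_fraction, combo_fraction = combo_fraction,
      rule_trigger_fractions = rule_trigger_fractions, rho = rho,
      seed = as.integer(seed)
    ),
    class = "bp_generator_config"
  )
}

# per-patient, per-class treatment effect on next-period mean SBP (mmHg)
patient_effects <- function(demo, effect_matrix, drug_classes) {
  em <- effect_matrix[match(drug_classes, effect_matrix$drug_class), ]
  n <- nrow(demo)
  E <- matrix(0, n, length(drug_classes), dimnames = list(NULL, drug_classes))
  for (j in seq_along(drug_classes)) {
    E[, j] <- em$base[j] +
      em$diabetes[j] * demo$diabetes +
      em$black[j] * (demo$race == "Black") +
      em$smoker[j] * demo$smoker +
      em$age10[j] * (demo$age - 60) / 10 +
      em$systolic_hf[j] * demo$systolic_hf
  }
  E
}

# sub-additive combination: strongest class in full, others at 40%
regimen_effect <- function(classes, eff_row) {
  if (length(classes) == 0) return(0)
  e <- sort(unname(eff_row[classes]))
  e[1] + 0.4 * sum(e[-1])
}

#' Generate a synthetic longitudinal cohort with ground-truth counterfactuals
#'
#' Simulates per-patient systolic blood pressure trajectories under a
#' first-order autoregressive drift toward a patient-specific setpoint, with
#' the drug regimen active during each 90-day review period shifting the next
#' period's mean SBP by a covariate-dependent class effect. Observed
#' assignments follow a confounded standard-of-care behavior policy (e.g.,
#' diabetics are preferentially started on ACE inhibitors), and the returned
#' truth table stores, for every evaluable period, the counterfactual
#' next-period mean SBP under each of the 7 monotherapies and under
#' continuation of the current regimen — sharing the period's process-noise
#' draw so that with `noise_sd = 0` the observed outcome equals the truth
#' entry for the administered option exactly.
#'
#' @param config A [generator_config()].
#' @return An object of class `bp_cohort`: a list with tibbles `measurements`
#'   (patient_id, day, kind, value), `prescriptions` (patient_id, start_day,
#'   end_day, drug_class), `demographics`, `truth` (patient_id, period_index,
#'   option, future_sbp), `latent` (per-period latent means and regimens), and
#'   `params` (the effect matrix, rho and per-patient latent traits).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "bp_generator_config")) {
    abort("`config` must be created by generator_config().",
          class = "bp_config_error")
  }
  set.seed(config$seed)
  n <- config$n_patients
  period <- config$visit_period
  n_periods <- max(1L, floor(config$horizon_days / period))
  classes <- config$drug_classes
  rtf <- config$rule_trigger_fractions

  race <- sample(c("Black", "White", "Hispanic", "Other"), n, TRUE,
                 prob = c(0.50, 0.26, 0.09, 0.15))
  demo <- tibble(
    patient_id = seq_len(n),
    age = pmin(95, pmax(25, round(rnorm(n, 61, 12)))),
    sex = sample(c("female", "male"), n, TRUE, prob = c(0.525, 0.475)),
    race = race,
    smoker = rbinom(n, 1, 0.28),
    diabetes = rbinom(n, 1, rtf[["diabetes"]]),
    systolic_hf = rbinom(n, 1, rtf[["systolic_hf"]]),
    atherosclerosis = rbinom(n, 1, 0.13),
    pvd = rbinom(n, 1, 0.07)
  )
  setpoint <- rnorm(n, 150, 12) + 0.25 * (demo$age - 61) +
    4 * demo$smoker + 3 * demo$diabetes
  demo$htn_dx <- as.integer(setpoint > 138 | runif(n) < 0.3)
  demo$htn_problem_list <- as.integer(demo$htn_dx == 1 & runif(n) < 0.5)

  # latent lab means; rule fractions force the clinical-rule predicates
  pulse_mean <- rnorm(n, 76, 8)
  low_pulse <- runif(n) < rtf[["low_pulse"]]
  pulse_mean[low_pulse] <- rnorm(sum(low_pulse), 54, 3)
  potassium_mean <- rnorm(n, 4.1, 0.25)
  k_hi <- runif(n) < rtf[["potassium_high"]]
  potassium_mean[k_hi] <- rnorm(sum(k_hi), 4.75, 0.12)
  k_vhi <- runif(n) < rtf[["potassium_very_high"]]
  potassium_mean[k_vhi] <- rnorm(sum(k_vhi), 5.25, 0.15)
  creatinine_mean <- exp(rnorm(n, log(0.95), 0.25))
  cr_hi <- runif(n) < rtf[["creatinine_high"]]
  creatinine_mean[cr_hi] <- rnorm(sum(cr_hi), 2.4, 0.3)
  spo2_mean <- pmin(100, rnorm(n, 97.3, 1.2))
  day0 <- sample(0:45, n, TRUE)

  E <- patient_effects(demo, config$effect_matrix, classes)

  # standard-of-care preference utilities (confounded with outcome covariates)
  base_pref <- c(CCB = 0.6, Thiazide = 0.4, ARB = 0.0, ACEi = 0.8,
                 BetaBlocker = 0.3, LoopDiuretic = -0.8, MRA = -1.8)
  util <- matrix(rep(base_pref[classes], each = n), n, length(classes),
                 dimnames = list(NULL, classes))
  util[, "ACEi"] <- util[, "ACEi"] + 1.5 * demo$diabetes
  util[, "ARB"] <- util[, "ARB"] + 1.2 * demo$diabetes
  util[, "BetaBlocker"] <- util[, "BetaBlocker"] + 1.5 * demo$systolic_hf
  util[, "CCB"] <- util[, "CCB"] + 0.8 * (demo$race == "Black")
  util[, "Thiazide"] <- util[, "Thiazide"] + 0.8 * (demo$race == "Black")

  choose_regimen <- function(i) {
    p <- exp(util[i, ]); p <- p / sum(p)
    k <- if (runif(1) < config$combo_fraction && length(classes) > 1) 2L else 1L
    sample(classes, k, prob = p)
  }

  meas <- vector("list", n)
  rx <- vector("list", n)
  truth <- vector("list", n)
  latent <- vector("list", n)
  meas_sd <- config$noise_sd / 2

  for (i in seq_len(n)) {
    S <- numeric(n_periods)
    S[1] <- setpoint[i] + rnorm(1, 0, 5)
    reg <- vector("list", n_periods)
    eta <- rnorm(n_periods, 0, config$noise_sd)
    treated <- runif(1) < 0.55
    cur <- if (treated) choose_regimen(i) else character(0)
    for (tt in seq_len(n_periods)) {
      if (length(cur) == 0) {
        if (runif(1) < 0.8 * plogis((S[tt] - 148) / 8)) cur <- choose_regimen(i)
      } else if (runif(1) < 0.25) {
        cur <- choose_regimen(i)
      } else if (length(cur) == 1 && S[tt] > 160 && runif(1) < 0.3) {
        extra <- setdiff(classes, cur)
        p <- exp(util[i, extra]); cur <- c(cur, sample(extra, 1, prob = p / sum(p)))
      }
      reg[[tt]] <- cur
      if (tt < n_periods) {
        S[tt + 1] <- config$rho * S[tt] + (1 - config$rho) * setpoint[i] +
          regimen_effect(cur, E[i, ]) + eta[tt]
      }
    }

    # counterfactual next-period mean SBP, sharing the period's noise draw
    if (n_periods >= 2) {
      tts <- seq_len(n_periods - 1)
      drift <- config$rho * S[tts] + (1 - config$rho) * setpoint[i] + eta[tts]
      cf <- lapply(tts, function(tt) {
        opts <- c(setNames(drift[tt] + E[i, classes], classes),
                  current = drift[tt] + regimen_effect(reg[[tt]], E[i, ]))
        tibble(period_index = tt - 1L, option = names(opts),
               future_sbp = unname(opts))
      })
      truth[[i]] <- mutate(bind_rows(cf), patient_id = i)
    }

    # measurement events: SBP/DBP 1-3 times per period, labs ~75% of periods;
    # the very first SBP record sits at day0 so builder periods align
    days_l <- list(); kind_l <- list(); val_l <- list()
    for (tt in seq_len(n_periods)) {
      n_sbp <- 1L + rpois(1, 1)
      offs <- floor(runif(n_sbp, 0, period))
      if (tt == 1L) offs[1] <- 0
      d <- day0[i] + (tt - 1L) * period + offs
      sbp <- S[tt] + rnorm(n_sbp, 0, meas_sd)
      dbp <- 0.55 * S[tt] + 14 + rnorm(n_sbp, 0, meas_sd)
      days_l[[length(days_l) + 1L]] <- c(d, d)
      kind_l[[length(kind_l) + 1L]] <- rep(c("sbp", "dbp"), each = n_sbp)
      val_l[[length(val_l) + 1L]] <- c(sbp, dbp)
      labs <- c(pulse = pulse_mean[i] + rnorm(1, 0, 2),
                potassium = potassium_mean[i] + rnorm(1, 0, 0.08),
                creatinine = pmax(0.3, creatinine_mean[i] + rnorm(1, 0, 0.06)),
                spo2 = pmin(100, spo2_mean[i] + rnorm(1, 0, 0.5)))
      take <- runif(4) < 0.75
      if (any(take)) {
        days_l[[length(days_l) + 1L]] <-
          day0[i] + (tt - 1L) * period + floor(runif(sum(take), 0, period))
        kind_l[[length(kind_l) + 1L]] <- names(labs)[take]
        val_l[[length(val_l) + 1L]] <- unname(labs[take])
      }
    }
    meas[[i]] <- tibble(patient_id = i, day = unlist(days_l),
                        kind = unlist(kind_l), value = unlist(val_l))

    # prescriptions: merge consecutive periods with identical regimens
    labels <- vapply(reg, regimen_label, character(1))
    runs <- rle(labels)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    rx_rows <- list()
    for (r in seq_along(runs$values)) {
      cls <- reg[[starts[r]]]
      if (length(cls) == 0) next
      rx_rows[[length(rx_rows) + 1L]] <- tibble(
        patient_id = i, drug_class = cls,
        start_day = day0[i] + (starts[r] - 1L) * period,
        end_day = day0[i] + ends[r] * period
      )
    }
    rx[[i]] <- if (length(rx_rows)) bind_rows(rx_rows) else NULL
    latent[[i]] <- tibble(patient_id = i, period_index = seq_len(n_periods) - 1L,
                          latent_sbp = S, regimen = labels)
  }

  measurements <- bind_rows(meas)
  # completely-at-random missingness, anchor record always kept
  if (config$missing_fraction > 0) {
    anchor <- measurements$kind == "sbp" &
      measurements$day == day0[measurements$patient_id]
    drop <- runif(nrow(measurements)) < config$missing_fraction & !anchor
    measurements <- measurements[!drop, ]
  }

  cohort <- structure(
    list(
      measurements = measurements,
      prescriptions = bind_rows(rx) %>%
        select("patient_id", "start_day", "end_day", "drug_class"),
      demographics = demo,
      truth = bind_rows(truth) %>%
        select("patient_id", "period_index", "option", "future_sbp"),
      latent = bind_rows(latent),
      params = list(effect_matrix = config$effect_matrix, rho = config$rho,
                    setpoint = setpoint, day0 = day0,
                    visit_period = period, n_periods = n_periods,
                    drug_classes = classes),
      config = config
    ),
    class = "bp_cohort"
  )
  if (config$outlier_fraction > 0) {
    cohort <- contaminate_outcomes(cohort, config$outlier_fraction,
                                   config$outlier_magnitude,
                                   seed = config$seed + 1L)
  }
  cohort
}

#' Corrupt a fraction of SBP measurements with entry-error style outliers
#'
#' Shifts exactly `round(fraction * n)` of the cohort's SBP measurement values
#' by `+magnitude` or `-magnitude` (random sign). The counterfactual truth
#' table is left untouched: outliers corrupt observations, not ground truth.
#'
#' @param cohort A `bp_cohort`.
#' @param fraction Fraction of SBP measurements to corrupt, in `[0, 1)`.
#' @param magnitude Shift magnitude in mmHg.
#' @param seed Integer seed controlling which rows are corrupted.
#' @return The cohort with corrupted `measurements`; the corrupted row indices
#'   are recorded in `attr(cohort$measurements, "corrupted_rows")`.
#' @export
contaminate_outcomes <- function(cohort, fraction, magnitude, seed = 1L) {
  if (fraction < 0 || fraction >= 1) {
    abort("`fraction` must lie in [0, 1).", class = "bp_config_error")
  }
  idx <- which(cohort$measurements$kind == "sbp")
  k <- round(fraction * length(idx))
  if (k > 0) {
    set.seed(seed)
    hit <- sample(idx, k)
    sgn <- sample(c(-1, 1), k, TRUE)
    cohort$measurements$value[hit] <- cohort$measurements$value[hit] +
      sgn * magnitude
    attr(cohort$measurements, "corrupted_rows") <- sort(hit)
  }
  cohort
}

#' Write a synthetic cohort to plain-text CSV files
#'
#' Writes `measurements.csv`, `prescriptions.csv`, `demographics.csv` and
#' `truth.csv` into `dir`.
#'
#' @param cohort A `bp_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(cohort$prescriptions, file.path(dir, "prescriptions.csv"))
  readr::write_csv(cohort$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read cohort CSV files written by [write_cohort()] (or user-supplied files
#' with the same schemas)
#'
#' @param dir Directory holding `measurements.csv`, `prescriptions.csv` and
#'   `demographics.csv`; `truth.csv` is attached when present.
#' @return A `bp_cohort` list (without generator params).
#' @export
read_cohort <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- if (file.exists(p("truth.csv"))) {
    readr::read_csv(p("truth.csv"), show_col_types = FALSE)
  } else NULL
  structure(
    list(measurements = readr::read_csv(p("measurements.csv"), show_col_types = FALSE),
         prescriptions = readr::read_csv(p("prescriptions.csv"), show_col_types = FALSE),
         demographics = readr::read_csv(p("demographics.csv"), show_col_types = FALSE),
         truth = truth),
    class = "bp_cohort"
  )
}

#' @export
print.bp_cohort <- function(x, ...) {
  cat("<bp_cohort> ", nrow(x$demographics), " patients, ",
      nrow(x$measurements), " measurement events, ",
      nrow(x$prescriptions), " prescription intervals\n", sep = "")
  invisible(x)
}
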