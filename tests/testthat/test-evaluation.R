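test_that("percent improvement reproduces hand arithmetic and rejects a zero
           baseline", {
  expect_equal(percent_improvement(-10, -10), 0)
  expect_equal(percent_improvement(-15, -10), 50)
  expect_equal(round(percent_improvement(-14.22, -8.35), 2), 70.30)
  expect_error(percent_improvement(-5, 0), class = "bp_config_error")
})

test_that("per-visit reductions are consistent subtractions and agree with
           the truth table on a noiseless cohort", {
  fx <- make_cohort(n_patients = 60, seed = 41, noise_sd = 0,
                    missing_fraction = 0)
  sp <- split_by_patient(fx$visits, seed = 5)
  schema <- fit_schema(modeling_visits(sp$train))
  models <- fit_outcome_models(sp$train, schema, algorithm = "ols")
  test <- modeling_visits(sp$test)
  panels <- suppressWarnings(
    build_panels(test, models, sp$train, schema, k = 5))
  recs <- recommend(panels, test, policy_config(mode = "deterministic"))
  ev <- evaluate_split(test, panels, recs, fx$cohort$truth)

  expect_equal(ev$model_reduction, ev$yhat_chosen - ev$current_sbp)
  expect_equal(ev$soc_reduction, ev$future_sbp - ev$current_sbp)
  # keeping the current regimen makes the model and current reductions match
  kept <- ev[recs$kept_current, ]
  expect_equal(kept$model_reduction, kept$current_reduction)
  # noiseless: the observed outcome equals the truth current-option entry
  expect_equal(ev$soc_reduction, ev$truth_current_reduction,
               tolerance = 1e-9)

  # a missing panel row is an error naming the visit
  expect_error(evaluate_split(test, panels[panels$visit_id !=
                                             recs$visit_id[1], ], recs),
               recs$visit_id[1], class = "bp_eval_error", fixed = TRUE)
})

test_that("repeated splits with identical seeds give identical reports and
           cover the configured rows", {
  fx <- make_cohort(n_patients = 60, seed = 43)
  r1 <- suppressWarnings(
    repeated_splits(fx$visits, truth = fx$cohort$truth, n_splits = 2,
                    algorithms = c("ols", "cart"), k = 5, seeds = c(7, 8)))
  r2 <- suppressWarnings(
    repeated_splits(fx$visits, truth = fx$cohort$truth, n_splits = 2,
                    algorithms = c("ols", "cart"), k = 5, seeds = c(7, 8)))
  expect_equal(r1$table, r2$table)
  expect_setequal(
    unique(paste(r1$table$algorithm, r1$table$mode)),
    c("ols deterministic", "ols randomized", "cart deterministic",
      "cart randomized", "current_regimen reference",
      "standard_of_care reference"))
  # identical split seeds -> zero dispersion across "different" splits
  r3 <- suppressWarnings(
    repeated_splits(fx$visits, n_splits = 2, algorithms = "ols", k = 5,
                    seeds = c(7, 7)))
  expect_equal(max(abs(r3$table$sd_reduction)), 0, tolerance = 1e-12)
  td <- tidy(r1)
  expect_true(all(c("algorithm", "mode", "mean_reduction") %in% names(td)))
  gl <- glance(r1)
  expect_true(is.finite(gl$pct_improvement_vs_soc))
})

test_that("deprescribing analysis counts the combination-therapy subgroup
           exactly", {
  ev <- tibble::tibble(
    visit_id = as.character(1:6),
    n_active_classes = c(2, 2, 2, 2, 1, 1),
    model_reduction = c(-10, -9, -8, -2, -5, -5),
    soc_reduction = c(-5, -5, -5, -5, -20, -1))
  visits <- tibble::tibble(visit_id = as.character(1:6), age = 60,
                           diabetes = c(1, 1, 0, 0, 0, 0),
                           systolic_hf = 0, atherosclerosis = 0, pvd = 0)
  out <- deprescribing_analysis(ev, visits)
  expect_equal(out$summary$n_subgroup, 4)
  expect_equal(out$summary$n_better, 3) # visits 1-3 beat standard of care
  expect_equal(out$summary$fraction_better_pct, 75)
  expect_equal(out$summary$model_reduction, mean(c(-10, -9, -8, -2)))
  prof <- out$profile
  expect_equal(prof$all_visits[prof$covariate == "diabetes"], 100 * 2 / 6)
})

test_that("the deprescribing fraction is better_count over subgroup size on
           a constructed large fixture", {
  n <- 9196
  set.seed(1)
  better <- sample(n, 7241)
  ev <- tibble::tibble(
    visit_id = as.character(seq_len(n)),
    n_active_classes = 2,
    model_reduction = rep(-8, n),
    soc_reduction = rep(-8.5, n))
  ev$model_reduction[better] <- -14.33
  visits <- tibble::tibble(visit_id = ev$visit_id, age = 65, diabetes = 0,
                           systolic_hf = 0)
  out <- deprescribing_analysis(ev, visits)
  expect_equal(out$summary$n_subgroup, 9196)
  expect_equal(out$summary$n_better, 7241)
  expect_equal(round(out$summary$fraction_better_pct, 2), 78.74)
})

test_that("neighborhood profiles pool the winning neighborhoods and report
           exact percentages", {
  train <- tibble::tibble(
    visit_id = paste0("t", 1:10),
    age = c(60, 62, 64, 66, 68, 70, 72, 74, 76, 78),
    diabetes = c(rep(1, 7), rep(0, 3)),
    male = c(rep(0, 10)))
  test <- tibble::tibble(visit_id = "q1", age = 50, diabetes = 0, male = 1)
  panels <- tibble::tibble(
    visit_id = "q1", option = "ARB", estimate = 130, flagged = FALSE,
    n_neighbors = 10, neighbors = list(paste0("t", 1:10)))
  recs <- tibble::tibble(visit_id = "q1", chosen = "ARB")
  prof <- neighborhood_profiles(recs, panels, train, test,
                                features = c("age", "diabetes", "male"))
  expect_equal(prof$neighborhood[prof$feature == "diabetes"], 70)
  expect_equal(prof$neighborhood[prof$feature == "male"], 0)
  expect_equal(prof$neighborhood[prof$feature == "age"], 69)
  expect_equal(prof$n_pooled, rep(10, 3))
})

test_that("importance aggregation averages per-model normalized magnitudes
           and sums to one", {
  m1 <- bpmenu:::new_bp_regressor("ols", c(a = 1, b = 0), 0, 0)
  m2 <- bpmenu:::new_bp_regressor("ols", c(a = 0, b = -1), 0, 0)
  agg <- aggregate_importance(list(m1, m2))
  expect_equal(agg$score, c(0.5, 0.5))
  expect_equal(sum(agg$score), 1)

  m3 <- bpmenu:::new_bp_regressor("ols", c(a = 3, b = 0), 0, 0)
  agg2 <- aggregate_importance(list(m1, m3))
  expect_equal(agg2$score[agg2$feature == "b"], 0)
  expect_identical(agg2$feature[2], "b") # zero-everywhere feature ranks last

  m4 <- bpmenu:::new_bp_regressor("ols", c(c = 1), 0, 0)
  expect_error(aggregate_importance(list(m1, m4)), class = "bp_config_error")
})

test_that("drug-naive initiation shares exclude previously exposed patients
           and sum to 100", {
  visits <- tibble::tibble(
    visit_id = c("1.0", "1.1", "2.0", "2.1", "3.0"),
    patient_id = c(1, 1, 2, 2, 3),
    period_index = c(0, 1, 0, 1, 0),
    n_active_classes = c(0, 1, 1, 0, 0),
    diabetes = c(0, 0, 0, 0, 1))
  recs <- tibble::tibble(
    visit_id = visits$visit_id,
    chosen = c("Thiazide", "CCB", "ACEi", "ACEi", "CCB"))
  out <- naive_initiation_analysis(recs, visits)
  # eligible: only 1.0 — 1.1 is treated in its own period, patient 2 has
  # prior ACEi exposure at both visits, patient 3 is diabetic
  expect_identical(out$shares$chosen, "Thiazide")
  expect_equal(sum(out$shares$share_pct), 100)
  expect_equal(out$summary$n_naive, 1)
})

test_that("dossier export draws a reproducible sample whose chosen class is
           never excluded", {
  fx <- make_cohort(n_patients = 80, seed = 47)
  sp <- split_by_patient(fx$visits, seed = 9)
  schema <- fit_schema(modeling_visits(sp$train))
  models <- fit_outcome_models(sp$train, schema, algorithm = "ols")
  test <- modeling_visits(sp$test)
  panels <- suppressWarnings(
    build_panels(test, models, sp$train, schema, k = 5))
  recs <- recommend(panels, test, policy_config(mode = "deterministic"))
  n <- min(10, nrow(recs))
  d1 <- export_dossiers(recs, test, panels, n = n, seed = 3)
  d2 <- export_dossiers(recs, test, panels, n = n, seed = 3)
  expect_length(d1, n)
  expect_identical(vapply(d1, `[[`, "", "visit_id"),
                   vapply(d2, `[[`, "", "visit_id"))
  for (d in d1) {
    expect_false(d$chosen %in% d$excluded$option)
    expect_named(d$features)
  }
  expect_error(export_dossiers(recs, test, panels, n = nrow(recs) + 1),
               class = "bp_config_error")
  path <- withr::local_tempfile(fileext = ".json")
  export_dossiers(recs, test, panels, n = n, seed = 3, path = path)
  expect_true(file.exists(path))
  expect_length(jsonlite::read_json(path), n)
})
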