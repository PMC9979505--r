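#' Per-visit SBP reductions under the model, standard of care and current
#' regimen
#'
#' Reductions are negative-signed mmHg changes relative to the visit's
#' current SBP: the model reduction uses the predicted SBP under the chosen
#' option, standard of care uses the observed outcome under the clinicians'
#' actual prescription, and the current-regimen reduction uses the predicted
#' SBP under continuing the active prescription. On synthetic cohorts a truth
#' table adds oracle counterparts: the true counterfactual reduction under
#' the chosen option, under standard of care, and the expected reduction of a
#' uniform draw over the rule-allowed options.
#'
#' @param test_visits Visit table with `current_sbp` and `future_sbp`.
#' @param panels The `bp_panel` for these visits.
#' @param recommendations The `bp_recommendations` for these visits.
#' @param truth Optional generator truth table (`patient_id`, `period_index`,
#'   `option`, `future_sbp`).
#' @return Tibble, one row per recommended visit, with the reduction columns.
#' @export
evaluate_split <- function(test_visits, panels, recommendations, truth = NULL) {
  missing <- setdiff(recommendations$visit_id, panels$visit_id)
  if (length(missing)) {
    abort(paste0("Missing panel rows for visit(s): ",
                 paste(head(missing, 3), collapse = ", ")),
          class = "bp_eval_error")
  }
  ev <- recommendations %>%
    select("visit_id", "chosen", "kept_current", "yhat_chosen",
           "yhat_current", "probabilities") %>%
    dplyr::inner_join(
      select(test_visits, "visit_id", "patient_id", "period_index",
             "current_sbp", "future_sbp", "n_active_classes"),
      by = "visit_id") %>%
    mutate(
      model_reduction = .data$yhat_chosen - .data$current_sbp,
      soc_reduction = .data$future_sbp - .data$current_sbp,
      current_reduction = .data$yhat_current - .data$current_sbp
    )

  if (!is.null(truth)) {
    tr <- truth %>%
      mutate(visit_id = visit_key(.data$patient_id, .data$period_index)) %>%
      select("visit_id", "option", truth_sbp = "future_sbp")
    chosen_truth <- ev %>%
      select("visit_id", "chosen") %>%
      left_join(tr, by = c("visit_id", chosen = "option"))
    ev$truth_model_reduction <- chosen_truth$truth_sbp - ev$current_sbp
    tr_by_visit <- split(tr, tr$visit_id)
    ev$truth_uniform_reduction <- purrr::map2_dbl(
      ev$visit_id, ev$probabilities,
      function(vid, p) {
        t <- tr_by_visit[[vid]]
        if (is.null(t)) return(NA_real_)
        al <- intersect(names(p)[p > 0], t$option)
        if (length(al) == 0) return(NA_real_)
        mean(t$truth_sbp[match(al, t$option)])
      }) - ev$current_sbp
    cur_tr <- tr %>% filter(.data$option == "current")
    ev$truth_current_reduction <-
      cur_tr$truth_sbp[match(ev$visit_id, cur_tr$visit_id)] - ev$current_sbp
  }
  select(ev, -"probabilities")
}

#' Relative improvement of one SBP reduction over another, in percent
#'
#' `(|a| - |b|) / |b| * 100`: by how many percent the magnitude of reduction
#' `a` exceeds the magnitude of reduction `b` (both negative-signed mmHg
#' changes).
#'
#' @param a,b Reductions in mmHg.
#' @return Percent improvement (positive when `a` is the larger reduction).
#' @export
percent_improvement <- function(a, b) {
  if (any(b == 0)) {
    abort("`b` must be nonzero.", class = "bp_config_error")
  }
  (abs(a) - abs(b)) / abs(b) * 100
}

#' Run the full comparison protocol over repeated patient-disjoint splits
#'
#' For each split: partition patients 80/10/10, fit the per-class outcome
#' models for every requested algorithm on the training visits, build
#' counterfactual panels for the test visits, issue recommendations under the
#' deterministic and randomized policies, and measure mean SBP reductions.
#' The report aggregates means and standard deviations across splits in the
#' familiar layout: one row per (algorithm, policy mode) plus the
#' current-regimen and standard-of-care reference rows.
#'
#' @param visits Visit table with outcomes attached.
#' @param truth Optional generator truth table for oracle policy values.
#' @param n_splits Number of random splits (>= 2).
#' @param algorithms Subset of `c("drlr", "ols", "lasso", "cart")`.
#' @param k Neighbors per counterfactual prediction.
#' @param policy Base [policy_config()]; both modes are derived from it.
#' @param seeds Integer seeds, one per split (default `seed + 1:n_splits`).
#' @param seed Base seed used when `seeds` is not given.
#' @return An object of class `bp_report`: `table` (the aggregate layout),
#'   `per_split` (per-split means) and `evaluations` (per-visit reductions of
#'   the last split, for downstream subgroup analyses).
#' @export
repeated_splits <- function(visits, truth = NULL, n_splits = 5,
                            algorithms = c("lasso", "cart", "ols", "drlr"),
                            k = 50, policy = policy_config(),
                            seeds = NULL, seed = 1L) {
  if (n_splits < 2) abort("`n_splits` must be >= 2.", class = "bp_config_error")
  if (is.null(seeds)) seeds <- seed + seq_len(n_splits)
  if (length(seeds) != n_splits) {
    abort("`seeds` must have length `n_splits`.", class = "bp_config_error")
  }
  per_split <- list()
  last_eval <- list()
  for (s in seq_len(n_splits)) {
    sp <- split_by_patient(visits, seed = seeds[s])
    schema <- fit_schema(modeling_visits(sp$train))
    test <- modeling_visits(sp$test)
    ref_done <- FALSE
    for (alg in algorithms) {
      models <- fit_outcome_models(sp$train, schema, algorithm = alg)
      panels <- build_panels(test, models, sp$train, schema, k = k)
      for (mode in c("deterministic", "randomized")) {
        cfg <- policy_config(xi = policy$xi, delta = policy$delta, mode = mode,
                             soft_preference_weight = policy$soft_preference_weight,
                             seed = policy$seed + seeds[s])
        recs <- recommend(panels, test, cfg)
        ev <- evaluate_split(test, panels, recs, truth)
        last_eval[[paste(alg, mode, sep = ".")]] <-
          list(evaluation = ev, panels = panels, recommendations = recs,
               models = models, test = test, train = sp$train,
               schema = schema)
        row <- tibble(
          split = s, algorithm = alg, mode = mode,
          reduction = mean(ev$model_reduction, na.rm = TRUE),
          n_visits = sum(!is.na(ev$model_reduction))
        )
        if (!is.null(truth)) {
          row$truth_reduction <- mean(ev$truth_model_reduction, na.rm = TRUE)
          row$truth_uniform_reduction <-
            mean(ev$truth_uniform_reduction, na.rm = TRUE)
        }
        per_split[[length(per_split) + 1L]] <- row
        if (!ref_done) {
          refs <- tibble(
            split = s,
            algorithm = c("current_regimen", "standard_of_care"),
            mode = "reference",
            reduction = c(mean(ev$current_reduction, na.rm = TRUE),
                          mean(ev$soc_reduction, na.rm = TRUE)),
            n_visits = c(sum(!is.na(ev$current_reduction)),
                         sum(!is.na(ev$soc_reduction)))
          )
          if (!is.null(truth)) {
            refs$truth_reduction <- c(
              mean(ev$truth_current_reduction, na.rm = TRUE),
              mean(ev$soc_reduction, na.rm = TRUE))
            refs$truth_uniform_reduction <- NA_real_
          }
          per_split[[length(per_split) + 1L]] <- refs
          ref_done <- TRUE
        }
      }
    }
  }
  per_split <- bind_rows(per_split)
  table <- per_split %>%
    group_by(.data$algorithm, .data$mode) %>%
    summarise(
      mean_reduction = mean(.data$reduction),
      sd_reduction = sd(.data$reduction),
      across(dplyr::any_of(c("truth_reduction", "truth_uniform_reduction")),
             list(mean = ~ mean(.x))),
      n_visits = sum(.data$n_visits),
      .groups = "drop"
    ) %>%
    arrange(.data$mode, .data$mean_reduction)
  structure(list(table = table, per_split = per_split, last = last_eval,
                 n_splits = n_splits, algorithms = algorithms),
            class = "bp_report")
}

#' @export
print.bp_report <- function(x, ...) {
  cat("<bp_report> mean SBP reduction (mmHg) over", x$n_splits, "splits\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Aggregate table of a repeated-splits report
#' @param x A `bp_report`.
#' @param ... Unused.
#' @export
tidy.bp_report <- function(x, ...) x$table

#' One-row summary of a repeated-splits report (best model vs standard of
#' care, with the percent improvement between them)
#' @param x A `bp_report`.
#' @param ... Unused.
#' @export
glance.bp_report <- function(x, ...) {
  models <- filter(x$table, !.data$algorithm %in%
                     c("current_regimen", "standard_of_care"))
  best <- models[which.min(models$mean_reduction), ]
  soc <- filter(x$table, .data$algorithm == "standard_of_care")
  tibble(best_algorithm = best$algorithm, best_mode = best$mode,
         best_reduction = best$mean_reduction,
         soc_reduction = soc$mean_reduction,
         pct_improvement_vs_soc = percent_improvement(best$mean_reduction,
                                                      soc$mean_reduction))
}

#' Deprescribing subgroup analysis
#'
#' Restricts to test visits on two or more antihypertensive classes, where the
#' model (a monotherapy menu) implicitly deprescribes, and compares the model
#' reduction against standard of care per visit. Returns the subgroup means,
#' the count and share of visits where the model does better, and a covariate
#' profile of the effectively-deprescribed visits next to the all-test-visit
#' baseline.
#'
#' @param evaluation Output of [evaluate_split()].
#' @param test_visits The test visit table (for covariates).
#' @return List with `summary` (one row) and `profile` (covariate table).
#' @export
deprescribing_analysis <- function(evaluation, test_visits) {
  sub <- filter(evaluation, .data$n_active_classes >= 2,
                !is.na(.data$model_reduction), !is.na(.data$soc_reduction))
  better <- filter(sub, .data$model_reduction < .data$soc_reduction)
  covars <- c("age", "diabetes", "systolic_hf", "atherosclerosis", "pvd")
  covars <- intersect(covars, names(test_visits))
  prof_of <- function(ids) {
    v <- filter(test_visits, .data$visit_id %in% ids)
    tibble(covariate = covars,
           value = vapply(covars, function(cv) {
             x <- mean(v[[cv]], na.rm = TRUE)
             if (cv == "age") x else 100 * x
           }, numeric(1), USE.NAMES = FALSE))
  }
  profile <- prof_of(test_visits$visit_id) %>%
    rename(all_visits = "value") %>%
    left_join(rename(prof_of(better$visit_id), deprescribed = "value"),
              by = "covariate")
  list(
    summary = tibble(
      n_subgroup = nrow(sub),
      n_better = nrow(better),
      fraction_better_pct = if (nrow(sub)) 100 * nrow(better) / nrow(sub)
                            else NA_real_,
      model_reduction = mean(sub$model_reduction),
      soc_reduction = mean(sub$soc_reduction),
      pct_improvement = if (nrow(sub) && mean(sub$soc_reduction) != 0)
        percent_improvement(mean(sub$model_reduction), mean(sub$soc_reduction))
      else NA_real_
    ),
    profile = profile
  )
}

#' Neighborhood (affinity) profiles behind each recommended drug class
#'
#' For every drug class, pools the neighbor visits behind the winning option
#' across all recommendations of that class and summarizes their features,
#' next to the test-set baseline. Binary features are reported as
#' percentages.
#'
#' @param recommendations A `bp_recommendations` tibble.
#' @param panels The `bp_panel` the recommendations came from.
#' @param train_visits Training visits (the neighbors live here).
#' @param test_visits Test visits (the baseline).
#' @param features Feature columns to profile.
#' @return Tibble `drug_class`, `feature`, `neighborhood`, `baseline`,
#'   `n_pooled`, of class `bp_profiles`.
#' @export
neighborhood_profiles <- function(recommendations, panels, train_visits,
                                  test_visits,
                                  features = c("age", "male", "race_black",
                                               "race_white", "diabetes",
                                               "systolic_hf")) {
  features <- intersect(features, names(train_visits))
  is_pct <- vapply(features, function(f)
    all(train_visits[[f]] %in% c(0, 1, NA)), logical(1))
  summarise_pool <- function(v, f) {
    x <- mean(v[[f]], na.rm = TRUE)
    if (is_pct[[f]]) 100 * x else x
  }
  win <- recommendations %>%
    filter(.data$chosen %in% bp_drug_classes()) %>%
    select("visit_id", "chosen") %>%
    dplyr::inner_join(as_tibble(panels)[c("visit_id", "option", "neighbors")],
                      by = c("visit_id", chosen = "option"))
  out <- purrr::map_dfr(split(win, win$chosen), function(w) {
    ids <- unlist(w$neighbors)
    if (length(ids) == 0) return(NULL) # direct panels carry no neighborhoods
    pool <- train_visits[match(ids, train_visits$visit_id), ]
    tibble(drug_class = w$chosen[1], feature = features,
           neighborhood = vapply(features, function(f)
             summarise_pool(pool, f), numeric(1), USE.NAMES = FALSE),
           baseline = vapply(features, function(f)
             summarise_pool(test_visits, f), numeric(1), USE.NAMES = FALSE),
           n_pooled = length(ids))
  })
  class(out) <- c("bp_profiles", class(out))
  out
}

#' Aggregate feature importance across the per-class sub-models
#'
#' Each sub-model's absolute coefficient vector is normalized to unit sum and
#' the per-feature scores are averaged over sub-models, so every class
#' contributes equally regardless of its coefficient scale. Scores sum to 1.
#'
#' @param models Output of [fit_outcome_models()] (or a list of
#'   `bp_regressor` objects sharing one schema).
#' @return Tibble `feature`, `score` sorted by decreasing score, of class
#'   `bp_importance`.
#' @export
aggregate_importance <- function(models) {
  fits <- if (is.data.frame(models)) models$model else models
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) abort("No fitted models.", class = "bp_config_error")
  nms <- lapply(fits, function(m) names(m$coefficients))
  if (length(unique(lapply(nms, identity))) > 1 ||
      any(vapply(nms, function(x) !identical(x, nms[[1]]), logical(1)))) {
    abort("Sub-models do not share a feature schema.",
          class = "bp_config_error")
  }
  W <- vapply(fits, function(m) {
    a <- abs(m$coefficients)
    s <- sum(a)
    if (s > 0) a / s else a
  }, numeric(length(nms[[1]])))
  out <- tibble(feature = nms[[1]], score = unname(rowMeans(W))) %>%
    arrange(dplyr::desc(.data$score))
  class(out) <- c("bp_importance", class(out))
  out
}

#' Recommended-class shares among non-diabetic drug-naive visits
#'
#' Restricts the test set to non-diabetic visits whose patient had no
#' antihypertensive class active in the current or any earlier period — the
#' clinical-equipoise treatment-initiation scenario — and reports the share
#' of each recommended class plus the subgroup's mean predicted reduction.
#'
#' @param recommendations A `bp_recommendations` tibble.
#' @param test_visits Test visits (full per-patient period history).
#' @param evaluation Optional [evaluate_split()] output for the subgroup's
#'   mean reduction.
#' @return List with `shares` (tibble `chosen`, `n`, `share_pct`) and
#'   `summary`.
#' @export
naive_initiation_analysis <- function(recommendations, test_visits,
                                      evaluation = NULL) {
  hist <- test_visits %>%
    arrange(.data$patient_id, .data$period_index) %>%
    group_by(.data$patient_id) %>%
    mutate(ever_treated = cumsum(.data$n_active_classes > 0) > 0) %>%
    ungroup()
  naive_ids <- hist$visit_id[!hist$ever_treated & hist$diabetes == 0]
  sub <- filter(recommendations, .data$visit_id %in% naive_ids)
  shares <- sub %>%
    count(.data$chosen, name = "n") %>%
    mutate(share_pct = 100 * .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$n))
  mean_red <- if (!is.null(evaluation)) {
    mean(evaluation$model_reduction[evaluation$visit_id %in% naive_ids],
         na.rm = TRUE)
  } else NA_real_
  list(shares = shares,
       summary = tibble(n_naive = nrow(sub), model_reduction = mean_red))
}

#' Export a seeded sample of recommendation dossiers
#'
#' Draws `n` recommendations and packages each with the visit's features, the
#' full counterfactual panel, the policy probabilities, the rule exclusions
#' and (when supplied) the recommended class's neighborhood profile — the
#' machine-readable analog of a clinician review packet.
#'
#' @param recommendations A `bp_recommendations` tibble.
#' @param test_visits The matching visit table.
#' @param panels The matching `bp_panel`.
#' @param profiles Optional [neighborhood_profiles()] output.
#' @param n Number of dossiers (<= number of recommendations).
#' @param seed Integer seed for the sample.
#' @param path Optional file path; when given, the dossiers are written as
#'   JSON.
#' @return List of dossiers (class `bp_dossiers`), invisibly when `path` is
#'   given.
#' @export
export_dossiers <- function(recommendations, test_visits, panels,
                            profiles = NULL, n = 350, seed = 1L,
                            path = NULL) {
  if (n > nrow(recommendations)) {
    abort(paste0("Requested ", n, " dossiers but only ",
                 nrow(recommendations), " recommendations exist."),
          class = "bp_config_error")
  }
  set.seed(seed)
  take <- sort(sample(nrow(recommendations), n))
  pan <- as_tibble(panels)
  dossiers <- purrr::map(take, function(i) {
    r <- recommendations[i, ]
    v <- test_visits[match(r$visit_id, test_visits$visit_id), ]
    prof <- if (!is.null(profiles)) {
      filter(as_tibble(profiles), .data$drug_class == r$chosen)
    } else NULL
    list(
      visit_id = r$visit_id,
      chosen = r$chosen,
      kept_current = r$kept_current,
      current_regimen = v$regimen[[1]],
      features = as.list(select(
        v, dplyr::any_of(c("age", "sex", "current_sbp", "dbp", "pulse",
                           "potassium", "creatinine", "diabetes",
                           "systolic_hf")))),
      panel = filter(pan, .data$visit_id == r$visit_id) %>%
        select("option", "estimate", "n_neighbors"),
      probabilities = as.list(r$probabilities[[1]]),
      excluded = r$excluded[[1]],
      neighborhood_profile = prof
    )
  })
  class(dossiers) <- "bp_dossiers"
  if (!is.null(path)) {
    jsonlite::write_json(dossiers, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(dossiers))
  }
  dossiers
}
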