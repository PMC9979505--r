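#' Apply the study inclusion criteria to raw event streams
#'
#' A patient enters the cohort when all of the following hold: (i) evidence of
#' hypertension — a recorded diagnosis, a problem-list flag, any SBP above
#' 130 mmHg or any DBP above 90 mmHg; (ii) at least two SBP measurements
#' within some 180-day window; and (iii) at least one prescription among the
#' seven antihypertensive drug classes.
#'
#' @param measurements Tibble with columns `patient_id`, `day`, `kind`,
#'   `value` (`kind` includes `"sbp"` and `"dbp"`).
#' @param prescriptions Tibble with columns `patient_id`, `start_day`,
#'   `end_day`, `drug_class`.
#' @param demographics Tibble with `patient_id` and optional diagnosis flags
#'   `htn_dx`, `htn_problem_list`.
#' @param drug_classes Menu of drug classes counted as antihypertensives.
#' @return Sorted vector of included patient ids.
#' @export
select_cohort <- function(measurements, prescriptions, demographics,
                          drug_classes = bp_drug_classes()) {
  check_events(measurements)
  sbp <- filter(measurements, .data$kind == "sbp")
  dbp <- filter(measurements, .data$kind == "dbp")

  high_bp <- union(unique(sbp$patient_id[sbp$value > 130]),
                   unique(dbp$patient_id[dbp$value > 90]))
  dx <- demographics$patient_id[
    (demographics$htn_dx %||% 0) == 1 | (demographics$htn_problem_list %||% 0) == 1]
  hypertensive <- union(high_bp, dx)

  # >= 2 SBP measurements within a 180-day window: for day-sorted records it
  # suffices that some consecutive pair is <= 180 days apart
  two_in_180 <- sbp %>%
    group_by(.data$patient_id) %>%
    summarise(ok = n() >= 2 && min(diff(sort(.data$day))) <= 180,
              .groups = "drop") %>%
    filter(.data$ok) %>%
    pull("patient_id")

  treated <- unique(prescriptions$patient_id[
    prescriptions$drug_class %in% drug_classes])

  sort(intersect(intersect(hypertensive, two_in_180), treated))
}

check_events <- function(measurements) {
  need <- c("patient_id", "day", "kind", "value")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    abort(paste0("Malformed events: missing column(s) ",
                 paste(miss, collapse = ", "), "."), class = "bp_parse_error")
  }
  bad <- which(!is.finite(measurements$day) | measurements$day < 0)
  if (length(bad)) {
    abort(paste0("Malformed events: negative or non-finite day at row ",
                 bad[1], "."), class = "bp_parse_error")
  }
  invisible(TRUE)
}

# numeric feature columns assembled per visit (before demographics one-hots)
bp_timevarying_features <- c("current_sbp", "sbp_1tau", "sbp_2tau", "dbp",
                             "pulse", "potassium", "creatinine", "spo2")

#' Build the visit-level analysis table from event streams
#'
#' Splits each patient's record into 90-day review periods anchored at the
#' patient's first SBP measurement: period k covers
#' `[first_day + 90k, first_day + 90(k+1))` (half-open, so a measurement
#' exactly on a boundary belongs to the next period). Time-varying
#' measurements are averaged within each period; periods without a
#' measurement carry the last observed value forward within the patient.
#' The regimen of a visit is the set of drug classes whose prescription
#' interval overlaps the period.
#'
#' @param measurements,prescriptions,demographics Event-stream tibbles as in
#'   [select_cohort()].
#' @param patients Optional patient ids to restrict to (e.g., the output of
#'   [select_cohort()]).
#' @param visit_period Period length in days (default 90).
#' @return A tibble with one row per (patient, period): identifiers
#'   (`visit_id`, `patient_id`, `period_index`, `period_start`), the averaged
#'   vitals/labs, SBP history (`sbp_1tau`, `sbp_2tau`), demographics one-hots,
#'   the regimen as a list-column plus `regimen_label` and `n_active_classes`.
#' @export
build_visits <- function(measurements, prescriptions, demographics,
                         patients = NULL, visit_period = 90) {
  check_events(measurements)
  if (!is.null(patients)) {
    measurements <- filter(measurements, .data$patient_id %in% patients)
    prescriptions <- filter(prescriptions, .data$patient_id %in% patients)
  }
  first_day <- measurements %>%
    filter(.data$kind == "sbp") %>%
    group_by(.data$patient_id) %>%
    summarise(first_day = min(.data$day), last_day = max(.data$day),
              .groups = "drop")

  m <- measurements %>%
    dplyr::inner_join(first_day, by = "patient_id") %>%
    filter(.data$day >= .data$first_day) %>%
    mutate(period_index = (.data$day - .data$first_day) %/% visit_period)

  wide <- m %>%
    group_by(.data$patient_id, .data$period_index, .data$kind) %>%
    summarise(value = mean(.data$value), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "kind", values_from = "value")

  grid <- first_day %>%
    mutate(n_periods = (.data$last_day - .data$first_day) %/% visit_period + 1L) %>%
    tidyr::uncount(.data$n_periods, .id = "period_row") %>%
    mutate(period_index = .data$period_row - 1L,
           period_start = .data$first_day + visit_period * .data$period_index) %>%
    select("patient_id", "period_index", "period_start")

  visits <- grid %>%
    left_join(wide, by = c("patient_id", "period_index")) %>%
    rename(current_sbp = "sbp")
  for (v in setdiff(c("dbp", "pulse", "potassium", "creatinine", "spo2"),
                    names(visits))) {
    visits[[v]] <- NA_real_
  }

  visits <- visits %>%
    arrange(.data$patient_id, .data$period_index) %>%
    group_by(.data$patient_id) %>%
    mutate(
      sbp_1tau = dplyr::lag(.data$current_sbp, 1),
      sbp_2tau = dplyr::lag(.data$current_sbp, 2),
      across(all_of(c("dbp", "pulse", "potassium", "creatinine", "spo2",
                      "sbp_1tau", "sbp_2tau")),
             ~ locf(.x))
    ) %>%
    ungroup()

  # regimen: classes whose prescription interval overlaps [start, start + 90)
  visits$regimen <- regimen_for_periods(visits, prescriptions, visit_period)
  visits$regimen_label <- vapply(visits$regimen, regimen_label, character(1))
  visits$n_active_classes <- lengths(visits$regimen)

  demo <- demographics %>%
    mutate(male = as.integer(.data$sex == "male"),
           race_black = as.integer(.data$race == "Black"),
           race_white = as.integer(.data$race == "White"),
           race_hispanic = as.integer(.data$race == "Hispanic")) %>%
    select(all_of(c("patient_id", "age", "male", "race_black", "race_white",
                    "race_hispanic", "smoker", "diabetes", "systolic_hf")),
           dplyr::any_of(c("atherosclerosis", "pvd")))

  visits %>%
    left_join(demo, by = "patient_id") %>%
    mutate(visit_id = visit_key(.data$patient_id, .data$period_index)) %>%
    select("visit_id", dplyr::everything())
}

locf <- function(x) {
  i <- cumsum(!is.na(x))
  out <- x[which(!is.na(x))[pmax(i, 1)]]
  out[i == 0] <- NA
  out
}

regimen_for_periods <- function(visits, prescriptions, visit_period) {
  out <- vector("list", nrow(visits))
  rx_by_pat <- split(prescriptions, prescriptions$patient_id)
  for (r in seq_len(nrow(visits))) {
    rx <- rx_by_pat[[as.character(visits$patient_id[r])]]
    if (is.null(rx)) { out[[r]] <- character(0); next }
    s <- visits$period_start[r]; e <- s + visit_period
    out[[r]] <- sort(unique(rx$drug_class[rx$start_day < e & rx$end_day > s]))
  }
  out
}

#' Attach the future-SBP outcome to each visit
#'
#' The outcome of a visit is the average SBP measured in the window
#' `[period_start + offset, period_start + offset + window)` — by default 90
#' to 180 days after the period start, i.e., the next review period. Visits
#' with no SBP measurement in the window get `future_sbp = NA` and are
#' excluded from modeling by [modeling_visits()].
#'
#' @param visits Output of [build_visits()].
#' @param measurements The measurement event stream.
#' @param offset Days from `period_start` to the start of the outcome window.
#' @param window Width of the outcome window in days.
#' @return `visits` with a `future_sbp` column.
#' @export
attach_outcomes <- function(visits, measurements, offset = 90, window = 90) {
  sbp <- filter(measurements, .data$kind == "sbp")
  sbp_by_pat <- split(sbp, sbp$patient_id)
  y <- vapply(seq_len(nrow(visits)), function(r) {
    s <- visits$period_start[r] + offset
    m <- sbp_by_pat[[as.character(visits$patient_id[r])]]
    if (is.null(m)) return(NA_real_)
    v <- m$value[m$day >= s & m$day < s + window]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  mutate(visits, future_sbp = y)
}

#' Visits usable for model fitting (valid outcome and current SBP)
#' @param visits Output of [attach_outcomes()].
#' @return The filtered tibble.
#' @export
modeling_visits <- function(visits) {
  filter(visits, !is.na(.data$future_sbp), !is.na(.data$current_sbp))
}

#' Patient-disjoint train/validation/test split
#'
#' Partitions patients (never visits) at the given proportions so that no
#' patient contributes rows to more than one set.
#'
#' @param visits Visit table with a `patient_id` column.
#' @param fractions Length-3 proportions summing to 1 (train, validation, test).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return Named list of tibbles `train`, `validation`, `test`.
#' @export
split_by_patient <- function(visits, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3) {
    abort("`fractions` must be three proportions summing to 1.",
          class = "bp_config_error")
  }
  ids <- sort(unique(visits$patient_id))
  if (length(ids) < 3) {
    abort("Need at least 3 patients for a three-way split.",
          class = "bp_config_error")
  }
  set.seed(seed)
  ids <- sample(ids)
  n <- length(ids)
  n_val <- max(1L, round(fractions[2] * n))
  n_test <- max(1L, round(fractions[3] * n))
  n_train <- n - n_val - n_test
  sets <- list(train = ids[seq_len(n_train)],
               validation = ids[n_train + seq_len(n_val)],
               test = ids[n_train + n_val + seq_len(n_test)])
  lapply(sets, function(s) filter(visits, .data$patient_id %in% s))
}

#' Fit a feature schema (names, kinds, standardization) on training visits
#'
#' Numeric features get train-set z-score standardization (constant features
#' fall back to scale 1) and train-set median imputation; binary features are
#' kept on their 0/1 scale. The schema is fit once on training data and then
#' applied unchanged to validation/test visits, so no test-set statistics leak
#' into the metric.
#'
#' @param visits Training visits from [build_visits()].
#' @param numeric_features,binary_features Feature column names by kind;
#'   defaults cover the vitals/labs, SBP history and demographics columns the
#'   builder assembles.
#' @return An object of class `bp_schema`.
#' @export
fit_schema <- function(visits,
                       numeric_features = c(bp_timevarying_features, "age",
                                            "n_active_classes"),
                       binary_features = c("male", "race_black", "race_white",
                                           "race_hispanic", "smoker",
                                           "diabetes", "systolic_hf")) {
  feats <- c(numeric_features, binary_features)
  miss <- setdiff(feats, names(visits))
  if (length(miss)) {
    abort(paste0("Schema features absent from visits: ",
                 paste(miss, collapse = ", ")), class = "bp_config_error")
  }
  if (anyDuplicated(feats)) {
    abort("Feature names must be unique.", class = "bp_config_error")
  }
  tab <- tibble(
    name = feats,
    kind = rep(c("numeric", "binary"),
               c(length(numeric_features), length(binary_features)))
  )
  tab$center <- vapply(tab$name, function(f) {
    if (tab$kind[match(f, tab$name)] == "binary") 0 else
      mean(visits[[f]], na.rm = TRUE)
  }, numeric(1))
  tab$scale <- vapply(tab$name, function(f) {
    if (tab$kind[match(f, tab$name)] == "binary") return(1)
    s <- sd(visits[[f]], na.rm = TRUE)
    if (!is.finite(s) || s <= 0) 1 else s
  }, numeric(1))
  tab$impute <- vapply(tab$name, function(f) {
    v <- median(visits[[f]], na.rm = TRUE)
    if (!is.finite(v)) 0 else v
  }, numeric(1))
  structure(list(features = tab), class = "bp_schema")
}

#' @export
print.bp_schema <- function(x, ...) {
  cat("<bp_schema> ", nrow(x$features), " features (",
      sum(x$features$kind == "numeric"), " numeric, ",
      sum(x$features$kind == "binary"), " binary)\n", sep = "")
  invisible(x)
}

#' Assemble the standardized feature matrix for a set of visits
#'
#' Imputes missing values with the schema's training medians and applies the
#' schema's centering/scaling.
#'
#' @param visits A visit table.
#' @param schema A [fit_schema()] object.
#' @return Numeric matrix, one row per visit, with `visit_id` rownames.
#' @export
build_features <- function(visits, schema) {
  tab <- schema$features
  X <- matrix(NA_real_, nrow(visits), nrow(tab),
              dimnames = list(visits$visit_id, tab$name))
  for (j in seq_len(nrow(tab))) {
    v <- visits[[tab$name[j]]]
    v[is.na(v)] <- tab$impute[j]
    X[, j] <- (v - tab$center[j]) / tab$scale[j]
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
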