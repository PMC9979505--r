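# shared fixtures, built in code

# small default cohort with outcomes attached; memoised per (n, seed, ...)
.cohort_cache <- new.env(parent = emptyenv())

make_cohort <- function(n_patients = 120, seed = 42, ...) {
  key <- paste(n_patients, seed, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- generator_config(n_patients = n_patients, seed = seed, ...)
  cohort <- generate_cohort(cfg)
  visits <- build_visits(cohort$measurements, cohort$prescriptions,
                         cohort$demographics)
  visits <- attach_outcomes(visits, cohort$measurements)
  out <- list(cohort = cohort, visits = visits, config = cfg)
  .cohort_cache[[key]] <- out
  out
}

# linear regression test-bed: y = b0 + X beta + noise, optional outliers
make_linear <- function(n, p, beta = NULL, b0 = 3, noise = 1,
                        outlier_fraction = 0, outlier_magnitude = 50,
                        seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", seq_len(p))))
  if (is.null(beta)) beta <- rnorm(p, 0, 2)
  y <- b0 + drop(X %*% beta) + rnorm(n, 0, noise)
  if (outlier_fraction > 0) {
    k <- round(outlier_fraction * n)
    hit <- sample(n, k)
    y[hit] <- y[hit] + outlier_magnitude * sample(c(-1, 1), k, TRUE)
  }
  list(X = X, y = y, beta = beta, b0 = b0)
}

# independent least-absolute-deviations oracle: LP via scipy linprog (HiGHS)
lad_lp_oracle <- function(X, y) {
  script <- file.path(test_path("..", ".."), "inst", "oracles", "lad_lp.py")
  if (!file.exists(script)) {
    script <- system.file("oracles", "lad_lp.py", package = "bpmenu")
  }
  inp <- jsonlite::toJSON(list(X = X, y = y), digits = NA)
  out <- suppressWarnings(system2("python", shQuote(script), stdout = TRUE,
                                  stderr = FALSE, input = inp))
  if (length(out) == 0) return(NULL)
  res <- jsonlite::fromJSON(paste(out, collapse = ""))
  if (!identical(res$status, 0L) && !identical(res$status, 0)) return(NULL)
  list(theta = res$theta, obj = res$obj)
}

# toy event stream used by the timeline worked examples
toy_measurements <- function() {
  tibble::tibble(
    patient_id = 1L,
    day = c(10, 50, 130),
    kind = "sbp",
    value = c(150, 140, 135)
  )
}

toy_prescriptions <- function() {
  tibble::tibble(patient_id = 1L, start_day = 10, end_day = 190,
                 drug_class = "Thiazide")
}

toy_demographics <- function() {
  tibble::tibble(patient_id = 1L, age = 60, sex = "female", race = "Black",
                 smoker = 0L, diabetes = 0L, systolic_hf = 0L,
                 htn_dx = 1L, htn_problem_list = 0L)
}
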