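#' Coefficient-weighted distance between two standardized feature vectors
#'
#' `sqrt(sum((x - z)^2 * beta^2))`: each feature's squared difference is
#' weighted by the squared regression coefficient it received in the
#' per-class outcome model, so features that predict next-period SBP dominate
#' the notion of patient similarity. With all-ones weights this is ordinary
#' Euclidean distance.
#'
#' @param x,z Numeric feature vectors of equal length.
#' @param beta Coefficient vector of the same length.
#' @return A non-negative scalar.
#' @export
weighted_distance <- function(x, z, beta) {
  if (length(x) != length(z) || length(x) != length(beta)) {
    abort("`x`, `z` and `beta` must have the same length.",
          class = "bp_config_error")
  }
  sqrt(sum((x - z)^2 * beta^2))
}

# all pairwise weighted distances: queries (rows of Q) vs pool (rows of P)
weighted_cross_distances <- function(Q, P, beta) {
  w <- beta^2
  Qw <- sweep(Q, 2, w, `*`)
  q2 <- rowSums(Qw * Q)
  p2 <- rowSums(sweep(P, 2, w, `*`) * P)
  d2 <- outer(q2, p2, `+`) - 2 * Qw %*% t(P)
  sqrt(pmax(d2, 0))
}

#' K-nearest-neighbor counterfactual prediction for one query
#'
#' Finds the `k` training visits closest to `x` under [weighted_distance()]
#' and returns the unweighted mean of their observed future-SBP outcomes.
#' Distance ties are broken by ascending pool visit id. If the pool holds
#' fewer than `k` visits, all of them are used and the result is flagged.
#'
#' @param x Standardized query feature vector.
#' @param pool_X Standardized feature matrix of the class's training visits
#'   (rownames are visit ids).
#' @param pool_y Their observed future-SBP outcomes.
#' @param beta Metric coefficients.
#' @param k Number of neighbors (>= 1).
#' @param exclude Pool visit ids to exclude (e.g., the query patient's own
#'   visits).
#' @return List with `estimate`, `neighbors` (visit ids), `flagged`.
#' @export
knn_predict <- function(x, pool_X, pool_y, beta, k = 50, exclude = NULL) {
  if (k < 1) abort("`k` must be >= 1.", class = "bp_config_error")
  keep <- if (is.null(exclude)) seq_len(nrow(pool_X)) else
    which(!(rownames(pool_X) %in% exclude))
  if (length(keep) == 0) {
    abort("Empty neighbor pool after exclusions.", class = "bp_empty_pool")
  }
  P <- pool_X[keep, , drop = FALSE]
  d <- sqrt(colSums((t(P) - x)^2 * beta^2))
  ord <- order(d, rownames(P))
  take <- ord[seq_len(min(k, length(ord)))]
  list(estimate = mean(pool_y[keep][take]),
       neighbors = rownames(P)[take],
       flagged = length(keep) < k)
}

# vectorized neighbor search for many queries against one pool
knn_block <- function(Q, pool_X, pool_y, pool_patients, query_patients,
                      beta, k) {
  D <- weighted_cross_distances(Q, pool_X, beta)
  # leakage guard: no neighbor from the query's own patient
  for (i in seq_len(nrow(Q))) {
    D[i, pool_patients == query_patients[i]] <- Inf
  }
  pool_ids <- rownames(pool_X)
  id_rank <- order(pool_ids)
  est <- numeric(nrow(Q)); nn <- vector("list", nrow(Q))
  flagged <- logical(nrow(Q))
  for (i in seq_len(nrow(Q))) {
    d <- D[i, ]
    avail <- which(is.finite(d))
    if (length(avail) == 0) { est[i] <- NA_real_; flagged[i] <- TRUE; next }
    ord <- avail[order(d[avail], pool_ids[avail])]
    take <- ord[seq_len(min(k, length(ord)))]
    est[i] <- mean(pool_y[take])
    nn[[i]] <- pool_ids[take]
    flagged[i] <- length(avail) < k
  }
  list(estimate = est, neighbors = nn, flagged = flagged)
}

#' Predict next-period SBP for every menu option of every visit
#'
#' For each of the seven monotherapy options, the neighbor pool is the set of
#' training visits whose regimen contains that class; the per-class model's
#' coefficients define the metric. The current-regimen option of a visit uses
#' the pool of training visits with exactly the same regimen set (metric from
#' the strongest-coefficient constituent class model, or the pooled mean for
#' untreated regimens); when fewer than `k` exact-regimen visits exist, the
#' pool falls back to the union of the constituent classes' pools and the row
#' is flagged. A visit on monotherapy needs no separate current-regimen row —
#' its current option coincides with that class's option. Visits never draw
#' neighbors from their own patient.
#'
#' Regression-only algorithms (lasso, CART) predict each option directly
#' from their per-class fit instead of through neighbor search; with
#' `prediction = "auto"` the engine follows the algorithm the models were
#' fitted with. Direct panels carry empty neighbor sets; their
#' current-regimen option for combination visits averages the constituent
#' class predictions, and for untreated visits uses the mean outcome of
#' untreated training visits.
#'
#' @param visits Query visit table (features + `regimen`).
#' @param models Output of [fit_outcome_models()].
#' @param train_visits Training visits supplying the neighbor pools.
#' @param schema A [fit_schema()] object.
#' @param k Neighbors per prediction.
#' @param prediction `"auto"`, `"knn"` or `"direct"`.
#' @return A tibble of class `bp_panel`: one row per (visit, option) with
#'   `estimate`, `n_neighbors`, `flagged` and a `neighbors` list-column.
#' @export
build_panels <- function(visits, models, train_visits, schema, k = 50,
                         prediction = c("auto", "knn", "direct")) {
  prediction <- match.arg(prediction)
  if (prediction == "auto") {
    alg <- attr(models, "algorithm") %||% "drlr"
    prediction <- if (alg %in% c("lasso", "cart")) "direct" else "knn"
  }
  train_visits <- modeling_visits(train_visits)
  Q <- build_features(visits, schema)
  if (prediction == "direct") {
    return(build_panels_direct(visits, Q, models, train_visits))
  }
  classes <- models$drug_class
  out <- vector("list", length(classes) + 1L)

  pool_cache <- list()
  class_pool <- function(cl) {
    if (!is.null(pool_cache[[cl]])) return(pool_cache[[cl]])
    sub <- train_visits[purrr::map_lgl(train_visits$regimen, ~ cl %in% .x), ]
    res <- list(X = build_features(sub, schema), y = sub$future_sbp,
                patients = sub$patient_id)
    pool_cache[[cl]] <<- res
    res
  }

  for (j in seq_along(classes)) {
    cl <- classes[j]
    m <- models$model[[j]]
    if (is.null(m)) next
    pool <- class_pool(cl)
    if (nrow(pool$X) == 0) {
      warn(paste0("Empty training pool for option ", cl, "; option omitted."))
      next
    }
    blk <- knn_block(Q, pool$X, pool$y, pool$patients, visits$patient_id,
                     m$coefficients, k)
    out[[j]] <- tibble(visit_id = visits$visit_id, option = cl,
                       estimate = blk$estimate, flagged = blk$flagged,
                       n_neighbors = lengths(blk$neighbors),
                       neighbors = blk$neighbors)
  }

  # current-regimen option for visits not on monotherapy (combos / untreated)
  cur_rows <- which(lengths(visits$regimen) != 1L)
  if (length(cur_rows)) {
    train_labels <- vapply(train_visits$regimen, regimen_label, character(1))
    cur <- visits[cur_rows, ]
    cur_l <- vapply(cur$regimen, regimen_label, character(1))
    res <- vector("list", length(cur_rows))
    for (g in split(seq_along(cur_rows), cur_l)) {
      lbl <- cur_l[g[1]]
      reg <- cur$regimen[[g[1]]]
      exact <- which(train_labels == lbl)
      fellback <- length(exact) < k && length(reg) > 0
      idx <- if (fellback) {
        which(purrr::map_lgl(train_visits$regimen,
                             ~ length(intersect(.x, reg)) > 0))
      } else exact
      if (length(idx) == 0) {
        warn(paste0("Empty training pool for current regimen '", lbl,
                    "'; option omitted."))
        next
      }
      beta <- current_metric(reg, models)
      blk <- knn_block(Q[cur_rows[g], , drop = FALSE],
                       build_features(train_visits[idx, ], schema),
                       train_visits$future_sbp[idx],
                       train_visits$patient_id[idx],
                       cur$patient_id[g], beta, k)
      res[g] <- purrr::pmap(
        list(cur$visit_id[g], blk$estimate, blk$flagged | fellback,
             blk$neighbors),
        function(v, e, f, nn) tibble(visit_id = v, option = "current",
                                     estimate = e, flagged = f,
                                     n_neighbors = length(nn),
                                     neighbors = list(nn)))
    }
    out[[length(classes) + 1L]] <- bind_rows(res)
  }

  panel <- bind_rows(out) %>% filter(!is.na(.data$estimate))
  class(panel) <- c("bp_panel", class(panel))
  panel
}

# direct-prediction panels: every option scored by its per-class fit
build_panels_direct <- function(visits, Q, models, train_visits) {
  out <- vector("list", nrow(models) + 1L)
  for (j in seq_len(nrow(models))) {
    m <- models$model[[j]]
    if (is.null(m)) next
    out[[j]] <- tibble(visit_id = visits$visit_id,
                       option = models$drug_class[j],
                       estimate = predict(m, Q), flagged = FALSE,
                       n_neighbors = 0L,
                       neighbors = list(character(0)))
  }
  cur_rows <- which(lengths(visits$regimen) != 1L)
  if (length(cur_rows)) {
    untreated_mean <- mean(train_visits$future_sbp[
      lengths(train_visits$regimen) == 0])
    est <- vapply(cur_rows, function(r) {
      reg <- visits$regimen[[r]]
      if (length(reg) == 0) return(untreated_mean)
      fits <- models$model[match(reg, models$drug_class)]
      fits <- fits[!vapply(fits, is.null, logical(1))]
      if (length(fits) == 0) return(NA_real_)
      mean(vapply(fits, function(m)
        predict(m, Q[r, , drop = FALSE]), numeric(1)))
    }, numeric(1))
    out[[nrow(models) + 1L]] <- tibble(
      visit_id = visits$visit_id[cur_rows], option = "current",
      estimate = est, flagged = FALSE, n_neighbors = 0L,
      neighbors = list(character(0)))
  }
  panel <- bind_rows(out) %>% filter(!is.na(.data$estimate))
  class(panel) <- c("bp_panel", class(panel))
  panel
}

# metric for the current-regimen option: strongest constituent class model;
# untreated regimens fall back to an unweighted (Euclidean) metric
current_metric <- function(reg, models) {
  p <- length(models$model[[which(!vapply(models$model, is.null,
                                          logical(1)))[1]]]$coefficients)
  if (length(reg) == 0) return(rep(1, p))
  cand <- models$model[match(reg, models$drug_class)]
  cand <- cand[!vapply(cand, is.null, logical(1))]
  if (length(cand) == 0) return(rep(1, p))
  norms <- vapply(cand, function(m) sum(abs(m$coefficients)), numeric(1))
  cand[[which.max(norms)]]$coefficients
}

#' Look up a visit's current-regimen prediction from a panel
#'
#' For monotherapy visits this is the prediction of the class option itself;
#' for combination or untreated visits it is the `"current"` option row.
#'
#' @param panels A `bp_panel`.
#' @param visits The visit table the panel was built for.
#' @return Tibble `visit_id`, `current_estimate`.
#' @export
current_predictions <- function(panels, visits) {
  lbl <- tibble(visit_id = visits$visit_id,
                mono = if_else(lengths(visits$regimen) == 1L,
                               vapply(visits$regimen, function(r)
                                 if (length(r) == 1) r else NA_character_,
                                 character(1)),
                               "current"))
  panels %>%
    dplyr::inner_join(lbl, by = "visit_id") %>%
    filter(.data$option == .data$mono) %>%
    select("visit_id", current_estimate = "estimate")
}
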