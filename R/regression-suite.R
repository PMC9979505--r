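new_bp_regressor <- function(algorithm, coefficients, intercept, train_loss,
                             hyperparams = list(), drug_class = NA_character_,
                             fit = NULL) {
  structure(
    list(algorithm = algorithm, coefficients = coefficients,
         intercept = intercept, train_loss = train_loss,
         hyperparams = hyperparams, drug_class = drug_class, fit = fit),
    class = "bp_regressor"
  )
}

#' @export
print.bp_regressor <- function(x, ...) {
  cat("<bp_regressor> ", x$algorithm,
      if (!is.na(x$drug_class)) paste0(" [", x$drug_class, "]"),
      ": p = ", length(x$coefficients),
      ", train loss = ", signif(x$train_loss, 5), "\n", sep = "")
  invisible(x)
}

#' @export
predict.bp_regressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$algorithm == "cart") {
    df <- as.data.frame(X)
    names(df) <- names(object$coefficients)
    return(unname(predict(object$fit, df)))
  }
  unname(drop(X %*% object$coefficients) + object$intercept)
}

#' Broom-style coefficient table for a fitted per-class regressor
#' @param x A `bp_regressor`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` and the metric weight `abs(estimate)`.
#' @export
tidy.bp_regressor <- function(x, ...) {
  tibble(term = names(x$coefficients) %||% paste0("x", seq_along(x$coefficients)),
         estimate = unname(x$coefficients),
         weight = abs(unname(x$coefficients)))
}

#' One-row model summary for a fitted per-class regressor
#' @param x A `bp_regressor`.
#' @param ... Unused.
#' @export
glance.bp_regressor <- function(x, ...) {
  tibble(algorithm = x$algorithm, drug_class = x$drug_class,
         p = length(x$coefficients), intercept = x$intercept,
         train_loss = x$train_loss)
}

as_xy <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) {
    abort("`X` and `y` have incompatible sizes.", class = "bp_config_error")
  }
  list(X = X, y = as.numeric(y))
}

#' Ordinary least squares outcome regression
#'
#' Minimizes the mean squared residual of `y ~ X` with an intercept. With a
#' rank-deficient design, a small ridge fallback is engaged when
#' `ridge_fallback = TRUE`; otherwise the collinear columns are named in the
#' error.
#'
#' @param X Feature matrix (visits x features).
#' @param y Outcome vector (next-period mean SBP, mmHg).
#' @param drug_class Optional class label carried on the fit.
#' @param ridge_fallback Engage a 1e-8 ridge on rank deficiency.
#' @return A `bp_regressor`.
#' @export
fit_ols <- function(X, y, drug_class = NA_character_, ridge_fallback = TRUE) {
  d <- as_xy(X, y)
  Xa <- cbind(`(Intercept)` = 1, d$X)
  qr_ <- qr(Xa)
  if (qr_$rank < ncol(Xa)) {
    if (!ridge_fallback) {
      drop_cols <- colnames(Xa)[qr_$pivot[seq(qr_$rank + 1, ncol(Xa))]]
      abort(paste0("Rank-deficient design; collinear column(s): ",
                   paste(drop_cols, collapse = ", ")), class = "bp_fit_error")
    }
    th <- solve(crossprod(Xa) + 1e-8 * diag(ncol(Xa)), crossprod(Xa, d$y))
    th <- drop(th)
  } else {
    th <- qr.coef(qr_, d$y)
  }
  beta <- th[-1]
  r <- d$y - drop(Xa %*% th)
  new_bp_regressor("ols", beta, unname(th[1]), mean(r^2),
                   drug_class = drug_class)
}

#' L1-penalized (lasso) outcome regression
#'
#' Minimizes `mean((y - b0 - X b)^2) + lambda * sum(|b|)` via glmnet (the
#' glmnet penalty is `lambda/2` under its 1/(2n) loss scaling). When `lambda`
#' is `NULL` and validation data are supplied, the penalty is chosen by grid
#' search on validation MSE.
#'
#' @inheritParams fit_ols
#' @param lambda Non-negative penalty, or `NULL` to select on validation data.
#' @param validation Optional `list(X =, y =)` used to select `lambda`.
#' @param lambda_grid Candidate penalties for selection.
#' @return A `bp_regressor`.
#' @export
fit_lasso <- function(X, y, lambda = NULL, drug_class = NA_character_,
                      validation = NULL,
                      lambda_grid = 10^seq(-3, 1, length.out = 9)) {
  d <- as_xy(X, y)
  if (!is.null(lambda) && lambda < 0) {
    abort("`lambda` must be >= 0.", class = "bp_config_error")
  }
  if (is.null(lambda)) {
    lambda <- if (is.null(validation)) 0.1 else {
      errs <- vapply(lambda_grid, function(l) {
        m <- lasso_once(d$X, d$y, l)
        mean((validation$y - predict(m, validation$X))^2)
      }, numeric(1))
      lambda_grid[which.min(errs)]
    }
  }
  m <- lasso_once(d$X, d$y, lambda, drug_class)
  m
}

lasso_once <- function(X, y, lambda, drug_class = NA_character_) {
  lg <- lambda / 2
  if (ncol(X) == 1) {
    # single predictor: exact soft-threshold solution of
    # mean((y - b0 - x b)^2) + lambda |b|
    xc <- X[, 1] - mean(X[, 1]); yc <- y - mean(y)
    m2 <- mean(xc^2)
    b <- if (m2 > 0) {
      rho <- mean(xc * yc)
      sign(rho) * max(abs(rho) - lambda / 2, 0) / m2
    } else 0
    b0 <- mean(y) - b * mean(X[, 1])
    r <- y - b0 - X[, 1] * b
    return(new_bp_regressor("lasso", setNames(b, colnames(X)), b0,
                            mean(r^2) + lambda * abs(b),
                            hyperparams = list(lambda = lambda),
                            drug_class = drug_class))
  }
  # glmnet wants a decreasing path; warm-start down to the target penalty
  path <- sort(unique(c(max(lg * 100, 1), lg * c(100, 10, 3, 1))),
               decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = path, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12)
  co <- as.numeric(glmnet::coef.glmnet(fit, s = lg, exact = TRUE, x = X, y = y))
  beta <- setNames(co[-1], colnames(X))
  b0 <- co[1]
  r <- y - drop(X %*% beta) - b0
  new_bp_regressor("lasso", beta, b0, mean(r^2) + lambda * sum(abs(beta)),
                   hyperparams = list(lambda = lambda), drug_class = drug_class)
}

#' Regression-tree outcome model with variance-reduction importances
#'
#' Fits a depth-limited CART via rpart (variance-reduction splitting,
#' prediction = leaf mean). Because a tree has no coefficient vector, the
#' slot that downstream code reads as "coefficients" holds the per-feature
#' total deviance (variance x n) reduction over the tree's primary splits —
#' a non-negative surrogate importance usable as metric weights.
#'
#' @inheritParams fit_ols
#' @param depth Maximum tree depth (>= 1).
#' @param minbucket Minimum observations in a leaf.
#' @return A `bp_regressor` with the rpart fit attached.
#' @export
fit_cart <- function(X, y, depth = 5, drug_class = NA_character_,
                     minbucket = 5) {
  if (depth < 1) abort("`depth` must be >= 1.", class = "bp_config_error")
  d <- as_xy(X, y)
  df <- as.data.frame(d$X)
  df$.y <- d$y
  fit <- rpart::rpart(
    .y ~ ., data = df, method = "anova",
    control = rpart::rpart.control(maxdepth = depth, cp = 0, xval = 0,
                                   minsplit = max(2 * minbucket, 4),
                                   minbucket = minbucket, maxsurrogate = 0,
                                   maxcompete = 0)
  )
  imp <- cart_importance(fit, colnames(d$X))
  r <- d$y - unname(predict(fit, df))
  new_bp_regressor("cart", imp, mean(d$y), mean(r^2),
                   hyperparams = list(depth = depth), drug_class = drug_class,
                   fit = fit)
}

# total deviance reduction credited to each feature over primary splits;
# children of node k in rpart's frame are nodes 2k and 2k+1
cart_importance <- function(fit, feature_names) {
  imp <- setNames(numeric(length(feature_names)), feature_names)
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  for (i in which(fr$var != "<leaf>")) {
    k <- nodes[i]
    l <- match(2L * k, nodes); rgt <- match(2L * k + 1L, nodes)
    gain <- fr$dev[i] - fr$dev[l] - fr$dev[rgt]
    v <- as.character(fr$var[i])
    imp[v] <- imp[v] + gain
  }
  imp
}

#' Distributionally robust linear regression (Wasserstein-DRO absolute loss)
#'
#' Fits `min_{b0, b} mean(|y - b0 - X b|) + eps * ||(-b, 1)||_dual`, the
#' regularized equivalent of absolute-loss regression hedged over a
#' Wasserstein ball of radius `eps` around the empirical distribution. With
#' the default l2 ground metric the dual norm is `sqrt(1 + ||b||^2)`;
#' `dual_norm = "linf"` (ground l1) gives `max(1, max|b|)` and
#' `dual_norm = "l1"` (ground linf) gives `1 + sum|b|`. The intercept is
#' unpenalized. At `eps = 0` this is least absolute deviations, whose optimum
#' interpolates at least p+1 observations; the solver runs a smoothed
#' continuation (BFGS on `sqrt(r^2 + mu^2)` with `mu` driven to 1e-8) and, at
#' `eps = 0`, polishes by enumerating interpolating subsets among the
#' smallest residuals, which recovers the exact LP optimum.
#'
#' @inheritParams fit_ols
#' @param eps Ambiguity radius (>= 0), or `NULL` to select on validation data
#'   by mean absolute error.
#' @param dual_norm One of `"l2"`, `"linf"`, `"l1"`.
#' @param validation Optional `list(X =, y =)` for selecting `eps`.
#' @param eps_grid Candidate radii for selection.
#' @return A `bp_regressor` with the attained objective in `train_loss`.
#' @export
fit_drlr <- function(X, y, eps = NULL, drug_class = NA_character_,
                     dual_norm = c("l2", "linf", "l1"), validation = NULL,
                     eps_grid = c(0, 0.001, 0.01, 0.1)) {
  dual_norm <- match.arg(dual_norm)
  d <- as_xy(X, y)
  if (!is.null(eps) && eps < 0) {
    abort("`eps` must be >= 0.", class = "bp_config_error")
  }
  if (is.null(eps)) {
    eps <- if (is.null(validation)) 0.01 else {
      errs <- vapply(eps_grid, function(e) {
        m <- drlr_solve(d$X, d$y, e, dual_norm)
        mean(abs(validation$y - (drop(validation$X %*% m$beta) + m$b0)))
      }, numeric(1))
      eps_grid[which.min(errs)]
    }
  }
  sol <- drlr_solve(d$X, d$y, eps, dual_norm)
  new_bp_regressor("drlr", setNames(sol$beta, colnames(d$X)), sol$b0, sol$obj,
                   hyperparams = list(eps = eps, dual_norm = dual_norm),
                   drug_class = drug_class)
}

drlr_penalty <- function(b, dual_norm) {
  switch(dual_norm,
         l2 = sqrt(1 + sum(b^2)),
         linf = max(1, if (length(b)) max(abs(b)) else 0),
         l1 = 1 + sum(abs(b)))
}

drlr_objective <- function(theta, X, y, eps, dual_norm) {
  r <- y - theta[1] - if (ncol(X)) drop(X %*% theta[-1]) else 0
  mean(abs(r)) + eps * drlr_penalty(theta[-1], dual_norm)
}

drlr_solve <- function(X, y, eps, dual_norm = "l2", mu_final = 1e-8) {
  n <- nrow(X); p <- ncol(X)
  # smoothed objective: |r| ~ sqrt(r^2 + mu^2); l1/linf penalties smoothed
  # the same way so BFGS applies for every dual norm
  sabs <- function(v, mu) sqrt(v^2 + mu^2)
  obj <- function(theta, mu) {
    b <- theta[-1]
    r <- y - theta[1] - if (p) drop(X %*% b) else 0
    pen <- switch(dual_norm,
                  l2 = sqrt(1 + sum(b^2)),
                  linf = max(1, if (p) max(sabs(b, mu)) else 0),
                  l1 = 1 + sum(sabs(b, mu)))
    mean(sabs(r, mu)) + eps * pen
  }
  grad <- function(theta, mu) {
    b <- theta[-1]
    r <- y - theta[1] - if (p) drop(X %*% b) else 0
    s <- r / sabs(r, mu)
    g0 <- -mean(s)
    if (!p) return(g0)
    gb <- -drop(crossprod(X, s)) / n
    gpen <- switch(dual_norm,
                   l2 = b / sqrt(1 + sum(b^2)),
                   linf = {
                     sm <- sabs(b, mu)
                     g <- numeric(p)
                     if (max(sm) > 1) { j <- which.max(sm); g[j] <- b[j] / sm[j] }
                     g
                   },
                   l1 = b / sabs(b, mu))
    c(g0, gb + eps * gpen)
  }
  theta <- c(if (n) median(y) else 0, rep(0, p))
  if (p && n > p + 1) {
    ols <- tryCatch(qr.coef(qr(cbind(1, X)), y), error = function(e) NULL)
    if (!is.null(ols) && !anyNA(ols)) theta <- unname(ols)
  }
  mu <- max(sd(y), 1, na.rm = TRUE)
  repeat {
    o <- optim(theta, obj, grad, mu = mu, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    theta <- o$par
    if (mu <= mu_final) break
    mu <- mu / 10
  }
  best <- theta
  bobj <- drlr_objective(theta, X, y, eps, dual_norm)
  if (eps == 0 && n >= p + 1) {
    pol <- drlr_polish(X, y, theta)
    if (!is.null(pol) && pol$obj < bobj) { best <- pol$theta; bobj <- pol$obj }
  }
  list(b0 = best[1], beta = best[-1], obj = bobj)
}

# an optimal LAD fit interpolates >= p+1 points: enumerate interpolating
# subsets among the smallest absolute residuals of the smoothed solution
drlr_polish <- function(X, y, theta, pool_extra = 2L) {
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  r <- y - drop(Xa %*% theta)
  m <- min(n, 2L * (p + 1L) + pool_extra)
  cand <- order(abs(r))[seq_len(m)]
  if (m < p + 1) return(NULL)
  combs <- combn(cand, p + 1L)
  best <- NULL; bobj <- Inf
  for (j in seq_len(ncol(combs))) {
    S <- combs[, j]
    th <- tryCatch(solve(Xa[S, , drop = FALSE], y[S]), error = function(e) NULL)
    if (is.null(th) || anyNA(th)) next
    ob <- mean(abs(y - drop(Xa %*% th)))
    if (ob < bobj) { bobj <- ob; best <- th }
  }
  if (is.null(best)) NULL else list(theta = best, obj = bobj)
}

#' Fit one outcome regression per drug class
#'
#' For each class on the menu, the training rows are the visits whose active
#' regimen contains that class (so combination-therapy visits contribute to
#' every constituent class sub-model) and that carry a valid outcome.
#'
#' @param train_visits Training visit table (see [attach_outcomes()]).
#' @param schema A [fit_schema()] object.
#' @param algorithm One of `"drlr"`, `"ols"`, `"lasso"`, `"cart"`.
#' @param classes Drug classes to fit.
#' @param validation Optional validation visit table for hyperparameter
#'   selection (DRLR radius by validation MAE, lasso penalty by MSE).
#' @param ... Passed on to the per-class fitter.
#' @return Tibble with `drug_class`, `n_train` and a `model` list-column.
#' @export
fit_outcome_models <- function(train_visits, schema,
                               algorithm = c("drlr", "ols", "lasso", "cart"),
                               classes = bp_drug_classes(), validation = NULL,
                               ...) {
  algorithm <- match.arg(algorithm)
  train_visits <- modeling_visits(train_visits)
  rows <- purrr::map(classes, function(cl) {
    sub <- train_visits[purrr::map_lgl(train_visits$regimen, ~ cl %in% .x), ]
    if (nrow(sub) < 2) {
      warn(paste0("No usable training visits for class ", cl, "; skipped."))
      return(tibble(drug_class = cl, n_train = nrow(sub), model = list(NULL)))
    }
    X <- build_features(sub, schema)
    val <- NULL
    if (!is.null(validation)) {
      vs <- modeling_visits(validation)
      vs <- vs[purrr::map_lgl(vs$regimen, ~ cl %in% .x), ]
      if (nrow(vs) >= 2) val <- list(X = build_features(vs, schema),
                                     y = vs$future_sbp)
    }
    m <- switch(algorithm,
                drlr = fit_drlr(X, sub$future_sbp, drug_class = cl,
                                validation = val, ...),
                ols = fit_ols(X, sub$future_sbp, drug_class = cl, ...),
                lasso = fit_lasso(X, sub$future_sbp, drug_class = cl,
                                  validation = val, ...),
                cart = fit_cart(X, sub$future_sbp, drug_class = cl, ...))
    tibble(drug_class = cl, n_train = nrow(sub), model = list(m))
  })
  out <- bind_rows(rows)
  attr(out, "algorithm") <- algorithm
  out
}
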