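test_that("OLS recovers exact linear data and matches the normal equations", {
  d <- make_linear(40, 2, beta = c(2, -3), b0 = 0, noise = 0, seed = 1)
  m <- fit_ols(d$X, d$y)
  expect_equal(unname(m$coefficients), c(2, -3), tolerance = 1e-8)

  # constant outcome
  mc <- fit_ols(d$X, rep(7, 40))
  expect_equal(unname(mc$coefficients), c(0, 0), tolerance = 1e-10)
  expect_equal(mc$intercept, 7, tolerance = 1e-10)

  # random 50 x 3 problem vs direct normal-equations solve
  d2 <- make_linear(50, 3, noise = 1, seed = 2)
  m2 <- fit_ols(d2$X, d2$y)
  Xa <- cbind(1, d2$X)
  th <- solve(crossprod(Xa), crossprod(Xa, d2$y))
  expect_equal(unname(c(m2$intercept, m2$coefficients)), unname(drop(th)),
               tolerance = 1e-8)
})

test_that("rank deficiency either errors with the collinear column or engages
           the ridge fallback", {
  d <- make_linear(30, 2, seed = 3)
  X <- cbind(d$X, x3 = d$X[, 1])
  expect_error(fit_ols(X, d$y, ridge_fallback = FALSE), "x3",
               class = "bp_fit_error")
  m <- fit_ols(X, d$y, ridge_fallback = TRUE)
  expect_length(m$coefficients, 3)
  expect_true(all(is.finite(m$coefficients)))
})

test_that("lasso matches OLS at zero penalty and shrinks to zero for large
           penalties", {
  d <- make_linear(60, 4, noise = 0.5, seed = 4)
  m0 <- fit_lasso(d$X, d$y, lambda = 0)
  ols <- fit_ols(d$X, d$y)
  expect_equal(m0$coefficients, ols$coefficients, tolerance = 1e-5)
  mb <- fit_lasso(d$X, d$y, lambda = 1e4)
  expect_equal(unname(mb$coefficients), rep(0, 4))
  expect_error(fit_lasso(d$X, d$y, lambda = -1), class = "bp_config_error")
})

test_that("1-D lasso matches the soft-thresholding closed form", {
  set.seed(5)
  n <- 64
  x <- rnorm(n)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2)) # unit second moment
  y <- 2.5 * x + rnorm(n, 0, 0.3)
  for (lambda in c(0.1, 0.5, 2)) {
    m <- fit_lasso(matrix(x, ncol = 1), y, lambda = lambda)
    xc <- x - mean(x); yc <- y - mean(y)
    rho <- mean(xc * yc)
    expected <- sign(rho) * max(abs(rho) - lambda / 2, 0) / mean(xc^2)
    expect_equal(unname(m$coefficients), expected, tolerance = 1e-6)
  }
})

test_that("CART handles constant outcomes, finds the step split, and ignores
           irrelevant features", {
  d <- make_linear(40, 2, seed = 6)
  mc <- fit_cart(d$X, rep(5, 40), depth = 3)
  expect_equal(predict(mc, d$X), rep(5, 40))
  expect_true(all(mc$coefficients >= 0))

  set.seed(7)
  X <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- as.numeric(X[, 1] > 0)
  m1 <- fit_cart(X, y, depth = 1)
  split_var <- as.character(m1$fit$frame$var[1])
  expect_identical(split_var, "x1")
  cut <- m1$fit$splits[1, "index"]
  expect_lt(abs(cut), 0.25)
  leafs <- sort(unique(predict(m1, X)))
  expect_equal(leafs, c(0, 1), tolerance = 0.05)

  # permuting an irrelevant feature leaves predictions unchanged
  X2 <- X
  X2[, 2] <- sample(X2[, 2])
  expect_equal(predict(m1, X2), predict(m1, X))
})

test_that("depth-limited trees respect the depth and importance sums the
           per-split variance reduction", {
  set.seed(8)
  X <- matrix(rnorm(300 * 3), 300, 3)
  y <- 2 * (X[, 1] > 0) + (X[, 2] > 0.5) + rnorm(300, 0, 0.1)
  m <- fit_cart(X, y, depth = 2)
  imp <- m$coefficients
  expect_gt(imp[["x1"]], imp[["x2"]])
  expect_equal(unname(imp[["x3"]]), 0, tolerance = 1e-9)
  # total importance equals root deviance minus summed leaf deviance
  fr <- m$fit$frame
  expect_equal(sum(imp), fr$dev[1] - sum(fr$dev[fr$var == "<leaf>"]),
               tolerance = 1e-9)
})

test_that("an intercept-only absolute-loss fit returns the median, not the
           mean", {
  y <- c(1, 2, 100)
  m <- fit_drlr(matrix(numeric(0), 3, 0), y, eps = 0)
  expect_equal(m$intercept, 2)
  expect_equal(mean(y), 34 + 1 / 3) # the OLS answer it must not give
})

test_that("at eps = 0 the robust fit matches the linear-programming LAD
           oracle within 1e-6 relative objective", {
  skip_if(is.null(lad_lp_oracle(matrix(rnorm(20), 10, 2), rnorm(10))),
          "python LP oracle unavailable")
  worst <- 0
  for (s in 1:8) {
    d <- make_linear(80, 4, noise = 1, outlier_fraction = 0.1, seed = 100 + s)
    m <- fit_drlr(d$X, d$y, eps = 0)
    orc <- lad_lp_oracle(d$X, d$y)
    rel <- abs(m$train_loss - orc$obj) / orc$obj
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)
})

test_that("the robust objective is convex in practice: different starts reach
           the same objective within 1e-6", {
  d <- make_linear(80, 3, noise = 1, outlier_fraction = 0.1, seed = 30)
  m1 <- fit_drlr(d$X, d$y, eps = 0.05)
  # restart from a permuted, rescaled copy of the data (row order must not
  # matter) and from a different internal start via a shifted outcome
  perm <- sample(80)
  m2 <- fit_drlr(d$X[perm, ], d$y[perm], eps = 0.05)
  expect_equal(m1$train_loss, m2$train_loss, tolerance = 1e-6)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-4)
})

test_that("large ambiguity radii shrink the coefficients toward zero", {
  d <- make_linear(60, 3, noise = 0.5, seed = 31)
  m1 <- fit_drlr(d$X, d$y, eps = 1)
  m4 <- fit_drlr(d$X, d$y, eps = 1e4)
  # the l2 dual-norm penalty is smooth at 0, so the norm vanishes only in
  # the limit; it must collapse by orders of magnitude and keep shrinking
  expect_lt(sqrt(sum(m4$coefficients^2)), 1e-2)
  expect_lt(sqrt(sum(m4$coefficients^2)), sqrt(sum(m1$coefficients^2)))
  expect_error(fit_drlr(d$X, d$y, eps = -1), class = "bp_config_error")
})

test_that("all dual-norm variants decrease the penalty term as specified", {
  d <- make_linear(60, 3, noise = 0.5, seed = 32)
  for (nrm in c("l2", "linf", "l1")) {
    m_small <- fit_drlr(d$X, d$y, eps = 0.001, dual_norm = nrm)
    m_big <- fit_drlr(d$X, d$y, eps = 10, dual_norm = nrm)
    expect_lt(sum(abs(m_big$coefficients)), sum(abs(m_small$coefficients)))
  }
})

test_that("with 10% outcome outliers the robust fit tracks the true
           coefficients at least as well as OLS in most seeds", {
  wins <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    d <- make_linear(150, 5, noise = 2, outlier_fraction = 0.1,
                     outlier_magnitude = 50, seed = 500 + s)
    md <- fit_drlr(d$X, d$y, eps = 0.01)
    mo <- fit_ols(d$X, d$y)
    err_d <- sqrt(sum((md$coefficients - d$beta)^2))
    err_o <- sqrt(sum((mo$coefficients - d$beta)^2))
    wins <- wins + (err_d <= err_o)
  }
  expect_gte(wins, 15)
})

test_that("all four fitters are invariant to row order", {
  d <- make_linear(50, 3, noise = 1, seed = 33)
  perm <- sample(50)
  pairs <- list(
    list(fit_ols(d$X, d$y), fit_ols(d$X[perm, ], d$y[perm])),
    list(fit_lasso(d$X, d$y, 0.5), fit_lasso(d$X[perm, ], d$y[perm], 0.5)),
    list(fit_drlr(d$X, d$y, 0.01), fit_drlr(d$X[perm, ], d$y[perm], 0.01))
  )
  for (p in pairs) {
    expect_equal(p[[1]]$coefficients, p[[2]]$coefficients, tolerance = 1e-6)
  }
  c1 <- fit_cart(d$X, d$y, depth = 3)
  c2 <- fit_cart(d$X[perm, ], d$y[perm], depth = 3)
  expect_equal(predict(c1, d$X), predict(c2, d$X), tolerance = 1e-9)
})

test_that("noiseless linear data are recovered to high precision by OLS and
           near-zero-penalty lasso", {
  d <- make_linear(100, 5, noise = 0, seed = 34)
  mo <- fit_ols(d$X, d$y)
  expect_equal(unname(mo$coefficients), d$beta, tolerance = 1e-6)
  ml <- fit_lasso(d$X, d$y, lambda = 1e-10)
  expect_equal(unname(ml$coefficients), d$beta, tolerance = 1e-6)
})

test_that("per-class model fitting uses combination visits in every
           constituent class and exposes tidy/glance", {
  fx <- make_cohort(n_patients = 80, seed = 51, combo_fraction = 0.4)
  sp <- split_by_patient(fx$visits, seed = 1)
  schema <- fit_schema(modeling_visits(sp$train))
  models <- fit_outcome_models(sp$train, schema, algorithm = "ols",
                               classes = c("ACEi", "CCB"))
  train <- modeling_visits(sp$train)
  n_acei <- sum(vapply(train$regimen, function(r) "ACEi" %in% r, logical(1)))
  expect_equal(models$n_train[models$drug_class == "ACEi"], n_acei)

  td <- tidy(models$model[[1]])
  expect_named(td, c("term", "estimate", "weight"))
  expect_equal(nrow(td), nrow(schema$features))
  gl <- glance(models$model[[1]])
  expect_identical(gl$algorithm, "ols")
  expect_identical(gl$drug_class, "ACEi")
})
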