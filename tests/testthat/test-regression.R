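test_that("age scaling maps [0, 228] months onto the unit interval exactly", {
  expect_identical(scale_age(0), 0)
  expect_identical(scale_age(228), 1)
  expect_identical(scale_age(114), 0.5)
  m <- 0:228
  expect_equal(unscale_age(scale_age(m)), m)
  expect_error(scale_age(-1), class = "handbaa_contract_error")
  expect_error(scale_age(250), class = "handbaa_contract_error")
  expect_warning(out <- unscale_age(1.2), "clipped")
  expect_identical(out, 228)
})

test_that("linear KRR recovers exact linear maps at tiny regularization", {
  set.seed(31)
  X <- matrix(runif(60, -1, 1), 20, 3)
  w <- c(0.2, -0.1, 0.4)
  y <- as.numeric(X %*% w) + 0.3
  fit <- fit_regressor(X, y, regressor_config("krr", krr_regularization = 1e-8))
  expect_equal(predict(fit, X), y, tolerance = 1e-4)
})

test_that("linear KRR predictions equal the explicit closed-form ridge path", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(8:15, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- runif(n)
    lam <- runif(1, 0.01, 2)
    fit <- fit_regressor(X, y, regressor_config("krr", krr_regularization = lam))
    Xnew <- matrix(rnorm(5 * p), 5, p)
    # independent oracle: primal ridge on centered data with intercept
    xm <- colMeans(X); ym <- mean(y)
    Xc <- sweep(X, 2, xm)
    wstar <- solve(crossprod(Xc) + diag(lam, p), crossprod(Xc, y - ym))
    oracle <- as.numeric(sweep(Xnew, 2, xm) %*% wstar + ym)
    expect_equal(predict(fit, Xnew), oracle, tolerance = 1e-6)
    expect_equal(predict(fit, X),
                 as.numeric(Xc %*% wstar + ym), tolerance = 1e-6)
  }
})

test_that("constant targets are predicted everywhere and zero-variance features warn", {
  X <- matrix(runif(20), 10, 2)
  fit <- fit_regressor(X, rep(0.4, 10), regressor_config("krr"))
  expect_equal(predict(fit, X), rep(0.4, 10), tolerance = 1e-6)
  Xz <- cbind(X, 1)
  expect_warning(fit_regressor(Xz, runif(10), regressor_config("krr")),
                 "zero-variance")
})

test_that("SVR and polynomial-kernel KRR fit noisy linear data sensibly", {
  set.seed(33)
  X <- matrix(runif(120, 0, 1), 60, 2)
  y <- 0.2 + 0.5 * X[, 1] + 0.2 * X[, 2] + rnorm(60, 0, 0.02)
  svr <- fit_regressor(X, y, regressor_config("svr"))
  expect_lt(mean(abs(predict(svr, X) - y)), 0.05)
  kp <- fit_regressor(X, y, regressor_config("krr", kernel = "polynomial",
                                             krr_regularization = 0.1))
  expect_lt(mean(abs(predict(kp, X) - y)), 0.05)
})

test_that("cross-validation partitions, reproduces and pools correctly", {
  set.seed(34)
  X <- matrix(runif(80), 40, 2)
  ages <- round(228 * (0.3 * X[, 1] + 0.5 * X[, 2]))
  cv1 <- cross_validate(X, ages, regressor_config("krr"), folds = 5L, seed = 2L)
  cv2 <- cross_validate(X, ages, regressor_config("krr"), folds = 5L, seed = 2L)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(sort(unique(cv1$predictions$fold)), 1:5)
  expect_identical(tabulate(cv1$predictions$fold), rep(8L, 5))
  # pooled MAE equals MAE recomputed from stored predictions
  expect_equal(cv1$pooled$mae,
               mean(abs(cv1$predictions$truth - cv1$predictions$pred)),
               tolerance = 1e-12)
  expect_error(cross_validate(X, ages, folds = 50L), class = "handbaa_config_error")
})

test_that("bagging degenerates to its base fit and averages its members", {
  set.seed(35)
  X <- matrix(runif(60), 30, 2)
  y <- 0.1 + 0.6 * X[, 1] + rnorm(30, 0, 0.05)
  base <- regressor_config("krr")
  single <- ensemble_config("bagging", n_estimators = 1L, base = base,
                            resample = FALSE)
  ens1 <- fit_ensemble(X, y, single)
  direct <- fit_regressor(X, y, base)
  Xn <- matrix(runif(10), 5, 2)
  expect_equal(predict(ens1, Xn), predict(direct, Xn), tolerance = 1e-12)
  ens <- fit_ensemble(X, y, ensemble_config("bagging", n_estimators = 7L,
                                            base = base, seed = 4L))
  P <- ensemble_member_predictions(ens, Xn)
  expect_identical(dim(P), c(5L, 7L))
  expect_equal(predict(ens, Xn), rowMeans(P), tolerance = 1e-12)
})

test_that("bagged prediction variance shrinks as the ensemble grows", {
  set.seed(36)
  X <- matrix(runif(80), 40, 2)
  y <- 0.1 + 0.5 * X[, 1] + 0.3 * X[, 2] + rnorm(40, 0, 0.1)
  Xn <- matrix(runif(8), 4, 2)
  spread <- vapply(c(1L, 5L, 21L), function(ne) {
    preds <- vapply(1:6, function(s) {
      ens <- fit_ensemble(X, y, ensemble_config("bagging", n_estimators = ne,
                                                seed = 100L + s))
      mean(predict(ens, Xn))
    }, numeric(1))
    stats::var(preds)
  }, numeric(1))
  expect_lt(spread[3], spread[1])
  expect_lte(spread[2], spread[1] * 1.5)
})

test_that("AdaBoost.R2 is deterministic and beats a constant predictor", {
  set.seed(37)
  X <- matrix(runif(120), 60, 2)
  y <- 0.2 + 0.5 * X[, 1]^2 + rnorm(60, 0, 0.03)
  cfg <- ensemble_config("adaboost", n_estimators = 8L, seed = 5L)
  e1 <- fit_ensemble(X, y, cfg)
  e2 <- fit_ensemble(X, y, cfg)
  Xn <- matrix(runif(20), 10, 2)
  expect_identical(predict(e1, Xn), predict(e2, Xn))
  expect_lt(mean(abs(predict(e1, X) - y)), mean(abs(mean(y) - y)))
  expect_true(length(e1$members) >= 1)
})

test_that("sex-stratified fits bookkeep cohorts and beat the mixed fit when the map differs by sex", {
  gains <- numeric(3)
  for (s in 1:3) {
    set.seed(40 + s)
    n <- 150
    male <- runif(n) < 0.5
    x <- runif(n)
    ages <- ifelse(male, 40 + 150 * x, 90 + 90 * x) + rnorm(n, 0, 5)
    ages <- pmin(pmax(round(ages), 0), 228)
    X <- cbind(x, runif(n, 0, 0.05))
    strat <- stratified_fit(X, ages, male, regressor_config("krr"), seed = s)
    expect_setequal(names(strat), c("all", "male", "female"))
    expect_identical(length(strat$male$indices) + length(strat$female$indices),
                     length(strat$all$indices))
    expect_identical(strat$male$cv$pooled$n, sum(male))
    per_sex <- (strat$male$cv$pooled$mae * sum(male) +
                  strat$female$cv$pooled$mae * sum(!male)) / n
    gains[s] <- strat$all$cv$pooled$mae - per_sex
  }
  expect_gt(mean(gains), 0)
})

test_that("an empty cohort is skipped with a warning", {
  X <- matrix(runif(40), 20, 2)
  ages <- round(runif(20, 20, 200))
  expect_warning(out <- stratified_fit(X, ages, rep(TRUE, 20),
                                       regressor_config("krr")),
                 "female")
  expect_null(out$female)
  expect_identical(strat_names <- names(out), c("all", "male"))
})

test_that("age-bin balancing equalizes bin counts", {
  ages <- c(rep(5, 10), rep(30, 4), rep(100, 7))
  keep <- balance_by_age(ages, bin_width = 12L, seed = 1L)
  kept_bins <- table(floor(ages[keep] / 12))
  expect_true(all(kept_bins == 4))
  expect_identical(length(keep), 12L)
})
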