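# Bone age regression: ages scaled from [0, 228] months to [0, 1], linear
# SVR / kernel ridge regressors, 5-fold cross-validation, sex-stratified
# fits and bagging / AdaBoost.R2 ensembles of KRR.

AGE_MAX_MONTHS <- 228

#' Scale bone ages between months and the unit interval
#'
#' `scale_age` maps `[0, 228]` months to `[0, 1]`; `unscale_age` projects
#' back, clipping to the valid range with a warning when a prediction falls
#' outside it.
#'
#' @param months ages in months (each in `[0, 228]`).
#' @param scaled real values (any finite value; clipped on unscaling).
#' @return scaled values / months.
#' @export
scale_age <- function(months) {
  if (any(months < 0) || any(months > AGE_MAX_MONTHS)) {
    contract_error("ages must lie in [0, 228] months")
  }
  months / AGE_MAX_MONTHS
}

#' @rdname scale_age
#' @export
unscale_age <- function(scaled) {
  months <- scaled * AGE_MAX_MONTHS
  if (any(months < 0 | months > AGE_MAX_MONTHS)) {
    warning("predictions outside [0, 228] months were clipped")
    months <- pmin(pmax(months, 0), AGE_MAX_MONTHS)
  }
  months
}

#' Regressor configuration
#'
#' Defaults follow the method's stated settings: SVR penalty 1.0 with
#' stopping tolerance 1e-3; KRR regularization 1.0. Both use a linear kernel
#' by default; a degree-3 polynomial kernel is available as the alternative
#' reading of the method's kernel description.
#'
#' @param family `"krr"` or `"svr"`.
#' @param kernel `"linear"` or `"polynomial"`.
#' @param svr_penalty SVR cost parameter C.
#' @param svr_tolerance SVR stopping tolerance.
#' @param svr_epsilon epsilon of the insensitive tube (scaled age units).
#' @param krr_regularization ridge strength lambda.
#' @param poly_degree polynomial degree (used only when kernel is polynomial).
#' @return a `regressor_config` list.
#' @export
regressor_config <- function(family = c("krr", "svr"),
                             kernel = c("linear", "polynomial"),
                             svr_penalty = 1.0, svr_tolerance = 1e-3,
                             svr_epsilon = 0.01,
                             krr_regularization = 1.0, poly_degree = 3L) {
  family <- match.arg(family)
  kernel <- match.arg(kernel)
  if (svr_penalty <= 0 || krr_regularization <= 0) {
    config_error("penalty and regularization must be > 0")
  }
  structure(list(family = family, kernel = kernel, svr_penalty = svr_penalty,
                 svr_tolerance = svr_tolerance, svr_epsilon = svr_epsilon,
                 krr_regularization = krr_regularization,
                 poly_degree = as.integer(poly_degree)),
            class = "regressor_config")
}

krr_kernel <- function(A, B, config) {
  if (config$kernel == "linear") {
    tcrossprod(A, B)
  } else {
    (1 + tcrossprod(A, B))^config$poly_degree
  }
}

#' Fit a single age regressor
#'
#' KRR solves the dual ridge system `(K + lambda I) alpha = y` on
#' mean-centered features and targets (the centering plays the role of an
#' unpenalized intercept); SVR is epsilon-insensitive support vector
#' regression via \pkg{e1071}. Deterministic given its inputs.
#'
#' @param features a `feature_matrix` or numeric matrix (>= 2 rows).
#' @param scaled_ages targets scaled to `[0, 1]`.
#' @param config a [regressor_config()].
#' @return a `baa_regressor`; use [predict()] to obtain scaled predictions.
#' @export
fit_regressor <- function(features, scaled_ages, config = regressor_config()) {
  X <- feature_matrix_of(features)
  y <- as.numeric(scaled_ages)
  if (nrow(X) < 2L) contract_error("need at least 2 training rows")
  if (nrow(X) != length(y)) contract_error("features and ages differ in length")
  if (any(apply(X, 2L, stats::var) == 0)) {
    warning("zero-variance feature column; fit proceeds")
  }
  fit <- if (config$family == "krr") {
    center <- if (config$kernel == "linear") colMeans(X) else rep(0, ncol(X))
    Xc <- sweep(X, 2L, center)
    ybar <- mean(y)
    K <- krr_kernel(Xc, Xc, config)
    alpha <- solve(K + diag(config$krr_regularization, nrow(K)), y - ybar)
    list(kind = "krr", alpha = alpha, X = Xc, center = center, ybar = ybar)
  } else {
    m <- e1071::svm(x = X, y = y, type = "eps-regression",
                    kernel = config$kernel, degree = config$poly_degree,
                    cost = config$svr_penalty, tolerance = config$svr_tolerance,
                    epsilon = config$svr_epsilon, scale = FALSE)
    list(kind = "svr", model = m)
  }
  structure(list(config = config, fit = fit, p = ncol(X)),
            class = "baa_regressor")
}

#' @export
predict.baa_regressor <- function(object, newdata, ...) {
  X <- feature_matrix_of(newdata)
  if (ncol(X) != object$p) contract_error("feature dimension mismatch")
  if (object$fit$kind == "krr") {
    Xc <- sweep(X, 2L, object$fit$center)
    as.numeric(krr_kernel(Xc, object$fit$X, object$config) %*% object$fit$alpha +
                 object$fit$ybar)
  } else {
    as.numeric(stats::predict(object$fit$model, X))
  }
}

cv_fold_assignment <- function(n, folds, seed) {
  ord <- withr::with_seed(derive_seed(seed, 77L), sample.int(n))
  rep_len(seq_len(folds), n)[order(ord)]
}

#' K-fold cross-validation of an age regressor
#'
#' Seeded shuffled fold assignment; for each fold the regressor is fit on
#' the training portion (ages scaled to `[0, 1]`) and evaluated on the test
#' portion in months. The pooled report concatenates all fold predictions.
#'
#' @param features a `feature_matrix` or numeric matrix.
#' @param ages_months integer ages in `[0, 228]`.
#' @param config a [regressor_config()] or [ensemble_config()].
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return a `cv_report`: list with `folds` (per-fold data.frame), `pooled`
#'   (one-row data.frame) and `predictions` (`index`, `fold`, `truth`, `pred`).
#' @export
cross_validate <- function(features, ages_months, config = regressor_config(),
                           folds = 5L, seed = 0L) {
  X <- feature_matrix_of(features)
  n <- nrow(X)
  if (folds > n) config_error("more folds than observations")
  assign <- cv_fold_assignment(n, folds, seed)
  y_scaled <- scale_age(ages_months)
  preds <- numeric(n)
  fold_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(assign == f)
    tr <- which(assign != f)
    model <- if (inherits(config, "ensemble_config")) {
      fit_ensemble(X[tr, , drop = FALSE], y_scaled[tr], config)
    } else {
      fit_regressor(X[tr, , drop = FALSE], y_scaled[tr], config)
    }
    p_months <- unscale_age(stats::predict(model, X[te, , drop = FALSE]))
    preds[te] <- p_months
    # single-observation or constant folds have no defined ccc
    fold_ccc <- tryCatch(ccc(ages_months[te], p_months),
                         error = function(e) NA_real_)
    fold_rows[[f]] <- data.frame(fold = f, cohort = "fold", n = length(te),
                                 mae = mae(ages_months[te], p_months),
                                 rmse = rmse(ages_months[te], p_months),
                                 ccc = fold_ccc, stringsAsFactors = FALSE)
  }
  structure(list(
    folds = do.call(rbind, fold_rows),
    pooled = regression_report(ages_months, preds),
    predictions = data.frame(index = seq_len(n), fold = assign,
                             truth = ages_months, pred = preds)
  ), class = "cv_report")
}

#' Ensemble configuration
#'
#' @param method `"bagging"` (bootstrap aggregation, mean prediction) or
#'   `"adaboost"` (AdaBoost.R2 with linear loss, weighted-median prediction).
#' @param n_estimators number of base fits (>= 1).
#' @param base a [regressor_config()] for the base estimator (KRR by default).
#' @param seed resampling seed.
#' @param resample bagging only: draw bootstrap resamples (disabling this
#'   with one estimator reduces the ensemble to the single base fit).
#' @return an `ensemble_config` list.
#' @export
ensemble_config <- function(method = c("bagging", "adaboost"),
                            n_estimators = 21L, base = regressor_config(),
                            seed = 0L, resample = TRUE) {
  method <- match.arg(method)
  if (n_estimators < 1L) config_error("n_estimators must be >= 1")
  structure(list(method = method, n_estimators = as.integer(n_estimators),
                 base = base, seed = as.integer(seed), resample = resample),
            class = "ensemble_config")
}

#' Fit a regression ensemble
#'
#' Bagging fits the base regressor on seeded bootstrap resamples and
#' averages predictions. AdaBoost.R2 fits the base regressor on weighted
#' resamples, reweighting hard examples by the linear loss, and predicts
#' with the weighted median of its members.
#'
#' @inheritParams fit_regressor
#' @param config an [ensemble_config()].
#' @return a `baa_ensemble`; use [predict()] for scaled predictions.
#' @export
fit_ensemble <- function(features, scaled_ages, config = ensemble_config()) {
  X <- feature_matrix_of(features)
  y <- as.numeric(scaled_ages)
  n <- nrow(X)
  members <- list()
  weights <- numeric(0)
  if (config$method == "bagging") {
    for (e in seq_len(config$n_estimators)) {
      idx <- if (config$resample) {
        withr::with_seed(derive_seed(config$seed, e), sample.int(n, replace = TRUE))
      } else seq_len(n)
      members[[e]] <- fit_regressor(X[idx, , drop = FALSE], y[idx], config$base)
      weights[e] <- 1
    }
  } else {
    w <- rep(1 / n, n)
    for (e in seq_len(config$n_estimators)) {
      idx <- withr::with_seed(derive_seed(config$seed, e),
                              sample.int(n, replace = TRUE, prob = w))
      m <- fit_regressor(X[idx, , drop = FALSE], y[idx], config$base)
      pred <- stats::predict(m, X)
      err <- abs(pred - y)
      D <- max(err)
      if (D == 0) {      # perfect member: give it dominant weight and stop
        members[[length(members) + 1L]] <- m
        weights[length(weights) + 1L] <- log(1 / 1e-10)
        break
      }
      L <- err / D
      ebar <- sum(w * L)
      if (ebar >= 0.5) {
        if (length(members) == 0L) {   # keep one member regardless
          members[[1L]] <- m
          weights[1L] <- 1
        }
        break
      }
      beta <- ebar / (1 - ebar)
      members[[length(members) + 1L]] <- m
      weights[length(weights) + 1L] <- log(1 / max(beta, 1e-10))
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  }
  structure(list(config = config, members = members, weights = weights),
            class = "baa_ensemble")
}

weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  cw <- cumsum(w)
  v[which(cw >= sum(w) / 2)[1]]
}

#' @export
predict.baa_ensemble <- function(object, newdata, ...) {
  X <- feature_matrix_of(newdata)
  P <- vapply(object$members, function(m) stats::predict(m, X),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  if (object$config$method == "bagging") {
    rowMeans(P)
  } else {
    apply(P, 1L, weighted_median, weights = object$weights)
  }
}

#' Per-member predictions of an ensemble
#'
#' @param ensemble a `baa_ensemble`.
#' @param newdata feature matrix.
#' @return n x n_members matrix of scaled predictions.
#' @export
ensemble_member_predictions <- function(ensemble, newdata) {
  X <- feature_matrix_of(newdata)
  P <- vapply(ensemble$members, function(m) stats::predict(m, X),
              numeric(nrow(X)))
  matrix(P, nrow = nrow(X))
}

#' Sex-stratified regression fits
#'
#' Fits and cross-validates three models — on all rows, male-only rows and
#' female-only rows. An empty cohort is skipped with a warning.
#'
#' @param features a `feature_matrix` or matrix.
#' @param ages_months ages in months.
#' @param male logical vector aligned with rows.
#' @param config a [regressor_config()] or [ensemble_config()].
#' @param folds CV folds.
#' @param seed CV seed.
#' @return named list (`all`, `male`, `female`) of lists with `model`, `cv`
#'   and the cohort row `indices`.
#' @export
stratified_fit <- function(features, ages_months, male,
                           config = regressor_config(), folds = 5L, seed = 0L) {
  X <- feature_matrix_of(features)
  cohorts <- list(all = seq_len(nrow(X)), male = which(male),
                  female = which(!male))
  out <- list()
  for (nm in names(cohorts)) {
    idx <- cohorts[[nm]]
    if (length(idx) < 2L) {
      warning(sprintf("cohort '%s' is empty or too small; skipped", nm))
      next
    }
    cohort_folds <- min(folds, length(idx))
    Xi <- X[idx, , drop = FALSE]
    yi <- ages_months[idx]
    model <- if (inherits(config, "ensemble_config")) {
      fit_ensemble(Xi, scale_age(yi), config)
    } else {
      fit_regressor(Xi, scale_age(yi), config)
    }
    out[[nm]] <- list(model = model,
                      cv = cross_validate(Xi, yi, config, folds = cohort_folds,
                                          seed = seed),
                      indices = idx)
  }
  out
}

#' Balance a cohort by age bin
#'
#' Downsamples each `bin_width`-month age bin to the size of the smallest
#' non-empty bin (seeded), emulating equal-frequency sampling over bone age.
#'
#' @param ages_months ages in months.
#' @param bin_width bin width in months (default 12).
#' @param seed sampling seed.
#' @return integer indices of the retained rows.
#' @export
balance_by_age <- function(ages_months, bin_width = 12L, seed = 0L) {
  bins <- floor(ages_months / bin_width)
  counts <- table(bins)
  target <- min(counts)
  keep <- withr::with_seed(derive_seed(seed, 99L), {
    unlist(lapply(names(counts), function(b) {
      idx <- which(bins == as.numeric(b))
      if (length(idx) > target) sample(idx, target) else idx
    }))
  })
  sort(keep)
}
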