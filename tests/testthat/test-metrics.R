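brute_confusion <- function(truth, pred) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    else if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
    else if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

test_that("confusion counts match a per-pixel loop oracle", {
  a <- random_binary_mask(4, 4); b <- random_binary_mask(4, 4)
  expect_equal(sum(confusion_counts(a, b)), 16)
  same <- random_binary_mask(8, 8)
  cc <- confusion_counts(same, same)
  expect_equal(unname(cc[c("fp", "fn")]), c(0, 0))
  comp <- confusion_counts(same, 1 - same)
  expect_equal(unname(comp[c("tp", "tn")]), c(0, 0))
  set.seed(15)
  for (rep in 1:20) {
    t <- random_binary_mask(8, 8); p <- random_binary_mask(8, 8)
    expect_equal(confusion_counts(t, p), brute_confusion(t, p))
  }
  expect_error(confusion_counts(matrix(2, 2, 2), matrix(0, 2, 2)),
               class = "handbaa_contract_error")
})

test_that("overlap metrics match worked values and brute-force oracles", {
  m <- matrix(0, 4, 4); m[1:2, 1] <- 1; m[3, 3] <- 1      # 3 foreground px
  p <- matrix(0, 4, 4); p[1:2, 1] <- 1                    # 2 px, overlap 2
  expect_equal(dice(m, p), 0.8)
  ident <- random_binary_mask(6, 6); ident[1, 1] <- 1; ident[2, 2] <- 0
  expect_equal(dice(ident, ident), 1)
  expect_equal(sensitivity(ident, ident), 1)
  expect_equal(specificity(ident, ident), 1)
  a <- matrix(0, 3, 3); a[1, 1] <- 1
  b <- matrix(0, 3, 3); b[3, 3] <- 1
  expect_equal(dice(a, b), 0)
  expect_equal(sensitivity(a, b), 0)
  set.seed(16)
  for (rep in 1:100) {
    t <- random_binary_mask(16, 16); p <- random_binary_mask(16, 16)
    cc <- brute_confusion(t, p)
    expect_equal(dice(t, p), 2 * cc["tp"] / (2 * cc["tp"] + cc["fp"] + cc["fn"]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sensitivity(t, p), cc["tp"] / (cc["tp"] + cc["fn"]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(specificity(t, p), cc["tn"] / (cc["tn"] + cc["fp"]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(dice(t, p), dice(p, t))   # symmetry
  }
  empty <- matrix(0, 3, 3)
  expect_error(dice(empty, empty), class = "handbaa_degenerate_error")
  expect_error(sensitivity(empty, random_binary_mask(3, 3)),
               class = "handbaa_degenerate_error")
  expect_error(specificity(matrix(1, 3, 3), empty),
               class = "handbaa_degenerate_error")
})

test_that("mae and rmse match hand arithmetic and Jensen's inequality", {
  expect_equal(mae(c(12, 16), c(12, 16)), 0)
  expect_equal(rmse(c(12, 16), c(12, 16)), 0)
  expect_equal(mae(c(12, 16), c(10, 20)), 3)
  expect_equal(rmse(c(12, 16), c(10, 20)), sqrt(10), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:100) {
    x <- runif(20, 0, 228); y <- runif(20, 0, 228)
    s1 <- 0; s2 <- 0
    for (i in 1:20) { s1 <- s1 + abs(x[i] - y[i]); s2 <- s2 + (x[i] - y[i])^2 }
    expect_equal(mae(x, y), s1 / 20, tolerance = 1e-9)
    expect_equal(rmse(x, y), sqrt(s2 / 20), tolerance = 1e-9)
    expect_lte(mae(x, y), rmse(x, y) + 1e-12)
  }
  expect_error(mae(1:3, 1:4), class = "handbaa_contract_error")
})

test_that("ccc matches Lin's formula, its worked value and known properties", {
  expect_equal(ccc(c(1, 5, 9), c(1, 5, 9)), 1.0)
  expect_equal(ccc(c(1, 2, 3), c(2, 4, 6)), 4 / 11, tolerance = 1e-12)
  set.seed(18)
  for (rep in 1:100) {
    x <- rnorm(30, 100, 30)
    y <- (x - mean(x)) * runif(1, 0.5, 1.5) + mean(x) + rnorm(30, 0, 10)
    # brute-force population moments
    mx <- sum(x) / 30; my <- sum(y) / 30
    vx <- sum((x - mx)^2) / 30; vy <- sum((y - my)^2) / 30
    cxy <- sum((x - mx) * (y - my)) / 30
    expect_equal(ccc(x, y), 2 * cxy / (vx + vy + (mx - my)^2), tolerance = 1e-9)
    expect_lte(abs(ccc(x, y)), abs(stats::cor(x, y)) + 1e-12)
    expect_true(ccc(x, y) >= -1 && ccc(x, y) <= 1)
    # shifting both sequences together leaves ccc unchanged
    expect_equal(ccc(x + 13, y + 13), ccc(x, y), tolerance = 1e-9)
    # shifting only one sequence strictly attenuates agreement
    if (ccc(x, y) > 0) expect_lt(ccc(x, y + 25), ccc(x, y))
  }
  expect_error(ccc(rep(1, 5), 1:5), class = "handbaa_degenerate_error")
  expect_error(ccc(1, 2), class = "handbaa_contract_error")
})

test_that("report builders aggregate cohort and strategy rows", {
  r <- regression_report(c(10, 20, 30), c(12, 18, 33), cohort = "male")
  expect_identical(r$n, 3L)
  expect_lte(r$mae, r$rmse)
  set.seed(19)
  truths <- lapply(1:4, function(i) random_binary_mask(8, 8))
  preds <- lapply(1:4, function(i) random_binary_mask(8, 8))
  s <- segmentation_report(truths, preds, "FSL")
  expect_identical(s$strategy, "FSL")
  expect_equal(s$dice, mean(mapply(dice, truths, preds)))
})
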