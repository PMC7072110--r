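test_that("parameter sampling and rendering are deterministic given a seed", {
  cfg <- variation_config()
  p1 <- sample_phantom_params(cfg, seed = 3L)
  p2 <- sample_phantom_params(cfg, seed = 3L)
  expect_identical(p1, p2)
  expect_false(identical(p1, sample_phantom_params(cfg, seed = 4L)))
  r1 <- render_phantom(p1)
  r2 <- render_phantom(p1)
  expect_identical(r1, r2)
})

test_that("degenerate and invalid variation ranges are handled", {
  cfg <- variation_config(noise_sd = c(0, 0))
  p <- sample_phantom_params(cfg, seed = 1L)
  expect_identical(p$noise_sd, 0)
  expect_error(variation_config(contrast = c(1.5, 0.5)), class = "handbaa_config_error")
})

test_that("finger-length-to-palm ratio increases strictly with maturity", {
  expect_gt(finger_palm_ratio(1), finger_palm_ratio(0))
  ratios <- finger_palm_ratio(seq(0, 1, by = 0.1))
  expect_true(all(diff(ratios) > 0))
  # jitter-free sampling realizes the documented mapping exactly
  cfg <- jitterfree_config()
  for (s in 1:5) {
    p <- sample_phantom_params(cfg, seed = s)
    expect_equal(phantom_age_ratio(p), finger_palm_ratio(p$maturity),
                 tolerance = 1e-12)
  }
})

test_that("maturity carries an exact age signal in jitter-free geometry", {
  cfg <- jitterfree_config()
  params <- lapply(1:200, function(i) sample_phantom_params(cfg, seed = i))
  mat <- vapply(params, function(p) p$maturity, numeric(1))
  ratio <- vapply(params, phantom_age_ratio, numeric(1))
  expect_equal(stats::cor(mat, ratio), 1.0, tolerance = 1e-9)
  # and the signal survives rasterization into the mask
  recs <- generate_phantom_records(60, 11, cfg)
  m <- vapply(recs, function(r) r$params$maturity, numeric(1))
  h <- vapply(recs, function(r) geometry_features(r$mask)["height"], numeric(1))
  expect_gt(stats::cor(m, h), 0.99)
})

test_that("rendered masks match a brute-force geometric membership oracle", {
  cfg <- variation_config(shape = c(32L, 32L))
  point_in_phantom <- function(r, c, p) {
    r0 <- p$palm_center[1]; c0 <- p$palm_center[2]
    a <- p$palm_axes[1]; b <- p$palm_axes[2]
    if (((r - r0) / a)^2 + ((c - c0) / b)^2 <= 1) return(TRUE)
    th <- p$finger_angles
    for (i in 1:5) {
      br <- r0 - a * cos(th[i]) * 0.92; bc <- c0 + b * sin(th[i]) * 0.92
      tr <- br - cos(th[i]) * p$finger_lengths[i]
      tc <- bc + sin(th[i]) * p$finger_lengths[i]
      vr <- tr - br; vc <- tc - bc
      t <- ((r - br) * vr + (c - bc) * vc) / (vr^2 + vc^2)
      t <- min(max(t, 0), 1)
      d2 <- (r - (br + t * vr))^2 + (c - (bc + t * vc))^2
      if (d2 <= (p$finger_widths[i] / 2)^2) return(TRUE)
    }
    FALSE
  }
  for (s in 1:20) {
    p <- sample_phantom_params(cfg, seed = 100L + s)
    mask <- render_phantom(p)$mask
    oracle <- matrix(0, 32, 32)
    for (r in 1:32) for (c in 1:32) {
      oracle[r, c] <- as.numeric(point_in_phantom(r, c, p))
    }
    expect_identical(mask, oracle)
  }
})

test_that("phantom records satisfy their invariants", {
  recs <- generate_phantom_records(10, 5, variation_config())
  for (r in recs) {
    expect_gte(sum(r$mask), 1)
    expect_identical(dim(r$image), dim(r$mask))
    expect_identical(r$age_months, as.integer(round(228 * r$params$maturity)))
    expect_true(r$age_months >= 0 && r$age_months <= 228)
    expect_true(all(r$image >= 0 & r$image <= 255))
  }
})

test_that("hands that cannot fit the frame raise a geometry error naming the culprit", {
  p <- sample_phantom_params(variation_config(), seed = 1L)
  p$finger_lengths <- p$finger_lengths * 10
  expect_error(render_phantom(p), "finger", class = "handbaa_geometry_error")
})

test_that("artifacts stay outside the hand bounding box", {
  cfg <- variation_config(artifact_count = c(3L, 3L), noise_sd = c(0, 0),
                          brightness = c(0, 0), contrast = c(1, 1))
  for (s in 1:5) {
    p <- sample_phantom_params(cfg, seed = 200L + s)
    out <- render_phantom(p)
    base <- p$contrast * 25 + p$brightness   # background level
    fg <- which(out$mask == 1, arr.ind = TRUE)
    rr <- (min(fg[, 1]) - 1):(max(fg[, 1]) + 1)
    cc <- (min(fg[, 2]) - 1):(max(fg[, 2]) + 1)
    rr <- rr[rr >= 1 & rr <= nrow(out$image)]
    cc <- cc[cc >= 1 & cc <= ncol(out$image)]
    box <- out$image[rr, cc]
    boxmask <- out$mask[rr, cc]
    expect_true(all(box[boxmask == 0] == round(base)))
  }
})

test_that("dataset generation is byte-reproducible with unique ids", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(10, 7, d1)
  generate_dataset(10, 7, d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  for (f in list.files(file.path(d1, "images"))) {
    expect_identical(readBin(file.path(d1, "images", f), "raw", 1e6),
                     readBin(file.path(d2, "images", f), "raw", 1e6))
  }
  d3 <- withr::local_tempdir()
  man <- generate_dataset(100, 1, d3)
  expect_identical(anyDuplicated(man$records$id), 0L)
  expect_identical(nrow(man$records), 100L)
  expect_true(all(file.exists(file.path(d3, man$records$image))))
  expect_true(all(file.exists(file.path(d3, man$records$mask))))
})

test_that("uniform maturity covers nearly the full 0-228 month range", {
  ages <- vapply(1:1000, function(i) {
    phantom_age_months(sample_phantom_params(variation_config(),
                                             seed = derive_seed(0L, i)))
  }, integer(1))
  expect_lte(min(ages), 10)
  expect_gte(max(ages), 218)
})
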