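# Synthetic hand-phantom generator.
#
# Phantoms are deliberately simple geometry — an elliptical palm plus five
# finger capsules — rendered with the nuisance variation (brightness,
# contrast, noise, bright labelling artifacts) that makes real radiograph
# collections hard to segment. A latent maturity in [0,1] drives finger
# length relative to the palm, so image geometry carries a recoverable age
# signal; age in months is defined as round(228 * maturity).

FINGER_REL_LENGTH <- c(0.62, 0.88, 1.00, 0.92, 0.70)
FINGER_REL_WIDTH <- c(1.15, 1.00, 1.00, 0.95, 0.85)
FINGER_ANGLE <- c(-0.62, -0.25, 0.00, 0.22, 0.45)

#' Variation configuration for phantom sampling
#'
#' Ranges emulate hand radiograph collections that vary considerably in
#' intensity, contrast and brightness. Defaults are the study conditions used
#' throughout the package; `geometry_jitter = 0` yields jitter-free phantoms
#' whose geometry is an exact deterministic function of maturity.
#'
#' @param shape image shape `(rows, cols)`, at least 32 x 32.
#' @param brightness additive intensity offset range.
#' @param contrast multiplicative gain range.
#' @param noise_sd Gaussian pixel noise standard deviation range.
#' @param artifact_count integer range of spurious bright blobs / border bars.
#' @param geometry_jitter half-width of the relative jitter applied to
#'   geometric parameters (palm placement, finger lengths/widths/angles).
#' @param male_prob probability that a phantom is flagged male.
#' @return a `variation_config` list.
#' @export
variation_config <- function(shape = c(64L, 64L),
                             brightness = c(-40, 40),
                             contrast = c(0.7, 1.3),
                             noise_sd = c(2, 8),
                             artifact_count = c(0L, 3L),
                             geometry_jitter = 0.06,
                             male_prob = 0.5) {
  cfg <- list(shape = as.integer(shape), brightness = brightness,
              contrast = contrast, noise_sd = noise_sd,
              artifact_count = as.integer(artifact_count),
              geometry_jitter = geometry_jitter, male_prob = male_prob)
  for (f in c("brightness", "contrast", "noise_sd", "artifact_count")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1] > r[2]) {
      config_error(sprintf("variation range '%s' must be (min, max) with min <= max", f))
    }
  }
  if (any(cfg$shape < 32L)) config_error("phantom shape must be at least 32 x 32")
  if (geometry_jitter < 0) config_error("geometry_jitter must be >= 0")
  class(cfg) <- "variation_config"
  cfg
}

#' Finger-length-to-palm ratio as a function of maturity
#'
#' The documented monotone mapping carrying the age signal: the middle-finger
#' length equals `finger_palm_ratio(maturity) * palm semi-major axis` before
#' jitter. Affine and strictly increasing on `[0, 1]`.
#'
#' @param maturity real in `[0, 1]`.
#' @return the jitter-free length ratio.
#' @export
finger_palm_ratio <- function(maturity) 0.9 + 0.9 * maturity

#' Sample hand-phantom parameters
#'
#' Draws one `hand_phantom_params` set from the ranges in `config`. Maturity
#' is uniform on `[0, 1]`; geometric fields that encode maturity are
#' deterministic monotone functions of it plus bounded jitter.
#'
#' @param config a [variation_config()].
#' @param seed optional integer; when given the draw is deterministic.
#' @return an object of class `hand_phantom_params`.
#' @export
sample_phantom_params <- function(config = variation_config(), seed = NULL) {
  if (!inherits(config, "variation_config")) config <- do.call(variation_config, config)
  draw <- function() {
    sh <- config$shape
    s <- min(sh)
    gj <- config$geometry_jitter
    jit <- function(n = 1L) if (gj > 0) stats::runif(n, -gj, gj) else rep(0, n)
    maturity <- stats::runif(1)
    center <- c(sh[1] * 0.66 + s * 0.3 * jit(), sh[2] * 0.5 + s * 0.3 * jit())
    axes <- c(s * 0.145 * (1 + jit()), s * 0.125 * (1 + jit()))
    ratio <- finger_palm_ratio(maturity) + jit()
    lengths <- ratio * axes[1] * FINGER_REL_LENGTH * (1 + 0.5 * jit(5L))
    widths <- axes[2] * 0.26 * FINGER_REL_WIDTH * (1 + jit(5L))
    angles <- FINGER_ANGLE + 0.5 * jit(5L)
    params <- list(
      palm_center = center, palm_axes = axes, finger_count = 5L,
      finger_lengths = lengths, finger_widths = widths,
      finger_angles = angles, maturity = maturity,
      brightness = stats::runif(1, config$brightness[1], config$brightness[2]),
      contrast = stats::runif(1, config$contrast[1], config$contrast[2]),
      noise_sd = stats::runif(1, config$noise_sd[1], config$noise_sd[2]),
      artifact_count = if (config$artifact_count[1] == config$artifact_count[2]) {
        config$artifact_count[1]
      } else {
        sample(seq(config$artifact_count[1], config$artifact_count[2]), 1L)
      },
      male = stats::runif(1) < config$male_prob,
      noise_seed = sample.int(2147483646L, 1L),
      shape = config$shape
    )
    class(params) <- "hand_phantom_params"
    params
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(params) {
  if (params$maturity < 0 || params$maturity > 1) {
    config_error("maturity must lie in [0, 1]")
  }
  if (any(params$finger_lengths <= 0) || any(params$finger_widths <= 0)) {
    config_error("finger lengths and widths must be strictly positive")
  }
  invisible(params)
}

#' Age in months encoded by a parameter set
#' @param params a `hand_phantom_params` object.
#' @return integer months in `[0, 228]`.
#' @export
phantom_age_months <- function(params) as.integer(round(228 * params$maturity))

#' The realized finger-length-to-palm ratio of a parameter set
#'
#' Middle-finger length divided by the palm semi-major axis; equals
#' [finger_palm_ratio()] of the maturity exactly when geometry jitter is 0.
#'
#' @param params a `hand_phantom_params` object.
#' @return real ratio.
#' @export
phantom_age_ratio <- function(params) {
  params$finger_lengths[3] / params$palm_axes[1]
}

finger_segments <- function(params) {
  r0 <- params$palm_center[1]; c0 <- params$palm_center[2]
  a <- params$palm_axes[1]; b <- params$palm_axes[2]
  th <- params$finger_angles
  base <- cbind(r0 - a * cos(th) * 0.92, c0 + b * sin(th) * 0.92)
  tip <- base + cbind(-cos(th), sin(th)) * params$finger_lengths
  list(base = base, tip = tip, width = params$finger_widths)
}

check_fits_frame <- function(params, shape) {
  r0 <- params$palm_center[1]; c0 <- params$palm_center[2]
  a <- params$palm_axes[1]; b <- params$palm_axes[2]
  if (r0 - a < 1.5 || r0 + a > shape[1] - 0.5 ||
      c0 - b < 1.5 || c0 + b > shape[2] - 0.5) {
    geometry_error("palm (palm_center/palm_axes) does not fit inside the frame")
  }
  fg <- finger_segments(params)
  hw <- fg$width / 2
  if (any(fg$tip[, 1] - hw < 1.5) || any(fg$tip[, 1] + hw > shape[1] - 0.5)) {
    geometry_error("finger_lengths push a finger tip outside the frame rows")
  }
  if (any(fg$tip[, 2] - hw < 1.5) || any(fg$tip[, 2] + hw > shape[2] - 0.5)) {
    geometry_error("finger_angles/finger_lengths push a finger outside the frame cols")
  }
  invisible(TRUE)
}

phantom_geometry_fields <- function(params, shape) {
  h <- shape[1]; w <- shape[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r0 <- params$palm_center[1]; c0 <- params$palm_center[2]
  a <- params$palm_axes[1]; b <- params$palm_axes[2]
  ell <- ((rr - r0) / a)^2 + ((cc - c0) / b)^2
  mask <- ell <= 1
  core <- ell <= 0.55^2
  fg <- finger_segments(params)
  for (i in 1:5) {
    vr <- fg$tip[i, 1] - fg$base[i, 1]; vc <- fg$tip[i, 2] - fg$base[i, 2]
    len2 <- vr^2 + vc^2
    t <- ((rr - fg$base[i, 1]) * vr + (cc - fg$base[i, 2]) * vc) / len2
    tcl <- pmin(pmax(t, 0), 1)
    d2 <- (rr - (fg$base[i, 1] + tcl * vr))^2 + (cc - (fg$base[i, 2] + tcl * vc))^2
    mask <- mask | (d2 <= (fg$width[i] / 2)^2)
    core <- core | (d2 <= (0.35 * fg$width[i])^2 & t >= 0.08 & t <= 0.95)
  }
  list(mask = mask * 1, core = core & mask)
}

#' Deterministic base intensity of a phantom
#'
#' Background 25, hand soft tissue 110, ossified core `140 + 50 * maturity`;
#' this is the noise-free, unit-contrast, zero-brightness image.
#'
#' @param params a `hand_phantom_params` object.
#' @param shape image shape `(rows, cols)`.
#' @return numeric matrix.
#' @keywords internal
phantom_base_intensity <- function(params, shape) {
  g <- phantom_geometry_fields(params, shape)
  base <- matrix(25, shape[1], shape[2])
  base[g$mask == 1] <- 110
  base[g$core] <- 140 + 50 * params$maturity
  base
}

render_artifacts <- function(shape, mask, count) {
  art <- matrix(0, shape[1], shape[2])
  if (count < 1) return(art)
  fg <- which(mask == 1, arr.ind = TRUE)
  rmin <- min(fg[, 1]); rmax <- max(fg[, 1])
  cmin <- min(fg[, 2]); cmax <- max(fg[, 2])
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  allowed <- rr < rmin - 1 | rr > rmax + 1 | cc < cmin - 1 | cc > cmax + 1
  allowed_idx <- which(allowed)
  if (length(allowed_idx) == 0L) return(art)
  for (i in seq_len(count)) {
    if (stats::runif(1) < 0.5) {        # bright blob (film label)
      ctr <- allowed_idx[sample.int(length(allowed_idx), 1L)]
      cr <- (ctr - 1L) %% shape[1] + 1L
      ccol <- (ctr - 1L) %/% shape[1] + 1L
      rad <- stats::runif(1, 1.5, 3.5)
      hit <- (rr - cr)^2 + (cc - ccol)^2 <= rad^2
    } else {                            # collimator border bar
      side <- sample.int(4L, 1L)
      thick <- sample.int(3L, 1L)
      hit <- switch(side,
        rr <= thick, rr > shape[1] - thick,
        cc <= thick, cc > shape[2] - thick)
    }
    art[hit & allowed] <- art[hit & allowed] + stats::runif(1, 140, 190)
  }
  art
}

#' Render a phantom image and its ground-truth mask
#'
#' The mask is the union of the palm ellipse and five finger capsules,
#' rasterized by pixel-centre membership. The image is
#' `contrast * base + brightness + N(0, noise_sd) + artifacts`, clipped to
#' `[0, 255]` and rounded to 8-bit levels. Artifacts never intersect the
#' interior of the mask bounding box. A pure function of `params` (noise is
#' driven by the embedded `noise_seed`).
#'
#' @param params a `hand_phantom_params` object.
#' @param shape image shape `(rows, cols)`, at least 32 x 32; defaults to the
#'   shape the parameters were sampled for.
#' @return list with elements `image` (matrix in `[0,255]`) and `mask`
#'   (0/1 matrix).
#' @export
render_phantom <- function(params, shape = params$shape) {
  if (any(shape < 32L)) config_error("render shape must be at least 32 x 32")
  validate_phantom_params(params)
  check_fits_frame(params, shape)
  g <- phantom_geometry_fields(params, shape)
  base <- matrix(25, shape[1], shape[2])
  base[g$mask == 1] <- 110
  base[g$core] <- 140 + 50 * params$maturity
  img <- params$contrast * base + params$brightness
  img <- img + withr::with_seed(params$noise_seed, {
    extra <- render_artifacts(shape, g$mask, params$artifact_count)
    if (params$noise_sd > 0) {
      extra <- extra + matrix(stats::rnorm(length(base), 0, params$noise_sd),
                              shape[1], shape[2])
    }
    extra
  })
  list(image = round(pmin(pmax(img, 0), 255)), mask = g$mask)
}

#' Generate phantom records in memory
#'
#' @param n number of phantoms (>= 1).
#' @param seed integer master seed; the i-th record depends only on
#'   `(seed, i, config)`.
#' @param config a [variation_config()].
#' @return list of records, each with `id`, `image`, `mask`, `age_months`,
#'   `male` and the generating `params`.
#' @export
generate_phantom_records <- function(n, seed, config = variation_config()) {
  if (n < 1) config_error("n must be >= 1")
  lapply(seq_len(n), function(i) {
    params <- sample_phantom_params(config, seed = derive_seed(seed, i))
    rendered <- render_phantom(params)
    list(id = sprintf("ph%05d", i), image = rendered$image, mask = rendered$mask,
         age_months = phantom_age_months(params), male = params$male,
         params = params)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` PNG image/mask pairs plus a CSV manifest with header
#' `id,boneage,male,image,mask` (boneage in months, male in `{True,False}`),
#' mirroring the RSNA challenge manifest layout. Fully reproducible from
#' `(n, seed, config)`.
#'
#' @inheritParams generate_phantom_records
#' @param out_dir output directory (created if missing).
#' @return a `dataset_manifest` (see [read_manifest()]), invisibly reread
#'   from disk.
#' @export
generate_dataset <- function(n, seed, out_dir, config = variation_config()) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  records <- generate_phantom_records(n, seed, config)
  rows <- lapply(records, function(rec) {
    img_rel <- file.path("images", paste0(rec$id, ".png"))
    msk_rel <- file.path("masks", paste0(rec$id, ".png"))
    write_image_png(rec$image, file.path(out_dir, img_rel))
    write_mask_png(rec$mask, file.path(out_dir, msk_rel))
    data.frame(id = rec$id, boneage = rec$age_months,
               male = ifelse(rec$male, "True", "False"),
               image = img_rel, mask = msk_rel, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  invisible(read_manifest(file.path(out_dir, "manifest.csv")))
}

#' Geometry features measured from a binary mask
#'
#' Bounding-box height, width, their ratio, foreground area and top-row
#' extent. On jitter-free phantoms the height is (up to pixel rasterization)
#' affine in maturity, so these features carry the age signal used by the
#' regression stage.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return named numeric vector.
#' @export
geometry_features <- function(mask) {
  assert_binary_mask(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) degenerate_error("mask has no foreground pixels")
  h <- diff(range(fg[, 1])) + 1
  w <- diff(range(fg[, 2])) + 1
  c(height = h, width = w, aspect = h / w, area = nrow(fg), top = min(fg[, 1]))
}
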