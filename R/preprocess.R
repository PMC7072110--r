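# Image preprocessing: per-image standardization, CLAHE, probability-map
# thresholding and mask-driven cropping.

#' Standardize an image to zero mean and unit variance
#'
#' `(img - mean(img)) / sd(img)` with the population (divide by n) standard
#' deviation, computed over all pixels.
#'
#' @param image non-empty numeric matrix.
#' @return numeric matrix with mean 0 and population sd 1.
#' @export
standardize <- function(image) {
  assert_matrix_image(image)
  mu <- mean(image)
  sd_pop <- sqrt(mean((image - mu)^2))
  if (sd_pop == 0) degenerate_error("cannot standardize a constant image (sd = 0)")
  (image - mu) / sd_pop
}

clahe_tile_lut <- function(values, clip_limit) {
  n <- length(values)
  h <- tabulate(values + 1L, nbins = 256L)
  if (is.finite(clip_limit)) {
    cap <- clip_limit * n / 256
    excess <- sum(pmax(h - cap, 0))
    h <- pmin(h, cap) + excess / 256
  }
  round(255 * cumsum(h) / n)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a `tiles` grid; each tile's 256-bin histogram is
#' clipped at `clip_limit` times the uniform bin count (the clipped excess is
#' redistributed evenly) and turned into an integer CDF lookup table mapping
#' to `[0, 255]`. Pixels are mapped by bilinear interpolation between the
#' four surrounding tile tables. With one tile and an infinite clip limit
#' this reduces to global histogram equalization.
#'
#' @param image numeric matrix with values in `[0, 255]`.
#' @param clip_limit positive clip factor (relative to the uniform histogram
#'   level); `Inf` disables clipping.
#' @param tiles integer grid `(rows, cols)`.
#' @return equalized matrix with values in `[0, 255]`.
#' @export
apply_clahe <- function(image, clip_limit = 2.0, tiles = c(8L, 8L)) {
  assert_matrix_image(image)
  if (min(image) < 0 || max(image) > 255) {
    contract_error("apply_clahe expects intensities in [0, 255]")
  }
  if (clip_limit <= 0) config_error("clip_limit must be > 0")
  tiles <- as.integer(tiles)
  if (any(tiles < 1L)) config_error("tiles must be >= (1, 1)")
  h <- nrow(image); w <- ncol(image)
  if (tiles[1] > h || tiles[2] > w) {
    config_error("tile grid is larger than the image")
  }
  tr <- tiles[1]; tc <- tiles[2]
  vals <- pmin(pmax(floor(image), 0), 255)
  # Tile index boundaries (as equal as possible) and tile centres.
  rb <- floor(seq(0, h, length.out = tr + 1))
  cb <- floor(seq(0, w, length.out = tc + 1))
  luts <- vector("list", tr * tc)
  rcen <- (rb[-(tr + 1)] + 1 + rb[-1]) / 2
  ccen <- (cb[-(tc + 1)] + 1 + cb[-1]) / 2
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- vals[(rb[i] + 1):rb[i + 1], (cb[j] + 1):cb[j + 1]]
      luts[[(j - 1L) * tr + i]] <- clahe_tile_lut(tile, clip_limit)
    }
  }
  # Bilinear blend of the four surrounding tile mappings, clamped at edges.
  ri <- findInterval(seq_len(h), rcen, rightmost.closed = FALSE)
  ci <- findInterval(seq_len(w), ccen, rightmost.closed = FALSE)
  r0 <- pmin(pmax(ri, 1L), tr); r1 <- pmin(r0 + 1L, tr)
  c0 <- pmin(pmax(ci, 1L), tc); c1 <- pmin(c0 + 1L, tc)
  fr <- ifelse(r1 > r0, (seq_len(h) - rcen[r0]) / (rcen[r1] - rcen[r0]), 0)
  fr <- pmin(pmax(fr, 0), 1)
  fc <- ifelse(c1 > c0, (seq_len(w) - ccen[c0]) / (ccen[c1] - ccen[c0]), 0)
  fc <- pmin(pmax(fc, 0), 1)
  bin <- vals + 1L
  # Four corner lookups, vectorized over rows within each column.
  m00 <- matrix(0, h, w); m10 <- m00; m01 <- m00; m11 <- m00
  for (j in seq_len(w)) {
    b <- bin[, j]
    for (i in unique(r0)) {
      rows <- which(r0 == i)
      m00[rows, j] <- luts[[(c0[j] - 1L) * tr + i]][b[rows]]
      m01[rows, j] <- luts[[(c1[j] - 1L) * tr + i]][b[rows]]
    }
    for (i in unique(r1)) {
      rows <- which(r1 == i)
      m10[rows, j] <- luts[[(c0[j] - 1L) * tr + i]][b[rows]]
      m11[rows, j] <- luts[[(c1[j] - 1L) * tr + i]][b[rows]]
    }
  }
  frm <- matrix(fr, h, w)
  fcm <- matrix(fc, h, w, byrow = TRUE)
  out <- (m00 * (1 - frm) + m10 * frm) * (1 - fcm) +
    (m01 * (1 - frm) + m11 * frm) * fcm
  pmin(pmax(out, 0), 255)
}

#' Threshold a probability map into a binary mask
#'
#' @param prob_map matrix with values in `[0, 1]`.
#' @param threshold scalar in `[0, 1]`; a pixel is foreground iff its
#'   probability is `>= threshold`.
#' @return 0/1 matrix.
#' @export
binarize <- function(prob_map, threshold = 0.5) {
  assert_matrix_image(prob_map, "prob_map")
  if (min(prob_map) < 0 || max(prob_map) > 1) {
    contract_error("probability map values must lie in [0, 1]")
  }
  if (threshold < 0 || threshold > 1) {
    config_error("threshold must lie in [0, 1]")
  }
  (prob_map >= threshold) * 1
}

#' Crop an image to the mask bounding box
#'
#' Returns the tight bounding box of the mask foreground expanded by
#' `margin` pixels on every side and clipped to the frame.
#'
#' @param image numeric matrix.
#' @param mask 0/1 matrix of the same shape.
#' @param margin non-negative integer margin in pixels.
#' @return the cropped sub-image.
#' @export
crop_to_mask <- function(image, mask, margin = 0L) {
  assert_matrix_image(image)
  assert_binary_mask(mask)
  if (!all(dim(image) == dim(mask))) {
    contract_error("image and mask shapes differ")
  }
  if (margin < 0) config_error("margin must be >= 0")
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) degenerate_error("cannot crop to an empty mask")
  r1 <- max(min(fg[, 1]) - margin, 1L)
  r2 <- min(max(fg[, 1]) + margin, nrow(image))
  c1 <- max(min(fg[, 2]) - margin, 1L)
  c2 <- min(max(fg[, 2]) + margin, ncol(image))
  image[r1:r2, c1:c2, drop = FALSE]
}
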