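# Shared internal helpers: seed derivation, validation, image plumbing.

#' Derive a child seed from a parent seed
#'
#' Deterministic integer mixing used to hand independent seeds to the
#' generator, committee members, fold shuffles and bootstrap resamples while
#' keeping a single user-facing seed. Result is always a valid 32-bit R
#' integer in `[0, 2^31 - 2]`.
#'
#' @param seed integer parent seed.
#' @param offset integer stream offset (>= 0).
#' @return integer child seed.
#' @keywords internal
derive_seed <- function(seed, offset = 0L) {
  # 2^31 - 1 is prime; multiplier is a Lehmer-style constant small enough
  # that the product stays exact in doubles (< 2^53).
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m)
  x <- (x * 48271 + as.numeric(offset) * 1299709 + 12345) %% m
  as.integer(x)
}

stop_handbaa <- function(msg, class) {
  stop(structure(
    class = c(class, "handbaa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) stop_handbaa(msg, "handbaa_config_error")
contract_error <- function(msg) stop_handbaa(msg, "handbaa_contract_error")
geometry_error <- function(msg) stop_handbaa(msg, "handbaa_geometry_error")
degenerate_error <- function(msg) stop_handbaa(msg, "handbaa_degenerate_error")

assert_matrix_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L) {
    contract_error(sprintf("%s must be a non-empty numeric matrix", name))
  }
  invisible(x)
}

assert_binary_mask <- function(x, name = "mask") {
  assert_matrix_image(x, name)
  if (!all(x %in% c(0, 1))) {
    contract_error(sprintf("%s must contain only 0/1 values", name))
  }
  invisible(x)
}

#' Bilinear image resize
#'
#' @param image numeric matrix.
#' @param shape integer vector `(rows, cols)` of the output.
#' @return resized numeric matrix.
#' @keywords internal
resize_bilinear <- function(image, shape) {
  assert_matrix_image(image)
  h <- nrow(image); w <- ncol(image)
  oh <- shape[1]; ow <- shape[2]
  if (oh == h && ow == w) return(image)
  # Pixel-centre alignment: output centre u maps to input centre.
  rs <- (seq_len(oh) - 0.5) * h / oh + 0.5
  cs <- (seq_len(ow) - 0.5) * w / ow + 0.5
  r0 <- pmin(pmax(floor(rs), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(cs), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(rs - r0, 0), 1); fc <- pmin(pmax(cs - c0, 0), 1)
  a <- image[r0, c0, drop = FALSE]; b <- image[r1, c0, drop = FALSE]
  d <- image[r0, c1, drop = FALSE]; e <- image[r1, c1, drop = FALSE]
  top <- a * (1 - fr) + b * fr
  bot <- d * (1 - fr) + e * fr
  top * rep(1 - fc, each = oh) + bot * rep(fc, each = oh)
}

#' Nearest-neighbour resize (for masks)
#' @inheritParams resize_bilinear
#' @keywords internal
resize_nearest <- function(image, shape) {
  assert_matrix_image(image)
  h <- nrow(image); w <- ncol(image)
  oh <- shape[1]; ow <- shape[2]
  if (oh == h && ow == w) return(image)
  ri <- pmin(pmax(ceiling((seq_len(oh) - 0.5) * h / oh), 1), h)
  ci <- pmin(pmax(ceiling((seq_len(ow) - 0.5) * w / ow), 1), w)
  image[ri, ci, drop = FALSE]
}

#' Read / write 8-bit grayscale PNG images
#'
#' Images are kept in-memory as numeric matrices with values in `[0, 255]`;
#' masks as 0/1 matrices, stored on disk as 0/255 per the manifest contract.
#'
#' @param path file path.
#' @return `read_image_png` a matrix in `[0,255]`; `read_mask_png` a 0/1 matrix.
#' @keywords internal
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  round(arr * 255)
}

#' @rdname read_image_png
#' @keywords internal
read_mask_png <- function(path) {
  img <- read_image_png(path)
  (img >= 128) * 1
}

#' @rdname read_image_png
#' @param image matrix in `[0,255]`.
#' @keywords internal
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname read_image_png
#' @param mask 0/1 matrix.
#' @keywords internal
write_mask_png <- function(mask, path) {
  png::writePNG(pmin(pmax(mask, 0), 1), path)
  invisible(path)
}
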