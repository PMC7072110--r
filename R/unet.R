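# A small U-Net (encoder-decoder with skip connections, sigmoid head)
# implemented directly on base R matrix algebra. Convolutions use
# precomputed im2col index maps so forward and backward passes are BLAS
# matrix products; the optimizer is Adam. Activations are stored as
# (H*W) x channels matrices in column-major pixel order.

#' U-Net configuration
#'
#' @param depth number of down-sampling stages; the bottleneck sits at
#'   spatial resolution `input_size / 2^depth`.
#' @param base_filters filters at the first stage; doubled at every stage.
#' @param input_size `(rows, cols)`, each divisible by `2^depth`.
#' @param seed integer initialization seed; two builds with equal config are
#'   byte-identical, distinct seeds give distinct parameters.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size for one training epoch.
#' @return a `unet_config` list.
#' @export
unet_config <- function(depth = 4L, base_filters = 32L,
                        input_size = c(128L, 128L), seed = 1L,
                        learning_rate = 1e-3, batch_size = 4L) {
  cfg <- list(depth = as.integer(depth), base_filters = as.integer(base_filters),
              input_size = as.integer(input_size), seed = as.integer(seed),
              learning_rate = learning_rate, batch_size = as.integer(batch_size))
  if (cfg$base_filters < 1L) config_error("base_filters must be >= 1")
  if (cfg$depth < 1L) config_error("depth must be >= 1")
  if (any(cfg$input_size %% (2L^cfg$depth) != 0L)) {
    config_error("input_size must be divisible by 2^depth")
  }
  class(cfg) <- "unet_config"
  cfg
}

pool_geom <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(seq_len(H2), W2)
  c2 <- rep(seq_len(W2), each = H2)
  list(i1 = (2L * r2 - 1L) + (2L * c2 - 2L) * H,
       i2 = (2L * r2) + (2L * c2 - 2L) * H,
       i3 = (2L * r2 - 1L) + (2L * c2 - 1L) * H,
       i4 = (2L * r2) + (2L * c2 - 1L) * H)
}

upsample_map <- function(H, W) {
  # output (H, W) pulled from input (H/2, W/2), nearest neighbour
  H2 <- H %/% 2L
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  ceiling(rr / 2) + (ceiling(cc / 2) - 1L) * H2
}

new_conv_layer <- function(name, level, Cin, Cout, H, W, ksize = 3L) {
  fan_in <- if (ksize == 3L) 9L * Cin else Cin
  W0 <- matrix(stats::rnorm(fan_in * Cout, 0, sqrt(2 / fan_in)), fan_in, Cout)
  list(name = name, level = level, Cin = Cin, Cout = Cout, ksize = ksize,
       W = W0, b = numeric(Cout), H = H, W_sp = W)
}

#' Build a seeded U-Net segmentation model
#'
#' Encoder: `depth` stages of two 3x3 conv + ReLU layers followed by 2x2 max
#' pooling; bottleneck: two conv + ReLU layers at `base_filters * 2^depth`
#' channels; decoder: nearest-neighbour upsampling, concatenation with the
#' skip connection and two conv + ReLU layers per stage; head: 1x1 conv with
#' sigmoid. All parameters are drawn from `config$seed`.
#'
#' @param config a [unet_config()].
#' @return an object of class `unet_model`.
#' @export
build_unet <- function(config) {
  if (!inherits(config, "unet_config")) config <- do.call(unet_config, config)
  d <- config$depth; f0 <- config$base_filters
  H <- config$input_size[1]; W <- config$input_size[2]
  layers <- list()
  pool <- list(); up <- list()
  withr::with_seed(config$seed, {
    h <- H; w <- W
    for (i in seq_len(d)) {
      cin <- if (i == 1L) 1L else f0 * 2L^(i - 2L)
      cout <- f0 * 2L^(i - 1L)
      layers[[paste0("enc", i, "a")]] <- new_conv_layer(paste0("enc", i, "a"), i, cin, cout, h, w)
      layers[[paste0("enc", i, "b")]] <- new_conv_layer(paste0("enc", i, "b"), i, cout, cout, h, w)
      pool[[i]] <- pool_geom(h, w)
      h <- h %/% 2L; w <- w %/% 2L
    }
    cb <- f0 * 2L^d
    layers[["bot_a"]] <- new_conv_layer("bot_a", d + 1L, cb %/% 2L, cb, h, w)
    layers[["bot_b"]] <- new_conv_layer("bot_b", d + 1L, cb, cb, h, w)
    for (i in rev(seq_len(d))) {
      h <- H %/% 2L^(i - 1L); w <- W %/% 2L^(i - 1L)
      up[[i]] <- upsample_map(h, w)
      cup <- f0 * 2L^i
      cskip <- f0 * 2L^(i - 1L)
      layers[[paste0("dec", i, "a")]] <- new_conv_layer(paste0("dec", i, "a"), i, cup + cskip, cskip, h, w)
      layers[[paste0("dec", i, "b")]] <- new_conv_layer(paste0("dec", i, "b"), i, cskip, cskip, h, w)
    }
    layers[["head"]] <- new_conv_layer("head", 1L, f0, 1L, H, W, ksize = 1L)
  })
  opt <- lapply(layers, function(l) {
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
  structure(list(config = config, layers = layers, pool = pool, up = up,
                 opt = opt, opt_t = 0L, trained_epochs = 0L),
            class = "unet_model")
}

conv3_fwd <- function(layer, A) {
  patches <- im2col3(A, layer$H, layer$W_sp)
  Z <- patches %*% layer$W
  Z <- Z + rep(layer$b, each = nrow(Z))
  list(Z = Z, patches = patches)
}

conv3_bwd <- function(layer, dZ, patches, need_dA = TRUE) {
  out <- list(dW = crossprod(patches, dZ), db = colSums(dZ), dA = NULL)
  if (need_dA) {
    out$dA <- col2im3(dZ %*% t(layer$W), layer$H, layer$W_sp)
  }
  out
}

maxpool_fwd <- function(A, pg) {
  A1 <- A[pg$i1, , drop = FALSE]; A2 <- A[pg$i2, , drop = FALSE]
  A3 <- A[pg$i3, , drop = FALSE]; A4 <- A[pg$i4, , drop = FALSE]
  M <- pmax(pmax(A1, A2), pmax(A3, A4))
  m1 <- A1 >= M
  m2 <- !m1 & A2 >= M
  m3 <- !m1 & !m2 & A3 >= M
  m4 <- !(m1 | m2 | m3)
  list(M = M, m1 = m1, m2 = m2, m3 = m3, m4 = m4)
}

maxpool_bwd <- function(dM, cache, pg, HW, C) {
  dA <- matrix(0, HW, C)
  dA[pg$i1, ] <- dM * cache$m1
  dA[pg$i2, ] <- dA[pg$i2, ] + dM * cache$m2
  dA[pg$i3, ] <- dA[pg$i3, ] + dM * cache$m3
  dA[pg$i4, ] <- dA[pg$i4, ] + dM * cache$m4
  dA
}

sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -30), 30)))

as_input_column <- function(model, image) {
  sz <- model$config$input_size
  if (is.matrix(image)) {
    if (!all(dim(image) == sz)) {
      contract_error(sprintf("image shape (%d, %d) does not match input_size (%d, %d)",
                             nrow(image), ncol(image), sz[1], sz[2]))
    }
    matrix(as.vector(image), ncol = 1L)
  } else {
    if (length(image) != prod(sz)) contract_error("image length does not match input_size")
    matrix(image, ncol = 1L)
  }
}

unet_forward <- function(model, x, mode = "predict") {
  d <- model$config$depth
  ly <- model$layers
  caches <- if (mode == "train") list() else NULL
  skips <- vector("list", d)
  A <- x
  for (i in seq_len(d)) {
    for (part in c("a", "b")) {
      nm <- paste0("enc", i, part)
      cf <- conv3_fwd(ly[[nm]], A)
      A <- pmax(cf$Z, 0)
      if (mode == "train") caches[[nm]] <- list(patches = cf$patches, mask = cf$Z > 0)
    }
    skips[[i]] <- A
    pf <- maxpool_fwd(A, model$pool[[i]])
    if (mode == "train") caches[[paste0("pool", i)]] <- pf[c("m1", "m2", "m3", "m4")]
    A <- pf$M
  }
  for (nm in c("bot_a", "bot_b")) {
    cf <- conv3_fwd(ly[[nm]], A)
    A <- pmax(cf$Z, 0)
    if (mode == "train") caches[[nm]] <- list(patches = cf$patches, mask = cf$Z > 0)
  }
  if (mode == "bottleneck") return(colMeans(A))
  if (mode == "botmaps") return(A)
  for (i in rev(seq_len(d))) {
    U <- A[model$up[[i]], , drop = FALSE]
    A <- cbind(U, skips[[i]])
    for (part in c("a", "b")) {
      nm <- paste0("dec", i, part)
      cf <- conv3_fwd(ly[[nm]], A)
      A <- pmax(cf$Z, 0)
      if (mode == "train") caches[[nm]] <- list(patches = cf$patches, mask = cf$Z > 0)
    }
  }
  z <- A %*% ly$head$W + ly$head$b[1]
  p <- sigmoid(z)
  if (mode == "train") {
    caches$head_in <- A
    list(p = p, caches = caches)
  } else {
    p
  }
}

unet_backward <- function(model, caches, dz) {
  d <- model$config$depth
  f0 <- model$config$base_filters
  ly <- model$layers
  g <- list()
  g$head <- list(dW = crossprod(caches$head_in, dz), db = sum(dz))
  dA <- dz %*% t(ly$head$W)
  dskips <- vector("list", d)
  for (i in seq_len(d)) {
    for (part in c("b", "a")) {
      nm <- paste0("dec", i, part)
      dZ <- dA * caches[[nm]]$mask
      bw <- conv3_bwd(ly[[nm]], dZ, caches[[nm]]$patches)
      g[[nm]] <- bw[c("dW", "db")]
      dA <- bw$dA
    }
    cup <- f0 * 2L^i
    dU <- dA[, seq_len(cup), drop = FALSE]
    dskips[[i]] <- dA[, -seq_len(cup), drop = FALSE]
    dA <- rowsum(dU, model$up[[i]])
  }
  for (nm in c("bot_b", "bot_a")) {
    dZ <- dA * caches[[nm]]$mask
    bw <- conv3_bwd(ly[[nm]], dZ, caches[[nm]]$patches)
    g[[nm]] <- bw[c("dW", "db")]
    dA <- bw$dA
  }
  H <- model$config$input_size[1]; W <- model$config$input_size[2]
  for (i in rev(seq_len(d))) {
    HWi <- (H %/% 2L^(i - 1L)) * (W %/% 2L^(i - 1L))
    C <- f0 * 2L^(i - 1L)
    dA <- maxpool_bwd(dA, caches[[paste0("pool", i)]], model$pool[[i]], HWi, C)
    dA <- dA + dskips[[i]]
    for (part in c("b", "a")) {
      nm <- paste0("enc", i, part)
      dZ <- dA * caches[[nm]]$mask
      bw <- conv3_bwd(ly[[nm]], dZ, caches[[nm]]$patches,
                      need_dA = !(i == 1L && part == "a"))
      g[[nm]] <- bw[c("dW", "db")]
      dA <- bw$dA
    }
  }
  g
}

adam_step <- function(model, grads) {
  lr <- model$config$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  model$opt_t <- model$opt_t + 1L
  t <- model$opt_t
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  for (nm in names(grads)) {
    o <- model$opt[[nm]]
    gW <- grads[[nm]]$dW; gb <- grads[[nm]]$db
    o$mW <- b1 * o$mW + (1 - b1) * gW
    o$vW <- b2 * o$vW + (1 - b2) * gW^2
    o$mb <- b1 * o$mb + (1 - b1) * gb
    o$vb <- b2 * o$vb + (1 - b2) * gb^2
    model$layers[[nm]]$W <- model$layers[[nm]]$W -
      lr * (o$mW / corr1) / (sqrt(o$vW / corr2) + eps)
    model$layers[[nm]]$b <- model$layers[[nm]]$b -
      lr * (o$mb / corr1) / (sqrt(o$vb / corr2) + eps)
    model$opt[[nm]] <- o
  }
  model
}

#' Pixel-wise cross-entropy loss
#'
#' Summed (not averaged) over all pixels:
#' `sum_i -y_i log(p_i) - (1 - y_i) log(1 - p_i)`, with probabilities clipped
#' to `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param truth_mask 0/1 matrix (or vector).
#' @param prob_map matrix (or vector) of probabilities in `[0, 1]`, same shape.
#' @return non-negative scalar loss.
#' @export
pixelwise_cross_entropy <- function(truth_mask, prob_map) {
  if (length(truth_mask) != length(prob_map) ||
      (is.matrix(truth_mask) && is.matrix(prob_map) &&
       !all(dim(truth_mask) == dim(prob_map)))) {
    contract_error("truth and probability map shapes differ")
  }
  y <- as.vector(truth_mask)
  if (!all(y %in% c(0, 1))) contract_error("truth mask must be 0/1")
  p <- as.vector(prob_map)
  if (min(p) < 0 || max(p) > 1) contract_error("probabilities must lie in [0, 1]")
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(-y * log(p) - (1 - y) * log(1 - p))
}

pool_item_tensors <- function(model, pool) {
  lapply(pool, function(item) {
    x <- as_input_column(model, item$image)
    y <- item$mask
    if (length(y) != nrow(x)) contract_error(
      sprintf("mask size for '%s' does not match model input_size", item$id %||% "?"))
    list(x = x, y = as.vector(y))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a U-Net for one epoch
#'
#' One pass over seeded, shuffled mini-batches of the labeled pool,
#' minimizing the summed pixel-wise cross-entropy (per-image sums averaged
#' within each mini-batch) with Adam.
#'
#' @param model a `unet_model`.
#' @param pool non-empty list of items, each with `image` (standardized
#'   matrix at `input_size`) and `mask` (0/1 matrix); an `id` field is
#'   carried through error messages.
#' @param learning_rate optional override of the configured step size.
#' @return list with the updated `model` and `loss`, the mean per-image
#'   summed cross-entropy over the epoch.
#' @export
train_epoch <- function(model, pool, learning_rate = NULL) {
  if (length(pool) == 0L) contract_error("labeled pool is empty")
  if (!is.null(learning_rate)) model$config$learning_rate <- learning_rate
  tensors <- pool_item_tensors(model, pool)
  n <- length(tensors)
  ord <- withr::with_seed(
    derive_seed(model$config$seed, 100000L + model$trained_epochs),
    sample.int(n))
  bs <- max(1L, model$config$batch_size)
  losses <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    idx <- ord[pos:min(pos + bs - 1L, n)]
    B <- length(idx)
    grads <- NULL
    for (j in idx) {
      it <- tensors[[j]]
      fw <- unet_forward(model, it$x, mode = "train")
      losses[j] <- pixelwise_cross_entropy(it$y, fw$p)
      dz <- (fw$p - it$y) / B
      g <- unet_backward(model, fw$caches, dz)
      if (is.null(grads)) {
        grads <- g
      } else {
        for (nm in names(g)) {
          grads[[nm]]$dW <- grads[[nm]]$dW + g[[nm]]$dW
          grads[[nm]]$db <- grads[[nm]]$db + g[[nm]]$db
        }
      }
    }
    model <- adam_step(model, grads)
    pos <- pos + B
  }
  model$trained_epochs <- model$trained_epochs + 1L
  list(model = model, loss = mean(losses))
}

#' Predict a per-pixel foreground probability map
#'
#' Deterministic inference-mode forward pass.
#'
#' @param model a `unet_model`.
#' @param image standardized matrix at `input_size`.
#' @return matrix of probabilities in `[0, 1]`, same spatial shape as input.
#' @export
predict_probability_map <- function(model, image) {
  x <- as_input_column(model, image)
  p <- unet_forward(model, x, mode = "predict")
  matrix(p, model$config$input_size[1], model$config$input_size[2])
}

#' Extract the bottleneck deep feature vector
#'
#' Global average pooling of the deepest (bottleneck) feature maps, flattened
#' to a vector of length `base_filters * 2^depth`. This is the vector the
#' query-by-committee disagreement measure compares across members.
#'
#' @param model a `unet_model`.
#' @param image standardized matrix at `input_size`.
#' @return numeric feature vector.
#' @export
extract_feature_vector <- function(model, image) {
  if (!inherits(model, "unet_model") || is.null(model$layers$bot_b)) {
    contract_error("invalid segmentation model state")
  }
  x <- as_input_column(model, image)
  v <- unet_forward(model, x, mode = "bottleneck")
  if (any(!is.finite(v))) contract_error("non-finite feature vector (invalid model state)")
  v
}

#' Serialize / restore a segmentation model
#'
#' @param model a `unet_model`.
#' @param path file path for the versioned checkpoint.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "handbaa-unet", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "handbaa-unet")) {
    contract_error("not a handbaa model checkpoint")
  }
  obj$model
}
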