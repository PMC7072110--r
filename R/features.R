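# Transfer-style feature extraction: a pluggable backbone produces a 3-D
# feature tensor per image, global average pooling flattens it to a vector,
# and 2-D PCA decompositions support feature inspection. Large pretrained
# ImageNet backbones are out of desk scale; the default backbone reuses the
# encoder of a trained segmentation model.

#' Global average pooling
#'
#' Per-channel spatial mean of a `rows x cols x channels` feature tensor.
#'
#' @param feature_tensor 3-D numeric array (a matrix is treated as a single
#'   channel).
#' @return numeric vector, one entry per channel.
#' @export
global_average_pool <- function(feature_tensor) {
  if (is.matrix(feature_tensor)) {
    feature_tensor <- array(feature_tensor, c(dim(feature_tensor), 1L))
  }
  d <- dim(feature_tensor)
  if (length(d) != 3L || any(d == 0L)) {
    contract_error("feature tensor must be a non-empty rows x cols x channels array")
  }
  colMeans(matrix(feature_tensor, d[1] * d[2], d[3]))
}

#' Feature backbones
#'
#' A backbone is a list with a `name` and a deterministic `forward` function
#' mapping a preprocessed image to a 3-D feature tensor.
#' `backbone_identity` copies intensities into a single channel (so GAP
#' yields the mean intensity — mostly useful for testing);
#' `backbone_from_unet` reuses the encoder + bottleneck of a trained
#' segmentation model, the desk-scale stand-in for large pretrained CNNs.
#'
#' @return a `feature_backbone` list.
#' @export
backbone_identity <- function() {
  structure(list(
    name = "identity",
    forward = function(image) array(image, c(dim(image), 1L))
  ), class = "feature_backbone")
}

#' @rdname backbone_identity
#' @param model a trained `unet_model`.
#' @export
backbone_from_unet <- function(model) {
  if (!inherits(model, "unet_model")) contract_error("model must be a unet_model")
  d <- model$config$depth
  h <- model$config$input_size[1] %/% 2L^d
  w <- model$config$input_size[2] %/% 2L^d
  structure(list(
    name = "unet-bottleneck",
    forward = function(image) {
      A <- unet_forward(model, as_input_column(model, image), mode = "botmaps")
      array(A, c(h, w, ncol(A)))
    }
  ), class = "feature_backbone")
}

#' Extract a feature matrix from a list of images
#'
#' Row i is the global-average-pooled backbone output of image i; row order
#' preserves input order.
#'
#' @param backbone a `feature_backbone`.
#' @param images list of preprocessed image matrices at the backbone's
#'   expected size.
#' @param ids optional character ids, aligned with `images`.
#' @return a `feature_matrix`: list with `features` (n x channels matrix),
#'   `ids` and `backbone` name.
#' @export
extract_features <- function(backbone, images, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("img%04d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    tensor <- tryCatch(backbone$forward(images[[i]]), error = function(e) {
      contract_error(sprintf("backbone '%s' failed on image '%s': %s",
                             backbone$name, ids[i], conditionMessage(e)))
    })
    global_average_pool(tensor)
  })
  structure(list(features = do.call(rbind, rows), ids = ids,
                 backbone = backbone$name), class = "feature_matrix")
}

feature_matrix_of <- function(x) {
  if (inherits(x, "feature_matrix")) x$features else as.matrix(x)
}

fix_score_signs <- function(scores) {
  for (j in seq_len(ncol(scores))) {
    col <- scores[, j]
    if (any(col != 0)) {
      i <- which.max(abs(col))
      if (col[i] < 0) scores[, j] <- -col
    }
  }
  scores
}

#' Incremental principal component analysis
#'
#' Sequential merge-SVD over mini-batches; on a single batch it is exact PCA.
#'
#' @param x numeric data matrix (rows = observations).
#' @param ncomp number of components to keep.
#' @param batch_size rows per batch; `NULL` processes all rows at once.
#' @return list with `components` (ncomp x p), `center`, `sdev` and `scores`
#'   (projection of all rows of `x`).
#' @export
incremental_pca <- function(x, ncomp = 2L, batch_size = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (is.null(batch_size)) batch_size <- n
  r <- min(ncomp + 5L, p, n)    # carry a few extra components for accuracy
  mu <- NULL; S <- NULL; V <- NULL; seen <- 0L
  pos <- 1L
  while (pos <= n) {
    B <- x[pos:min(pos + batch_size - 1L, n), , drop = FALSE]
    m <- nrow(B)
    bm <- colMeans(B)
    if (seen == 0L) {
      M <- sweep(B, 2L, bm)
      mu <- bm
    } else {
      newmu <- (seen * mu + m * bm) / (seen + m)
      corr <- sqrt(seen * m / (seen + m)) * (bm - mu)
      M <- rbind(V * S, sweep(B, 2L, bm), corr)
      mu <- newmu
    }
    sv <- svd(M, nu = 0, nv = min(r, ncol(M)))
    keep <- seq_len(min(r, length(sv$d)))
    S <- sv$d[keep]
    V <- t(sv$v[, keep, drop = FALSE])
    seen <- seen + m
    pos <- pos + m
  }
  comp <- V[seq_len(min(ncomp, nrow(V))), , drop = FALSE]
  scores <- sweep(x, 2L, mu) %*% t(comp)
  list(components = comp, center = mu, sdev = S[seq_len(nrow(comp))] / sqrt(max(seen - 1L, 1L)),
       scores = scores)
}

#' Decompose a feature matrix into 2-D for inspection
#'
#' Centered decomposition to the top two components by incremental PCA or
#' kernel PCA (linear or RBF kernel, via \pkg{kernlab}); the RBF bandwidth
#' defaults to the median pairwise-distance heuristic. Score column signs
#' are fixed so the largest-magnitude entry of each column is positive,
#' making embeddings reproducible.
#'
#' @param features a `feature_matrix` or plain matrix with >= 3 rows and
#'   >= 2 columns.
#' @param method one of `"incremental-pca"`, `"kernel-pca-linear"`,
#'   `"kernel-pca-rbf"`.
#' @param seed integer (kept for interface stability; the decompositions are
#'   deterministic).
#' @param ages optional ages in months, aligned with rows, carried for
#'   coloring.
#' @param batch_size passed to [incremental_pca()].
#' @return an `embedding2d`: list with `points` (n x 2), `method`, `ages`,
#'   `ids`.
#' @export
decompose_2d <- function(features,
                         method = c("incremental-pca", "kernel-pca-linear",
                                    "kernel-pca-rbf"),
                         seed = 0L, ages = NULL, batch_size = NULL) {
  method <- match.arg(method)
  X <- feature_matrix_of(features)
  ids <- if (inherits(features, "feature_matrix")) features$ids else rownames(X)
  if (nrow(X) < 3L) contract_error("decompose_2d needs at least 3 rows")
  if (ncol(X) < 2L) contract_error("decompose_2d needs feature dimension >= 2")
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-10)
  if (rank < 2L) {
    warning("feature matrix has rank < 2; degenerate embedding with zero columns")
    pts <- matrix(0, nrow(X), 2L)
    if (rank == 1L) {
      pc <- incremental_pca(X, ncomp = 1L)
      pts[, 1] <- pc$scores[, 1]
    }
    pts <- fix_score_signs(pts)
  } else {
    pts <- switch(method,
      "incremental-pca" = incremental_pca(X, ncomp = 2L, batch_size = batch_size)$scores,
      "kernel-pca-linear" = {
        kp <- kernlab::kpca(X, kernel = "vanilladot", kpar = list(), features = 2L)
        # kernlab scales projections by sqrt(n) relative to the usual
        # principal-component score convention; undo it.
        kernlab::rotated(kp) / sqrt(nrow(X))
      },
      "kernel-pca-rbf" = {
        med <- stats::median(stats::dist(X))
        sigma <- if (med > 0) 1 / (2 * med^2) else 1
        kp <- kernlab::kpca(X, kernel = "rbfdot", kpar = list(sigma = sigma),
                            features = 2L)
        kernlab::rotated(kp) / sqrt(nrow(X))
      })
    pts <- fix_score_signs(pts[, 1:2, drop = FALSE])
  }
  structure(list(points = unname(pts), method = method, ages = ages, ids = ids),
            class = "embedding2d")
}

#' Export a 2-D embedding as a scatter plot and CSV
#'
#' Writes a PNG scatter colored by age (when ages are present) and a CSV
#' `id,x,y,age` of the points next to it.
#'
#' @param embedding an `embedding2d`.
#' @param out_path path of the PNG to write; the CSV uses the same stem.
#' @return named character vector of the written paths, invisibly.
#' @export
export_scatter <- function(embedding, out_path) {
  pts <- embedding$points
  n <- nrow(pts)
  ids <- embedding$ids %||% sprintf("img%04d", seq_len(n))
  ages <- embedding$ages %||% rep(NA_real_, n)
  csv_path <- paste0(sub("\\.png$", "", out_path), ".csv")
  df <- data.frame(id = ids, x = pts[, 1], y = pts[, 2], age = ages,
                   stringsAsFactors = FALSE)
  utils::write.table(df, csv_path, sep = ",", quote = FALSE, row.names = FALSE)
  grDevices::png(out_path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  col <- if (all(is.na(ages))) "steelblue" else {
    pal <- grDevices::hcl.colors(100, "viridis")
    pal[pmin(100L, 1L + floor(99 * (ages - min(ages)) /
                                max(max(ages) - min(ages), 1)))]
  }
  graphics::plot(pts[, 1], pts[, 2], col = col, pch = 19,
                 xlab = "component 1", ylab = "component 2",
                 main = sprintf("2-D embedding (%s)", embedding$method))
  invisible(c(png = out_path, csv = csv_path))
}
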