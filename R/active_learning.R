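# Query-by-committee active learning for hand segmentation.
#
# A committee of k U-Nets differs only in initialization seed. After every
# training epoch each member extracts a deep feature vector from every
# unlabeled image; low mean pairwise cosine similarity across members marks
# the images the committee disagrees on, and those are sent to the oracle
# for annotation.

#' Cosine similarity between two feature vectors
#'
#' `dot(v1, v2) / (|v1| * |v2|)`, in `[-1, 1]`.
#'
#' @param v1,v2 numeric vectors of equal length, each with nonzero norm.
#' @return scalar similarity.
#' @export
cosine_similarity <- function(v1, v2) {
  if (length(v1) != length(v2)) contract_error("feature vectors differ in length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) degenerate_error("cosine similarity undefined for a zero vector")
  s <- sum(v1 * v2) / (n1 * n2)
  min(max(s, -1), 1)
}

#' Active-learning schedule configuration
#'
#' Defaults follow the annotation schedule the method was designed around:
#' an initial pool of 100 labeled radiographs, 10 images queried after each
#' of the first 20 training epochs (so 300 labeled in total), then 80 more
#' epochs without querying.
#'
#' @param k committee size (>= 2).
#' @param initial_labeled size of the initial labeled pool.
#' @param queries_per_epoch images annotated after each query epoch.
#' @param query_epochs number of epochs with querying.
#' @param post_epochs additional epochs without querying (>= 0).
#' @param master_seed seed; member i is initialized with `master_seed + i`.
#' @param aggregate committee disagreement aggregate over member pairs:
#'   `"mean"` (default) or `"min"`.
#' @return an `al_config` list.
#' @export
al_config <- function(k = 3L, initial_labeled = 100L, queries_per_epoch = 10L,
                      query_epochs = 20L, post_epochs = 80L, master_seed = 0L,
                      aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  cfg <- list(k = as.integer(k), initial_labeled = as.integer(initial_labeled),
              queries_per_epoch = as.integer(queries_per_epoch),
              query_epochs = as.integer(query_epochs),
              post_epochs = as.integer(post_epochs),
              master_seed = as.integer(master_seed), aggregate = aggregate)
  if (cfg$k < 2L) config_error("committee size k must be >= 2")
  if (cfg$initial_labeled < 1L || cfg$queries_per_epoch < 1L || cfg$query_epochs < 0L) {
    config_error("initial_labeled and queries_per_epoch must be >= 1, query_epochs >= 0")
  }
  if (cfg$post_epochs < 0L) config_error("post_epochs must be >= 0")
  class(cfg) <- "al_config"
  cfg
}

#' Build a committee of seeded U-Nets
#'
#' All members share one architecture config and differ only in their
#' initialization seed (`master_seed + index`, pairwise distinct).
#'
#' @param net_config a [unet_config()] (its `seed` field is overridden
#'   per member).
#' @param k committee size.
#' @param master_seed integer.
#' @return an object of class `committee`.
#' @export
build_committee <- function(net_config, k, master_seed = 0L) {
  if (k < 2L) config_error("committee size k must be >= 2")
  seeds <- as.integer(master_seed) + seq_len(k)
  members <- lapply(seeds, function(s) {
    cfg <- net_config
    cfg$seed <- s
    build_unet(cfg)
  })
  structure(list(members = members, member_seeds = seeds,
                 net_config = net_config), class = "committee")
}

member_features <- function(member, image) {
  if (is.function(member)) member(image) else extract_feature_vector(member, image)
}

#' Committee disagreement score of an image
#'
#' Each member extracts its deep feature vector from the image; the score is
#' the aggregate (mean by default, optionally min) of cosine similarities
#' over all `k(k-1)/2` member pairs. Lower scores mean stronger disagreement,
#' i.e. more informative images.
#'
#' @param committee a `committee` (members may also be plain functions
#'   mapping image -> feature vector, which is convenient for testing).
#' @param image standardized image at the members' input size.
#' @param aggregate `"mean"` or `"min"` over member pairs.
#' @return scalar in `[-1, 1]`.
#' @export
disagreement_score <- function(committee, image, aggregate = c("mean", "min")) {
  aggregate <- match.arg(aggregate)
  members <- committee$members
  k <- length(members)
  if (k < 2L) config_error("disagreement needs a committee of k >= 2")
  feats <- lapply(members, member_features, image = image)
  sims <- utils::combn(k, 2L, function(ij) {
    cosine_similarity(feats[[ij[1]]], feats[[ij[2]]])
  })
  if (aggregate == "mean") mean(sims) else min(sims)
}

#' Select the most informative images to annotate
#'
#' Returns the `batch` ids with the lowest disagreement scores, in ascending
#' score order; ties are broken lexicographically by id.
#'
#' @param committee a `committee`.
#' @param unlabeled list of items with fields `id` and `image` (standardized).
#' @param batch number of ids to return (`<= length(unlabeled)`).
#' @param aggregate passed to [disagreement_score()].
#' @param scores optional precomputed named score vector (names = ids); when
#'   given, no model forward passes are run.
#' @return character vector of ids, ascending by score.
#' @export
select_queries <- function(committee, unlabeled = list(), batch,
                           aggregate = c("mean", "min"), scores = NULL) {
  if (length(unlabeled) == 0L && is.null(scores)) {
    contract_error("unlabeled pool is empty")
  }
  if (is.null(scores)) {
    aggregate <- match.arg(aggregate)
    ids <- vapply(unlabeled, function(it) it$id, character(1))
    scores <- vapply(unlabeled, function(it) {
      disagreement_score(committee, it$image, aggregate)
    }, numeric(1))
    names(scores) <- ids
  }
  if (batch > length(scores)) contract_error("batch exceeds unlabeled pool size")
  ord <- order(scores, names(scores), method = "radix")
  names(scores)[ord][seq_len(batch)]
}

prepare_record <- function(record, input_size, clahe = FALSE,
                           clahe_clip = 2.0, clahe_tiles = c(8L, 8L)) {
  img <- record$image
  if (clahe) img <- apply_clahe(img, clahe_clip, clahe_tiles)
  if (!all(dim(img) == input_size)) img <- resize_bilinear(img, input_size)
  msk <- record$mask
  if (!is.null(msk) && !all(dim(msk) == input_size)) msk <- resize_nearest(msk, input_size)
  list(id = record$id, image = standardize(img), mask = msk)
}

#' Run the query-by-committee active-learning loop
#'
#' Builds a committee from `al$master_seed`, then for each of
#' `al$query_epochs` epochs: trains every member one epoch on the current
#' labeled pool, scores all unlabeled images, queries the
#' `al$queries_per_epoch` lowest-similarity ids, obtains their masks from the
#' oracle and moves them into the labeled pool. Training then continues for
#' `al$post_epochs` epochs without querying. Raw images are (optionally
#' CLAHE-equalized,) resized to the network input size and standardized
#' internally; oracle masks are resized nearest-neighbour.
#'
#' @param labeled list of records with `id`, `image`, `mask`; its length must
#'   equal `al$initial_labeled`.
#' @param unlabeled list of records with `id`, `image`; ids disjoint from
#'   `labeled`.
#' @param oracle function `id -> 0/1 mask` at the raw image size.
#' @param al an [al_config()].
#' @param net_config a [unet_config()].
#' @param clahe apply CLAHE before standardization.
#' @return list with `committee`, `history` (one data.frame row per epoch:
#'   `epoch`, `mean_loss`, `labeled_size`, `queried`, `scores`), `labeled`
#'   (final prepared pool) and `provenance` (id -> `"initial"` or
#'   `"queried-at-epoch-<e>"`).
#' @export
run_active_learning <- function(labeled, unlabeled, oracle, al, net_config,
                                clahe = FALSE) {
  if (!inherits(al, "al_config")) al <- do.call(al_config, al)
  if (length(labeled) != al$initial_labeled) {
    contract_error(sprintf("labeled pool size %d != initial_labeled %d",
                           length(labeled), al$initial_labeled))
  }
  lab_ids <- vapply(labeled, `[[`, character(1), "id")
  unl_ids <- vapply(unlabeled, `[[`, character(1), "id")
  if (anyDuplicated(c(lab_ids, unl_ids))) {
    contract_error("labeled and unlabeled pools must have disjoint, unique ids")
  }
  input_size <- net_config$input_size
  lab <- lapply(labeled, prepare_record, input_size = input_size, clahe = clahe)
  unl <- lapply(unlabeled, prepare_record, input_size = input_size, clahe = clahe)
  provenance <- stats::setNames(rep("initial", length(lab)), lab_ids)
  committee <- build_committee(net_config, al$k, al$master_seed)
  total_epochs <- al$query_epochs + al$post_epochs
  history <- vector("list", total_epochs)
  for (epoch in seq_len(total_epochs)) {
    losses <- numeric(al$k)
    for (m in seq_len(al$k)) {
      res <- train_epoch(committee$members[[m]], lab)
      committee$members[[m]] <- res$model
      losses[m] <- res$loss
    }
    queried <- character(0)
    qscores <- numeric(0)
    if (epoch <= al$query_epochs && length(unl) > 0L) {
      ids <- vapply(unl, `[[`, character(1), "id")
      scores <- vapply(unl, function(it) {
        disagreement_score(committee, it$image, al$aggregate)
      }, numeric(1))
      names(scores) <- ids
      batch <- min(al$queries_per_epoch, length(unl))
      if (batch < al$queries_per_epoch) {
        message(sprintf("epoch %d: unlabeled pool nearly exhausted, querying %d", epoch, batch))
      }
      queried <- select_queries(committee, scores = scores, batch = batch)
      qscores <- unname(scores[queried])
      for (qid in queried) {
        mask <- tryCatch(oracle(qid), error = function(e) {
          contract_error(sprintf("oracle failed for queried id '%s': %s",
                                 qid, conditionMessage(e)))
        })
        assert_binary_mask(mask, sprintf("oracle mask for '%s'", qid))
        pos <- match(qid, ids)
        item <- unl[[pos]]
        if (!all(dim(mask) == input_size)) mask <- resize_nearest(mask, input_size)
        item$mask <- mask
        lab[[length(lab) + 1L]] <- item
        provenance[qid] <- sprintf("queried-at-epoch-%d", epoch)
        unl <- unl[-pos]
        ids <- ids[-pos]
      }
    }
    history[[epoch]] <- data.frame(
      epoch = epoch, mean_loss = mean(losses), labeled_size = length(lab),
      queried = paste(queried, collapse = ";"),
      scores = paste(formatC(qscores, digits = 8, format = "g"), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  list(committee = committee, history = do.call(rbind, history),
       labeled = lab, provenance = provenance)
}

#' Fully supervised baseline at a fixed annotation budget
#'
#' Trains a single U-Net for `epochs` epochs on a seeded random subset of
#' `budget` labeled records — the comparison arm for the active-learning
#' committee.
#'
#' @param labeled non-empty list of records with `id`, `image`, `mask`.
#' @param net_config a [unet_config()].
#' @param epochs training epochs (0 returns the untrained model).
#' @param budget annotation budget; `NULL` uses the whole pool.
#' @param seed subset-selection seed.
#' @param clahe apply CLAHE before standardization.
#' @return a trained `unet_model`.
#' @export
run_fully_supervised_baseline <- function(labeled, net_config, epochs,
                                          budget = NULL, seed = 0L,
                                          clahe = FALSE) {
  if (length(labeled) == 0L) contract_error("labeled pool is empty")
  if (!is.null(budget) && budget < length(labeled)) {
    keep <- withr::with_seed(derive_seed(seed, 555L),
                             sample.int(length(labeled), budget))
    labeled <- labeled[sort(keep)]
  }
  lab <- lapply(labeled, prepare_record, input_size = net_config$input_size,
                clahe = clahe)
  model <- build_unet(net_config)
  for (e in seq_len(epochs)) {
    model <- train_epoch(model, lab)$model
  }
  model
}

#' Mean Dice of a model over labeled records
#'
#' @param model a `unet_model`.
#' @param records list of records with `image`, `mask` (raw scale).
#' @param threshold probability threshold for [binarize()].
#' @param clahe apply CLAHE before standardization.
#' @return mean Dice score.
#' @export
evaluate_model_dice <- function(model, records, threshold = 0.5, clahe = FALSE) {
  prepped <- lapply(records, prepare_record,
                    input_size = model$config$input_size, clahe = clahe)
  mean(vapply(prepped, function(it) {
    pred <- binarize(predict_probability_map(model, it$image), threshold)
    dice(it$mask, pred)
  }, numeric(1)))
}

#' Pick the committee member with the best validation Dice
#'
#' @param committee a `committee`.
#' @param validation list of records with `image`, `mask`.
#' @param threshold probability threshold.
#' @param clahe apply CLAHE before standardization.
#' @return list with `model`, `index` and the per-member `dice` vector.
#' @export
select_best_member <- function(committee, validation, threshold = 0.5,
                               clahe = FALSE) {
  scores <- vapply(committee$members, evaluate_model_dice, numeric(1),
                   records = validation, threshold = threshold, clahe = clahe)
  best <- which.max(scores)
  list(model = committee$members[[best]], index = best, dice = scores)
}

#' Build an oracle from a ground-truth mask store
#'
#' @param records list of records with `id` and `mask` (the synthetic
#'   ground truth).
#' @return function `id -> mask` suitable for [run_active_learning()].
#' @export
oracle_from_records <- function(records) {
  store <- stats::setNames(lapply(records, `[[`, "mask"),
                           vapply(records, `[[`, character(1), "id"))
  function(id) {
    m <- store[[id]]
    if (is.null(m)) stop(sprintf("no ground-truth mask for id '%s'", id))
    m
  }
}
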