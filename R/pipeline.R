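# Pipeline orchestration: configuration, manifest I/O, staged execution
# (generate -> al-train / fsl-train -> segment -> features -> regress ->
# evaluate) and the command-line dispatcher.

#' Default pipeline configuration
#'
#' A nested list with one block per stage; [read_pipeline_config()] merges a
#' YAML document over these defaults. The default sizes are desk-scale (a
#' 60-phantom run finishing in minutes), not the full annotation schedule of
#' [al_config()].
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    paths = list(work_dir = "handbaa-run", data_dir = NULL),
    synthetic = list(n = 60L, shape = c(64L, 64L)),
    preprocessing = list(clahe = FALSE, clip_limit = 2.0, tiles = c(8L, 8L),
                         threshold = 0.5, crop_margin = 2L),
    unet = list(depth = 2L, base_filters = 4L, input_size = c(64L, 64L),
                learning_rate = 5e-3, batch_size = 1L),
    al = list(k = 3L, initial_labeled = 10L, queries_per_epoch = 2L,
              query_epochs = 5L, post_epochs = 5L, aggregate = "mean"),
    fsl = list(epochs = 10L),
    split = list(test_fraction = 0.2, val_fraction = 0.1),
    backbone = "unet",
    regressor = list(family = "krr", kernel = "linear"),
    ensemble = list(method = "bagging", n_estimators = 11L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' @param path YAML file with any subset of the blocks of
#'   [default_pipeline_config()].
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file '%s' not found", path))
  merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

#' Read a dataset manifest CSV
#'
#' Expects header `id,boneage,male,image[,mask]`; bone ages are validated as
#' integers in `[0, 228]` months and every referenced image file must exist
#' (paths are relative to the manifest directory).
#'
#' @param path manifest CSV path.
#' @return a `dataset_manifest`: list with `records` (data.frame) and `dir`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) config_error(sprintf("manifest '%s' not found", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "boneage", "male", "image")
  if (!all(need %in% names(df))) {
    config_error(sprintf("manifest must have columns %s", paste(need, collapse = ",")))
  }
  if (anyDuplicated(df$id)) config_error("manifest ids are not unique")
  bad <- which(!is.finite(df$boneage) | df$boneage < 0 | df$boneage > 228 |
                 df$boneage != round(df$boneage))
  if (length(bad)) {
    config_error(sprintf("manifest line %d: boneage %s outside integer [0, 228]",
                         bad[1] + 1L, df$boneage[bad[1]]))
  }
  df$male <- df$male %in% c("True", "TRUE", "true", "1")
  base <- dirname(path)
  for (i in seq_len(nrow(df))) {
    if (!file.exists(file.path(base, df$image[i]))) {
      config_error(sprintf("image file missing for id '%s'", df$id[i]))
    }
    if (!is.null(df$mask) && !is.na(df$mask[i]) && nzchar(df$mask[i]) &&
        !file.exists(file.path(base, df$mask[i]))) {
      config_error(sprintf("mask file missing for id '%s'", df$id[i]))
    }
  }
  structure(list(records = df, dir = base), class = "dataset_manifest")
}

#' Load manifest rows into in-memory records
#'
#' @param manifest a `dataset_manifest`.
#' @return list of records with `id`, `image`, `mask` (or `NULL`),
#'   `age_months`, `male`.
#' @export
load_manifest_records <- function(manifest) {
  df <- manifest$records
  lapply(seq_len(nrow(df)), function(i) {
    mask <- NULL
    if (!is.null(df$mask) && !is.na(df$mask[i]) && nzchar(df$mask[i])) {
      mask <- read_mask_png(file.path(manifest$dir, df$mask[i]))
    }
    list(id = df$id[i], image = read_image_png(file.path(manifest$dir, df$image[i])),
         mask = mask, age_months = df$boneage[i], male = df$male[i])
  })
}

#' Write binary masks as 0/255 PNG files
#'
#' @param ids character ids (file stems).
#' @param masks aligned list of 0/1 matrices.
#' @param out_dir output directory.
#' @return character vector of written paths.
#' @export
write_masks <- function(ids, masks, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_along(ids), function(i) {
    p <- file.path(out_dir, paste0(ids[i], ".png"))
    write_mask_png(masks[[i]], p)
    p
  }, character(1))
}

log_event <- function(ws, stage, event, detail = list()) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage, event = event), detail)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(ws, "runlog.jsonl"), sep = "", append = TRUE)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    config_error(sprintf("missing artifact '%s': run the '%s' stage first",
                         path, produced_by))
  }
  path
}

pipeline_split <- function(ids, cfg) {
  n <- length(ids)
  n_test <- max(1L, round(cfg$split$test_fraction * n))
  n_val <- max(1L, round(cfg$split$val_fraction * n))
  ord <- withr::with_seed(derive_seed(cfg$seed, 31L), sample.int(n))
  role <- rep("pool", n)
  role[ord[seq_len(n_test)]] <- "test"
  role[ord[n_test + seq_len(n_val)]] <- "val"
  pool_idx <- which(role == "pool")
  lab <- withr::with_seed(derive_seed(cfg$seed, 32L),
                          sample(pool_idx, cfg$al$initial_labeled))
  role[lab] <- "labeled"
  data.frame(id = ids, role = role, stringsAsFactors = FALSE)
}

stage_generate <- function(cfg, ws) {
  log_event(ws, "generate", "start", list(n = cfg$synthetic$n, seed = cfg$seed))
  vc_args <- cfg$synthetic[setdiff(names(cfg$synthetic), "n")]
  vc <- do.call(variation_config, vc_args)
  manifest <- generate_dataset(cfg$synthetic$n, derive_seed(cfg$seed, 1L),
                               file.path(ws, "data"), vc)
  log_event(ws, "generate", "end",
            list(manifest = file.path(ws, "data", "manifest.csv")))
  manifest
}

pipeline_records <- function(cfg, ws) {
  man_path <- if (!is.null(cfg$paths$data_dir)) {
    file.path(cfg$paths$data_dir, "manifest.csv")
  } else {
    file.path(ws, "data", "manifest.csv")
  }
  require_artifact(man_path, "generate")
  load_manifest_records(read_manifest(man_path))
}

pipeline_net_config <- function(cfg) {
  do.call(unet_config, c(cfg$unet, list(seed = derive_seed(cfg$seed, 2L))))
}

stage_al_train <- function(cfg, ws) {
  records <- pipeline_records(cfg, ws)
  ids <- vapply(records, `[[`, character(1), "id")
  splits <- pipeline_split(ids, cfg)
  utils::write.table(splits, file.path(ws, "splits.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  log_event(ws, "al-train", "start", list(k = cfg$al$k))
  labeled <- records[splits$role == "labeled"]
  unlabeled <- lapply(records[splits$role == "pool"],
                      function(r) list(id = r$id, image = r$image))
  al <- do.call(al_config, c(cfg$al, list(master_seed = derive_seed(cfg$seed, 3L))))
  res <- run_active_learning(labeled, unlabeled, oracle_from_records(records),
                             al, pipeline_net_config(cfg),
                             clahe = isTRUE(cfg$preprocessing$clahe))
  dir.create(file.path(ws, "models"), showWarnings = FALSE)
  saveRDS(res$committee, file.path(ws, "models", "committee.rds"))
  utils::write.table(res$history, file.path(ws, "al_history.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  log_event(ws, "al-train", "end",
            list(labeled_final = nrow(res$history)[1] * 0 + utils::tail(res$history$labeled_size, 1),
                 history = file.path(ws, "al_history.csv")))
  res
}

stage_fsl_train <- function(cfg, ws) {
  records <- pipeline_records(cfg, ws)
  splits <- utils::read.csv(require_artifact(file.path(ws, "splits.csv"), "al-train"))
  hist <- utils::read.csv(require_artifact(file.path(ws, "al_history.csv"), "al-train"))
  budget <- utils::tail(hist$labeled_size, 1)
  log_event(ws, "fsl-train", "start", list(budget = budget))
  trainable <- records[splits$role %in% c("labeled", "pool")]
  epochs <- cfg$fsl$epochs
  model <- run_fully_supervised_baseline(
    trainable, pipeline_net_config(cfg), epochs, budget = budget,
    seed = derive_seed(cfg$seed, 4L), clahe = isTRUE(cfg$preprocessing$clahe))
  saveRDS(model, file.path(ws, "models", "fsl.rds"))
  log_event(ws, "fsl-train", "end", list())
  model
}

pipeline_best_member <- function(cfg, ws, records, splits) {
  committee <- readRDS(require_artifact(file.path(ws, "models", "committee.rds"),
                                        "al-train"))
  val <- records[splits$role == "val"]
  select_best_member(committee, val, threshold = cfg$preprocessing$threshold,
                     clahe = isTRUE(cfg$preprocessing$clahe))
}

stage_segment <- function(cfg, ws) {
  records <- pipeline_records(cfg, ws)
  splits <- utils::read.csv(require_artifact(file.path(ws, "splits.csv"), "al-train"))
  log_event(ws, "segment", "start", list())
  best <- pipeline_best_member(cfg, ws, records, splits)
  saveRDS(best$model, file.path(ws, "models", "segmenter.rds"))
  masks <- list(); crops_dir <- file.path(ws, "crops")
  dir.create(crops_dir, showWarnings = FALSE, recursive = TRUE)
  for (r in records) {
    prep <- prepare_record(r, best$model$config$input_size,
                           clahe = isTRUE(cfg$preprocessing$clahe),
                           clahe_clip = cfg$preprocessing$clip_limit,
                           clahe_tiles = cfg$preprocessing$tiles)
    pred <- binarize(predict_probability_map(best$model, prep$image),
                     cfg$preprocessing$threshold)
    masks[[r$id]] <- pred
    if (sum(pred) > 0) {
      crop <- crop_to_mask(r$image, resize_nearest(pred, dim(r$image)),
                           cfg$preprocessing$crop_margin)
      write_image_png(crop, file.path(crops_dir, paste0(r$id, ".png")))
    }
  }
  paths <- write_masks(names(masks), masks, file.path(ws, "masks_pred"))
  log_event(ws, "segment", "end", list(masks = length(paths)))
  invisible(masks)
}

stage_features <- function(cfg, ws) {
  records <- pipeline_records(cfg, ws)
  log_event(ws, "features", "start", list(backbone = cfg$backbone))
  backbone <- if (identical(cfg$backbone, "identity")) {
    backbone_identity()
  } else {
    model <- readRDS(require_artifact(file.path(ws, "models", "segmenter.rds"),
                                      "segment"))
    backbone_from_unet(model)
  }
  input_size <- if (identical(cfg$backbone, "identity")) {
    cfg$unet$input_size
  } else NULL
  prepped <- lapply(records, function(r) {
    sz <- input_size %||% cfg$unet$input_size
    prepare_record(r, sz, clahe = isTRUE(cfg$preprocessing$clahe))$image
  })
  ids <- vapply(records, `[[`, character(1), "id")
  fm <- extract_features(backbone, prepped, ids)
  df <- data.frame(id = fm$ids, fm$features)
  names(df) <- c("id", paste0("f", seq_len(ncol(fm$features)) - 1L))
  utils::write.table(df, file.path(ws, "features.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  ages <- vapply(records, `[[`, numeric(1), "age_months")
  emb <- decompose_2d(fm, "incremental-pca", seed = cfg$seed, ages = ages)
  export_scatter(emb, file.path(ws, "embedding.png"))
  log_event(ws, "features", "end", list(features = file.path(ws, "features.csv")))
  fm
}

stage_regress <- function(cfg, ws) {
  records <- pipeline_records(cfg, ws)
  fpath <- require_artifact(file.path(ws, "features.csv"), "features")
  df <- utils::read.csv(fpath, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  ids <- df$id
  ages <- vapply(records, `[[`, numeric(1), "age_months")[match(ids, vapply(records, `[[`, character(1), "id"))]
  male <- vapply(records, `[[`, logical(1), "male")[match(ids, vapply(records, `[[`, character(1), "id"))]
  log_event(ws, "regress", "start", list(family = cfg$regressor$family))
  rc <- do.call(regressor_config, cfg$regressor)
  strat <- stratified_fit(X, ages, male, rc, seed = derive_seed(cfg$seed, 5L))
  ec <- do.call(ensemble_config,
                c(cfg$ensemble, list(base = rc, seed = derive_seed(cfg$seed, 6L))))
  ens_cv <- cross_validate(X, ages, ec, seed = derive_seed(cfg$seed, 5L))
  rows <- lapply(names(strat), function(nm) {
    cbind(model = cfg$regressor$family, strat[[nm]]$cv$pooled)
  })
  rows[[length(rows) + 1L]] <- cbind(model = paste0(cfg$ensemble$method, "-",
                                                    cfg$regressor$family),
                                     ens_cv$pooled)
  report <- do.call(rbind, rows)
  utils::write.table(format(report, digits = 10), file.path(ws, "regression_report.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  log_event(ws, "regress", "end",
            list(report = file.path(ws, "regression_report.csv")))
  report
}

stage_evaluate <- function(cfg, ws) {
  records <- pipeline_records(cfg, ws)
  splits <- utils::read.csv(require_artifact(file.path(ws, "splits.csv"), "al-train"))
  log_event(ws, "evaluate", "start", list())
  test <- records[splits$role == "test"]
  best_model <- readRDS(require_artifact(file.path(ws, "models", "segmenter.rds"),
                                         "segment"))
  eval_masks <- function(model) {
    truths <- list(); preds <- list()
    for (r in test) {
      prep <- prepare_record(r, model$config$input_size,
                             clahe = isTRUE(cfg$preprocessing$clahe))
      truths[[r$id]] <- prep$mask
      preds[[r$id]] <- binarize(predict_probability_map(model, prep$image),
                                cfg$preprocessing$threshold)
    }
    list(truths = truths, preds = preds)
  }
  al_pair <- eval_masks(best_model)
  rows <- list(segmentation_report(al_pair$truths, al_pair$preds,
                                   sprintf("AL (k = %d)", cfg$al$k)))
  fsl_path <- file.path(ws, "models", "fsl.rds")
  if (file.exists(fsl_path)) {
    fsl_pair <- eval_masks(readRDS(fsl_path))
    rows[[2]] <- segmentation_report(fsl_pair$truths, fsl_pair$preds, "FSL")
  }
  report <- do.call(rbind, rows)
  utils::write.table(format(report, digits = 10),
                     file.path(ws, "segmentation_report.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  log_event(ws, "evaluate", "end",
            list(report = file.path(ws, "segmentation_report.csv")))
  report
}

#' Run the full pipeline
#'
#' Executes generate, al-train, fsl-train, segment, features, regress and
#' evaluate in order inside the configured work directory. One global seed
#' drives every stage, so two runs with the same configuration produce
#' identical metric reports.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param seed optional global seed override.
#' @param work_dir optional work directory override.
#' @return list with the `segmentation` and `regression` report data.frames
#'   and the workspace path.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = NULL,
                         work_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  ws <- work_dir %||% cfg$paths$work_dir
  dir.create(ws, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg$paths$data_dir)) stage_generate(cfg, ws)
  stage_al_train(cfg, ws)
  stage_fsl_train(cfg, ws)
  stage_segment(cfg, ws)
  stage_features(cfg, ws)
  reg <- stage_regress(cfg, ws)
  seg <- stage_evaluate(cfg, ws)
  list(segmentation = seg, regression = reg, workspace = ws)
}

cli_usage <- function() {
  paste(
    "usage: baa <command> [--config FILE] [--seed INT] [--out DIR] [--n INT]",
    "commands:",
    "  generate    write a synthetic phantom dataset",
    "  al-train    run query-by-committee active learning",
    "  fsl-train   train the fully supervised baseline",
    "  segment     apply the best member; write masks and cropped hands",
    "  features    extract GAP features, 2-D embedding and scatter",
    "  regress     cross-validated regression, ensembles, sex strata",
    "  evaluate    segmentation and regression reports",
    "  pipeline    all stages in order",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) config_error(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3L)
    if (i == length(args)) config_error(sprintf("flag '--%s' needs a value", key))
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Command-line entry point
#'
#' Dispatches one pipeline stage (or all of them). Designed to be called
#' from the thin `Rscript` wrapper shipped in `inst/cli/baa.R`; returns the
#' process exit status instead of quitting so it is testable in-process.
#'
#' @param args character vector, e.g. `c("pipeline", "--seed", "1")`.
#' @return integer exit status (0 on success), invisibly.
#' @export
baa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat(cli_usage(), "\n")
    return(invisible(2L))
  }
  command <- args[1]
  known <- c("generate", "al-train", "fsl-train", "segment", "features",
             "regress", "evaluate", "pipeline")
  if (!command %in% known) {
    message(sprintf("unknown command '%s'", command))
    cat(cli_usage(), "\n")
    return(invisible(2L))
  }
  status <- tryCatch({
    flags <- parse_cli_flags(args[-1])
    cfg <- if (!is.null(flags$config)) read_pipeline_config(flags$config) else
      default_pipeline_config()
    if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
    if (!is.null(flags$n)) cfg$synthetic$n <- as.integer(flags$n)
    ws <- flags$out %||% cfg$paths$work_dir
    dir.create(ws, recursive = TRUE, showWarnings = FALSE)
    switch(command,
      "generate" = stage_generate(cfg, ws),
      "al-train" = stage_al_train(cfg, ws),
      "fsl-train" = stage_fsl_train(cfg, ws),
      "segment" = stage_segment(cfg, ws),
      "features" = stage_features(cfg, ws),
      "regress" = stage_regress(cfg, ws),
      "evaluate" = stage_evaluate(cfg, ws),
      "pipeline" = run_pipeline(cfg, work_dir = ws))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
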