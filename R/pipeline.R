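#' Early fusion of feature blocks
#'
#' Column-wise concatenation of per-modality feature matrices with
#' provenance retained for every column.
#'
#' @param blocks List of blocks, each `list(values = matrix, modality =
#'   character, ids = column identifiers)`; `ids` defaults to the column
#'   names.
#' @return A `fused_dataset`: `values` matrix and `provenance` data frame
#'   (`modality`, `id`, `position_in_block`).
#' @export
early_fuse <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  n <- nrow(blocks[[1]]$values)
  for (b in blocks) {
    if (nrow(b$values) != n) {
      stop("row count mismatch in fusion: ", nrow(b$values), " vs ", n)
    }
  }
  values <- do.call(cbind, lapply(blocks, function(b) as.matrix(b$values)))
  prov <- do.call(rbind, lapply(blocks, function(b) {
    ids <- b$ids %||% colnames(b$values) %||%
      as.character(seq_len(ncol(b$values)))
    data.frame(modality = b$modality, id = as.character(ids),
               position_in_block = seq_len(ncol(b$values)),
               stringsAsFactors = FALSE)
  }))
  stopifnot(nrow(prov) == ncol(values))
  structure(list(values = values, provenance = prov),
            class = "fused_dataset")
}

#' Pipeline run configuration
#'
#' @param data Either `list(source = "synthetic", spec = synthetic_spec())`
#'   (default) or `list(source = "csv", spectra = path, image = path)`.
#' @param sg Savitzky-Golay parameters ([sg_params()]).
#' @param split_ratio Training fraction (default 0.8).
#' @param cars_n Sampling runs for CARS, used for both modalities (default
#'   20).
#' @param pls PLS configuration for CARS ([pls_config()]).
#' @param koa KOA budget for hyperparameter tuning ([koa_config()]).
#' @param tune_cv_folds Folds of the KOA fitness CV (default 2; with 80
#'   training samples per class a stratified half split already estimates
#'   the error rate stably, and the fitness stays a deterministic function
#'   of position).
#' @param stacking_k Stacking folds (default 5).
#' @param meta_feature_mode `"labels"` or `"probabilities"`.
#' @param families Base-learner families to tune (default all six).
#' @param modality `"fused"` (default), `"spectra"` or `"image"` — which
#'   feature blocks enter the model stage.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @param seed Global seed; fans out deterministically to every stage.
#' @return A `run_config` object.
#' @export
run_config <- function(data = list(source = "synthetic",
                                   spec = synthetic_spec()),
                       sg = sg_params(), split_ratio = 0.8, cars_n = 20,
                       pls = pls_config(),
                       koa = koa_config(pop_size = 10, max_iter = 50),
                       tune_cv_folds = 2, stacking_k = 5,
                       meta_feature_mode = "labels",
                       families = classifier_families(),
                       modality = c("fused", "spectra", "image"),
                       out_dir = NULL, seed = 1L) {
  structure(list(data = data, sg = sg, split_ratio = split_ratio,
                 cars_n = cars_n, pls = pls, koa = koa,
                 tune_cv_folds = tune_cv_folds, stacking_k = stacking_k,
                 meta_feature_mode = meta_feature_mode,
                 families = families, modality = match.arg(modality),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

load_pipeline_data <- function(config) {
  if (config$data$source == "synthetic") {
    spec <- config$data$spec
    spec$seed <- derive_seed(config$seed, "synthetic")
    generate_multimodal(spec)
  } else {
    list(spectra = read_spectra_csv(config$data$spectra),
         image = read_image_csv(config$data$image),
         labels = read_spectra_csv(config$data$spectra)$labels)
  }
}

#' Run the full classification pipeline
#'
#' Executes the six-stage flow: data (synthetic or CSV) -> train/test split
#' -> preprocessing (Savitzky-Golay smoothing of spectra; min-max scaling of
#' both modalities, fitted on the training split only) -> per-modality CARS
#' selection on the training split -> early fusion (spectral block first) ->
#' KOA tuning of the base-learner families -> meta-learner selection and
#' stacking -> evaluation on the held-out test split.
#'
#' Every randomised stage derives its seed from `config$seed`, so a rerun
#' with an identical config reproduces the run exactly. The returned
#' `audit` records which original row indices each fitted stage saw, for
#' leakage checks.
#'
#' @param config A [run_config()].
#' @return A list with the split, per-modality CARS results, the fused
#'   dataset, tuning results, the meta-learner selection report, the final
#'   stacked model, test-set evaluations of the stack and every tuned base
#'   learner (Table-style comparison data frames), and the `audit` record.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "setup"
  tryCatch(
    run_pipeline_impl(config, function(s) stage <<- s),
    error = function(e) {
      stop("pipeline failed in stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
}

run_pipeline_impl <- function(config, note_stage = function(s) NULL) {
  audit <- list()
  note_stage("data")
  dataset <- load_pipeline_data(config)
  labels <- dataset$labels
  n <- length(labels)

  # --- split --------------------------------------------------------------
  note_stage("split")
  split_seed <- derive_seed(config$seed, "split")
  sp <- split_train_test(dataset$spectra$intensities, labels,
                         ratio = config$split_ratio, seed = split_seed)
  tr_idx <- sp$train$idx
  te_idx <- sp$test$idx
  audit$split <- list(train = tr_idx, test = te_idx)

  # --- preprocessing ------------------------------------------------------
  note_stage("preprocess")
  # SG smoothing is a fixed per-row linear filter (no statistics fitted), so
  # it may be applied to all rows; min-max statistics are fitted on the
  # training rows only.
  spectra_sm <- savitzky_golay_smooth(dataset$spectra$intensities, config$sg)
  mm_spec <- fit_min_max(spectra_sm[tr_idx, , drop = FALSE])
  audit$fit_min_max_spectra <- tr_idx
  spectra_scaled <- apply_min_max(spectra_sm, mm_spec)

  img <- dataset$image$values
  mm_img <- fit_min_max(img[tr_idx, , drop = FALSE])
  audit$fit_min_max_image <- tr_idx
  img_scaled <- apply_min_max(img, mm_img)

  # --- CARS per modality (training rows only) -----------------------------
  note_stage("cars")
  y_tr <- labels[tr_idx]
  cars_spec <- run_cars(spectra_scaled[tr_idx, , drop = FALSE], y_tr,
                        N = config$cars_n, config = config$pls,
                        seed = derive_seed(config$seed, "cars-spectra"))
  audit$cars_spectra <- tr_idx
  cars_img <- run_cars(img_scaled[tr_idx, , drop = FALSE], y_tr,
                       N = config$cars_n, config = config$pls,
                       seed = derive_seed(config$seed, "cars-image"))
  audit$cars_image <- tr_idx

  # --- early fusion (spectral block first) --------------------------------
  note_stage("fuse")
  wn <- dataset$spectra$grid$wavenumbers
  blocks <- list(
    spectra = list(
      values = spectra_scaled[, cars_spec$selected_features, drop = FALSE],
      modality = "spectra",
      ids = wn[cars_spec$selected_features]),
    image = list(
      values = img_scaled[, cars_img$selected_features, drop = FALSE],
      modality = "image",
      ids = dataset$image$feature_names[cars_img$selected_features]))
  blocks <- switch(config$modality,
                   fused = blocks,
                   spectra = blocks["spectra"],
                   image = blocks["image"])
  fused <- early_fuse(blocks)
  X_tr <- fused$values[tr_idx, , drop = FALSE]
  X_te <- fused$values[te_idx, , drop = FALSE]

  # --- KOA tuning of the base learners ------------------------------------
  note_stage("tune")
  tuned <- list()
  for (fam in config$families) {
    kcfg <- config$koa
    kcfg$seed <- derive_seed(config$seed, paste0("koa-", fam))
    tuned[[fam]] <- tune_model(fam, X_tr, y_tr, config = kcfg,
                               cv_folds = config$tune_cv_folds)
  }
  audit$koa_fitness <- tr_idx

  base_learners <- lapply(tuned, function(tm) {
    list(family = tm$family, params = tm$best_params)
  })

  # --- meta-learner selection (training split only) -----------------------
  note_stage("stack")
  spec_stack <- stacking_spec(base_learners = base_learners,
                              k = config$stacking_k,
                              meta_feature_mode = config$meta_feature_mode,
                              seed = derive_seed(config$seed, "stack"))
  selection <- select_meta_learner(spec = spec_stack, X = X_tr, y = y_tr,
                                   seed = derive_seed(config$seed,
                                                      "meta-select"))
  audit$meta_selection <- tr_idx

  # --- final stack + evaluation on the held-out test split ---------------
  note_stage("evaluate")
  spec_stack$meta_learner <- selection$chosen
  stack <- fit_stacking(spec_stack, X_tr, y_tr)
  y_te <- labels[te_idx]
  pred_te <- predict(stack, X_te)
  prob_te <- predict(stack, X_te, type = "prob")
  eval_stack <- evaluate_predictions(y_te, pred_te, scores = prob_te,
                                     classes = levels(labels))

  base_rows <- lapply(names(tuned), function(fam) {
    pred <- predict_classifier(tuned[[fam]]$model, X_te)
    met <- classification_metrics(
      confusion_matrix(y_te, pred, levels(labels)))
    data.frame(model = paste0("KOA-", fam), accuracy = met$accuracy,
               precision = met$macro_precision, recall = met$macro_recall,
               f1 = met$macro_f1)
  })
  base_report <- do.call(rbind, base_rows)

  # Table-3-style comparison: every candidate meta-learner on the shared
  # base layer, scored on the test split. Base refits and their test-set
  # predictions are shared; only the meta-learner differs per candidate.
  enc_tr <- meta_encode(stack$meta_features$matrix,
                        stack$meta_features$mode, stack$meta_features$classes,
                        stack$meta_features$learners)
  enc_te <- base_layer_predict(stack, X_te)
  stack_rows <- lapply(classifier_families(), function(fam) {
    ms <- derive_seed(config$seed, paste0("stackeval-", fam))
    meta <- fit_classifier(fam, enc_tr, y_tr, list(), seed = ms)
    pred <- predict_classifier(meta, enc_te)
    met <- classification_metrics(
      confusion_matrix(y_te, pred, levels(labels)))
    data.frame(model = paste0(fam, "-stacking"), accuracy = met$accuracy,
               precision = met$macro_precision, recall = met$macro_recall,
               f1 = met$macro_f1)
  })
  stack_report <- do.call(rbind, stack_rows)

  result <- list(
    config = config, seed = config$seed,
    fingerprint = fingerprint(config),
    split = list(train_idx = tr_idx, test_idx = te_idx),
    min_max = list(spectra = mm_spec, image = mm_img),
    cars = list(spectra = cars_spec, image = cars_img),
    fused = fused, tuned = tuned, selection = selection,
    stack = stack,
    test_predictions = pred_te, test_probabilities = prob_te,
    test_labels = y_te,
    evaluation = eval_stack,
    base_report = base_report, stack_report = stack_report,
    audit = audit)
  if (!is.null(config$out_dir)) write_run_artifacts(result, config$out_dir)
  result
}

write_run_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(seed = result$seed, fingerprint = result$fingerprint)
  jsonlite::write_json(stamp, file.path(dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  write_cars_report(result$cars$spectra,
                    file.path(dir, "cars_spectra_report.csv"),
                    file.path(dir, "cars_spectra_selected.json"))
  write_cars_report(result$cars$image,
                    file.path(dir, "cars_image_report.csv"),
                    file.path(dir, "cars_image_selected.json"))
  write_min_max_json(result$min_max$spectra,
                     file.path(dir, "min_max_spectra.json"))
  write_min_max_json(result$min_max$image,
                     file.path(dir, "min_max_image.json"))
  hist_df <- do.call(rbind, lapply(names(result$tuned), function(fam) {
    data.frame(family = fam,
               iteration = seq_along(result$tuned[[fam]]$history),
               best_fitness = result$tuned[[fam]]$history)
  }))
  write.csv(hist_df, file.path(dir, "tuning_history.csv"),
            row.names = FALSE)
  jsonlite::write_json(lapply(result$tuned, `[[`, "best_params"),
                       file.path(dir, "best_params.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(result$base_report, file.path(dir, "comparison_base.csv"),
            row.names = FALSE)
  write.csv(result$stack_report, file.path(dir, "comparison_stacks.csv"),
            row.names = FALSE)
  write.csv(result$selection$report, file.path(dir, "meta_selection.csv"),
            row.names = FALSE)
  write.csv(data.frame(row = result$split$test_idx,
                       truth = as.character(result$test_labels),
                       predicted = as.character(result$test_predictions)),
            file.path(dir, "predictions.csv"), row.names = FALSE)
  invisible(dir)
}

#' Ablation comparison: spectra-only vs image-only vs fused
#'
#' Runs the pipeline three times from the same config and seed, once per
#' modality setting, and collects the stack's test accuracy for each — the
#' single-modality versus early-fusion comparison.
#'
#' @param config A [run_config()]; its `modality` field is overridden.
#' @return List with `report` (data frame: modality, accuracy, macro F1)
#'   and the three full run results.
#' @export
run_ablation <- function(config) {
  runs <- lapply(c("fused", "spectra", "image"), function(m) {
    cfg <- config
    cfg$modality <- m
    cfg$out_dir <- if (is.null(config$out_dir)) NULL else
      file.path(config$out_dir, m)
    run_pipeline(cfg)
  })
  names(runs) <- c("fused", "spectra", "image")
  report <- do.call(rbind, lapply(names(runs), function(m) {
    ev <- runs[[m]]$evaluation
    data.frame(modality = m, accuracy = ev$accuracy,
               macro_f1 = ev$macro_f1)
  }))
  list(report = report, runs = runs)
}
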