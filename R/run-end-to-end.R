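#' Configuration for an end-to-end run
#'
#' Gathers every knob of the generate / train / fuse / simulate pipeline:
#' data, split and model seeds, the staffing model, the exemplar rule-out
#' threshold and the sensitivity-analysis grid. All randomness flows from
#' these seeds; nothing reads global state.
#'
#' @param n_patients synthetic cohort size.
#' @param seed master seed; data, split and model seeds are derived from
#'   it unless given explicitly.
#' @param data_seed,split_seed,model_seed component seeds.
#' @param threshold exemplar rule-out threshold (default 0.2).
#' @param grid threshold grid for the sensitivity analysis.
#' @param staffing a [staffing_model()].
#' @param fusion_kind fusion head (see [fit_fusion_head()]).
#' @param cnn_epochs,max_train_images image-model training budget: epochs,
#'   and a cap on rendered training images (all SSI-positive images are
#'   kept; negatives are subsampled).
#' @param generator optional [synth_config()] overriding `n_patients` /
#'   `data_seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_patients = 200, seed = 1,
                       data_seed = derive_seed(seed, 11),
                       split_seed = derive_seed(seed, 22),
                       model_seed = derive_seed(seed, 33),
                       threshold = 0.2,
                       grid = seq(0, 0.5, by = 0.05),
                       staffing = staffing_model(),
                       fusion_kind = "logistic_stack",
                       cnn_epochs = 30, max_train_images = 240,
                       generator = NULL) {
  structure(list(n_patients = n_patients, seed = seed,
                 data_seed = data_seed, split_seed = split_seed,
                 model_seed = model_seed, threshold = threshold,
                 grid = grid, staffing = staffing,
                 fusion_kind = fusion_kind, cnn_epochs = cnn_epochs,
                 max_train_images = max_train_images,
                 generator = generator),
            class = "run_config")
}

# Select training images: keep every SSI-positive image, subsample
# negatives to the cap. Returns indices into `labels`.
select_training_images <- function(labels, max_images, seed) {
  if (length(labels) <= max_images) return(seq_along(labels))
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  keep_neg <- max(max_images - length(pos), min(length(neg), length(pos)))
  with_seed(seed, sort(c(pos, sample(neg, min(keep_neg, length(neg))))))
}

render_image_batch <- function(cohort, image_ids, labels = NULL) {
  image_batch(lapply(image_ids, function(id) cohort_image(cohort, id)),
              labels = labels)
}

#' Predict per-image SSI risk across (part of) a cohort
#'
#' Renders each requested image and scores it with the image model.
#'
#' @param cohort an `ssi_cohort`.
#' @param model a `cnn_model`.
#' @param image_ids image ids (default: all images in the cohort).
#' @return Data frame `image_id`, `response_id`, `p_image`.
#' @export
predict_cohort_images <- function(cohort, model,
                                  image_ids = cohort$images$image_id) {
  p <- vapply(image_ids, function(id)
    predict(model, cohort_image(cohort, id)$pixels), numeric(1))
  data.frame(image_id = image_ids,
             response_id = cohort$images$response_id[
               match(image_ids, cohort$images$image_id)],
             p_image = unname(p), stringsAsFactors = FALSE)
}

#' Run the full pipeline: generate, train, fuse, simulate
#'
#' Generates a synthetic cohort, performs the grouped stratified 4:1
#' split, trains the PROMs MLP and its logistic comparator, trains the
#' image CNN on a capped training-image subset, fits the late-fusion head,
#' builds per-response multimodal predictions (PROMs-only where no image
#' was submitted; max over per-image fused risks otherwise), then
#' simulates the three implementation strategies at the exemplar threshold
#' and sweeps the threshold grid. Identical config (and seeds) reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, predictions, the
#'   Table-style pathway summary, the sweep table, AUC benchmarks and a
#'   config echo are written as CSV/YAML, and a short log is emitted.
#' @param quiet suppress progress messages.
#' @return List with the cohort, split, models, prediction table, pathway
#'   outcomes, sweep table and AUC benchmarks.
#' @export
run_end_to_end <- function(config = run_config(), out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  gen <- config$generator %||%
    synth_config(config$n_patients, seed = config$data_seed)
  say("generating cohort (%d patients, seed %d)", gen$n_patients, gen$seed)
  cohort <- generate_cohort(gen)
  resp <- cohort$responses

  split <- grouped_stratified_split(resp, seed = config$split_seed)
  train <- split$assignment$partition == "train"

  say("training tabular models on %d responses", sum(train))
  feats_train <- encode_proms(resp[train, ])
  mlp <- fit_tabular(feats_train, resp$ssi48[train], kind = "mlp",
                     seed = config$model_seed)
  logit <- fit_tabular(feats_train, resp$ssi48[train], kind = "logistic")
  p_proms <- setNames(predict(mlp, resp), resp$response_id)
  p_logit <- setNames(predict(logit, resp), resp$response_id)

  img <- cohort$images
  resp_of_img <- match(img$response_id, resp$response_id)
  img_y <- resp$ssi48[resp_of_img]
  if (nrow(img) > 0) {
    img_train <- which(train[resp_of_img])
    sel <- img_train[select_training_images(
      img_y[img_train], config$max_train_images,
      derive_seed(config$model_seed, 5))]
    say("training image model on %d of %d training images", length(sel),
        length(img_train))
    train_batch <- render_image_batch(cohort, img$image_id[sel],
                                      labels = img_y[sel])
    cnn <- fit_cnn(train_batch, epochs = config$cnn_epochs,
                   seed = config$model_seed)

    say("scoring %d cohort images", nrow(img))
    img_pred <- predict_cohort_images(cohort, cnn)

    # fusion head fitted on training-partition image predictions, with
    # cross-fitted PROMs probabilities (stacked generalisation)
    p_proms_oof <- crossfit_proms(resp[train, ], resp$ssi48[train],
                                  seed = config$model_seed)
    fit_rows <- img_pred[train[resp_of_img], ]
    head_fit <- fit_fusion_head(
      p_proms_oof[fit_rows$response_id], fit_rows$p_image,
      resp$ssi48[match(fit_rows$response_id, resp$response_id)],
      kind = config$fusion_kind, seed = config$model_seed)
  } else {
    # image-free cohort: every response falls back to the PROMs model
    say("cohort has no images; skipping the image model")
    cnn <- NULL
    img_pred <- data.frame(image_id = character(0),
                           response_id = character(0),
                           p_image = numeric(0))
    head_fit <- fit_fusion_head(kind = "average")
  }
  predictions <- fuse_predictions(p_proms, img_pred, head_fit)

  test_ids <- split$assignment$response_id[!train]
  test_rows <- match(test_ids, resp$response_id)
  auc_tbl <- data.frame(
    model = c("mlp_proms", "logistic_proms", "cnn_image", "fused"),
    auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_, band = NA_character_)
  scores <- list(p_proms[test_ids], p_logit[test_ids],
                 NULL, predictions$p_fused[match(test_ids,
                                                 predictions$response_id)])
  img_test <- !train[resp_of_img]
  if (any(img_test)) {
    scores[[3]] <- img_pred$p_image[img_test]
  }
  labels <- list(resp$ssi48[test_rows], resp$ssi48[test_rows],
                 img_y[img_test], resp$ssi48[test_rows])
  for (i in seq_len(4)) {
    if (is.null(scores[[i]]) || length(unique(labels[[i]])) < 2) next
    a <- roc_auc(scores[[i]], labels[[i]])
    auc_tbl$auc[i] <- a$auc
    auc_tbl$ci_low[i] <- a$ci[1]
    auc_tbl$ci_high[i] <- a$ci[2]
    auc_tbl$band[i] <- discrimination_band(a$auc)
  }

  say("simulating implementation strategies (threshold %.2f)",
      config$threshold)
  sm <- config$staffing
  baseline <- nrow(resp)
  outcomes <- list(
    full_clinical = pathway_outcome(resp, predictions,
                                    triage_strategy("full_clinical"), sm,
                                    baseline),
    hybrid = pathway_outcome(resp, predictions,
                             triage_strategy("hybrid", config$threshold),
                             sm, baseline),
    full_auto = pathway_outcome(resp, predictions,
                                triage_strategy("full_auto",
                                                config$threshold),
                                sm, baseline))
  sweep <- rbind(
    threshold_sweep(resp, predictions, "hybrid", config$grid, sm, baseline),
    threshold_sweep(resp, predictions, "full_auto", config$grid, sm,
                    baseline))

  result <- list(config = config, cohort = cohort, split = split,
                 models = list(mlp = mlp, logistic = logit, cnn = cnn,
                               fusion = head_fit),
                 predictions = predictions, auc = auc_tbl,
                 outcomes = outcomes, sweep = sweep)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

pathway_summary_table <- function(outcomes) {
  do.call(rbind, lapply(names(outcomes), function(nm) {
    po <- outcomes[[nm]]
    est <- function(m) po$diagnostics$metrics[[m]]$estimate
    data.frame(strategy = nm,
               threshold = po$strategy$threshold %||% NA_real_,
               n_responses = po$n_responses,
               n_clinician_reviewed = po$n_clinician_reviewed,
               n_in_person = po$n_in_person,
               tp = po$counts$tp, fp = po$counts$fp,
               tn = po$counts$tn, fn = po$counts$fn,
               sensitivity = est("sensitivity"),
               specificity = est("specificity"),
               ppv = est("ppv"), npv = est("npv"),
               failure_rate = est("failure_rate"),
               staff_hours = po$staff_hours,
               staff_hours_reduction = po$staff_hours_reduction,
               fte_per_caseload = po$fte_per_caseload)
  }))
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_predictions(result$predictions,
                    file.path(out_dir, "predictions.csv"))
  write.csv(pathway_summary_table(result$outcomes),
            file.path(out_dir, "pathway_summary.csv"), row.names = FALSE)
  write.csv(result$sweep, file.path(out_dir, "threshold_sweep.csv"),
            row.names = FALSE)
  write.csv(result$auc, file.path(out_dir, "auc_benchmarks.csv"),
            row.names = FALSE)
  cfg <- result$config
  cfg$staffing <- unclass(cfg$staffing)
  cfg$generator <- if (!is.null(cfg$generator)) unclass(cfg$generator)
  writeLines(yaml::as.yaml(unclass(cfg), precision = 15),
             file.path(out_dir, "run_config.yaml"))
  writeLines(c(sprintf("run completed %s", format(Sys.time())),
               sprintf("responses: %d, images: %d",
                       nrow(result$cohort$responses),
                       nrow(result$cohort$images)),
               sprintf("seeds: data %d, split %d, model %d",
                       cfg$data_seed, cfg$split_seed, cfg$model_seed)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
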