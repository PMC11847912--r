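resp_col_classes <- function() {
  c(response_id = "character", patient_id = "character",
    postop_day = "integer",
    setNames(rep("integer", 8), prom_items()),
    setNames(rep("character", 8), paste0(prom_items(), "_trend")),
    n_images = "integer", image_ids = "character",
    triage_label = "character", ssi48 = "integer")
}

#' Write a cohort to disk
#'
#' Writes `responses.csv` (one row per response; schema in the README),
#' `images.csv` (per-image generative truth), `config.yaml` (the generator
#' config echo) and, optionally, rendered `images/<image_id>.png` files.
#'
#' @param cohort an `ssi_cohort`.
#' @param dir output directory (created if missing).
#' @param overwrite allow replacing existing cohort files.
#' @param render_images render and write PNG wound images (slower; the
#'   tables alone round-trip the cohort).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE,
                         render_images = FALSE) {
  stopifnot(inherits(cohort, "ssi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(dir, c("responses.csv", "images.csv", "config.yaml"))
  if (!overwrite && any(file.exists(files))) {
    stop("cohort files already exist in `", dir,
         "`; use overwrite = TRUE to replace them", call. = FALSE)
  }
  write.csv(cohort$responses, files[1], row.names = FALSE)
  img <- cohort$images
  for (nm in c("erythema_intensity", "skin_tone")) {
    img[[nm]] <- sprintf("%.17g", img[[nm]])  # doubles round-trip exactly
  }
  write.csv(img, files[2], row.names = FALSE, quote = FALSE)
  cfg <- unclass(cohort$config)
  for (nm in c("symptom_base_rates", "symptom_effects",
               "triage_calibration", "images_per_response")) {
    cfg[[nm]] <- as.list(cfg[[nm]])  # yaml maps keep the names
  }
  writeLines(yaml::as.yaml(cfg, precision = 15), files[3])
  if (render_images && nrow(cohort$images) > 0) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (id in cohort$images$image_id) {
      png::writePNG(cohort_image(cohort, id)$pixels,
                    file.path(img_dir, paste0(id, ".png")))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return An `ssi_cohort` equal to the one written.
#' @export
read_cohort <- function(dir) {
  responses <- read_responses(file.path(dir, "responses.csv"))
  images <- read.csv(file.path(dir, "images.csv"),
                     colClasses = c(image_id = "character",
                                    response_id = "character",
                                    erythema_intensity = "numeric",
                                    pus_count = "integer",
                                    skin_tone = "numeric",
                                    render_seed = "integer"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$symptom_base_rates <- unlist(cfg$symptom_base_rates)
  cfg$symptom_effects <- unlist(cfg$symptom_effects)
  cfg$triage_calibration <- unlist(cfg$triage_calibration)
  cfg$images_per_response <- unlist(cfg$images_per_response)
  cfg$skin_tone_range <- unlist(cfg$skin_tone_range)
  cfg$erythema_shape <- lapply(cfg$erythema_shape, unlist)
  config <- do.call(synth_config, cfg)
  structure(list(responses = responses, images = images, config = config,
                 triage_thresholds = calibrate_triage(config)),
            class = "ssi_cohort")
}

#' Read and validate a responses table
#'
#' Enforces the documented schema: ids present, `postop_day` within 1-30,
#' symptom items 0/1/NA, triage labels `low`/`moderate`/`high`, `ssi48`
#' binary. Violations raise an error naming the column and row. An empty
#' `image_ids` field means no image was submitted.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_responses <- function(path) {
  df <- read.csv(path, colClasses = resp_col_classes(),
                 na.strings = "NA")
  df$image_ids[is.na(df$image_ids)] <- ""
  fail <- function(col, rows) {
    stop(sprintf("invalid `%s` at row(s) %s of %s", col,
                 paste(head(rows, 5), collapse = ", "), basename(path)),
         call. = FALSE)
  }
  bad <- which(is.na(df$postop_day) | df$postop_day < 1 | df$postop_day > 30)
  if (length(bad)) fail("postop_day", bad)
  for (item in prom_items()) {
    bad <- which(!(df[[item]] %in% c(0L, 1L, NA)))
    if (length(bad)) fail(item, bad)
  }
  bad <- which(!df$triage_label %in% c("low", "moderate", "high"))
  if (length(bad)) fail("triage_label", bad)
  bad <- which(!df$ssi48 %in% c(0L, 1L))
  if (length(bad)) fail("ssi48", bad)
  if (anyDuplicated(df$response_id)) {
    fail("response_id", which(duplicated(df$response_id)))
  }
  df
}

#' Write a prediction table
#'
#' @param predictions data frame with `response_id`, `p_proms`,
#'   `p_image_max`, `p_fused`, `provenance` (from [fuse_predictions()]).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  need <- c("response_id", "p_proms", "p_fused", "provenance")
  missing <- setdiff(need, names(predictions))
  if (length(missing)) {
    stop("prediction table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stop_if_not_prob(predictions$p_fused, "p_fused")
  write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_predictions <- function(path) {
  read.csv(path, colClasses = c(response_id = "character"))
}
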