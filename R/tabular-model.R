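#' Encode PROM responses into a model feature matrix
#'
#' Builds the 8-wide numeric design matrix for the tabular models. Missing
#' symptom answers (partial questionnaire completion) are imputed as
#' "absent" *before* encoding, matching clinical practice. Each binary item
#' keeps a single indicator column, so the input stays eight columns wide;
#' columns are then centred and scaled using statistics learned on the
#' training data only. Passing a previously fitted `encoder` reuses its
#' stored centre/scale (and column order) without re-learning anything, so
#' unseen data are transformed exactly as the training data were.
#'
#' @param responses data frame with the eight symptom columns named as in
#'   [prom_items()], coded 0/1 (NA allowed, treated as absent).
#' @param encoder optional encoder from a previous call (fields `items`,
#'   `centre`, `scale`).
#' @return List of class `prom_features`: `values` (n x 8 matrix), `raw`
#'   (pre-scaling indicator matrix) and `encoder`.
#' @export
encode_proms <- function(responses, encoder = NULL) {
  items <- if (is.null(encoder)) prom_items() else encoder$items
  missing_cols <- setdiff(items, names(responses))
  if (length(missing_cols)) {
    stop("responses are missing symptom columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- as.matrix(responses[, items, drop = FALSE])
  bad <- !(is.na(raw) | raw == 0 | raw == 1)
  if (any(bad)) {
    j <- which(bad, arr.ind = TRUE)[1, 2]
    stop(sprintf("symptom item `%s` contains a value other than 0/1/NA",
                 items[j]), call. = FALSE)
  }
  raw[is.na(raw)] <- 0  # missing symptom answers mean the symptom is absent
  storage.mode(raw) <- "double"
  if (is.null(encoder)) {
    centre <- colMeans(raw)
    scale <- apply(raw, 2, sd)
    scale[scale == 0 | is.na(scale)] <- 1  # constant column: leave centred only
    encoder <- list(items = items, centre = centre, scale = scale)
  }
  values <- sweep(sweep(raw, 2, encoder$centre, `-`), 2, encoder$scale, `/`)
  structure(list(values = values, raw = raw, encoder = encoder),
            class = "prom_features")
}

#' Fit a tabular classifier on encoded PROMs
#'
#' Two model kinds are available for either outcome of interest:
#' `"mlp"`, a sequential multilayer perceptron on the 8-wide feature array
#' (two rectified hidden layers of 16 and 8 units, sigmoid output, Adam
#' updates, early stopping on training loss), and `"logistic"`, the
#' multivariable logistic-regression comparator fitted by [stats::glm()]
#' on the same inputs.
#'
#' @param features a `prom_features` object from [encode_proms()].
#' @param y binary outcome vector (one per row of the feature matrix).
#' @param kind `"mlp"` or `"logistic"`.
#' @param seed integer seed for the MLP (weight init and batch order).
#' @param class_weights length-2 weights for classes 0/1; default inverse
#'   prevalence, which stabilises training at the ~3.7% event rate.
#'   `NULL` disables weighting. Ignored for `"logistic"`.
#' @param epochs,patience,lr,batch_size MLP training controls.
#' @return Object of class `tabular_model` with a stored copy of the
#'   encoder, so prediction on raw responses re-encodes consistently.
#' @export
fit_tabular <- function(features, y, kind = c("mlp", "logistic"), seed = 1,
                        class_weights = "inverse_prevalence",
                        epochs = 200, patience = 10, lr = 1e-3,
                        batch_size = 32) {
  kind <- match.arg(kind)
  stopifnot(inherits(features, "prom_features"))
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(features$values), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    stop("outcome vector contains a single class; need at least one case ",
         "and one control", call. = FALSE)
  }
  fit <- if (kind == "logistic") {
    df <- as.data.frame(features$values)
    glm(y ~ ., data = cbind(y = y, df), family = binomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  } else {
    cw <- class_weights
    if (identical(cw, "inverse_prevalence")) {
      prev <- mean(y)
      cw <- c(1 / (1 - prev), 1 / prev)
    }
    nn_dense_fit(features$values, y, hidden = c(16, 8), epochs = epochs,
                 batch_size = batch_size, lr = lr, optimizer = "adam",
                 class_weights = cw, patience = patience, seed = seed)
  }
  structure(list(kind = kind, fit = fit, encoder = features$encoder,
                 seed = seed),
            class = "tabular_model")
}

#' Predict SSI risk from a tabular model
#'
#' @param object a `tabular_model`.
#' @param newdata either a `prom_features` object or a raw responses data
#'   frame (re-encoded with the model's own stored encoder).
#' @param ... unused.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict.tabular_model <- function(object, newdata, ...) {
  feats <- if (inherits(newdata, "prom_features")) newdata
           else encode_proms(newdata, object$encoder)
  X <- feats$values
  if (ncol(X) != length(object$encoder$items)) {
    stop("feature count mismatch between model encoder and new data",
         call. = FALSE)
  }
  p <- if (inherits(object$fit, "logistic_coefs")) {
    cf <- object$fit$coef
    as.vector(plogis(cf[1] + X[, names(cf)[-1], drop = FALSE] %*% cf[-1]))
  } else if (object$kind == "logistic") {
    as.vector(predict(object$fit, newdata = as.data.frame(X),
                      type = "response"))
  } else {
    nn_dense_predict(object$fit, X)
  }
  stop_if_not_prob(p, "predicted probabilities")
  p
}

#' @export
print.tabular_model <- function(x, ...) {
  cat(sprintf("tabular %s model on %d PROM features\n",
              x$kind, length(x$encoder$items)))
  if (x$kind == "mlp") {
    tm <- x$fit$training_meta
    cat(sprintf("  epochs run %d (best %d), training loss %.4f\n",
                tm$epochs_run, tm$best_epoch, tm$best_loss))
  }
  invisible(x)
}
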