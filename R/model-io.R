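# On-disk model bundles: plain-JSON weight dumps with a config echo, so a
# trained model can be reloaded in a fresh session and reproduce its
# predictions exactly.

# jsonlite writes a matrix as a list of rows; rebuild column-major
json_matrix <- function(rows) {
  matrix(unlist(rows), ncol = length(rows[[1]]), byrow = TRUE)
}

serialize_dense <- function(net) {
  list(sizes = net$sizes,
       layers = lapply(net$layers, function(l)
         list(W = l$W, b = l$b)),
       training_meta = net$training_meta)
}

deserialize_dense <- function(x) {
  structure(list(
    layers = lapply(x$layers, function(l)
      list(W = json_matrix(l$W), b = unlist(l$b))),
    sizes = unlist(x$sizes),
    training_meta = x$training_meta
  ), class = "dense_net")
}

#' Save a trained model as a JSON bundle
#'
#' Supports `tabular_model` (MLP and logistic), `cnn_model` and
#' `fusion_head`. The bundle holds every learned weight, the encoder map
#' where applicable, and the training configuration echo; reloading with
#' [load_model()] reproduces predictions exactly.
#'
#' @param model the fitted model object.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  bundle <- if (inherits(model, "tabular_model")) {
    list(type = "tabular_model", kind = model$kind,
         encoder = model$encoder, seed = model$seed,
         fit = if (model$kind == "logistic") {
           list(coef = as.list(coef(model$fit)))
         } else serialize_dense(model$fit))
  } else if (inherits(model, "cnn_model")) {
    a <- model$net$arch
    list(type = "cnn_model", input_size = model$input_size,
         arch = list(input_size = a$input_size, stem_pool = a$stem_pool,
                     filters = a$filters, pool = a$pool),
         conv = lapply(model$net$conv, function(l) list(W = l$W, b = l$b)),
         dense = model$net$dense,
         training_meta = model$training_meta)
  } else if (inherits(model, "fusion_head")) {
    list(type = "fusion_head", kind = model$kind,
         fit = switch(model$kind,
                      average = NULL,
                      logistic_stack = list(coef = as.list(coef(model$fit))),
                      shallow_net = serialize_dense(model$fit)))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model bundle written by [save_model()]
#'
#' @param path `.json` bundle file.
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path)
  switch(x$type,
    tabular_model = {
      enc <- list(items = unlist(x$encoder$items),
                  centre = unlist(x$encoder$centre),
                  scale = unlist(x$encoder$scale))
      fit <- if (x$kind == "logistic") {
        structure(list(coef = unlist(x$fit$coef)), class = "logistic_coefs")
      } else deserialize_dense(x$fit)
      structure(list(kind = x$kind, fit = fit, encoder = enc,
                     seed = x$seed),
                class = "tabular_model")
    },
    cnn_model = {
      arch <- cnn_architecture(x$arch$input_size, x$arch$stem_pool,
                               unlist(x$arch$filters), unlist(x$arch$pool))
      net <- cnn_init(arch, seed = 0)
      net$conv <- lapply(x$conv, function(l)
        list(W = json_matrix(l$W), b = unlist(l$b)))
      net$dense <- list(w = unlist(x$dense$w), b = unlist(x$dense$b))
      structure(list(net = net, input_size = x$input_size,
                     training_meta = x$training_meta),
                class = "cnn_model")
    },
    fusion_head = {
      fit <- switch(x$kind,
                    average = NULL,
                    logistic_stack = structure(
                      list(coef = unlist(x$fit$coef)),
                      class = "logistic_coefs"),
                    shallow_net = deserialize_dense(x$fit))
      structure(list(kind = x$kind, fit = fit), class = "fusion_head")
    },
    stop("unknown bundle type in ", path, call. = FALSE))
}
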