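#' Fit a late-fusion head on unimodal predictions
#'
#' Combines the PROMs-model and image-model output probabilities into a
#' single multimodal risk. Three heads are available:
#' \describe{
#'   \item{`average`}{parameter-free mean of the two probabilities;}
#'   \item{`logistic_stack`}{(default) a 2-input logistic model on the
#'     unimodal probabilities, fitted by [stats::glm()];}
#'   \item{`shallow_net`}{a small 2-input neural network (one rectified
#'     hidden layer of 4 units).}
#' }
#'
#' @param p_proms,p_image training-set unimodal probabilities, one pair per
#'   image-bearing response (responses without images play no role in
#'   fitting the head).
#' @param y binary outcome for each pair.
#' @param kind fusion head type.
#' @param seed seed for `shallow_net`.
#' @return Object of class `fusion_head`.
#' @export
fit_fusion_head <- function(p_proms, p_image, y,
                            kind = c("logistic_stack", "average",
                                     "shallow_net"),
                            seed = 1) {
  kind <- match.arg(kind)
  if (kind == "average") {
    return(structure(list(kind = kind), class = "fusion_head"))
  }
  stop_if_not_prob(p_proms, "p_proms")
  stop_if_not_prob(p_image, "p_image")
  y <- as.numeric(y)
  stopifnot(length(p_proms) == length(y), length(p_image) == length(y))
  if (length(unique(y)) < 2) {
    stop("fusion head training needs both classes present", call. = FALSE)
  }
  fit <- if (kind == "logistic_stack") {
    glm(y ~ p_proms + p_image,
        data = data.frame(y = y, p_proms = p_proms, p_image = p_image),
        family = binomial())
  } else {
    nn_dense_fit(cbind(p_proms, p_image), y, hidden = 4, epochs = 200,
                 batch_size = 32, lr = 1e-2, optimizer = "adam",
                 patience = 10, seed = seed)
  }
  structure(list(kind = kind, fit = fit), class = "fusion_head")
}

fusion_score <- function(head, p_proms, p_image) {
  if (head$kind == "logistic_stack" && inherits(head$fit, "logistic_coefs")) {
    cf <- head$fit$coef
    return(as.vector(plogis(cf[1] + cf[2] * p_proms + cf[3] * p_image)))
  }
  switch(head$kind,
         average = (p_proms + p_image) / 2,
         logistic_stack = as.vector(predict(
           head$fit, newdata = data.frame(p_proms = p_proms,
                                          p_image = p_image),
           type = "response")),
         shallow_net = nn_dense_predict(head$fit, cbind(p_proms, p_image)))
}

#' Fuse unimodal predictions for one response
#'
#' Applies the study's missing-image and multiple-image rules: when no
#' image was submitted the PROMs prediction is used unchanged; when one or
#' more images were submitted, each image is fused with the PROMs
#' probability and the highest resulting risk is taken.
#'
#' @param p_proms PROMs-model probability for the response.
#' @param p_image_list numeric vector of per-image probabilities (possibly
#'   empty).
#' @param head a `fusion_head`.
#' @return List with `p_fused` and `provenance` (`"fused"` or
#'   `"proms_only"`).
#' @examples
#' head <- fit_fusion_head(kind = "average")
#' fuse(0.3, numeric(0), head)              # -> 0.3, proms_only
#' fuse(0.1, c(0.2, 0.8), head)             # -> max(0.15, 0.45) = 0.45
#' @export
fuse <- function(p_proms, p_image_list, head) {
  stopifnot(inherits(head, "fusion_head"))
  stop_if_not_prob(p_proms, "p_proms")
  if (length(p_image_list) == 0) {
    return(list(p_fused = p_proms, provenance = "proms_only"))
  }
  stop_if_not_prob(p_image_list, "p_image_list")
  per_image <- fusion_score(head, rep(p_proms, length(p_image_list)),
                            p_image_list)
  list(p_fused = max(per_image), provenance = "fused")
}

#' Cross-fitted PROMs predictions for stacking
#'
#' Produces out-of-fold tabular-model probabilities for the training
#' responses, with folds grouped by patient. Fitting the fusion stack on
#' cross-fitted rather than in-sample probabilities is standard stacked
#' generalisation: in-sample MLP outputs are over-confident and can
#' quasi-separate the stacking regression.
#'
#' @param responses training responses (symptom columns, `patient_id`).
#' @param y binary outcome per response.
#' @param kind,seed passed to [fit_tabular()].
#' @param folds number of grouped folds (default 5).
#' @return Named probability vector (names = `response_id`).
#' @export
crossfit_proms <- function(responses, y, kind = "mlp", folds = 5, seed = 1) {
  patients <- unique(responses$patient_id)
  fold_of_patient <- with_seed(derive_seed(seed, 91), {
    setNames(rep_len(seq_len(folds), length(patients)),
             sample(patients))
  })
  fold <- fold_of_patient[responses$patient_id]
  out <- rep(NA_real_, nrow(responses))
  for (k in seq_len(folds)) {
    hold <- fold == k
    if (!any(hold) || length(unique(y[!hold])) < 2) next
    ft <- encode_proms(responses[!hold, ])
    m <- fit_tabular(ft, y[!hold], kind = kind,
                     seed = derive_seed(seed, k))
    out[hold] <- predict(m, responses[hold, ])
  }
  # folds that could not be scored fall back to a full-data fit
  if (anyNA(out)) {
    m <- fit_tabular(encode_proms(responses), y, kind = kind, seed = seed)
    out[is.na(out)] <- predict(m, responses[is.na(out), ])
  }
  setNames(out, responses$response_id)
}

#' Build the per-response multimodal prediction table
#'
#' @param p_proms named (by response_id) vector of PROMs probabilities.
#' @param image_predictions data frame with `response_id`, `image_id`,
#'   `p_image` (zero rows allowed).
#' @param head a `fusion_head`.
#' @return Data frame: `response_id`, `p_proms`, `p_image_max`, `p_fused`,
#'   `provenance`.
#' @export
fuse_predictions <- function(p_proms, image_predictions, head) {
  stopifnot(!is.null(names(p_proms)))
  img_by_resp <- split(image_predictions$p_image,
                       image_predictions$response_id)
  out <- lapply(names(p_proms), function(id) {
    pl <- img_by_resp[[id]] %||% numeric(0)
    f <- fuse(p_proms[[id]], pl, head)
    data.frame(response_id = id, p_proms = p_proms[[id]],
               p_image_max = if (length(pl)) max(pl) else NA_real_,
               p_fused = f$p_fused, provenance = f$provenance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
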