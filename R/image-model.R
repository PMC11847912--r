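as_ebimage <- function(x) {
  EBImage::Image(aperm(x, c(2, 1, 3)), colormode = EBImage::Color)
}

from_ebimage <- function(img) {
  aperm(array(EBImage::imageData(img), dim(img)), c(2, 1, 3))
}

#' Construct an image batch
#'
#' @param images list of `H x W x 3` arrays with values in \[0, 1\] (all the
#'   same size) or `synthetic_wound_image` objects.
#' @param labels optional binary labels, one per image.
#' @param augmented marks a batch produced by [augment()]; evaluation
#'   functions refuse augmented batches.
#' @return Object of class `image_batch`; `dim()` returns
#'   `c(n, H, W, 3)`.
#' @export
image_batch <- function(images, labels = NULL, augmented = FALSE) {
  images <- lapply(images, function(im) {
    if (inherits(im, "synthetic_wound_image")) im$pixels else im
  })
  d1 <- dim(images[[1]])
  ok <- vapply(images, function(im)
    length(dim(im)) == 3 && all(dim(im) == d1) && dim(im)[3] == 3,
    logical(1))
  if (!all(ok)) {
    stop("all images must be H x W x 3 arrays of identical size",
         call. = FALSE)
  }
  if (!is.null(labels)) stopifnot(length(labels) == length(images))
  structure(list(images = images, labels = labels,
                 size = d1[1:2], augmented = augmented),
            class = "image_batch")
}

#' @export
dim.image_batch <- function(x) {
  c(length(x$images), x$size[1], x$size[2], 3L)
}

#' @export
print.image_batch <- function(x, ...) {
  cat(sprintf("image batch: %d images of %dx%dx3%s\n", length(x$images),
              x$size[1], x$size[2],
              if (x$augmented) " (augmented)" else ""))
  invisible(x)
}

#' Read and standardise wound images
#'
#' Reads PNG/JPEG files, converts to RGB in \[0, 1\] and rescales to the
#' standard 256 x 256 input: the short side is resized to the target with
#' bilinear interpolation, then the long side is centre-cropped. Images
#' already at the target size pass through unchanged. Grayscale input is
#' replicated to three channels with a warning; unreadable files raise an
#' error naming the file.
#'
#' @param paths character vector of image file paths.
#' @param labels optional binary labels.
#' @param target side length after preprocessing (default 256).
#' @return An [image_batch()].
#' @export
preprocess_images <- function(paths, labels = NULL, target = 256) {
  images <- lapply(paths, function(p) {
    x <- tryCatch({
      if (grepl("\\.png$", p, ignore.case = TRUE)) png::readPNG(p)
      else from_ebimage(EBImage::readImage(p))
    }, error = function(e) {
      stop(sprintf("cannot read image file `%s`: %s", p, conditionMessage(e)),
           call. = FALSE)
    })
    if (length(dim(x)) == 2) {
      warning(sprintf("grayscale image `%s` replicated to 3 channels",
                      basename(p)), call. = FALSE)
      x <- array(rep(x, 3), c(dim(x), 3))
    }
    if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
    standardise_image(x, target)
  })
  image_batch(images, labels)
}

standardise_image <- function(x, target = 256) {
  d <- dim(x)
  if (d[1] == target && d[2] == target) return(clamp01(x))
  sc <- target / min(d[1], d[2])
  newd <- pmax(round(c(d[1], d[2]) * sc), target)
  img <- EBImage::resize(as_ebimage(x), w = newd[2], h = newd[1])
  x <- from_ebimage(img)
  r0 <- floor((dim(x)[1] - target) / 2)
  c0 <- floor((dim(x)[2] - target) / 2)
  clamp01(x[r0 + seq_len(target), c0 + seq_len(target), , drop = FALSE])
}

shift_image <- function(x, dr, dc) {
  if (dr == 0 && dc == 0) return(x)
  d <- dim(x)
  out <- array(0, d)
  src_r <- seq_len(d[1]) - dr
  src_c <- seq_len(d[2]) - dc
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[which(ok_r), which(ok_c), ] <- x[src_r[ok_r], src_c[ok_c], ,
                                       drop = FALSE]
  out
}

#' Augment a training image batch
#'
#' Applies label-preserving rigid/similarity transforms only — flips,
#' integer translation, rotation and isotropic scaling; no shear or
#' elastic deformation, so wound shape characteristics are preserved.
#' Intended for training data; the batch is marked `augmented` and
#' evaluation refuses it.
#'
#' @param batch an [image_batch()].
#' @param seed optional seed; otherwise the current RNG stream is used.
#' @param max_rotation maximum absolute rotation in degrees.
#' @param max_translation maximum shift as a fraction of image size.
#' @param scale_range isotropic scale factor range.
#' @param flip allow horizontal/vertical flips.
#' @return A new `image_batch` with identical labels.
#' @export
augment <- function(batch, seed = NULL, max_rotation = 15,
                    max_translation = 0.1, scale_range = c(0.9, 1.1),
                    flip = TRUE) {
  stopifnot(inherits(batch, "image_batch"))
  if (!is.null(seed)) {
    return(with_seed(seed, augment(batch, NULL, max_rotation,
                                   max_translation, scale_range, flip)))
  }
  S <- batch$size[1]
  images <- lapply(batch$images, function(x) {
    sc <- runif(1, scale_range[1], scale_range[2])
    if (abs(sc - 1) > 1e-8) {
      big <- from_ebimage(EBImage::resize(as_ebimage(x),
                                          w = round(S * sc),
                                          h = round(S * sc)))
      x <- if (dim(big)[1] >= S) {
        o <- floor((dim(big)[1] - S) / 2)
        big[o + seq_len(S), o + seq_len(S), , drop = FALSE]
      } else {
        pad <- array(0, c(S, S, 3))
        o <- floor((S - dim(big)[1]) / 2)
        pad[o + seq_len(dim(big)[1]), o + seq_len(dim(big)[2]), ] <- big
        pad
      }
    }
    ang <- runif(1, -max_rotation, max_rotation)
    if (abs(ang) > 1e-8) {
      x <- from_ebimage(EBImage::rotate(as_ebimage(x), ang,
                                        output.dim = c(S, S)))
    }
    x <- shift_image(x, sample(-round(max_translation * S):
                                 round(max_translation * S), 1),
                     sample(-round(max_translation * S):
                              round(max_translation * S), 1))
    if (flip && runif(1) < 0.5) x <- x[, S:1, , drop = FALSE]
    if (flip && runif(1) < 0.25) x <- x[S:1, , , drop = FALSE]
    clamp01(x)
  })
  image_batch(images, batch$labels, augmented = TRUE)
}

#' Train the convolutional wound-image classifier
#'
#' Fits the desk-scale backbone: a 4-block 3x3 convolutional network
#' (8/16/16/32 filters) over an average-pooled stem, global average
#' pooling and a sigmoid unit, trained with root-mean-square propagation
#' in batches of 10 for up to 30 epochs, binary cross-entropy monitored
#' every 10 optimisation steps with a patience of 10 evaluations and
#' best-weight restoration. Light label-preserving augmentation (flips and
#' small integer translations) is applied to training batches only.
#'
#' A VGG-style pretrained backbone (fine-tuned from its third pooling
#' stage) is the natural full-scale alternative; it requires user-supplied
#' weights via `backbone_weights` and is not needed for the synthetic
#' study.
#'
#' @param batch training [image_batch()] with labels.
#' @param epochs,batch_size,lr,optimizer training recipe.
#' @param eval_every,patience early-stopping controls (steps between loss
#'   evaluations; evaluations without improvement tolerated).
#' @param class_weights `"inverse_prevalence"` (default), `NULL`, or a
#'   length-2 vector.
#' @param augment_training apply cheap rigid augmentation to training
#'   minibatches.
#' @param stem_pool,filters,pool backbone geometry.
#' @param backbone_weights optional path to a pretrained VGG-style weight
#'   bundle; `NULL` (default) trains the small backbone from scratch.
#' @param seed integer seed; training is reproducible given the seed.
#' @return Object of class `cnn_model`.
#' @export
fit_cnn <- function(batch, epochs = 30, batch_size = 10, lr = 1e-3,
                    optimizer = "rmsprop", eval_every = 10, patience = 10,
                    class_weights = "inverse_prevalence",
                    augment_training = TRUE,
                    stem_pool = 4, filters = c(8, 16, 16, 32),
                    pool = c(TRUE, TRUE, TRUE, FALSE),
                    backbone_weights = NULL, seed = 1) {
  stopifnot(inherits(batch, "image_batch"))
  y <- as.numeric(batch$labels)
  if (length(unique(y)) < 2) {
    stop("image labels contain a single class; cannot train", call. = FALSE)
  }
  if (!is.null(backbone_weights)) {
    stop("pretrained VGG-style backbones require a supplied weight bundle ",
         "reader; the desk-scale backbone (backbone_weights = NULL) is ",
         "the supported configuration", call. = FALSE)
  }
  S <- batch$size[1]
  arch <- cnn_architecture(S, stem_pool, filters, pool)
  net <- cnn_init(arch, derive_seed(seed, 1))
  pooled <- lapply(batch$images, avg_pool, f = stem_pool)

  cw <- class_weights
  if (identical(cw, "inverse_prevalence")) {
    prev <- mean(y)
    cw <- c(1 / (1 - prev), 1 / prev)
  }
  if (is.null(cw)) cw <- c(1, 1)
  w <- cw[y + 1]
  w <- w / mean(w)

  n <- length(pooled)
  sp <- S / stem_pool
  state <- list()
  step <- 0L
  trace <- numeric(0)
  best <- list(loss = Inf, net = net, step = 0L)
  wait <- 0L
  stopped <- FALSE

  with_seed(derive_seed(seed, 2), {
    for (epoch in seq_len(epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        rows <- idx[start:min(start + batch_size - 1, n)]
        gconv <- NULL; gdense <- NULL
        for (r in rows) {
          x <- pooled[[r]]
          if (augment_training) {
            if (runif(1) < 0.5) x <- x[, sp:1, , drop = FALSE]
            if (runif(1) < 0.25) x <- x[sp:1, , , drop = FALSE]
            x <- shift_image(x, sample(-3:3, 1), sample(-3:3, 1))
          }
          fw <- cnn_forward(net, x, keep = TRUE)
          gr <- cnn_backward(net, fw, y[r], w[r])
          if (is.null(gconv)) {
            gconv <- gr$conv; gdense <- gr$dense
          } else {
            for (l in seq_along(gconv)) {
              gconv[[l]]$W <- gconv[[l]]$W + gr$conv[[l]]$W
              gconv[[l]]$b <- gconv[[l]]$b + gr$conv[[l]]$b
            }
            gdense$w <- gdense$w + gr$dense$w
            gdense$b <- gdense$b + gr$dense$b
          }
        }
        nb <- length(rows)
        step <- step + 1L
        for (l in seq_along(net$conv)) {
          up <- nn_opt_step(net$conv[[l]]$W, gconv[[l]]$W / nb, state,
                            paste0("cW", l), optimizer, lr, step)
          net$conv[[l]]$W <- up$theta; state <- up$state
          up <- nn_opt_step(net$conv[[l]]$b, gconv[[l]]$b / nb, state,
                            paste0("cb", l), optimizer, lr, step)
          net$conv[[l]]$b <- up$theta; state <- up$state
        }
        up <- nn_opt_step(net$dense$w, gdense$w / nb, state, "dw",
                          optimizer, lr, step)
        net$dense$w <- up$theta; state <- up$state
        up <- nn_opt_step(net$dense$b, gdense$b / nb, state, "db",
                          optimizer, lr, step)
        net$dense$b <- up$theta; state <- up$state

        if (step %% eval_every == 0) {
          # monitor the full (augmentation-free) training loss
          ev <- cnn_training_loss(net, pooled, y, w)
          trace <- c(trace, ev)
          if (ev < best$loss - 1e-5) {
            best <- list(loss = ev, net = net, step = step)
            wait <- 0L
          } else {
            wait <- wait + 1L
            if (wait >= patience) { stopped <- TRUE; break }
          }
        }
      }
      if (stopped) break
    }
  })

  structure(list(
    net = best$net, input_size = S,
    training_meta = list(loss_trace = trace, best_step = best$step,
                         best_loss = best$loss, steps_run = step,
                         early_stopped = stopped, optimizer = optimizer,
                         lr = lr, batch_size = batch_size, epochs = epochs,
                         class_weights = cw, seed = seed)
  ), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  a <- x$net$arch
  cat(sprintf("small CNN: %d px input, stem pool %d, filters %s, %dx%d feature maps\n",
              x$input_size, a$stem_pool,
              paste(a$filters, collapse = "-"), a$map_size, a$map_size))
  tm <- x$training_meta
  cat(sprintf("  %d steps (%s), best loss %.4f at step %d\n", tm$steps_run,
              if (tm$early_stopped) "early-stopped" else "full run",
              tm$best_loss, tm$best_step))
  invisible(x)
}

#' Predict SSI risk from wound images
#'
#' Evaluation is augmentation-free and deterministic for a fixed model;
#' augmented batches are refused.
#'
#' @param object a `cnn_model`.
#' @param newdata an [image_batch()], a list of arrays, or a single
#'   `H x W x 3` array.
#' @param ... unused.
#' @return Probability vector in \[0, 1\].
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (is.array(newdata)) newdata <- image_batch(list(newdata))
  if (!inherits(newdata, "image_batch")) {
    newdata <- image_batch(newdata)
  }
  if (isTRUE(newdata$augmented)) {
    stop("refusing to evaluate on an augmented batch; augmentation is for ",
         "training only", call. = FALSE)
  }
  if (newdata$size[1] != object$input_size) {
    stop(sprintf("image size %d does not match model input %d",
                 newdata$size[1], object$input_size), call. = FALSE)
  }
  pooled <- lapply(newdata$images, avg_pool,
                   f = object$net$arch$stem_pool)
  cnn_predict_pooled(object$net, pooled)
}

#' Class-activation heatmap for a wound image
#'
#' Gradient-weighted class-activation mapping at the last convolutional
#' stage: each feature map is weighted by the spatial mean of the gradient
#' of the pre-sigmoid score with respect to that map (for this
#' architecture, the corresponding output weight divided by the map area),
#' the weighted sum is rectified, max-normalised and bilinearly upsampled
#' to the input size. A map with no positive evidence anywhere is returned
#' as uniform (all ones): the model found nothing to localise.
#'
#' @param model a trained `cnn_model`.
#' @param image an `H x W x 3` array, `synthetic_wound_image` or one-image
#'   [image_batch()].
#' @return Object of class `activation_heatmap`: `weights` (matrix in
#'   \[0, 1\], same spatial extent as the input) and `overlay` (RGB
#'   composite).
#' @export
cam <- function(model, image) {
  if (!inherits(model, "cnn_model") || length(model$net$conv) == 0) {
    stop("`model` must be a convolutional model with at least one ",
         "convolutional layer", call. = FALSE)
  }
  if (inherits(image, "synthetic_wound_image")) image <- image$pixels
  if (inherits(image, "image_batch")) {
    stopifnot(length(image$images) == 1)
    image <- image$images[[1]]
  }
  S <- model$input_size
  stopifnot(all(dim(image)[1:2] == S))
  pooled <- avg_pool(image, model$net$arch$stem_pool)
  fw <- cnn_forward(model$net, pooled)
  dmap <- dim(fw$maps)
  alpha <- model$net$dense$w / (dmap[1] * dmap[2])
  raw <- matrix(matrix(fw$maps, dmap[1] * dmap[2], dmap[3]) %*% alpha,
                dmap[1], dmap[2])
  raw <- relu(raw)
  up <- EBImage::resize(EBImage::Image(t(raw)), w = S, h = S)
  hm <- t(EBImage::imageData(up))
  hm <- relu(hm)
  if (max(hm) > 0) {
    hm <- hm / max(hm)
  } else {
    hm[] <- 1  # no positive evidence anywhere: uniform, uninformative map
  }
  overlay <- image
  overlay[, , 1] <- clamp01(0.5 * image[, , 1] + 0.5 * hm)
  overlay[, , 2] <- 0.5 * image[, , 2]
  overlay[, , 3] <- 0.5 * image[, , 3]
  structure(list(weights = hm, overlay = overlay, p = fw$p),
            class = "activation_heatmap")
}

#' @export
print.activation_heatmap <- function(x, ...) {
  cat(sprintf("activation heatmap %dx%d, model probability %.3f\n",
              nrow(x$weights), ncol(x$weights), x$p))
  invisible(x)
}

#' Fraction of heatmap mass inside a region
#'
#' Localisation score used to check that a trained image model attends to
#' the wound: the share of total heatmap weight falling inside the
#' (dilated) wound mask.
#'
#' @param heatmap an `activation_heatmap`.
#' @param mask logical matrix of the same spatial extent.
#' @param dilate dilation radius in pixels applied to the mask (box
#'   kernel).
#' @return Scalar in \[0, 1\].
#' @export
heatmap_mass_inside <- function(heatmap, mask, dilate = 8) {
  stopifnot(inherits(heatmap, "activation_heatmap"),
            all(dim(mask) == dim(heatmap$weights)))
  if (dilate > 0) {
    kern <- EBImage::makeBrush(2 * dilate + 1, "box")
    mask <- EBImage::dilate(EBImage::Image(t(mask * 1)), kern)
    mask <- t(EBImage::imageData(mask)) > 0
  }
  tot <- sum(heatmap$weights)
  if (tot == 0) return(NA_real_)
  sum(heatmap$weights[mask]) / tot
}
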