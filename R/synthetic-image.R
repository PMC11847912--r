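#' Render a synthetic surgical wound image
#'
#' Draws a simple parametric wound photograph: a uniform skin-tone
#' background, a dark curvilinear incision, an erythema (redness) halo whose
#' strength scales with `erythema_intensity`, and optional small purulent
#' (yellow) spots along the incision. The generative law couples erythema
#' and pus to SSI status upstream (see [generate_cohort()]), so image
#' classifiers trained on these images have a recoverable signal.
#'
#' The function consumes the current RNG stream (or `seed` if supplied):
#' identical RNG state and parameters give an identical pixel array.
#'
#' @param erythema_intensity redness of the periwound halo in \[0, 1\].
#' @param pus_count number of purulent spots (0-3 typical).
#' @param skin_tone base skin tone in \[0, 1\] (0 lightest, 1 darkest).
#' @param image_size side length in pixels, at least 64.
#' @param noise_sd standard deviation of additive pixel noise.
#' @param seed optional integer; when given, rendering is wrapped in its own
#'   seed and the caller's RNG state is untouched.
#' @return An object of class `synthetic_wound_image`: list with `pixels`
#'   (`image_size x image_size x 3` array in \[0, 1\]), `wound_mask` (logical
#'   matrix marking the incision and periwound region) and `truth` (the
#'   generative parameters).
#' @examples
#' img <- render_wound_image(0.8, 2, 0.3, image_size = 64, seed = 1)
#' range(img$pixels)
#' @export
render_wound_image <- function(erythema_intensity, pus_count, skin_tone,
                               image_size = 256, noise_sd = 0.015,
                               seed = NULL) {
  if (!is.null(seed)) {
    return(with_seed(seed, render_wound_image(
      erythema_intensity, pus_count, skin_tone, image_size, noise_sd)))
  }
  stop_if_not_prob(erythema_intensity, "erythema_intensity")
  stop_if_not_prob(skin_tone, "skin_tone")
  if (image_size < 64) {
    stop("`image_size` below 64 px breaks the image model's receptive-field ",
         "assumptions", call. = FALSE)
  }
  S <- as.integer(image_size)

  # incision: quadratic Bezier with random position, orientation, curvature
  centre <- S * runif(2, 0.42, 0.58)
  theta <- runif(1, 0, pi)
  len <- S * runif(1, 0.40, 0.55)
  u <- c(cos(theta), sin(theta))
  v <- c(-u[2], u[1])
  bend <- S * runif(1, -0.08, 0.08)
  p0 <- centre - len / 2 * u
  p2 <- centre + len / 2 * u
  p1 <- centre + bend * v
  tt <- seq(0, 1, length.out = 64)
  bez <- cbind((1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1],
               (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2])

  gx <- rep(seq_len(S), times = S)   # row (y) index, column-major
  gy <- rep(seq_len(S), each = S)
  d2 <- rep(Inf, S * S)
  for (i in seq_len(nrow(bez))) {
    di <- (gx - bez[i, 2])^2 + (gy - bez[i, 1])^2
    d2 <- pmin(d2, di)
  }
  d <- sqrt(d2)

  light <- c(0.94, 0.80, 0.70)
  dark <- c(0.42, 0.28, 0.22)
  base <- light + skin_tone * (dark - light)
  R <- matrix(base[1], S, S); G <- matrix(base[2], S, S)
  B <- matrix(base[3], S, S)

  # erythema halo (red-shifted, gaussian falloff from the incision)
  halo <- erythema_intensity * exp(-(d / (0.06 * S))^2)
  R <- R + 0.35 * halo
  G <- G - 0.12 * halo
  B <- B - 0.15 * halo

  # incision core: dark red-brown, soft edge
  w_inc <- max(1.5, 0.008 * S)
  core <- pmax(0, 1 - d / (2 * w_inc))
  inc_col <- c(0.35, 0.15, 0.15)
  R <- R + core * (inc_col[1] - R)
  G <- G + core * (inc_col[2] - G)
  B <- B + core * (inc_col[3] - B)

  # purulent spots near the incision
  pus_count <- as.integer(pus_count)
  if (pus_count > 0) {
    pus_col <- c(0.93, 0.89, 0.55)
    for (j in seq_len(pus_count)) {
      at <- bez[sample.int(nrow(bez), 1), ] +
        runif(2, -0.015 * S, 0.015 * S)
      r_p <- runif(1, 0.010 * S, 0.020 * S)
      a <- exp(-(((gx - at[2])^2 + (gy - at[1])^2) / r_p^2))
      R <- R + a * (pus_col[1] - R)
      G <- G + a * (pus_col[2] - G)
      B <- B + a * (pus_col[3] - B)
    }
  }

  px <- array(0, c(S, S, 3))
  px[, , 1] <- clamp01(R + rnorm(S * S, 0, noise_sd))
  px[, , 2] <- clamp01(G + rnorm(S * S, 0, noise_sd))
  px[, , 3] <- clamp01(B + rnorm(S * S, 0, noise_sd))

  mask <- matrix(d < 0.07 * S, S, S)
  structure(list(
    pixels = px,
    wound_mask = mask,
    truth = list(erythema_intensity = erythema_intensity,
                 pus_count = pus_count, skin_tone = skin_tone)
  ), class = "synthetic_wound_image")
}

#' @export
print.synthetic_wound_image <- function(x, ...) {
  cat(sprintf("synthetic wound image %dx%d, erythema %.2f, pus %d, tone %.2f; wound mask %.1f%% of pixels\n",
              nrow(x$wound_mask), ncol(x$wound_mask),
              x$truth$erythema_intensity, x$truth$pus_count,
              x$truth$skin_tone, 100 * mean(x$wound_mask)))
  invisible(x)
}
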