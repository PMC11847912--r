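#' PROM symptom items
#'
#' The eight patient-reported symptom items used throughout the package:
#' localised pain, redness (erythema), swelling (oedema), warmth (calor),
#' discharge/pus, fever, wound opening (dehiscence) and general unwellness.
#'
#' @return Character vector of length 8.
#' @export
prom_items <- function() {
  c("pain", "erythema", "oedema", "warmth",
    "discharge", "fever", "wound_opening", "unwellness")
}

default_symptom_base_rates <- function() {
  setNames(c(0.35, 0.20, 0.20, 0.15, 0.08, 0.10, 0.08, 0.20), prom_items())
}

default_symptom_effects <- function() {
  # log-odds shift of each symptom when a confirmed SSI follows within 48 h;
  # erythema and discharge carry the strongest signal, oedema the weakest.
  setNames(c(1.2, 2.2, 0.3, 1.0, 2.6, 1.2, 1.0, 1.1), prom_items())
}

#' Configuration for the synthetic wound-monitoring cohort
#'
#' Bundles every rate, effect size and image parameter of the generator.
#' Defaults emulate the response-level structure reported for remote
#' postoperative wound monitoring after gastrointestinal surgery: about 72%
#' of responses symptom-free, about 17% with a single isolated symptom, a
#' confirmed-SSI-within-48-hours rate of 3.7% per response, and clinician
#' triage calibrated so that roughly 1.4% of low-risk and 24% of high-risk
#' triaged responses are followed by a confirmed SSI within 48 hours.
#'
#' @param n_patients number of patients enrolled (at least 2).
#' @param mean_responses_per_patient mean submissions per active patient
#'   (Poisson, zero-truncated).
#' @param nonusage_rate probability a patient never submits a response.
#' @param p_ssi48 per-response probability of confirmed SSI within 48 h.
#' @param p_no_symptoms,p_isolated_symptom target marginal fractions of
#'   symptom-free and single-symptom responses (must sum to at most 1).
#' @param symptom_base_rates named 8-vector of per-symptom presence
#'   probabilities among symptomatic non-SSI responses.
#' @param symptom_effects named 8-vector of log-odds shifts applied to the
#'   base rates when the response is followed by confirmed SSI.
#' @param triage_calibration numeric `c(low = , high = )`: target conditional
#'   confirmed-SSI rates among low- and high-risk triaged responses; must
#'   straddle `p_ssi48`.
#' @param p_suspected target marginal fraction of responses triaged
#'   moderate or high risk (suspected SSI on remote review).
#' @param triage_ssi_shift,triage_symptom_shift coefficients of the latent
#'   triage severity score (SSI status and symptom count respectively).
#' @param images_per_response probability vector over 0, 1, 2, 3 submitted
#'   wound images per response.
#' @param image_size side length in pixels of generated images (minimum 64).
#' @param skin_tone_range interval in \[0, 1\] from which each patient's base
#'   skin tone is drawn (0 = lightest, 1 = darkest).
#' @param erythema_shape beta shape pairs for the erythema intensity of
#'   non-SSI and SSI wounds, as a list with elements `no_ssi` and `ssi`.
#' @param seed integer seed; identical config and seed give byte-identical
#'   cohorts.
#' @return An object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_patients = 50, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
synth_config <- function(n_patients,
                         mean_responses_per_patient = 5,
                         nonusage_rate = 0.25,
                         p_ssi48 = 0.037,
                         p_no_symptoms = 0.719,
                         p_isolated_symptom = 0.168,
                         symptom_base_rates = default_symptom_base_rates(),
                         symptom_effects = default_symptom_effects(),
                         triage_calibration = c(low = 0.014, high = 0.240),
                         p_suspected = 0.150,
                         triage_ssi_shift = 2.0,
                         triage_symptom_shift = 0.8,
                         images_per_response = c(`0` = 0.45, `1` = 0.30,
                                                 `2` = 0.15, `3` = 0.10),
                         image_size = 256,
                         skin_tone_range = c(0.05, 0.95),
                         erythema_shape = list(no_ssi = c(1.5, 4.0),
                                               ssi = c(5.0, 1.8)),
                         seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  stop_if_not_prob(c(nonusage_rate, p_ssi48, p_no_symptoms,
                     p_isolated_symptom), "probability parameters")
  if (p_no_symptoms + p_isolated_symptom > 1) {
    stop("`p_no_symptoms` + `p_isolated_symptom` must not exceed 1",
         call. = FALSE)
  }
  stopifnot(length(symptom_base_rates) == 8, length(symptom_effects) == 8)
  stop_if_not_prob(symptom_base_rates, "symptom_base_rates")
  stop_if_not_prob(triage_calibration, "triage_calibration")
  stop_if_not_prob(p_suspected, "p_suspected")
  if (triage_calibration[["low"]] >= triage_calibration[["high"]]) {
    stop("triage calibration requires low-risk rate < high-risk rate",
         call. = FALSE)
  }
  images_per_response <- images_per_response / sum(images_per_response)
  if (length(images_per_response) != 4) {
    stop("`images_per_response` must give probabilities for 0..3 images",
         call. = FALSE)
  }
  if (image_size < 64) {
    stop("`image_size` below 64 px breaks the image model's receptive-field ",
         "assumptions", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    mean_responses_per_patient = mean_responses_per_patient,
    nonusage_rate = nonusage_rate,
    p_ssi48 = p_ssi48,
    p_no_symptoms = p_no_symptoms,
    p_isolated_symptom = p_isolated_symptom,
    symptom_base_rates = symptom_base_rates,
    symptom_effects = symptom_effects,
    triage_calibration = triage_calibration,
    p_suspected = p_suspected,
    triage_ssi_shift = triage_ssi_shift,
    triage_symptom_shift = triage_symptom_shift,
    images_per_response = images_per_response,
    image_size = as.integer(image_size),
    skin_tone_range = skin_tone_range,
    erythema_shape = erythema_shape,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic wound-monitoring cohort configuration\n")
  cat(sprintf("  patients: %d, mean responses/patient: %.1f (nonusage %.0f%%)\n",
              x$n_patients, x$mean_responses_per_patient,
              100 * x$nonusage_rate))
  cat(sprintf("  P(SSI within 48 h) = %.3f; symptom-free %.3f, isolated %.3f\n",
              x$p_ssi48, x$p_no_symptoms, x$p_isolated_symptom))
  cat(sprintf("  triage calibration: P(SSI|low) = %.3f, P(SSI|high) = %.3f\n",
              x$triage_calibration[["low"]], x$triage_calibration[["high"]]))
  cat(sprintf("  images per response: %s; image size %d px; seed %d\n",
              paste(sprintf("%d:%.2f", 0:3, x$images_per_response),
                    collapse = " "),
              x$image_size, x$seed))
  invisible(x)
}

# Distribution of the symptom count for each SSI status.
# Non-SSI responses follow an explicit none / isolated / multiple mixture
# whose weights are solved so the configured *marginal* symptom-free and
# isolated fractions hold exactly in expectation; SSI responses draw all
# eight symptoms independently at effect-shifted rates.
symptom_count_model <- function(config) {
  base <- config$symptom_base_rates
  p1 <- plogis(qlogis(base) + config$symptom_effects)
  pmf1 <- poisbinom_pmf(p1)
  p <- config$p_ssi48
  if (p < 1) {
    q0 <- (config$p_no_symptoms - p * pmf1[1]) / (1 - p)
    q1 <- (config$p_isolated_symptom - p * pmf1[2]) / (1 - p)
  } else {
    q0 <- q1 <- 0
  }
  if (q0 < 0 || q1 < 0 || q0 + q1 > 1) {
    stop("symptom mixture weights are infeasible for the configured ",
         "marginal fractions and SSI rate", call. = FALSE)
  }
  pmf0_base <- poisbinom_pmf(base)
  p_multi <- sum(pmf0_base[-(1:2)])
  cond_multi <- pmf0_base[-(1:2)] / p_multi
  pmf0 <- c(q0, q1, (1 - q0 - q1) * cond_multi)
  list(p_symptom_ssi = p1, pmf0 = pmf0, pmf1 = pmf1,
       q = c(none = q0, isolated = q1, multiple = 1 - q0 - q1),
       p_multi_base = p_multi)
}

# Solve the latent triage-severity model so that, in expectation,
#   P(ssi | triage = low)  = calibration target (default 0.014),
#   P(ssi | triage = high) = calibration target (default 0.240),
#   P(triage >= moderate)  = p_suspected (default 0.150).
# The latent severity is
#   eta = s * (a * ssi + b * n_symptoms) + logistic noise,
# labelled low if eta < t1, high if eta >= t2, moderate in between. The
# configured shifts (a, b) fix only the *relative* weight of SSI status
# versus symptom burden; the overall informativeness s is solved jointly
# with t1 so that both the low-risk contamination and the marginal
# suspected-SSI fraction are matched, and t2 then follows from the
# high-risk rate alone. Expectations are exact sums over the discrete
# (ssi, symptom count) distribution.
calibrate_triage <- function(config, count_model = symptom_count_model(config)) {
  a <- config$triage_ssi_shift
  b <- config$triage_symptom_shift
  n <- 0:8
  p <- config$p_ssi48
  w0 <- (1 - p) * count_model$pmf0
  w1 <- p * count_model$pmf1
  if (p == 0) {
    # no SSI signal to calibrate against: place thresholds so the marginal
    # triage mix is realistic (85% low, ~4% high) at unit scale
    eta0 <- a * 0 + b * n
    t1 <- uniroot(function(t) sum(count_model$pmf0 * plogis(t - eta0)) -
                    (1 - config$p_suspected), c(-60, 60))$root
    t2 <- uniroot(function(t) sum(count_model$pmf0 * plogis(eta0 - t)) - 0.040,
                  c(-60, 60))$root
    return(list(t1 = t1, t2 = max(t2, t1 + 1e-6), scale = 1))
  }
  target <- config$triage_calibration
  if (target[["low"]] >= p || target[["high"]] <= p) {
    stop("triage calibration targets must straddle `p_ssi48`", call. = FALSE)
  }
  low_rate <- function(t1, s) {
    num <- sum(w1 * plogis(t1 - s * (a + b * n)))
    num / (num + sum(w0 * plogis(t1 - s * b * n)))
  }
  review_frac <- function(t1, s) {
    sum(w1 * plogis(s * (a + b * n) - t1)) + sum(w0 * plogis(s * b * n - t1))
  }
  high_rate <- function(t2, s) {
    num <- sum(w1 * plogis(s * (a + b * n) - t2))
    num / (num + sum(w0 * plogis(s * b * n - t2)))
  }
  t_lim <- function(s) 50 + s * (a + 8 * b)  # thresholds live within +/- this
  t1_for_scale <- function(s) {
    uniroot(function(t) low_rate(t, s) - target[["low"]],
            c(-t_lim(s), t_lim(s)), tol = 1e-10)$root
  }
  excess_review <- function(s) {
    # below the scale at which the low-risk contamination target becomes
    # reachable, matching it would require reviewing (almost) everything
    if (low_rate(-t_lim(s), s) >= target[["low"]]) {
      return(1 - config$p_suspected)
    }
    review_frac(t1_for_scale(s), s) - config$p_suspected
  }
  s <- uniroot(excess_review, c(0.02, 25), tol = 1e-9)$root
  t1 <- t1_for_scale(s)
  t2 <- uniroot(function(t) high_rate(t, s) - target[["high"]],
                c(-t_lim(s), t_lim(s)), tol = 1e-10)$root
  if (t2 <= t1) {
    stop("triage calibration produced crossed thresholds; the configured ",
         "conditional rates and suspected-SSI fraction are jointly ",
         "infeasible", call. = FALSE)
  }
  list(t1 = t1, t2 = t2, scale = s)
}

draw_symptom_matrix <- function(ssi, count_model, base) {
  n <- length(ssi)
  out <- matrix(0L, n, 8, dimnames = list(NULL, prom_items()))
  is1 <- which(ssi == 1L)
  if (length(is1)) {
    out[is1, ] <- matrix(
      rbinom(length(is1) * 8, 1, rep(count_model$p_symptom_ssi,
                                     each = length(is1))),
      ncol = 8)
  }
  is0 <- which(ssi == 0L)
  if (length(is0)) {
    bucket <- sample(c("none", "isolated", "multiple"), length(is0),
                     replace = TRUE, prob = count_model$q)
    iso <- is0[bucket == "isolated"]
    if (length(iso)) {
      item <- sample.int(8, length(iso), replace = TRUE, prob = base)
      out[cbind(iso, item)] <- 1L
    }
    multi <- is0[bucket == "multiple"]
    todo <- multi
    while (length(todo)) {
      draw <- matrix(rbinom(length(todo) * 8, 1,
                            rep(base, each = length(todo))), ncol = 8)
      ok <- rowSums(draw) >= 2
      if (any(ok)) out[todo[ok], ] <- draw[ok, , drop = FALSE]
      todo <- todo[!ok]
    }
  }
  out
}

#' Generate a synthetic remote wound-monitoring cohort
#'
#' Draws patients, their submitted responses (eight PROM symptom items with
#' optional trend sub-answers), clinician triage labels from a calibrated
#' latent-severity model, confirmed-SSI-within-48-h outcomes, and generative
#' truth parameters for 0-3 wound images per response. Image pixels are not
#' rendered here; see [render_wound_image()] and [cohort_image()].
#'
#' @param config a [synth_config()] object.
#' @return An object of class `ssi_cohort`: a list with `responses` (one row
#'   per response), `images` (one row per image, generative truth only) and
#'   the `config` echo.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_patients < 2) {
    stop("at least 2 patients are required (grouped splitting is impossible ",
         "otherwise)", call. = FALSE)
  }
  cm <- symptom_count_model(config)
  thr <- calibrate_triage(config, cm)
  with_seed(config$seed, {
    n_pat <- config$n_patients
    active <- runif(n_pat) >= config$nonusage_rate
    k <- integer(n_pat)
    lambda <- config$mean_responses_per_patient
    k[active] <- pmax(1L, rpois(sum(active), lambda))
    patient_id <- rep(sprintf("P%04d", seq_len(n_pat)), k)
    n <- sum(k)
    if (n == 0) stop("cohort has no responses; lower `nonusage_rate`",
                     call. = FALSE)
    postop_day <- unlist(lapply(k[k > 0], function(ki)
      sort(sample.int(30, ki, replace = TRUE))), use.names = FALSE)
    ssi48 <- rbinom(n, 1, config$p_ssi48)
    sym <- draw_symptom_matrix(ssi48, cm, config$symptom_base_rates)
    nsym <- rowSums(sym)

    # trend sub-answers for present symptoms
    trend_levels <- c("new", "worse", "same", "better")
    trend <- matrix(NA_character_, n, 8,
                    dimnames = list(NULL, paste0(prom_items(), "_trend")))
    pres <- which(sym == 1L)
    if (length(pres)) {
      is_ssi <- rep(ssi48, 8)[pres] == 1  # column-major linear index -> row
      trend[pres[is_ssi]] <- sample(trend_levels, sum(is_ssi), TRUE,
                                    prob = c(0.40, 0.30, 0.20, 0.10))
      trend[pres[!is_ssi]] <- sample(trend_levels, sum(!is_ssi), TRUE,
                                     prob = c(0.25, 0.20, 0.35, 0.20))
    }

    eta <- thr$scale * (config$triage_ssi_shift * ssi48 +
                          config$triage_symptom_shift * nsym) + rlogis(n)
    triage_label <- ifelse(eta < thr$t1, "low",
                    ifelse(eta < thr$t2, "moderate", "high"))

    n_images <- sample(0:3, n, replace = TRUE,
                       prob = config$images_per_response)
    skin_tone_pat <- runif(n_pat, config$skin_tone_range[1],
                           config$skin_tone_range[2])
    resp_tone <- rep(skin_tone_pat, k)

    img_resp <- rep(seq_len(n), n_images)
    m <- length(img_resp)
    images <- data.frame(
      image_id = sprintf("I%06d", seq_len(m)),
      response_id = sprintf("R%05d", img_resp),
      erythema_intensity = numeric(m),
      pus_count = integer(m),
      skin_tone = resp_tone[img_resp],
      render_seed = vapply(seq_len(m), function(i)
        derive_seed(config$seed, 1000000 + i), integer(1)),
      stringsAsFactors = FALSE
    )
    if (m > 0) {
      s <- ssi48[img_resp]
      sh <- config$erythema_shape
      images$erythema_intensity <- ifelse(
        s == 1,
        rbeta(m, sh$ssi[1], sh$ssi[2]),
        rbeta(m, sh$no_ssi[1], sh$no_ssi[2]))
      images$pus_count <- rbinom(m, 3, 0.04 + 0.40 * s)
    }
    image_ids <- vapply(seq_len(n), function(i)
      paste(images$image_id[img_resp == i], collapse = ";"), character(1))

    responses <- data.frame(
      response_id = sprintf("R%05d", seq_len(n)),
      patient_id = patient_id,
      postop_day = postop_day,
      sym, trend,
      n_images = n_images,
      image_ids = image_ids,
      triage_label = triage_label,
      ssi48 = ssi48,
      stringsAsFactors = FALSE
    )
    structure(list(responses = responses, images = images, config = config,
                   triage_thresholds = thr),
              class = "ssi_cohort")
  })
}

#' @export
print.ssi_cohort <- function(x, ...) {
  r <- x$responses
  cat(sprintf("Synthetic wound-monitoring cohort: %d responses from %d patients\n",
              nrow(r), length(unique(r$patient_id))))
  cat(sprintf("  confirmed SSI within 48 h: %d (%.1f%%); images: %d\n",
              sum(r$ssi48), 100 * mean(r$ssi48), nrow(x$images)))
  tab <- table(factor(r$triage_label, c("low", "moderate", "high")))
  cat(sprintf("  triage: low %d, moderate %d, high %d\n",
              tab[["low"]], tab[["moderate"]], tab[["high"]]))
  invisible(x)
}

#' Render one wound image from a cohort's image table
#'
#' Looks up the stored generative truth for `image_id` and renders it with
#' the image's own derived seed, so rendering is reproducible regardless of
#' the order images are requested in.
#'
#' @param cohort an `ssi_cohort`.
#' @param image_id one image id from `cohort$images`.
#' @return A `synthetic_wound_image` (see [render_wound_image()]).
#' @export
cohort_image <- function(cohort, image_id) {
  stopifnot(inherits(cohort, "ssi_cohort"))
  row <- cohort$images[cohort$images$image_id == image_id, ]
  if (nrow(row) != 1) stop("unknown image_id: ", image_id, call. = FALSE)
  with_seed(row$render_seed, render_wound_image(
    erythema_intensity = row$erythema_intensity,
    pus_count = row$pus_count,
    skin_tone = row$skin_tone,
    image_size = cohort$config$image_size))
}
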