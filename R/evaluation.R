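#' Grouped, stratified train/test split
#'
#' Splits responses into development and validation partitions in a
#' `1 - test_frac` : `test_frac` ratio (default 4:1), with all responses of
#' a patient kept in the same partition (no leakage) and allocation
#' stratified by patient-level outcome (whether the patient has any
#' confirmed-SSI response). Within each stratum, patients are shuffled and
#' assigned to the test partition so the stratum's test response count is
#' as close as possible to the target fraction.
#'
#' @param responses data frame with `response_id`, `patient_id` and the
#'   outcome column.
#' @param test_frac target test fraction by responses (default 0.2).
#' @param outcome name of the binary outcome column (default `"ssi48"`).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return Object of class `split_plan`: data frame `assignment`
#'   (`response_id`, `patient_id`, `partition`) plus summary fields.
#' @export
grouped_stratified_split <- function(responses, test_frac = 0.2,
                                     outcome = "ssi48", seed = 1) {
  stopifnot(all(c("response_id", "patient_id", outcome) %in%
                  names(responses)))
  pat <- split(seq_len(nrow(responses)), responses$patient_id)
  if (length(pat) < 2) {
    stop("cannot split a single patient into train and test", call. = FALSE)
  }
  pat_n <- vapply(pat, length, integer(1))
  pat_case <- vapply(pat, function(i) as.integer(any(responses[[outcome]][i] == 1)),
                     integer(1))
  test_patients <- character(0)
  with_seed(seed, {
    for (s in unique(pat_case)) {
      ids <- names(pat)[pat_case == s]
      ids <- ids[sample.int(length(ids))]
      sizes <- pat_n[ids]
      target <- test_frac * sum(sizes)
      cum <- c(0, cumsum(sizes))
      k <- which.min(abs(cum - target)) - 1L
      if (k > 0) test_patients <- c(test_patients, ids[seq_len(k)])
    }
  })
  partition <- ifelse(responses$patient_id %in% test_patients,
                      "test", "train")
  if (!any(partition == "test") || !any(partition == "train")) {
    stop("split produced an empty partition; adjust `test_frac` or supply ",
         "more patients", call. = FALSE)
  }
  assignment <- data.frame(response_id = responses$response_id,
                           patient_id = responses$patient_id,
                           partition = partition,
                           stringsAsFactors = FALSE)
  rate <- function(p) mean(responses[[outcome]][partition == p])
  structure(list(assignment = assignment,
                 test_frac = mean(partition == "test"),
                 event_rate = c(train = rate("train"), test = rate("test")),
                 seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("grouped stratified split: %.1f%% of responses in test; event rate train %.3f / test %.3f\n",
              100 * x$test_frac, x$event_rate[["train"]],
              x$event_rate[["test"]]))
  invisible(x)
}

#' Area under the ROC curve with a DeLong confidence interval
#'
#' The point estimate is the rank-statistic (concordance) definition: the
#' probability that a random case scores above a random control, ties
#' counted one half, computed from midranks. The confidence interval uses
#' the asymptotic placement-value (DeLong) variance.
#'
#' @param scores numeric predictions.
#' @param labels binary outcomes (0/1).
#' @param level confidence level.
#' @return List of class `auc_estimate`: `auc`, `ci`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels, level = 0.95) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) {
    stop("AUC is undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties (counted half)
  auc <- (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)

  x <- scores[labels == 1]; y <- scores[labels == 0]
  # placement values via ranks within the pooled sample
  rx <- rank(c(x, y))[seq_len(m)]
  ry <- rank(c(y, x))[seq_len(n)]
  v10 <- (rx - rank(x)) / n          # P(Y < X_i) with ties half
  v01 <- 1 - (ry - rank(y)) / m      # P(X > Y_j)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(c(auc - z * se, auc + z * se), 0), 1)
  structure(list(auc = auc, ci = ci, se = se, n_case = m, n_control = n),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), %d cases / %d controls [%s]\n",
              x$auc, x$ci[1], x$ci[2], x$n_case, x$n_control,
              discrimination_band(x$auc)))
  invisible(x)
}

#' Qualitative discrimination band for an AUC value
#'
#' Maps an AUC to the conventional labels: 0.5-0.59 poor, 0.6-0.69
#' moderate, 0.7-0.79 good, 0.8 and above excellent. Bands are
#' lower-inclusive and upper-exclusive (0.695 is "moderate", 0.70 is
#' "good"); values below 0.5 are labelled "below-chance".
#'
#' @param auc_value numeric vector of AUCs in \[0, 1\].
#' @return Character vector of band labels.
#' @export
discrimination_band <- function(auc_value) {
  stop_if_not_prob(auc_value, "auc_value")
  as.character(cut(auc_value,
                   breaks = c(-Inf, 0.5, 0.6, 0.7, 0.8, Inf),
                   labels = c("below-chance", "poor", "moderate", "good",
                              "excellent"),
                   right = FALSE))
}
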