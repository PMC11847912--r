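table3_counts <- list(
  full_clinical = list(tp = 39, fp = 158, fn = 18, tn = 1330),
  hybrid = list(tp = 31, fp = 84, fn = 26, tn = 1404),
  full_auto = list(tp = 40, fp = 232, fn = 17, tn = 1256))

counts_to_vectors <- function(cc) {
  list(decisions = c(rep("in_person_review", cc$tp + cc$fp),
                     rep("low_risk", cc$fn + cc$tn)),
       ssi48 = c(rep(1, cc$tp), rep(0, cc$fp), rep(1, cc$fn), rep(0, cc$tn)))
}

test_that("confusion tallies match printed routing-by-outcome counts", {
  v <- counts_to_vectors(table3_counts$full_clinical)
  cc <- confusion_counts(v$decisions, v$ssi48)
  expect_equal(cc$tp, 39); expect_equal(cc$fp, 158)
  expect_equal(cc$fn, 18); expect_equal(cc$tn, 1330)
  expect_error(confusion_counts(v$decisions, v$ssi48[-1]), "lengths differ")
  # random vector equals a brute-force four-way tally
  set.seed(77)
  dec <- sample(c("low_risk", "in_person_review"), 20, replace = TRUE)
  y <- rbinom(20, 1, 0.3)
  cc <- confusion_counts(dec, y)
  brute <- table(factor(dec, c("in_person_review", "low_risk")),
                 factor(y, c(1, 0)))
  expect_equal(cc$tp, brute["in_person_review", "1"])
  expect_equal(cc$fp, brute["in_person_review", "0"])
  expect_equal(cc$fn, brute["low_risk", "1"])
  expect_equal(cc$tn, brute["low_risk", "0"])
})

test_that("diagnostics reproduce the printed accuracy metrics", {
  d1 <- diagnostics(confusion_counts(
    counts_to_vectors(table3_counts$full_clinical)$decisions,
    counts_to_vectors(table3_counts$full_clinical)$ssi48))
  est <- function(d, m) d$metrics[[m]]$estimate
  expect_equal(round(est(d1, "sensitivity"), 3), 0.684)
  expect_equal(round(est(d1, "specificity"), 3), 0.894)
  expect_equal(round(est(d1, "ppv"), 3), 0.198)
  expect_equal(round(est(d1, "npv"), 3), 0.987)
  d2 <- diagnostics(confusion_counts(
    counts_to_vectors(table3_counts$hybrid)$decisions,
    counts_to_vectors(table3_counts$hybrid)$ssi48))
  expect_equal(round(est(d2, "sensitivity"), 3), 0.544)
  expect_equal(round(est(d2, "specificity"), 3), 0.944)
  expect_equal(round(est(d2, "ppv"), 3), 0.270)
  expect_equal(round(100 * est(d2, "failure_rate"), 1), 1.8)
  # perfect classifier
  dp <- diagnostics(structure(list(tp = 10, fp = 0, tn = 50, fn = 0),
                              class = "confusion_counts"))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(est(dp, m), 1)
  }
  expect_equal(est(dp, "failure_rate"), 0)
})

test_that("zero denominators are flagged undefined, not silently zero", {
  d <- diagnostics(structure(list(tp = 0, fp = 0, tn = 20, fn = 0),
                             class = "confusion_counts"))
  expect_true(is.na(d$metrics$ppv$estimate))
  expect_true(is.na(d$metrics$sensitivity$estimate))
  expect_setequal(d$undefined, c("sensitivity", "ppv"))
})

test_that("failure rate is identically 1 - NPV", {
  set.seed(12)
  for (i in 1:25) {
    cc <- structure(as.list(setNames(rpois(4, 20) + 1,
                                     c("tp", "fp", "tn", "fn"))),
                    class = "confusion_counts")
    d <- diagnostics(cc)
    expect_identical(d$metrics$failure_rate$estimate,
                     1 - d$metrics$npv$estimate)
  }
})

test_that("printed confidence intervals match the Wald formula", {
  d <- diagnostics(confusion_counts(
    counts_to_vectors(table3_counts$full_clinical)$decisions,
    counts_to_vectors(table3_counts$full_clinical)$ssi48),
    ci_method = "wald")
  expect_equal(round(d$metrics$sensitivity$ci, 3), c(0.564, 0.805))
  expect_equal(round(100 * d$metrics$failure_rate$ci, 1), c(0.7, 1.9))
})

test_that("routing follows each strategy's rules", {
  resp <- data.frame(response_id = c("a", "b", "c", "d"),
                     triage_label = c("low", "moderate", "high", "low"),
                     ssi48 = c(0L, 0L, 1L, 1L))
  p <- setNames(c(0.10, 0.05, 0.90, 0.30), resp$response_id)
  full <- route(resp, NULL, triage_strategy("full_clinical"))
  expect_equal(full$decision, c("low_risk", "in_person_review",
                                "in_person_review", "low_risk"))
  expect_true(all(full$clinician_reviewed))

  hy <- route(resp, p, triage_strategy("hybrid", 0.2))
  # a and b ruled out automatically; c and d survive to the clinician,
  # whose triage label then decides (d is labelled low despite p = 0.3)
  expect_equal(hy$decision, c("low_risk", "low_risk", "in_person_review",
                              "low_risk"))
  expect_equal(hy$clinician_reviewed, c(FALSE, FALSE, TRUE, TRUE))

  # boundary thresholds
  hy1 <- route(resp, p, triage_strategy("hybrid", 1.0))
  expect_true(all(!hy1$clinician_reviewed))
  expect_true(all(hy1$decision == "low_risk"))
  fa0 <- route(resp, p, triage_strategy("full_auto", 0.0))
  expect_true(all(fa0$decision[p > 0] == "in_person_review"))
  expect_true(all(!fa0$clinician_reviewed))

  expect_error(route(resp, p[-1], triage_strategy("hybrid", 0.2)),
               "missing prediction")
  resp$triage_label[3] <- NA
  expect_error(route(resp, p, triage_strategy("hybrid", 0.2)),
               "triage label")
  expect_error(triage_strategy("hybrid"), "requires a probability threshold")
})

test_that("workload arithmetic matches the staffing model", {
  sm <- staffing_model()
  expect_equal(sm$annual_fte_hours, sm$weekly_fte_hours * 52)
  full <- staffing(1545, sm, 1545)
  expect_equal(round(full$staff_hours, 1), 51.5)
  expect_equal(round(full$fte_per_caseload, 3), 0.176)
  hy <- staffing(272, sm, 1545)
  expect_equal(round(hy$staff_hours, 1), 9.1)
  expect_equal(round(hy$reduction_pct, 1), -82.4)
  expect_equal(round(hy$fte_per_caseload, 3), 0.031)
  auto <- staffing(0, sm, 1545)
  expect_equal(auto$staff_hours, 0)
  expect_equal(auto$reduction_pct, -100)
  expect_error(staffing(10, sm, 0), "baseline review count is zero")
})

test_that("pathway outcomes conserve counts and workload invariants", {
  co <- small_cohort()
  r <- co$responses
  set.seed(5)
  p <- setNames(clamp <- pmin(pmax(
    r$ssi48 * 0.5 + runif(nrow(r), 0, 0.5), 0), 1), r$response_id)
  sm <- staffing_model()
  for (strat in list(triage_strategy("full_clinical"),
                     triage_strategy("hybrid", 0.2),
                     triage_strategy("full_auto", 0.2))) {
    po <- pathway_outcome(r, p, strat, sm, nrow(r))
    cc <- po$counts
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, nrow(r))
    expect_equal(po$staff_hours,
                 po$n_clinician_reviewed * sm$minutes_per_clinical_review / 60)
    expect_identical(po$diagnostics$metrics$failure_rate$estimate,
                     1 - po$diagnostics$metrics$npv$estimate)
  }
  expect_equal(pathway_outcome(r, p, triage_strategy("full_auto", 0.2),
                               sm, nrow(r))$n_clinician_reviewed, 0)
})

test_that("threshold sweep is monotone and hits the routing boundaries", {
  co <- small_cohort()
  r <- co$responses
  set.seed(6)
  p <- setNames(pmin(pmax(r$ssi48 * 0.6 + runif(nrow(r), 0, 0.4), 0), 1),
                r$response_id)
  grid <- seq(0, 1, 0.1)
  sw_h <- threshold_sweep(r, p, "hybrid", grid)
  expect_true(all(diff(sw_h$n_clinician_reviewed) <= 0))
  sw_a <- threshold_sweep(r, p, "full_auto", grid)
  expect_true(all(diff(sw_a$sensitivity) <= 1e-12))
  expect_true(all(sw_a$staff_hours == 0))
  # endpoints match direct routing
  r0 <- route(r, p, triage_strategy("hybrid", 0))
  expect_equal(sw_h$n_clinician_reviewed[1], sum(r0$clinician_reviewed))
  expect_equal(sw_h$n_clinician_reviewed[length(grid)], 0)
  expect_error(threshold_sweep(r, p, "hybrid", numeric(0)), "empty")
  expect_error(threshold_sweep(r, p, "hybrid", c(0.3, 0.1)), "sorted")
})

test_that("perfect model and perfect clinician give zero hybrid failures", {
  co <- small_cohort()
  r <- co$responses
  p <- setNames(as.numeric(r$ssi48), r$response_id)
  # clinicians downgrade some true-SSI survivors to low risk, so a perfect
  # model alone cannot zero the failure rate; with faultless triage labels
  # the hybrid pathway must make no failures at any interior threshold
  r$triage_label <- ifelse(r$ssi48 == 1, "high", "low")
  for (thr in c(0.1, 0.5, 0.9)) {
    po <- pathway_outcome(r, p, triage_strategy("hybrid", thr))
    expect_equal(po$diagnostics$metrics$failure_rate$estimate, 0)
    expect_equal(po$counts$fn, 0)
  }
  # and under full automation the perfect model is error-free outright
  po <- pathway_outcome(co$responses, p, triage_strategy("full_auto", 0.5))
  expect_equal(po$counts$fn + po$counts$fp, 0)
})
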