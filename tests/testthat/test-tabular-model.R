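test_that("missing symptom answers are imputed as absent before encoding", {
  df <- toy_responses(3)
  df$pain <- c(1L, NA, 0L)
  df$fever <- c(NA, NA, 0L)
  ft <- encode_proms(df)
  # row 2 (all missing/absent) equals the canonical all-absent row 3
  expect_equal(ft$raw[2, ], ft$raw[3, ])
  expect_equal(unname(ft$raw[, "pain"]), c(1, 0, 0))
  # after standardisation the all-absent row is -centre/scale
  expect_equal(ft$values[3, ], -ft$encoder$centre / ft$encoder$scale)
})

test_that("one-hot encoding of a toy table matches the hand-built matrix", {
  df <- toy_responses(3, set = list(pain = c(1L, 0L, 1L),
                                    fever = c(0L, 0L, 1L),
                                    erythema = c(0L, 1L, 0L)))
  ft <- encode_proms(df)
  hand <- matrix(0, 3, 8, dimnames = list(NULL, prom_items()))
  hand[, "pain"] <- c(1, 0, 1)
  hand[, "fever"] <- c(0, 0, 1)
  hand[, "erythema"] <- c(0, 1, 0)
  expect_equal(ft$raw, hand)
  # training transform standardises each non-constant column
  keep <- apply(ft$raw, 2, sd) > 0
  expect_equal(unname(colMeans(ft$values)), rep(0, 8), tolerance = 1e-9)
  expect_equal(unname(apply(ft$values[, keep], 2, sd)),
               rep(1, sum(keep)), tolerance = 1e-9)
})

test_that("a fitted encoder is reused verbatim on unseen data", {
  co <- small_cohort()
  r <- co$responses
  ft <- encode_proms(r[1:300, ])
  new <- encode_proms(r[301:400, ], ft$encoder)
  expect_identical(new$encoder, ft$encoder)
  # transforming training data with its own encoder is a no-op
  again <- encode_proms(r[1:300, ], ft$encoder)
  expect_identical(again$values, ft$values)
  expect_error(encode_proms(transform(r[1:5, ], pain = 2L)), "pain")
  expect_error(encode_proms(r[, -4]), "missing symptom columns")
})

test_that("logistic comparator reproduces the contingency-table odds ratio", {
  # 20 exposed cases, 80 exposed controls, 5 unexposed cases, 95 unexposed
  df <- toy_responses(200, set = list(
    pain = c(rep(1L, 100), rep(0L, 100))))
  y <- c(rep(1L, 20), rep(0L, 80), rep(1L, 5), rep(0L, 95))
  ft <- encode_proms(df)
  m <- fit_tabular(ft, y, kind = "logistic")
  p <- predict(m, df[c(1, 101), ])
  odds <- p / (1 - p)
  expect_equal(odds[1] / odds[2], (20 * 95) / (80 * 5), tolerance = 1e-6)
})

test_that("logistic fit matches an independent IRLS oracle", {
  co <- small_cohort()
  r <- co$responses[1:400, ]
  ft <- encode_proms(r)
  keep <- apply(ft$raw, 2, sd) > 0
  # well-conditioned outcome drawn from a moderate logistic law
  set.seed(9)
  y <- rbinom(nrow(r), 1, plogis(-1 + ft$raw %*% rep(0.5, 8)))
  m <- fit_tabular(ft, y, kind = "logistic")
  ours <- coef(m$fit)[c("(Intercept)", colnames(ft$values)[keep])]
  oracle <- irls_logistic(ft$values[, keep], y)
  expect_equal(unname(ours), oracle, tolerance = 1e-6)
})

test_that("logistic coefficient estimates recover known generative log-odds", {
  set.seed(404)
  n <- 2500
  X <- matrix(rbinom(n * 3, 1, 0.3), n, 3)
  beta <- c(-3, 1.5, 0.8, 0)
  y <- rbinom(n, 1, plogis(beta[1] + X %*% beta[-1]))
  fit <- glm(y ~ X, family = binomial())
  se <- summary(fit)$coefficients[, 2]
  expect_true(all(abs(coef(fit) - beta) < 3 * se))
})

test_that("MLP training is seed-deterministic and learns separable data", {
  df <- toy_responses(120, set = list(pain = rep(c(1L, 0L), 60)))
  y <- df$pain
  ft <- encode_proms(df)
  m1 <- fit_tabular(ft, y, kind = "mlp", seed = 7, epochs = 60)
  m2 <- fit_tabular(ft, y, kind = "mlp", seed = 7, epochs = 60)
  expect_identical(predict(m1, df), predict(m2, df))
  expect_gt(mean((predict(m1, df) > 0.5) == y), 0.99)
  # training loss trace reaches its recorded minimum at the best epoch
  tm <- m1$fit$training_meta
  expect_equal(min(tm$loss_trace), tm$best_loss)
  expect_error(fit_tabular(ft, rep(0, 120), kind = "mlp"), "single class")
})

test_that("predictions are probabilities, monotone in a positive effect", {
  co <- small_cohort()
  r <- co$responses
  ft <- encode_proms(r)
  m <- fit_tabular(ft, r$ssi48, kind = "logistic")
  p <- predict(m, r)
  expect_true(all(p >= 0 & p <= 1))
  # adding a positive-weight symptom never decreases logistic risk
  stopifnot(coef(m$fit)[["discharge"]] > 0)
  base <- toy_responses(1)
  with_sym <- transform(base, discharge = 1L)
  expect_gt(predict(m, with_sym), predict(m, base))
  # discrimination present when symptom effects are nonzero
  expect_gt(roc_auc(p, r$ssi48)$auc, 0.5)
})
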