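test_that("missing-image and multiple-image fusion rules hold", {
  avg <- fit_fusion_head(kind = "average")
  f <- fuse(0.30, numeric(0), avg)
  expect_equal(f$p_fused, 0.30)
  expect_equal(f$provenance, "proms_only")
  expect_equal(fuse(0.2, 0.2, avg)$p_fused, 0.2)
  # mean-then-max: max(mean(0.1, 0.2), mean(0.1, 0.8)) = 0.45
  f <- fuse(0.1, c(0.2, 0.8), avg)
  expect_equal(f$p_fused, 0.45)
  expect_equal(f$provenance, "fused")
  # permuting the image list never changes the fused risk
  expect_equal(fuse(0.1, c(0.8, 0.2), avg)$p_fused, f$p_fused)
  expect_error(fuse(1.3, c(0.2), avg), "\\[0, 1\\]")
  expect_error(fuse(0.3, c(-0.1), avg), "\\[0, 1\\]")
})

test_that("fusion heads are monotone in each unimodal input", {
  set.seed(52)
  n <- 600
  latent <- rbinom(n, 1, 0.3)
  p1 <- clamp <- pmin(pmax(latent * 0.5 + runif(n, 0, 0.5), 0), 1)
  p2 <- pmin(pmax(latent * 0.4 + runif(n, 0, 0.5), 0), 1)
  y <- rbinom(n, 1, plogis(-2 + 3 * latent))
  stack <- fit_fusion_head(p1, p2, y, kind = "logistic_stack")
  grid <- seq(0, 1, 0.1)
  for (head in list(fit_fusion_head(kind = "average"), stack)) {
    f_along_p1 <- vapply(grid, function(g) fuse(g, 0.4, head)$p_fused,
                         numeric(1))
    f_along_p2 <- vapply(grid, function(g) fuse(0.4, g, head)$p_fused,
                         numeric(1))
    expect_true(all(diff(f_along_p1) >= -1e-12))
    expect_true(all(diff(f_along_p2) >= -1e-12))
  }
})

test_that("responses without images keep the tabular prediction exactly", {
  co <- small_cohort()
  r <- co$responses
  ft <- encode_proms(r)
  m <- fit_tabular(ft, r$ssi48, kind = "logistic")
  p_proms <- setNames(predict(m, r), r$response_id)
  img_pred <- data.frame(image_id = co$images$image_id,
                         response_id = co$images$response_id,
                         p_image = runif(nrow(co$images)))
  head_fit <- fit_fusion_head(p_proms[img_pred$response_id],
                              img_pred$p_image,
                              r$ssi48[match(img_pred$response_id,
                                            r$response_id)],
                              kind = "logistic_stack")
  fused <- fuse_predictions(p_proms, img_pred, head_fit)
  no_img <- fused$provenance == "proms_only"
  expect_equal(sum(no_img), sum(r$n_images == 0))
  expect_identical(fused$p_fused[no_img],
                   unname(p_proms[fused$response_id[no_img]]))
  expect_true(all(is.na(fused$p_image_max[no_img])))
  expect_true(all(fused$p_fused >= 0 & fused$p_fused <= 1))
})

test_that("a stacked head keeps useful signal and discards pure noise", {
  set.seed(97)
  n <- 1200
  z <- rbinom(n, 1, 0.25)
  y <- rbinom(n, 1, plogis(-2.5 + 3.5 * z))
  p1 <- plogis(-1 + 2 * z + rnorm(n, 0, 0.8))
  p2 <- plogis(-1 + 2 * z + rnorm(n, 0, 0.8))  # independent second signal
  tr <- seq_len(n) <= 800
  stack <- fit_fusion_head(p1[tr], p2[tr], y[tr], kind = "logistic_stack")
  fused <- ssitriage:::fusion_score(stack, p1[!tr], p2[!tr])
  auc_f <- roc_auc(fused, y[!tr])$auc
  expect_gte(auc_f, roc_auc(p1[!tr], y[!tr])$auc - 0.02)
  expect_gte(auc_f, roc_auc(p2[!tr], y[!tr])$auc - 0.02)
  # pure-noise image stream gets a near-zero stacking weight
  p_noise <- runif(n)
  stack0 <- fit_fusion_head(p1, p_noise, y, kind = "logistic_stack")
  co <- summary(stack0$fit)$coefficients["p_image", ]
  expect_lt(abs(co[["Estimate"]]), 3 * co[["Std. Error"]])
  expect_error(fit_fusion_head(p1, p2, rep(0, n)), "both classes")
})

test_that("the shallow-net head behaves like a probability model", {
  set.seed(15)
  n <- 400
  z <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 2 * z))
  p1 <- plogis(z + rnorm(n, 0, 1))
  p2 <- plogis(z + rnorm(n, 0, 1))
  sn <- fit_fusion_head(p1, p2, y, kind = "shallow_net", seed = 3)
  out <- ssitriage:::fusion_score(sn, p1, p2)
  expect_true(all(out >= 0 & out <= 1))
  sn2 <- fit_fusion_head(p1, p2, y, kind = "shallow_net", seed = 3)
  expect_identical(out, ssitriage:::fusion_score(sn2, p1, p2))
})

test_that("cross-fitted PROMs predictions respect patient grouping", {
  co <- small_cohort()
  r <- co$responses[1:400, ]
  set.seed(41)
  y <- rbinom(nrow(r), 1, plogis(-2.5 + as.matrix(r[, prom_items()]) %*%
                                   rep(1.2, 8)))
  oof <- crossfit_proms(r, y, folds = 4, seed = 2)
  expect_named(oof, r$response_id)
  expect_true(all(oof >= 0 & oof <= 1))
  # out-of-fold predictions still rank the outcome
  expect_gt(roc_auc(oof, y)$auc, 0.7)
  # deterministic given the seed
  expect_identical(oof, crossfit_proms(r, y, folds = 4, seed = 2))
})
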