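write_test_png <- function(size, dir = tempdir(), gray = FALSE) {
  f <- tempfile(tmpdir = dir, fileext = ".png")
  if (gray) {
    png::writePNG(matrix(runif(size^2), size, size), f)
  } else {
    png::writePNG(array(runif(size^2 * 3), c(size, size, 3)), f)
  }
  f
}

test_that("preprocessing standardises images to 256 x 256 x 3", {
  set.seed(61)
  f512 <- write_test_png(512)
  f256 <- write_test_png(256)
  batch <- preprocess_images(c(f512, f256))
  expect_equal(dim(batch), c(2L, 256L, 256L, 3L))
  # already-at-size image passes through unchanged
  expect_equal(batch$images[[2]], png::readPNG(f256), tolerance = 1e-7)
  # batch of many files keeps the stated shape
  files <- replicate(10, write_test_png(64))
  expect_equal(dim(preprocess_images(files))[1], 10L)
  expect_warning(preprocess_images(write_test_png(256, gray = TRUE)),
                 "grayscale")
  bad <- tempfile(fileext = ".png")
  writeLines("not a png", bad)
  expect_error(preprocess_images(bad), basename(bad))
})

test_that("augmentation is rigid, label-preserving, and flagged", {
  set.seed(62)
  imgs <- replicate(4, array(runif(64 * 64 * 3), c(64, 64, 3)),
                    simplify = FALSE)
  batch <- image_batch(imgs, labels = c(0, 1, 1, 0))
  # identity transform parameters give back the input
  id <- augment(batch, seed = 1, max_rotation = 0, max_translation = 0,
                scale_range = c(1, 1), flip = FALSE)
  expect_equal(id$images, batch$images, tolerance = 1e-12)
  # a double flip is an involution
  x <- imgs[[1]]
  expect_identical(x[, 64:1, , drop = FALSE][, 64:1, , drop = FALSE], x)
  aug <- augment(batch, seed = 2)
  expect_true(aug$augmented)
  expect_identical(aug$labels, batch$labels)
  expect_equal(dim(aug), dim(batch))
  # translation-only augmentation preserves interior intensity
  tr <- augment(batch, seed = 3, max_rotation = 0, max_translation = 0.05,
                scale_range = c(1, 1), flip = FALSE)
  core <- 17:48
  for (i in 1:4) {
    expect_lt(abs(mean(tr$images[[i]][core, core, ]) -
                    mean(batch$images[[i]][core, core, ])), 0.05)
  }
})

test_that("training refuses degenerate input and evaluation refuses augmented data", {
  set.seed(63)
  imgs <- replicate(6, array(runif(64 * 64 * 3), c(64, 64, 3)),
                    simplify = FALSE)
  batch <- image_batch(imgs, labels = rep(1, 6))
  expect_error(fit_cnn(batch), "single class")
  batch$labels <- c(0, 1, 0, 1, 0, 1)
  m <- fit_cnn(batch, epochs = 1, eval_every = 1, stem_pool = 2,
               filters = c(4, 8), pool = c(TRUE, TRUE), seed = 1)
  expect_error(predict(m, augment(batch, seed = 1)), "augmented")
  p <- predict(m, batch)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(m, batch))  # evaluation is deterministic
  expect_true(length(m$training_meta$loss_trace) >= 1)
})

test_that("training is seed-reproducible and the loss trace improves", {
  set.seed(64)
  # images whose channel balance encodes the label
  make <- function(lab) {
    x <- array(runif(64 * 64 * 3, 0.2, 0.4), c(64, 64, 3))
    x[, , 1] <- x[, , 1] + lab * 0.3
    x
  }
  labs <- rep(c(0, 1), 10)
  batch <- image_batch(lapply(labs, make), labels = labs)
  m1 <- fit_cnn(batch, epochs = 10, eval_every = 2, stem_pool = 2,
                filters = c(4, 8), pool = c(TRUE, TRUE), seed = 5)
  m2 <- fit_cnn(batch, epochs = 10, eval_every = 2, stem_pool = 2,
                filters = c(4, 8), pool = c(TRUE, TRUE), seed = 5)
  expect_identical(predict(m1, batch), predict(m2, batch))
  tr <- m1$training_meta$loss_trace
  expect_equal(min(tr), m1$training_meta$best_loss)
  expect_lt(m1$training_meta$best_loss, tr[1])  # training reduced the loss
  expect_gt(roc_auc(predict(m1, batch), labs)$auc, 0.9)
})

test_that("activation heatmaps keep their normalisation contract", {
  set.seed(65)
  labs <- rep(c(0, 1), 8)
  imgs <- lapply(labs, function(l) {
    x <- array(runif(64 * 64 * 3, 0.2, 0.5), c(64, 64, 3))
    if (l == 1) x[20:40, 20:40, 1] <- 0.95
    x
  })
  batch <- image_batch(imgs, labels = labs)
  m <- fit_cnn(batch, epochs = 5, stem_pool = 2, filters = c(4, 8),
               pool = c(TRUE, FALSE), seed = 2)
  h <- cam(m, imgs[[2]])
  expect_equal(dim(h$weights), c(64, 64))
  expect_true(all(h$weights >= 0 & h$weights <= 1))
  expect_equal(max(h$weights), 1)
  # constant-colour image: no spatial signal, so away from the padding
  # border the heatmap is uniform
  hc <- cam(m, array(0.5, c(64, 64, 3)))
  expect_lt(sd(hc$weights[17:48, 17:48]), 1e-6)
  # a model without convolutional layers is refused
  fake <- structure(list(net = list(conv = list()), input_size = 64),
                    class = "cnn_model")
  expect_error(cam(fake, imgs[[1]]), "convolutional")
  expect_error(cam(lm(speed ~ dist, cars), imgs[[1]]), "convolutional")
})

test_that("heatmap mass concentrates where the model finds its evidence", {
  set.seed(66)
  labs <- rep(c(0, 1), 12)
  mask <- matrix(FALSE, 64, 64)
  mask[24:44, 24:44] <- TRUE
  imgs <- lapply(labs, function(l) {
    x <- array(runif(64 * 64 * 3, 0.2, 0.5), c(64, 64, 3))
    if (l == 1) x[, , 1][mask] <- x[, , 1][mask] + 0.45
    x
  })
  batch <- image_batch(imgs, labels = labs)
  m <- fit_cnn(batch, epochs = 8, stem_pool = 2, filters = c(4, 8),
               pool = c(TRUE, FALSE), seed = 3)
  h <- cam(m, imgs[[2]])
  mass <- heatmap_mass_inside(h, mask, dilate = 4)
  expect_gt(mass, mean(mask))  # better than a uniform heatmap would do
})
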