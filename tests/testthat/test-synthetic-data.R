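test_that("config validation rejects inconsistent parameters", {
  expect_error(synth_config(10, p_no_symptoms = 0.8, p_isolated_symptom = 0.3),
               "must not exceed 1")
  expect_error(synth_config(10, image_size = 32), "64 px")
  expect_error(synth_config(10, triage_calibration = c(low = 0.3, high = 0.2)),
               "low-risk rate < high-risk rate")
  expect_error(generate_cohort(synth_config(1)), "at least 2 patients")
  expect_error(generate_cohort(synth_config(
    100, p_ssi48 = 0.037, triage_calibration = c(low = 0.05, high = 0.24))),
    "straddle")
})

test_that("same config and seed give byte-identical serialized cohorts", {
  co1 <- generate_cohort(synth_config(n_patients = 60, seed = 42))
  co2 <- generate_cohort(synth_config(n_patients = 60, seed = 42))
  expect_identical(co1$responses, co2$responses)
  expect_identical(co1$images, co2$images)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1)
  write_cohort(co2, d2)
  for (f in c("responses.csv", "images.csv", "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(
    co1$responses,
    generate_cohort(synth_config(n_patients = 60, seed = 43))$responses))
})

test_that("event rate matches the configured binomial law", {
  co <- generate_cohort(synth_config(n_patients = 400, seed = 1))
  n <- nrow(co$responses)
  p <- 0.037
  expect_lt(abs(mean(co$responses$ssi48) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("zero SSI rate degenerates safely", {
  co <- generate_cohort(synth_config(n_patients = 80, seed = 2, p_ssi48 = 0))
  expect_true(all(co$responses$ssi48 == 0))
  high <- co$responses$triage_label == "high"
  expect_true(sum(co$responses$ssi48[high]) == 0)  # no high-risk SSI, no NaN
})

test_that("symptom-free and isolated-symptom fractions recover targets", {
  co <- generate_cohort(synth_config(n_patients = 1000, seed = 7))
  nsym <- rowSums(co$responses[, prom_items()])
  expect_lt(abs(mean(nsym == 0) - 0.719), 0.03)
  n <- nrow(co$responses)
  expect_lt(abs(mean(nsym == 1) - 0.168),
            3 * sqrt(0.168 * (1 - 0.168) / n))
})

test_that("response invariants hold across a generated cohort", {
  co <- small_cohort()
  r <- co$responses
  expect_true(all(r$postop_day >= 1 & r$postop_day <= 30))
  sym <- as.matrix(r[, prom_items()])
  trend <- as.matrix(r[, paste0(prom_items(), "_trend")])
  expect_true(all(sym %in% c(0L, 1L)))
  # trend defined exactly where the symptom is present
  expect_true(all(is.na(trend[sym == 0L])))
  expect_true(all(!is.na(trend[sym == 1L])))
  expect_true(all(trend[sym == 1L] %in% c("new", "worse", "same", "better")))
  expect_true(all(r$triage_label %in% c("low", "moderate", "high")))
  # image bookkeeping consistent
  expect_equal(sum(r$n_images), nrow(co$images))
  expect_true(all(co$images$response_id %in% r$response_id))
})

test_that("erythema couples monotonically to SSI status", {
  co <- generate_cohort(synth_config(n_patients = 400, seed = 9))
  ssi_of_img <- co$responses$ssi48[match(co$images$response_id,
                                         co$responses$response_id)]
  expect_gt(mean(co$images$erythema_intensity[ssi_of_img == 1]),
            mean(co$images$erythema_intensity[ssi_of_img == 0]))
})

test_that("rendered images carry the configured visual signal", {
  red_excess <- function(img, inside) {
    m <- if (inside) img$wound_mask else !img$wound_mask
    mean(img$pixels[, , 1][m]) -
      mean(((img$pixels[, , 2] + img$pixels[, , 3]) / 2)[m])
  }
  img0 <- render_wound_image(0, 0, 0.4, 128, seed = 11)
  expect_lt(abs(red_excess(img0, TRUE) - red_excess(img0, FALSE)), 0.03)
  img1 <- render_wound_image(1, 0, 0.4, 128, seed = 11)
  expect_gt(red_excess(img1, TRUE), red_excess(img1, FALSE))
  # determinism given the seed, sensitivity to it
  expect_identical(img1$pixels,
                   render_wound_image(1, 0, 0.4, 128, seed = 11)$pixels)
  expect_false(identical(img1$pixels,
                         render_wound_image(1, 0, 0.4, 128, seed = 12)$pixels))
  expect_error(render_wound_image(0.5, 0, 0.4, image_size = 32), "64 px")
  # mask coverage and pixel range contracts over varied parameters
  for (s in 1:5) {
    im <- render_wound_image(runif(1), sample(0:3, 1), runif(1), 96, seed = s)
    expect_gte(mean(im$wound_mask), 0.01)
    expect_lte(mean(im$wound_mask), 0.40)
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  }
})

test_that("cohorts round-trip through disk", {
  co <- generate_cohort(synth_config(n_patients = 30, seed = 5))
  d <- tempfile()
  write_cohort(co, d)
  expect_error(write_cohort(co, d), "already exist")
  back <- read_cohort(d)
  expect_identical(back$responses, co$responses)
  expect_identical(back$images, co$images)
  expect_equal(unclass(back$config), unclass(co$config), tolerance = 1e-12)
  # rendering round-trips through the stored per-image seed
  id <- co$images$image_id[1]
  expect_identical(cohort_image(back, id)$pixels, cohort_image(co, id)$pixels)
})

test_that("written PNG count matches the image table", {
  cfg <- synth_config(n_patients = 4, seed = 8, image_size = 64,
                      nonusage_rate = 0)
  co <- generate_cohort(cfg)
  d <- tempfile()
  write_cohort(co, d, render_images = TRUE)
  pngs <- list.files(file.path(d, "images"), pattern = "\\.png$")
  expect_equal(length(pngs), nrow(co$images))
})

test_that("a cohort configured without images yields an image-free table", {
  co <- generate_cohort(synth_config(
    n_patients = 10, seed = 6,
    images_per_response = c(`0` = 1, `1` = 0, `2` = 0, `3` = 0)))
  expect_equal(nrow(co$images), 0)
  d <- tempfile()
  write_cohort(co, d, render_images = TRUE)
  expect_identical(nrow(read.csv(file.path(d, "images.csv"))), 0L)
  expect_true(all(co$responses$image_ids == ""))
})
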