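test_that("disc median filter matches the naive oracle and ImageJ behaviours", {
  expect_equal(median_filter(matrix(3, 10, 10), 2), matrix(3, 10, 10))
  spike <- matrix(0, 11, 11); spike[6, 6] <- 10
  expect_equal(median_filter(spike, 2), matrix(0, 11, 11))
  withr::with_seed(42, img <- matrix(runif(32 * 32), 32, 32))
  expect_equal(median_filter(img, 2), brute_median_disc(img, 2), tolerance = 1e-12)
  expect_error(median_filter(img, 0), ">= 1")
})

test_that("despeckle is a 3x3 square median", {
  expect_equal(despeckle(matrix(1.5, 8, 8)), matrix(1.5, 8, 8))
  spike <- matrix(0, 9, 9); spike[5, 5] <- 7
  expect_equal(despeckle(spike), matrix(0, 9, 9))
  withr::with_seed(13, img <- matrix(runif(20 * 20), 20, 20))
  ds <- despeckle(img)
  # oracle: explicit 3x3 median with reflected edges
  refl <- function(v, n) pmin(pmax(ifelse(v < 1, 1 - v, ifelse(v > n, 2 * n - v + 1, v)), 1), n)
  for (pt in list(c(1, 1), c(10, 7), c(20, 20), c(3, 20))) {
    rs <- refl(pt[1] + (-1:1), 20); cs <- refl(pt[2] + (-1:1), 20)
    expect_equal(ds[pt[1], pt[2]], median(img[rs, cs][1:9]))
  }
})

test_that("otsu binarization matches an exhaustive search and obeys strict >", {
  img <- matrix(c(rep(10, 40), rep(200, 60)), 10, 10)
  bm <- binarize(img, "otsu")
  expect_equal(mean(bm$pixels), 0.60)
  withr::with_seed(3, bimodal <- matrix(c(rnorm(300, 0.2, 0.03), rnorm(200, 0.8, 0.05)), 25, 20))
  t_pkg <- otsu_threshold(bimodal)
  t_oracle <- brute_otsu(bimodal)
  expect_equal(mean(bimodal > t_pkg), mean(bimodal > t_oracle), tolerance = 0.01)
  expect_equal(sum(binarize(img, "manual", value = max(img))$pixels), 0)
  expect_equal(mean(binarize(img, "manual", value = -1)$pixels), 1)
  expect_error(binarize(img, "manual"), "value")
})

test_that("manual binarization is monotone in the threshold", {
  withr::with_seed(11, img <- matrix(runif(400), 20, 20))
  thrs <- c(0.2, 0.4, 0.6, 0.8)
  masks <- lapply(thrs, function(t) binarize(img, "manual", value = t)$pixels)
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("recipes run in order, record provenance, and reject empty ones", {
  withr::with_seed(2, img <- matrix(runif(2500), 50, 50))
  img[20:30, 10:40] <- img[20:30, 10:40] + 1
  recipe <- list(list(step = "median_filter", radius = 2), list(step = "despeckle"),
                 list(step = "threshold", method = "otsu"))
  bm <- run_recipe(img, recipe, pixel_size = 1)
  expect_s3_class(bm, "binary_mask")
  expect_equal(length(bm$recipe), 3)
  expect_equal(bm$recipe[[3]]$step, "threshold")
  expect_error(run_recipe(img, list()), "recipe")
  expect_error(run_recipe(img, list(list(step = "median_filter", radius = 2))),
               "binarizing")
  full <- run_recipe(img, list(list(step = "threshold", method = "manual", value = -1)))
  expect_true(all(full$pixels))
})

test_that("default recipe recovers rendered vessel area on a synthetic channel", {
  sim <- fixture_sim()
  bm <- run_recipe(sim$image$channels$pecam,
                   list(list(step = "median_filter", radius = 2),
                        list(step = "despeckle"),
                        list(step = "threshold", method = "otsu")))
  truth_area <- sum(sim$masks$pecam)
  expect_lt(abs(sum(bm$pixels) - truth_area) / truth_area, 0.10)
  # plain Otsu on the noise-free render recovers the ground-truth mask well
  bm2 <- binarize(sim$image$channels$pecam, "otsu")
  jacc <- sum(bm2$pixels & sim$masks$pecam) / sum(bm2$pixels | sim$masks$pecam)
  expect_gte(jacc, 0.98)
})

test_that("pixel classifier separates ribbon foreground and is deterministic", {
  sim <- fixture_sim()
  img <- sim$image$channels$coliv[151:350, 151:350]
  truth <- sim$masks$coliv[151:350, 151:350]
  labels <- matrix(NA_real_, nrow(img), ncol(img))
  withr::with_seed(4, pick <- sample(length(img), 4000))
  labels[pick] <- as.numeric(truth[pick])
  model <- train_pixel_classifier(img, labels, rng_seed = 99)
  pred <- classify_pixels(img, model)
  acc <- mean(pred$pixels == truth)
  expect_gte(acc, 0.99)
  pred2 <- classify_pixels(img, train_pixel_classifier(img, labels, rng_seed = 99))
  expect_identical(pred$pixels, pred2$pixels)
  expect_error(train_pixel_classifier(img, matrix(1, nrow(img), ncol(img))),
               "both classes")
  expect_error(train_pixel_classifier(img, labels[1:10, 1:10]), "mismatch")
})
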