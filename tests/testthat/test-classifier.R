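test_that("well-separated classes give the hard-margin midpoint boundary", {
  d <- tibble::tibble(slope = c(-5, 0, 3, 60, 80, 100),
                      type = rep(c("LP", "ORBvl"), each = 3))
  fit <- fit_ih_classifier(d, slope, type, C = 1e6)
  expect_equal(fit$boundary, 31.5, tolerance = 1e-6) # midpoint of 3 and 60
  expect_equal(fit$margin, 28.5, tolerance = 1e-4)
  expect_identical(fit$upper_class, "ORBvl")
})

test_that("the scan solver matches brute-force hinge minimization on small sets", {
  set.seed(42)
  for (rep in 1:6) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    x <- c(rnorm(n1, 0, 2), rnorm(n2, 4, 2))
    lab <- rep(c("a", "b"), c(n1, n2))
    C <- sample(c(0.3, 1, 3), 1)
    d <- tibble::tibble(slope = x, type = lab)
    fit <- fit_ih_classifier(d, slope, type, C = C)
    y <- ifelse(lab == fit$upper_class, 1, -1)
    u <- 0.5 / ifelse(lab == "a", n1, n2)
    bf <- brute_force_svm(x, y, u, C)
    # Equal objectives within the brute grid's resolution.
    expect_lte(fit$objective, bf$objective + 1e-6)
    expect_lt(abs(fit$objective - bf$objective), 0.02 * max(bf$objective, 0.05))
  }
})

test_that("degenerate inputs are flagged or rejected", {
  d <- tibble::tibble(slope = rep(1, 6), type = rep(c("a", "b"), 3))
  fit <- fit_ih_classifier(d, slope, type)
  expect_true(fit$degenerate)
  expect_error(fit_ih_classifier(
    tibble::tibble(slope = 1:4, type = "a"), slope, type), "two classes")
  expect_error(fit_ih_classifier(
    tibble::tibble(slope = 1:3, type = c("a", "a", "b")), slope, type),
    "at least two")
})

test_that("mirroring the data negates the boundary", {
  d <- tibble::tibble(slope = c(-5, 0, 3, 60, 80, 100),
                      type = rep(c("LP", "ORBvl"), each = 3))
  f1 <- fit_ih_classifier(d, slope, type, C = 1e6)
  d2 <- dplyr::mutate(d, slope = -slope)
  f2 <- fit_ih_classifier(d2, slope, type, C = 1e6)
  expect_equal(f2$boundary, -f1$boundary, tolerance = 1e-6)
  expect_identical(f2$upper_class, f1$lower_class)
})

test_that("prediction thresholds deterministically with ties to the upper class", {
  d <- tibble::tibble(slope = c(-5, 0, 3, 60, 80, 100),
                      type = rep(c("LP", "ORBvl"), each = 3))
  fit <- fit_ih_classifier(d, slope, type, C = 1e6)
  expect_identical(predict(fit, c(1000, -1000)), c("ORBvl", "LP"))
  expect_identical(predict(fit, fit$boundary), "ORBvl")
  xs <- c(10, 90, -20, 31.5, 50)
  expect_identical(predict(fit, xs), predict(fit, rev(xs))[c(5:1)])
})

test_that("cross-validation is perfect on separated data and reproducible", {
  set.seed(5)
  d <- tibble::tibble(slope = c(rnorm(40, 0, 1), rnorm(40, 50, 1)),
                      type = rep(c("a", "b"), each = 40))
  cv <- cross_validate_ih(d, slope, type, k = 10, repeats = 3, seed = 4)
  expect_equal(cv$mean_accuracy, 1)
  cv2 <- cross_validate_ih(d, slope, type, k = 10, repeats = 3, seed = 4)
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("random labels cross-validate at chance", {
  set.seed(8)
  d <- tibble::tibble(slope = rnorm(200),
                      type = sample(rep(c("a", "b"), each = 100)))
  cv <- cross_validate_ih(d, slope, type, k = 10, repeats = 5, seed = 9)
  expect_lt(abs(cv$mean_accuracy - 0.5), 0.05)
})

test_that("the shuffled null is centered on chance for balanced data", {
  set.seed(10)
  d <- tibble::tibble(slope = c(rnorm(50), rnorm(50, 3)),
                      type = rep(c("a", "b"), each = 50))
  nul <- shuffled_null_ih(d, slope, type, n_shuffles = 60, seed = 11)
  expect_lt(abs(mean(nul$null_accuracies) - 0.5), 0.03)
  expect_gte(nul$interval_95[1], 0)
  expect_lte(nul$interval_95[2], 1)
  # Separation worth detecting: true-label CV beats the null's upper bound.
  cv <- cross_validate_ih(d, slope, type, k = 10, repeats = 3, seed = 12)
  expect_gt(cv$mean_accuracy, nul$interval_95[2])
})

test_that("label swap leaves complementary accuracy at 1 - a", {
  pred <- c("a", "b", "a", "a", "b")
  truth <- c("a", "a", "b", "a", "b")
  a <- prediction_accuracy(pred, truth)
  flip <- function(z) ifelse(z == "a", "b", "a")
  expect_equal(prediction_accuracy(flip(pred), truth), 1 - a)
  expect_equal(prediction_accuracy(c("x", "x"), c("x", "y")), 0.5)
  expect_equal(prediction_accuracy(truth, truth), 1)
  expect_error(prediction_accuracy("a", c("a", "b")), "equal length")
})

test_that("tidy and glance expose the fit and CV summaries", {
  d <- tibble::tibble(slope = c(-5, 0, 3, 60, 80, 100),
                      type = rep(c("LP", "ORBvl"), each = 3))
  fit <- fit_ih_classifier(d, slope, type)
  expect_identical(tidy(fit)$term, c("boundary", "margin", "w"))
  expect_identical(glance(fit)$n_upper, 3L)
  cv <- cross_validate_ih(d, slope, type, k = 3, repeats = 2, seed = 1)
  expect_identical(nrow(tidy(cv)), 2L)
  expect_true(glance(cv)$mean_accuracy >= 0 && glance(cv)$mean_accuracy <= 1)
})
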