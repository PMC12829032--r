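test_that("Yeo-Johnson branches evaluate in closed form", {
  expect_equal(yeo_johnson(5, 1), 5)
  expect_equal(yeo_johnson(exp(1) - 1, 0), 1)
  expect_equal(yeo_johnson(-1, 2), -log(2))
  expect_equal(yeo_johnson(0, 0.37), 0)
  # lambda = 1 is the identity on nonnegative values only
  expect_equal(yeo_johnson(c(0, 2, 7.5), 1), c(0, 2, 7.5))
  expect_equal(yeo_johnson(-3, 1), -((4 - 1) / 1) * 1)  # -(((3+1)^1)-1)/1
})

test_that("Yeo-Johnson matches the reference implementation", {
  skip_if_not_installed("car")
  set.seed(5)
  y <- c(rnorm(20), -2.5, 0, 4.2)
  for (l in c(-2, -0.5, 0.5, 1, 1.5, 3)) {
    expect_equal(yeo_johnson(y, l), unname(car::yjPower(y, l)),
                 tolerance = 1e-12)
  }
})

test_that("Yeo-Johnson is continuous at the log-branch limits", {
  y <- c(-4.2, -1, -0.3, 0, 0.8, 3.7)
  expect_equal(yeo_johnson(y, 1e-8), yeo_johnson(y, 0), tolerance = 1e-6)
  expect_equal(yeo_johnson(y, -1e-8), yeo_johnson(y, 0), tolerance = 1e-6)
  expect_equal(yeo_johnson(y, 2 - 1e-8), yeo_johnson(y, 2),
               tolerance = 1e-6)
  expect_equal(yeo_johnson(y, 2 + 1e-8), yeo_johnson(y, 2),
               tolerance = 1e-6)
})

test_that("Yeo-Johnson is strictly increasing for any lambda", {
  y <- sort(c(seq(-5, 5, by = 0.25), -1e-6, 1e-6))
  for (l in c(-2, -1, 0, 0.5, 1, 2, 3)) {
    expect_true(all(diff(yeo_johnson(y, l)) > 0))
  }
})

test_that("lambda fitting recovers known transformation regimes", {
  set.seed(42)
  gauss <- rnorm(500)
  expect_lt(abs(fit_lambda(gauss) - 1), 0.3)
  lognorm <- exp(rnorm(500)) - 1
  expect_lt(abs(fit_lambda(lognorm) - 0), 0.3)
  const <- fit_lambda(rep(3, 10))
  expect_equal(as.numeric(const), 1)
  expect_identical(attr(const, "flag"), "constant_input")
  expect_error(fit_lambda(c(1, 2, 3)), "at least 5")
})

test_that("fitted lambda agrees with an independent ML estimate", {
  skip_if_not_installed("car")
  set.seed(9)
  y <- exp(rnorm(200, 0, 0.7))
  ours <- as.numeric(fit_lambda(y))
  theirs <- car::powerTransform(y, family = "yjPower")$lambda
  expect_equal(ours, unname(theirs), tolerance = 1e-3)
})

test_that("robust regression nails exact lines and resists outliers", {
  x <- seq(0, 5, length.out = 20)
  # a zero-residual line has MAD scale 0, so IRLS cannot formally converge
  exact <- suppressWarnings(robust_regress(x, 2 * x + 1))
  expect_equal(exact$slope, 2, tolerance = 1e-8)
  expect_equal(exact$intercept, 1, tolerance = 1e-8)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_error(robust_regress(rep(1, 10), rnorm(10)), "degenerate")
  set.seed(33)
  y <- 2 * x + 1 + rnorm(20, 0, 0.05)
  y[c(3, 9, 14, 19)] <- y[c(3, 9, 14, 19)] + 40   # 20% gross outliers
  rob <- suppressWarnings(robust_regress(x, y))
  ols <- lm(y ~ x)
  expect_lt(abs(rob$slope - 2) / 2, 0.05)
  expect_lt(abs(rob$slope - 2), abs(unname(coef(ols)[2]) - 2))
})

test_that("robust and OLS slopes agree on clean Gaussian data", {
  set.seed(14)
  x <- rnorm(100)
  y <- 1.5 * x + rnorm(100, 0, 0.5)
  rob <- robust_regress(x, y)
  fit <- lm(y ~ x)
  se <- summary(fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(rob$slope - unname(coef(fit)[2])), 2 * se)
})

test_that("independent variables yield a near-zero r-squared", {
  set.seed(77)
  x <- rnorm(200); y <- rnorm(200)
  expect_lt(robust_regress(x, y)$r2, 0.05)
})

test_that("the association wrapper transforms, fits, and reports", {
  set.seed(55)
  n <- 80L
  meth <- rbeta(n, 2, 5)
  expr <- (0.25 + 4.75 * meth) * exp(rnorm(n, 0, 0.3))
  scores <- data.frame(sample_id = sprintf("s%02d", 1:n), mean_meth = meth)
  ex <- data.frame(sample_id = sprintf("s%02d", 1:n), relative = expr,
                   excluded = FALSE)
  ex$excluded[1:3] <- TRUE
  res <- associate(scores, ex)
  expect_identical(res$n_used, n - 3L)
  expect_gt(res$fit$slope, 0)
  expect_gt(res$fit$r2, 0.3)
  expect_true(is.finite(res$lambda_x) && is.finite(res$lambda_y))
})
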