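make_ds <- function(X, y) {
  n <- length(y)
  icp_dataset(X, y, env = data.frame(e = rep(0:1, length.out = n)))
}

test_that("intercept-only fit recovers the closed-form MLE", {
  y <- c(rep(1, 3), rep(0, 9))
  d <- make_ds(data.frame(x = rnorm(12)), y)
  fit <- fit_logistic(d, character(0))
  expect_equal(unname(fit$coefficients), qlogis(mean(y)), tolerance = 1e-8)
  expect_true(all(abs(fit$fitted - mean(y)) < 1e-8))
  expect_equal(fit$regularization_used, "none")
})

test_that("saturated binary predictor recovers the log odds ratio", {
  # x = 0: 10 events / 100; x = 1: 30 events / 100
  x <- rep(c(0, 1), each = 100)
  y <- c(rep(1, 10), rep(0, 90), rep(1, 30), rep(0, 70))
  fit <- fit_logistic(make_ds(data.frame(x = x), y), "x")
  expect_equal(unname(fit$coefficients["x"]),
               log((30 / 70) / (10 / 90)), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               log(10 / 90), tolerance = 1e-6)
})

test_that("separation triggers the tiny-ridge stabilization", {
  x <- seq(-1, 1, length.out = 20)
  y <- as.integer(x >= 0)
  fit <- fit_logistic(make_ds(data.frame(x = x), y), "x")
  expect_false(fit$converged)
  expect_equal(fit$regularization_used, "tiny-ridge")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
})

test_that("degenerate and deficient designs are handled explicitly", {
  d_one_class <- suppressWarnings(
    icp_dataset(data.frame(x = rnorm(8)), rep(1, 8),
                env = data.frame(e = rep(0:1, 4))))
  expect_error(fit_logistic(d_one_class, "x"),
               class = "icpbin_degenerate_outcome")
  x <- rnorm(40)
  d_dup <- make_ds(data.frame(x1 = x, x2 = x), rep(0:1, 20))
  expect_warning(fit <- fit_logistic(d_dup, c("x1", "x2")),
                 "rank-deficient")
  expect_true(all(is.finite(fit$coefficients)))
  expect_error(fit_logistic(make_ds(data.frame(x = rnorm(10)), rep(0:1, 5)),
                            "nope"),
               class = "icpbin_argument_error")
})

test_that("residual definitions behave as documented", {
  y <- c(rep(1, 3), rep(0, 9))  # mean 0.25
  d <- make_ds(data.frame(x = rnorm(12)), y)
  fit <- fit_logistic(d, character(0))
  r <- residuals(fit)
  expect_setequal(round(unique(r), 10), c(-0.25, 0.75))
  # y equal to the fitted probabilities: all residuals vanish
  expect_true(all(residuals(fit, y = fit$fitted) == 0))
  # score equation: response residuals sum to zero for any MLE with intercept
  set.seed(42)
  for (rep in 1:5) {
    n <- 80
    X <- data.frame(a = rnorm(n), b = rnorm(n))
    eta <- 0.5 * X$a - 0.3 * X$b
    ds <- make_ds(X, rbinom(n, 1, plogis(eta)))
    f <- fit_logistic(ds, c("a", "b"))
    expect_lt(abs(sum(residuals(f))), 1e-8)
  }
  # pearson and deviance variants exist and differ from response
  f <- fit_logistic(d, "x")
  expect_false(isTRUE(all.equal(residuals(f, "pearson"), residuals(f))))
  expect_false(isTRUE(all.equal(residuals(f, "deviance"), residuals(f))))
  expect_error(residuals(f, y = c(0, 1)), class = "icpbin_argument_error")
})
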