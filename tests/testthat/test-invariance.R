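test_that("identical residual samples are invariant at every level", {
  r <- rep(c(1, -1, 1, -1), 2)
  env <- rep(0:1, each = 4)
  for (a in c(0.1, 0.05, 0.01)) {
    res <- invariance_test(r, env, alpha = a)
    expect_equal(res$t_statistic, 0)
    expect_equal(res$p_value, 1)
    expect_true(res$accepted)
  }
})

test_that("a clear mean shift is rejected, matching the hand-worked value", {
  res <- invariance_test(c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3),
                         rep(0:1, each = 3), alpha = 0.01)
  expect_equal(res$t_statistic, -1 / sqrt(2 * 0.01 / 3), tolerance = 1e-6)
  expect_equal(res$t_statistic, -12.247449, tolerance = 1e-5)
  expect_lt(res$p_value, 0.001)
  expect_false(res$accepted)
})

test_that("the test agrees with independent Welch implementations", {
  set.seed(99)
  max_dt <- 0; max_dp <- 0
  for (i in 1:1000) {
    n0 <- sample(3:30, 1); n1 <- sample(3:30, 1)
    r0 <- rnorm(n0, sd = runif(1, 0.2, 3))
    r1 <- rnorm(n1, mean = runif(1, -1, 1), sd = runif(1, 0.2, 3))
    res <- invariance_test(c(r0, r1), rep(0:1, c(n0, n1)))
    ora <- welch_oracle(r0, r1)
    max_dt <- max(max_dt, abs(res$t_statistic - ora$t))
    max_dp <- max(max_dp, abs(res$p_value - ora$p))
    if (i <= 50) {  # cross-check against stats::t.test as well
      tt <- t.test(r0, r1)
      expect_equal(res$t_statistic, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
    }
  }
  expect_lt(max_dt, 1e-10)
  expect_lt(max_dp, 1e-10)
})

test_that("label symmetry and alpha monotonicity hold", {
  set.seed(7)
  r <- rnorm(40)
  env <- rep(0:1, 20)
  a <- invariance_test(r, env)
  b <- invariance_test(r, 1L - env)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$dof, b$dof)
  # acceptance at a larger alpha implies acceptance at any smaller one
  for (i in 1:50) {
    r <- rnorm(30, mean = rep(c(0, runif(1, 0, 0.8)), c(15, 15)))
    env <- rep(0:1, each = 15)
    acc <- vapply(c(0.1, 0.05, 0.01),
                  function(a) invariance_test(r, env, a)$accepted, TRUE)
    expect_true(all(acc == cummax(acc)))
  }
})

test_that("untestable environments raise instead of being dropped", {
  expect_error(invariance_test(rnorm(5), c(0, 0, 0, 0, 1)),
               class = "icpbin_untestable_environment")
  expect_error(invariance_test(rnorm(5), c(0, 1, 1, 1, 1)),
               class = "icpbin_untestable_environment")
  expect_error(invariance_test(rnorm(5), c(0, 1, 1, 1)),
               class = "icpbin_argument_error")
})

test_that("test_subset composes fit, residuals and test", {
  d <- simulate_scm(scm_preset("strong"), n_per_env = 400, seed = 21)
  res <- test_subset(d, c("X1", "X2"), "env", alpha = 0.05)
  expect_s3_class(res, "subset_test")
  expect_equal(res$subset, c("X1", "X2"))
  expect_equal(sum(res$n_per_env), 800L)
  # identical decision from the standalone pieces
  fit <- fit_logistic(d, c("X1", "X2"))
  ref <- invariance_test(residuals(fit), d$env$env, 0.05)
  expect_equal(res$p_value, ref$p_value)
  expect_error(test_subset(d, "X1", "nope"), class = "icpbin_argument_error")
})

test_that("subsets missing a shifted ancestor path are rejected, supersets kept", {
  spec <- one_parent_spec(w = 1, shift = 1)
  rej_nonparent <- 0; acc_full <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    d <- simulate_scm(spec, n_per_env = 2000, seed = 800 + r)
    if (!test_subset(d, "X2", "env", alpha = 0.1)$accepted) {
      rej_nonparent <- rej_nonparent + 1
    }
    if (test_subset(d, c("X1", "X2", "X3"), "env", alpha = 0.05)$accepted) {
      acc_full <- acc_full + 1
    }
  }
  expect_gt(rej_nonparent / n_rep, 0.5)   # power against the non-parent
  expect_gte(acc_full / n_rep, 0.9)       # supersets of the parent stay invariant
})

test_that("reverse acceptance flag flips the decision rule", {
  r <- c(rnorm(20), rnorm(20, 2))
  env <- rep(0:1, each = 20)
  std <- invariance_test(r, env, alpha = 0.05)
  rev <- invariance_test(r, env, alpha = 0.05, reverse_acceptance = TRUE)
  expect_false(std$accepted)
  expect_true(rev$accepted)
})
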