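test_that("default schema carries the published cohort description", {
  sch <- default_schema()
  expect_s3_class(sch, "study_schema")
  expect_equal(nrow(sch$predictor_specs), 18L)
  expect_equal(nrow(sch$environment_specs), 6L)
  expect_equal(sch$n_default, 2744L)
  expect_equal(sch$outcome_rate, 0.021)
  shame <- sch$predictor_specs[sch$predictor_specs$name == "des_shame", ]
  expect_equal(shame$mean, 6.4)
  expect_equal(shame$sd, 3.4)
  expect_equal(c(shame$min, shame$max), c(3, 15))
  nssi <- sch$environment_specs[sch$environment_specs$name == "prior_nssi", ]
  expect_equal(nssi$prevalence, 312 / 2744)
})

test_that("schema construction rejects invalid targets", {
  sch <- default_schema()
  expect_error(study_schema(sch$predictor_specs, sch$environment_specs,
                            outcome_rate = 0),
               class = "icpbin_argument_error")
  bad <- sch$predictor_specs
  bad$sd[1] <- 0
  expect_error(study_schema(bad, sch$environment_specs),
               class = "icpbin_argument_error")
  bad <- sch$predictor_specs
  bad$min[2] <- bad$max[2]
  expect_error(study_schema(bad, sch$environment_specs),
               class = "icpbin_argument_error")
})

test_that("study emulator matches its schema and is reproducible", {
  sch <- default_schema()
  d <- generate_study_like(sch, n = 2744, seed = 3)
  expect_s3_class(d, "icp_dataset")
  expect_equal(dim(d), c(2744L, 18L))
  expect_equal(ncol(d$env), 6L)
  expect_identical(d, generate_study_like(sch, n = 2744, seed = 3))
  d2 <- generate_study_like(sch, n = 2744, seed = 4)
  expect_false(identical(d$X, d2$X))
  expect_error(generate_study_like(sch, n = 0), class = "icpbin_argument_error")

  big <- generate_study_like(sch, n = 20000, seed = 5)
  ps <- sch$predictor_specs
  expect_true(all(abs(colMeans(big$X) - ps$mean) < 0.05 * ps$sd))
  expect_true(all(vapply(names(big$X), function(nm) {
    mn <- ps$min[ps$name == nm]; mx <- ps$max[ps$name == nm]
    all(big$X[[nm]] >= mn & big$X[[nm]] <= mx)
  }, TRUE)))
  prev <- colMeans(big$env)
  expect_true(all(abs(prev - sch$environment_specs$prevalence) < 0.01))
})

test_that("SCM simulation honours the generating model", {
  # no parents: the outcome is a fair coin regardless of interventions
  A <- matrix(0, 2, 2)
  spec <- scm_spec(A, c(0, 0), interventions = list(
    "1" = list(list(var = "X1", type = "shift", magnitude = 3))))
  d <- simulate_scm(spec, n_per_env = 5000, seed = 10)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(d$y) - 0.5), 3 * se)

  # zero-weight parent, intercept at qlogis(0.021): closed-form rate 2.1%
  spec2 <- scm_spec(matrix(0, 1, 1), 0, outcome_intercept = qlogis(0.021))
  d2 <- simulate_scm(spec2, n_per_env = 50000, seed = 11)
  se2 <- sqrt(0.021 * 0.979 / 1e5)
  expect_lt(abs(mean(d2$y) - 0.021), 3 * se2)

  # determinism: same spec, same seed, bit-identical
  expect_identical(simulate_scm(spec, 100, seed = 7),
                   simulate_scm(spec, 100, seed = 7))
})

test_that("SCM structural contracts are enforced", {
  A <- matrix(0, 2, 2)
  A[1, 2] <- 1; A[2, 1] <- 1
  expect_error(scm_spec(A, c(1, 0)), class = "icpbin_structural_error")
  expect_error(
    scm_spec(matrix(0, 2, 2), c(1, 0), interventions = list(
      "1" = list(list(var = "y", type = "shift", magnitude = 1)))),
    class = "icpbin_contract_violation")
  expect_error(
    scm_spec(matrix(0, 2, 2), c(1, 0), interventions = list(
      "1" = list(list(var = "X9", type = "shift", magnitude = 1)))),
    class = "icpbin_contract_violation")
  expect_error(scm_spec(matrix(0, 2, 2), c(1, 0), noise_scales = c(1, -1)),
               class = "icpbin_structural_error")
})

test_that("invariance holds by construction on the true parent set", {
  # Null calibration: with interventions on variables unrelated to the
  # outcome's parents, the residual test's p-values on S* are uniform.
  # (When interventions shift the parents themselves, parameter estimation
  # makes the test conservative — see the methods vignette.)
  spec <- scm_preset("strong")
  spec$interventions <- list("1" = list(
    list(var = "X5", type = "shift", magnitude = 1),
    list(var = "X6", type = "shift", magnitude = 1)))
  pvals <- vapply(1:250, function(r) {
    d <- simulate_scm(spec, n_per_env = 300, seed = 5000 + r)
    test_subset(d, c("X1", "X2"), "env", alpha = 0.05)$p_value
  }, 1)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the type-I error at 5% stays within binomial noise
  rej <- mean(pvals < 0.05)
  expect_lte(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / 250))
})

test_that("specs, schemas and datasets round-trip through disk", {
  tmp <- withr::local_tempdir()
  spec <- scm_preset("strong")
  f <- file.path(tmp, "spec.yaml")
  write_scm_spec(spec, f)
  spec2 <- read_scm_spec(f)
  expect_equal(spec2$adjacency, spec$adjacency)
  expect_equal(spec2$outcome_weights, spec$outcome_weights)
  expect_equal(simulate_scm(spec, 50, seed = 1),
               simulate_scm(spec2, 50, seed = 1), tolerance = 1e-12)

  sch <- default_schema()
  g <- file.path(tmp, "schema.yaml")
  write_study_schema(sch, g)
  sch2 <- read_study_schema(g)
  expect_equal(sch2$predictor_specs$mu0, sch$predictor_specs$mu0)
  expect_equal(generate_study_like(sch, 200, seed = 2),
               generate_study_like(sch2, 200, seed = 2), tolerance = 1e-9)

  d <- simulate_scm(spec, 40, seed = 3)
  csv <- file.path(tmp, "data.csv")
  write_dataset(d, csv)
  expect_true(file.exists(paste0(csv, ".json")))
  d2 <- read_dataset(csv)
  expect_equal(d2$y, d$y)
  expect_equal(as.matrix(d2$X), as.matrix(d$X), tolerance = 1e-12)
  expect_equal(d2$env, d$env)
})

test_that("dataset container enforces its invariants", {
  X <- data.frame(a = rnorm(6))
  expect_error(icp_dataset(X, y = c(0, 1, 2, 0, 1, 0),
                           env = data.frame(e = rep(0:1, 3))),
               class = "icpbin_data_error")
  expect_error(icp_dataset(X, y = rep(0:1, 3), env = data.frame(e = rep(0, 6))),
               class = "icpbin_invalid_environment")
  expect_error(icp_dataset(X, y = rep(0:1, 2), env = data.frame(e = rep(0:1, 2))),
               class = "icpbin_data_error")
})
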