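test_that("subset enumeration is complete, ordered and capped", {
  s3 <- enumerate_subsets(c("c", "a", "b"))
  expect_length(s3, 8L)
  expect_identical(s3[[1]], character(0))
  expect_identical(s3[[8]], c("a", "b", "c"))
  sizes <- lengths(s3)
  expect_true(all(diff(sizes) >= 0))  # size-then-lex order
  expect_identical(s3[2:4], list("a", "b", "c"))

  expect_length(enumerate_subsets(paste0("p", 1:18)), 2^18)
  expect_length(enumerate_subsets(paste0("p", 1:5), max_size = 2), 16L)
  expect_error(enumerate_subsets(character(0)), class = "icpbin_argument_error")
  expect_error(enumerate_subsets(c("a", "a")), class = "icpbin_argument_error")
})

test_that("intersection of accepted sets distinguishes its three statuses", {
  r <- intersect_accepted(list(c("A", "B"), c("B", "C")))
  expect_equal(r$estimated_set, "B")
  expect_equal(r$status, "ok")

  r <- intersect_accepted(list())
  expect_equal(r$estimated_set, character(0))
  expect_equal(r$status, "model_rejected")

  r <- intersect_accepted(list(character(0), "A"))
  expect_equal(r$estimated_set, character(0))
  expect_equal(r$status, "empty_by_intersection")
})

test_that("lasso screen keeps planted signals and honours k_max", {
  spec <- scm_preset("planted")
  d <- simulate_scm(spec, n_per_env = 2500, seed = 31)
  keep <- lasso_screen(d, k_max = 8, seed = 31)
  expect_true(all(c("X1", "X2") %in% keep))
  expect_lte(length(keep), 8L)
  expect_identical(keep, lasso_screen(d, k_max = 8, seed = 31))
  expect_length(lasso_screen(d, k_max = 1, seed = 31), 1L)
  expect_error(lasso_screen(d, k_max = 0), class = "icpbin_argument_error")
})

test_that("icp recovers the parents of the strong ground truth", {
  for (s in 1:5) {
    d <- simulate_scm(scm_preset("strong"), n_per_env = 2000, seed = 100 + s)
    fit <- icp(d, env = "env", alpha = 0.05)
    expect_true(all(fit$estimated_set %in% c("X1", "X2")))
    expect_true(all(vapply(fit$accepted_sets,
                           function(a) all(fit$estimated_set %in% a), TRUE)))
    expect_equal(fit$n_subsets_tested, 64L)
  }
})

test_that("an environment unrelated to the system yields the empty estimate", {
  spec <- scm_preset("strong")
  spec$interventions <- list()  # both environments observational
  d <- simulate_scm(spec, n_per_env = 1000, seed = 77)
  fit <- icp(d, env = "env", alpha = 0.01)
  expect_true(fit$any_accepted)
  expect_equal(fit$estimated_set, character(0))
  expect_equal(fit$status, "empty_by_intersection")
  expect_gt(length(fit$accepted_sets) / fit$n_subsets_tested, 0.9)
})

test_that("estimates are monotone in alpha on every dataset", {
  # A smaller alpha accepts a superset of subsets, so its intersection is
  # contained in the larger-alpha estimate whenever the larger alpha does
  # not reject the model outright (the model-rejected state returns the
  # empty set by convention and is exempt from the containment).
  for (s in 1:25) {
    d <- simulate_scm(scm_preset("weak"), n_per_env = 500, seed = 200 + s)
    ptab <- icpbin:::subset_pvalue_table(
      d, enumerate_subsets(names(d$X)), "env")
    fits <- lapply(c(0.1, 0.05, 0.01), function(a) {
      icpbin:::icp_from_table(ptab, "env", a, "full", names(d$X), 64L)
    })
    for (k in 1:2) {
      if (fits[[k]]$status != "model_rejected") {
        expect_true(all(fits[[k + 1]]$estimated_set %in%
                          fits[[k]]$estimated_set))
      }
    }
    # accepted-set monotonicity itself is unconditional
    keys <- lapply(fits, function(f) vapply(f$accepted_sets,
                                            icpbin:::subset_key, ""))
    expect_true(all(keys[[1]] %in% keys[[2]]))
    expect_true(all(keys[[2]] %in% keys[[3]]))
  }
  # on a well-separated family the unconditional containment chain holds
  for (s in 1:10) {
    d <- simulate_scm(scm_preset("strong"), n_per_env = 1000, seed = 240 + s)
    ptab <- icpbin:::subset_pvalue_table(
      d, enumerate_subsets(names(d$X)), "env")
    ests <- lapply(c(0.1, 0.05, 0.01), function(a) {
      icpbin:::icp_from_table(ptab, "env", a, "full", names(d$X), 64L)$estimated_set
    })
    expect_true(all(ests[[3]] %in% ests[[2]]))
    expect_true(all(ests[[2]] %in% ests[[1]]))
  }
})

test_that("lasso and full methods agree when the screen keeps the parents", {
  agree <- 0; valid <- 0
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    d <- simulate_scm(scm_preset("strong"), n_per_env = 800, seed = 300 + s)
    full <- icp(d, env = "env", alpha = 0.05, method = "full")
    las <- icp(d, env = "env", alpha = 0.05, method = "lasso", seed = 300 + s)
    if (all(c("X1", "X2") %in% las$screened_predictors)) {
      valid <- valid + 1
      restricted <- intersect(full$estimated_set, las$screened_predictors)
      if (setequal(restricted, las$estimated_set)) agree <- agree + 1
    }
    expect_equal(las$n_subsets_tested, 2^length(las$screened_predictors))
  }
  expect_gt(valid, 0)
  expect_gte(agree / valid, 0.9)
})

test_that("icp works from a plain data.frame and honours max_size", {
  d <- simulate_scm(scm_preset("strong"), n_per_env = 400, seed = 55)
  df <- cbind(d$X, y = d$y, env_env = d$env$env)
  fit <- icp(df, env = "env", alpha = 0.05, max_size = 2)
  expect_s3_class(fit, "icp")
  expect_equal(fit$n_subsets_tested, 1 + 6 + 15)
  expect_true(all(lengths(fit$accepted_sets) <= 2))
})
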