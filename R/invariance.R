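# The residual-invariance test: if a subset contains all direct causes of
# the outcome, the conditional law of the outcome given the subset is the
# same in every environment, so the model's residuals have equal means
# across environment levels. A Welch two-sample t-test provides the check.

# Welch statistic, degrees of freedom and two-sided p for group 0 vs 1.
# Identical degenerate samples are invariant by definition (t = 0, p = 1);
# zero-variance samples with different means are maximally non-invariant.
welch_t <- function(r0, r1) {
  n0 <- length(r0)
  n1 <- length(r1)
  m0 <- mean(r0)
  m1 <- mean(r1)
  v0 <- stats::var(r0)
  v1 <- stats::var(r1)
  se2 <- v0 / n0 + v1 / n1
  if (se2 == 0) {
    if (m0 == m1) {
      return(list(t = 0, dof = n0 + n1 - 2, p = 1))
    }
    return(list(t = sign(m0 - m1) * Inf, dof = n0 + n1 - 2, p = 0))
  }
  t <- (m0 - m1) / sqrt(se2)
  dof <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  list(t = t, dof = dof, p = 2 * stats::pt(-abs(t), dof))
}

#' Two-sample invariance test of residual means across environments
#'
#' Splits the residuals by the two environment levels and applies a Welch
#' (unequal-variance) two-sided t-test of equal means. Under the invariance
#' null — the subset contains every direct cause and the environment acts
#' only on other variables — the residual means coincide, so a small
#' p-value is evidence against the subset. The subset is accepted when
#' `p >= alpha` (invariance not rejected); `reverse_acceptance = TRUE`
#' flips the direction for sensitivity analysis.
#'
#' @param residuals numeric residual vector.
#' @param env_labels 0/1 vector of the same length; both levels need at
#'   least two observations.
#' @param alpha significance level.
#' @param reverse_acceptance accept when `p < alpha` instead (non-standard;
#'   see the methods vignette).
#' @return A list with `t_statistic`, `dof`, `p_value`, `accepted`,
#'   `alpha` and `n_per_env`.
#' @examples
#' invariance_test(c(0.1, 0.2, 0.3, 1.1, 1.2, 1.3),
#'                 c(0, 0, 0, 1, 1, 1), alpha = 0.05)
#' @export
invariance_test <- function(residuals, env_labels, alpha = 0.05,
                            reverse_acceptance = FALSE) {
  if (length(residuals) != length(env_labels)) {
    stopf("residuals and env_labels lengths differ",
          class = "icpbin_argument_error")
  }
  keep <- !is.na(env_labels) & !is.na(residuals)
  residuals <- residuals[keep]
  env_labels <- env_labels[keep]
  if (!is_binary01(env_labels)) {
    stopf("environment labels must be 0/1", class = "icpbin_argument_error")
  }
  r0 <- residuals[env_labels == 0]
  r1 <- residuals[env_labels == 1]
  if (length(r0) < 2L || length(r1) < 2L) {
    stopf("each environment level needs at least 2 observations (have %d, %d)",
          length(r0), length(r1), class = "icpbin_untestable_environment")
  }
  w <- welch_t(r0, r1)
  accepted <- if (reverse_acceptance) w$p < alpha else w$p >= alpha
  list(t_statistic = w$t, dof = w$dof, p_value = w$p,
       accepted = accepted, alpha = alpha,
       n_per_env = c(n0 = length(r0), n1 = length(r1)))
}

#' Test one predictor subset for invariance across an environment
#'
#' The per-subset unit of the ICP procedure: fit the outcome on the subset
#' by logistic regression pooled over all rows, compute response residuals,
#' and compare their means between the two environment levels.
#'
#' @param dataset an [icp_dataset()].
#' @param subset character vector of predictor names (empty allowed).
#' @param env_name name of the environment column in `dataset$env`.
#' @param alpha significance level.
#' @param residual_type residual flavour passed to
#'   [residuals.icp_logit()].
#' @param reverse_acceptance see [invariance_test()].
#' @return An object of class `subset_test`: the invariance-test fields
#'   plus the subset and a fit summary.
#' @examples
#' d <- simulate_scm(scm_preset("strong"), 500, seed = 2)
#' test_subset(d, c("X1", "X2"), "env", alpha = 0.05)
#' @export
test_subset <- function(dataset, subset, env_name, alpha = 0.05,
                        residual_type = "response",
                        reverse_acceptance = FALSE) {
  stopifnot(inherits(dataset, "icp_dataset"))
  if (!env_name %in% names(dataset$env)) {
    stopf("unknown environment '%s'", env_name, class = "icpbin_argument_error")
  }
  fit <- fit_logistic(dataset, subset)
  r <- stats::residuals(fit, type = residual_type)
  tst <- invariance_test(r, dataset$env[[env_name]], alpha,
                         reverse_acceptance = reverse_acceptance)
  structure(
    c(list(subset = as.character(subset), env_name = env_name),
      tst,
      list(fit = list(coefficients = fit$coefficients,
                      converged = fit$converged,
                      regularization_used = fit$regularization_used))),
    class = "subset_test"
  )
}

#' @export
print.subset_test <- function(x, ...) {
  cat(sprintf("<subset_test> {%s} vs environment '%s'\n",
              subset_key(x$subset), x$env_name))
  cat(sprintf("  t = %.4f (dof %.1f), p = %.4g -> %s at alpha = %g\n",
              x$t_statistic, x$dof, x$p_value,
              if (x$accepted) "accepted" else "rejected", x$alpha))
  invisible(x)
}

#' Serialize subset test results
#'
#' A single result flattens to a JSON record; a list of results to a TSV
#' with columns `subset`, `t`, `dof`, `p`, `accepted`, `alpha`, `env`.
#'
#' @param results a `subset_test` or list of them.
#' @param path output file; extension picks the format (`.json` single,
#'   `.tsv` batch).
#' @return `path`, invisibly.
#' @export
write_subset_tests <- function(results, path) {
  if (inherits(results, "subset_test")) {
    rec <- list(subset = subset_key(results$subset),
                t = results$t_statistic, dof = results$dof,
                p = results$p_value, accepted = results$accepted,
                alpha = results$alpha, env = results$env_name)
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(results, function(x) {
      data.frame(subset = subset_key(x$subset), t = x$t_statistic,
                 dof = x$dof, p = x$p_value, accepted = x$accepted,
                 alpha = x$alpha, env = x$env_name)
    }))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
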