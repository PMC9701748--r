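# From-scratch Welch oracle: written directly from the textbook formulas,
# independent of the package's test path.
welch_oracle <- function(r0, r1) {
  n0 <- length(r0); n1 <- length(r1)
  m0 <- sum(r0) / n0; m1 <- sum(r1) / n1
  v0 <- sum((r0 - m0)^2) / (n0 - 1)
  v1 <- sum((r1 - m1)^2) / (n1 - 1)
  se <- sqrt(v0 / n0 + v1 / n1)
  t <- (m0 - m1) / se
  dof <- (v0 / n0 + v1 / n1)^2 /
    ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  list(t = t, dof = dof, p = 2 * stats::pt(-abs(t), dof))
}

# tiny SCM with one parent (X1) reached by a shifted non-parent ancestor
# (X2 -> X1); X3 is shifted noise
one_parent_spec <- function(w = 1, shift = 1) {
  A <- matrix(0, 3, 3)
  A[2, 1] <- 1
  scm_spec(A, c(w, 0, 0),
           interventions = list("1" = list(
             list(var = "X1", type = "shift", magnitude = shift),
             list(var = "X2", type = "shift", magnitude = shift),
             list(var = "X3", type = "shift", magnitude = shift))))
}

# fixed small cohort reused across pipeline tests
pipeline_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study_like(default_schema(), n = 600, seed = 401)
    }
    cache
  }
})
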