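# Cohort-schema emulator: marginally calibrated clipped-normal scale
# totals, binary pre-existing-condition environments, and a logistic
# outcome whose intercept is calibrated to a target (rare) event rate.

# closed-form mean/sd of X = min(max(Z, a), b), Z ~ N(mu, sd^2)
censored_normal_moments <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  dPhi <- stats::pnorm(be) - stats::pnorm(al)
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m1 <- a * stats::pnorm(al) + b * (1 - stats::pnorm(be)) +
    mu * dPhi + sd * dphi
  m2 <- a^2 * stats::pnorm(al) + b^2 * (1 - stats::pnorm(be)) +
    mu^2 * dPhi + 2 * mu * sd * dphi +
    sd^2 * (dPhi + al * stats::dnorm(al) - be * stats::dnorm(be))
  v <- max(m2 - m1^2, 0)
  c(mean = m1, sd = sqrt(v))
}

# underlying (mu, sd) of the clipped normal whose observed moments match
# the instrument's printed mean/SD as closely as the family allows
calibrate_censored_normal <- function(mean, sd, min, max) {
  obj <- function(par) {
    mo <- censored_normal_moments(par[1], exp(par[2]), min, max)
    ((mo["mean"] - mean) / sd)^2 + ((mo["sd"] - sd) / sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  c(mu0 = fit$par[1], sigma0 = exp(fit$par[2]))
}

#' Construct a cohort schema for the study emulator
#'
#' A schema records, per predictor, the published sample mean, SD and
#' instrument range, and per environment a prevalence of level 1. The
#' constructor calibrates, for every predictor, the underlying normal whose
#' clipped-to-range version reproduces the published moments; generation is
#' then a pure function of `(schema, n, seed)`.
#'
#' @param predictors data frame with columns `name`, `mean`, `sd`, `min`,
#'   `max` (and optionally `latent_loading`, the correlation with the shared
#'   distress factor; default `sqrt(rho)` for every scale, 0 for `age`).
#' @param environments data frame with columns `name`, `prevalence` and
#'   `latent_loading` (association of the environment's liability with the
#'   distress factor); an environment named `age_le23` is instead derived
#'   by thresholding the simulated age at 23.
#' @param outcome_rate target marginal event probability, in (0, 1).
#' @param n_default default cohort size.
#' @param rho exchangeable correlation among the clinical scales induced by
#'   a single shared latent factor.
#' @param outcome_weights named numeric vector of synthetic logistic slopes
#'   on standardized predictors. These are placeholders that make the
#'   pipeline exercisable; they are not estimates of any real cohort.
#' @return An object of class `study_schema`.
#' @seealso [default_schema()], [generate_study_like()]
#' @export
study_schema <- function(predictors, environments, outcome_rate = 0.021,
                         n_default = 2744L, rho = 0.3,
                         outcome_weights = numeric(0)) {
  predictors <- as.data.frame(predictors)
  environments <- as.data.frame(environments)
  need <- c("name", "mean", "sd", "min", "max")
  if (!all(need %in% names(predictors))) {
    stopf("predictors needs columns %s", paste(need, collapse = ", "),
          class = "icpbin_argument_error")
  }
  if (any(predictors$sd <= 0)) {
    stopf("every predictor sd must be > 0", class = "icpbin_argument_error")
  }
  if (any(predictors$min >= predictors$max)) {
    stopf("every predictor needs min < max", class = "icpbin_argument_error")
  }
  if (anyDuplicated(predictors$name)) {
    stopf("duplicate predictor names", class = "icpbin_argument_error")
  }
  if (!(outcome_rate > 0 && outcome_rate < 1)) {
    stopf("outcome_rate must be in (0, 1)", class = "icpbin_argument_error")
  }
  if (!all(c("name", "prevalence") %in% names(environments))) {
    stopf("environments needs columns name, prevalence",
          class = "icpbin_argument_error")
  }
  if (is.null(environments$latent_loading)) environments$latent_loading <- 0
  derived <- environments$name == "age_le23"
  if (any(!derived & (environments$prevalence <= 0 | environments$prevalence >= 1))) {
    stopf("environment prevalences must be in (0, 1)",
          class = "icpbin_argument_error")
  }
  if (is.null(predictors$latent_loading)) {
    predictors$latent_loading <- ifelse(predictors$name == "age", 0, sqrt(rho))
  }
  cal <- t(mapply(calibrate_censored_normal,
                  predictors$mean, predictors$sd,
                  predictors$min, predictors$max))
  predictors$mu0 <- cal[, "mu0"]
  predictors$sigma0 <- cal[, "sigma0"]
  if (any(derived)) {
    # prevalence of age <= 23 implied by the calibrated age marginal
    ag <- predictors[predictors$name == "age", ]
    if (nrow(ag) != 1L) {
      stopf("an 'age_le23' environment requires an 'age' predictor",
            class = "icpbin_argument_error")
    }
    environments$prevalence[derived] <- stats::pnorm((23 - ag$mu0) / ag$sigma0)
  }
  bad <- setdiff(names(outcome_weights), predictors$name)
  if (length(bad)) {
    stopf("outcome_weights name(s) not in schema: %s",
          paste(bad, collapse = ", "), class = "icpbin_argument_error")
  }
  structure(
    list(predictor_specs = predictors, environment_specs = environments,
         outcome_rate = outcome_rate, n_default = as.integer(n_default),
         rho = rho, outcome_weights = outcome_weights),
    class = "study_schema"
  )
}

#' @export
print.study_schema <- function(x, ...) {
  cat(sprintf("<study_schema> %d predictors, %d environments\n",
              nrow(x$predictor_specs), nrow(x$environment_specs)))
  cat(sprintf("  outcome rate %.3f, default n %d, scale correlation %.2f\n",
              x$outcome_rate, x$n_default, x$rho))
  cat(sprintf("  synthetic outcome weights: %s\n",
              if (length(x$outcome_weights))
                paste(names(x$outcome_weights), round(x$outcome_weights, 2),
                      sep = "=", collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' The default cohort schema
#'
#' The published descriptive table of the motivating cohort: 18 predictors
#' (17 clinical scale totals plus age) with their sample mean, SD and
#' instrument range, and 6 binary environments with prevalences computed
#' from the printed counts over n = 2744 (prior suicidal ideation 774,
#' prior suicide attempt 238, prior non-suicidal self-injury 312, White
#' race 1811, male gender 1380); the age (at most 23 vs 24+) prevalence is
#' derived from the calibrated age marginal. The marginal event rate is
#' 2.1% over one year.
#'
#' The outcome weights shipped here are synthetic placeholders (small
#' positive loadings on shame, suicide cognitions, negative affect and
#' internal entrapment) so that generated cohorts carry a plausible weak
#' signal; they are not estimates from any real data.
#'
#' @return A [study_schema()].
#' @examples
#' sch <- default_schema()
#' nrow(sch$predictor_specs)
#' @export
default_schema <- function() {
  predictors <- data.frame(
    name = c("age", "des_guilt", "des_shame", "des_hostility",
             "es_internal", "es_external",
             "isel_appraisal", "isel_belonging", "isel_tangible",
             "panas_positive", "panas_negative",
             "pc_ptsd", "phq9", "phq9_si", "scs_r",
             "acss_fad", "brfli", "isi"),
    mean = c(40.4, 6.8, 6.4, 5.2, 5.8, 3.3, 12.8, 12.3, 12.4,
             13.1, 7.9, 1.1, 6.0, 0.1, 6.6, 14.2, 53.0, 16.4),
    sd   = c(19.6, 3.4, 3.4, 3.1, 8.8, 5.7, 2.9, 3.0, 2.7,
             5.0, 3.9, 1.5, 6.0, 0.5, 11.0, 4.0, 16.6, 7.2),
    min  = c(18, 3, 3, 3, 0, 0, 4, 4, 4, 5, 5, 0, 0, 0, 0, 0, 14, 7),
    max  = c(85, 15, 15, 15, 40, 24, 16, 16, 16, 25, 25, 4, 27, 3, 64,
             32, 84, 35)
  )
  environments <- data.frame(
    name = c("prior_si", "prior_sa", "prior_nssi",
             "race_white", "age_le23", "gender_male"),
    prevalence = c(774 / 2744, 238 / 2744, 312 / 2744,
                   1811 / 2744, NA, 1380 / 2744),
    latent_loading = c(0.45, 0.45, 0.45, -0.15, 0, -0.10)
  )
  study_schema(
    predictors, environments,
    outcome_rate = 0.021, n_default = 2744L, rho = 0.3,
    outcome_weights = c(des_shame = 0.35, scs_r = 0.35,
                        panas_negative = 0.25, es_internal = 0.15)
  )
}

#' Generate a synthetic cohort from a study schema
#'
#' Scale totals are drawn as clipped normals sharing a single latent
#' distress factor (exchangeable correlation `rho` among the clinical
#' scales); age is drawn independently. Environment columns are liability
#' thresholdings correlated with the same factor at their schema
#' prevalences (the age environment thresholds the simulated age at 23, so
#' the emitted dataset carries every environment in binary form). The
#' outcome is Bernoulli-logistic on standardized predictors with the
#' schema's synthetic weights; the intercept is found by bisection on the
#' mean logistic response over the generated predictors so the marginal
#' event rate converges to `outcome_rate`.
#'
#' @param schema a [study_schema()].
#' @param n cohort size (default the schema's).
#' @param seed integer seed; output is a pure function of
#'   `(schema, n, seed)`.
#' @return An [icp_dataset()] with provenance `"study-schema"`.
#' @examples
#' d <- generate_study_like(default_schema(), n = 500, seed = 7)
#' colMeans(d$env)
#' @export
generate_study_like <- function(schema, n = schema$n_default, seed = 1L) {
  stopifnot(inherits(schema, "study_schema"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stopf("n must be >= 1", class = "icpbin_argument_error")
  ps <- schema$predictor_specs
  es <- schema$environment_specs
  sim <- with_seed(seed, {
    L <- stats::rnorm(n)
    X <- matrix(0, n, nrow(ps), dimnames = list(NULL, ps$name))
    for (j in seq_len(nrow(ps))) {
      lam <- ps$latent_loading[j]
      z <- lam * L + sqrt(1 - lam^2) * stats::rnorm(n)
      X[, j] <- clamp(ps$mu0[j] + ps$sigma0[j] * z, ps$min[j], ps$max[j])
    }
    env <- matrix(0L, n, nrow(es), dimnames = list(NULL, es$name))
    for (k in seq_len(nrow(es))) {
      if (es$name[k] == "age_le23") {
        env[, k] <- as.integer(X[, "age"] <= 23)
      } else {
        lam <- es$latent_loading[k]
        liab <- lam * L + sqrt(1 - lam^2) * stats::rnorm(n)
        env[, k] <- as.integer(liab > stats::qnorm(1 - es$prevalence[k]))
      }
    }
    list(X = X, env = env)
  })
  eta <- numeric(n)
  for (nm in names(schema$outcome_weights)) {
    j <- match(nm, ps$name)
    eta <- eta + schema$outcome_weights[[nm]] *
      (sim$X[, j] - ps$mean[j]) / ps$sd[j]
  }
  f <- function(b0) mean(stats::plogis(b0 + eta)) - schema$outcome_rate
  b0 <- stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
  y <- with_seed(seed + 1L, stats::rbinom(n, 1L, stats::plogis(b0 + eta)))
  icp_dataset(as.data.frame(sim$X), y, as.data.frame(sim$env),
              provenance = "study-schema", seed = seed)
}

#' Serialize / restore a study schema as YAML
#'
#' The calibrated underlying marginals are recomputed on read, so the file
#' stores only the published targets and emulator settings.
#'
#' @param schema a [study_schema()].
#' @param path YAML file path.
#' @return `write_study_schema`: `path` invisibly; `read_study_schema`: a
#'   [study_schema()].
#' @export
write_study_schema <- function(schema, path) {
  stopifnot(inherits(schema, "study_schema"))
  ps <- schema$predictor_specs
  obj <- list(
    predictors = lapply(seq_len(nrow(ps)), function(j) {
      list(name = ps$name[j], mean = ps$mean[j], sd = ps$sd[j],
           min = ps$min[j], max = ps$max[j],
           latent_loading = ps$latent_loading[j])
    }),
    environments = lapply(seq_len(nrow(schema$environment_specs)), function(k) {
      e <- schema$environment_specs[k, ]
      list(name = e$name, prevalence = e$prevalence,
           latent_loading = e$latent_loading)
    }),
    outcome_rate = schema$outcome_rate,
    n_default = schema$n_default,
    rho = schema$rho,
    outcome_weights = as.list(schema$outcome_weights)
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_study_schema
#' @export
read_study_schema <- function(path) {
  obj <- yaml::read_yaml(path)
  predictors <- do.call(rbind, lapply(obj$predictors, as.data.frame))
  environments <- do.call(rbind, lapply(obj$environments, function(e) {
    e$prevalence <- e$prevalence %||% NA_real_
    as.data.frame(e)
  }))
  study_schema(predictors, environments,
               outcome_rate = obj$outcome_rate,
               n_default = obj$n_default,
               rho = obj$rho,
               outcome_weights = unlist(obj$outcome_weights) %||% numeric(0))
}
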