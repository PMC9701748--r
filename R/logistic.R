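# Subset-wise logistic fitting with a stabilization path for separated or
# non-converged fits: refit with a tiny ridge penalty on the slopes (never
# the intercept) so every candidate subset yields finite coefficients and
# interior fitted probabilities. A subset is never silently dropped —
# dropping would bias the downstream intersection.

PROB_EPS <- 1e-12
RIDGE_LAMBDA <- 1e-6

#' Fit a logistic regression of the outcome on a predictor subset
#'
#' Maximum-likelihood fit by iteratively reweighted least squares, pooled
#' over all environments. If the IRLS does not converge or the fitted
#' probabilities hit the boundary (the signature of separation, where the
#' MLE does not exist), the model is refit with a ridge penalty of
#' `1e-6` on the slopes and flagged. An empty subset gives the
#' intercept-only model whose fitted probability is the outcome's sample
#' mean. A rank-deficient design is fit through the pseudo-inverse with a
#' warning.
#'
#' @param dataset an [icp_dataset()].
#' @param subset character vector of predictor names; `character(0)` for
#'   the intercept-only model.
#' @return An object of class `icp_logit`: coefficients (intercept first),
#'   `fitted` probabilities (strictly inside (0, 1)), `converged`,
#'   `regularization_used` (`"none"` or `"tiny-ridge"`), the outcome and
#'   subset.
#' @examples
#' d <- simulate_scm(scm_preset("strong"), 200, seed = 1)
#' fit_logistic(d, c("X1", "X2"))
#' @export
fit_logistic <- function(dataset, subset = character(0)) {
  stopifnot(inherits(dataset, "icp_dataset"))
  subset <- as.character(subset)
  missing <- setdiff(subset, names(dataset$X))
  if (length(missing)) {
    stopf("unknown predictor(s): %s", paste(missing, collapse = ", "),
          class = "icpbin_argument_error")
  }
  y <- dataset$y
  if (length(unique(y)) < 2L) {
    stopf("outcome has a single class; logistic fit is degenerate",
          class = "icpbin_degenerate_outcome")
  }
  n <- length(y)
  Xm <- cbind(`(Intercept)` = rep(1, n))
  if (length(subset)) {
    Xm <- cbind(Xm, as.matrix(dataset$X[subset]))
  }
  rank_deficient <- qr(Xm)$rank < ncol(Xm)
  if (rank_deficient) {
    warning("rank-deficient design for subset {", subset_key(subset),
            "}; using pseudo-inverse fit", call. = FALSE)
    res <- irls_logistic(Xm, y, lambda = 0, use_ginv = TRUE)
  } else {
    glmfit <- suppressWarnings(
      stats::glm.fit(Xm, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    )
    res <- list(coefficients = glmfit$coefficients,
                fitted = glmfit$fitted.values,
                converged = glmfit$converged)
  }
  boundary <- any(res$fitted < 1e-8 | res$fitted > 1 - 1e-8)
  regularization <- "none"
  converged <- isTRUE(res$converged)
  if (length(subset) && (!converged || boundary)) {
    # separation / non-existence of the MLE: stabilize with a tiny ridge
    converged <- FALSE
    regularization <- "tiny-ridge"
    res <- irls_logistic(Xm, y, lambda = RIDGE_LAMBDA,
                         use_ginv = rank_deficient)
  }
  structure(
    list(subset = subset,
         coefficients = stats::setNames(as.numeric(res$coefficients),
                                        colnames(Xm)),
         fitted = clamp(as.numeric(res$fitted), PROB_EPS, 1 - PROB_EPS),
         converged = converged,
         regularization_used = regularization,
         y = y, n = n),
    class = "icp_logit"
  )
}

# penalized IRLS; lambda penalizes slopes only, never the intercept
irls_logistic <- function(Xm, y, lambda = 0, use_ginv = FALSE,
                          maxit = 100L, tol = 1e-10) {
  k <- ncol(Xm)
  pen <- diag(c(0, rep(lambda, k - 1L)), k)
  beta <- numeric(k)
  beta[1] <- stats::qlogis(clamp(mean(y), 1e-6, 1 - 1e-6))
  for (it in seq_len(maxit)) {
    eta <- clamp(drop(Xm %*% beta), -30, 30)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    A <- crossprod(Xm * w, Xm) + pen
    b <- crossprod(Xm, w * z)
    beta_new <- if (use_ginv) drop(MASS::ginv(A) %*% b) else {
      drop(solve(A, b))
    }
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  eta <- clamp(drop(Xm %*% beta), -30, 30)
  list(coefficients = beta, fitted = stats::plogis(eta), converged = TRUE)
}

#' @export
print.icp_logit <- function(x, ...) {
  cat(sprintf("<icp_logit> subset {%s}, n = %d\n",
              subset_key(x$subset), x$n))
  print(round(x$coefficients, 4))
  cat(sprintf("  converged: %s; regularization: %s\n",
              x$converged, x$regularization_used))
  invisible(x)
}

#' @export
coef.icp_logit <- function(object, ...) object$coefficients

#' @export
fitted.icp_logit <- function(object, ...) object$fitted

#' Residuals of a subset logistic fit
#'
#' The default response residual is the observed outcome minus the fitted
#' event probability — the quantity whose between-environment mean
#' difference the invariance test examines. Pearson and deviance residuals
#' are available; the three types can disagree on borderline decisions, so
#' the choice is surfaced rather than hidden.
#'
#' @param object an `icp_logit` fit.
#' @param type `"response"` (default), `"pearson"` or `"deviance"`.
#' @param y outcome vector; defaults to the one the model was fit on.
#' @param ... unused.
#' @return Numeric residual vector.
#' @export
residuals.icp_logit <- function(object,
                                type = c("response", "pearson", "deviance"),
                                y = object$y, ...) {
  type <- match.arg(type)
  p <- object$fitted
  if (length(y) != length(p)) {
    stopf("outcome length %d does not match fit length %d",
          length(y), length(p), class = "icpbin_argument_error")
  }
  r <- y - p
  switch(type,
    response = r,
    pearson = r / sqrt(p * (1 - p)),
    deviance = sign(r) * sqrt(-2 * (y * log(p) + (1 - y) * log1p(-p)))
  )
}
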