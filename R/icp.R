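# Subset enumeration, lasso pre-screening and the ICP estimator: the
# intersection of all subsets whose invariance is not rejected.

#' Enumerate predictor subsets in size-then-lexicographic order
#'
#' Yields every subset of the given predictors including the empty set,
#' deterministically ordered (by size, then lexicographically within size)
#' so reports reproduce byte-for-byte.
#'
#' @param predictors character vector of predictor names, duplicate-free.
#' @param max_size optional cap on subset size.
#' @return List of character vectors; first element `character(0)`.
#' @examples
#' length(enumerate_subsets(c("a", "b", "c")))  # 8
#' @export
enumerate_subsets <- function(predictors, max_size = NULL) {
  predictors <- as.character(predictors)
  if (length(predictors) == 0L) {
    stopf("predictors must be non-empty", class = "icpbin_argument_error")
  }
  if (anyDuplicated(predictors)) {
    stopf("duplicate predictor names", class = "icpbin_argument_error")
  }
  kmax <- min(length(predictors), max_size %||% length(predictors))
  sorted <- sort(predictors)
  out <- list(character(0))
  for (k in seq_len(kmax)) {
    combos <- utils::combn(sorted, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

#' Lasso screen: shrink the candidate predictor pool
#'
#' With p predictors the exhaustive search costs 2^p logistic fits, so the
#' candidate pool is first reduced by L1-penalized logistic regression of
#' the outcome on all (standardized) predictors, with the penalty chosen by
#' 10-fold cross-validated deviance at the CV minimum. The minimum — not
#' the 1-SE rule — is deliberate: the screen should over-select rather than
#' drop a true parent, because the downstream intersection tolerates extra
#' candidates but is broken by missing ones. Predictors with non-zero
#' coefficients are kept, truncated to the `k_max` largest absolute
#' coefficients.
#'
#' @param dataset an [icp_dataset()].
#' @param k_max maximum number of predictors returned.
#' @param seed seed for the cross-validation folds; the screen is
#'   deterministic given the seed.
#' @return Character vector of retained predictor names, in the dataset's
#'   column order. Empty (with a warning) when the selected penalty zeroes
#'   every coefficient.
#' @export
lasso_screen <- function(dataset, k_max = 8L, seed = 1L) {
  stopifnot(inherits(dataset, "icp_dataset"))
  k_max <- as.integer(k_max)
  if (k_max < 1L) stopf("k_max must be >= 1", class = "icpbin_argument_error")
  x <- as.matrix(dataset$X)
  y <- dataset$y
  cv <- with_seed(seed, {
    foldid <- sample(rep_len(1:10, nrow(x)))
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                      foldid = foldid, standardize = TRUE)
  })
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  nz <- beta[beta != 0]
  if (length(nz) == 0L) {
    warning("lasso screen retained no predictors; only the empty subset ",
            "will be testable", call. = FALSE)
    return(character(0))
  }
  ord <- order(-abs(nz), names(nz))
  keep <- names(nz)[ord][seq_len(min(k_max, length(nz)))]
  names(dataset$X)[names(dataset$X) %in% keep]
}

#' Intersect the accepted subsets
#'
#' The ICP estimate with its status: `"ok"` for a non-empty intersection,
#' `"empty_by_intersection"` when subsets were accepted but share no
#' predictor (in particular whenever the empty subset is accepted), and
#' `"model_rejected"` when no subset at all was accepted — the invariance
#' assumption failed for every candidate, a distinct state from an empty
#' estimate.
#'
#' @param accepted_sets list of character vectors.
#' @return List with `estimated_set` and `status`.
#' @examples
#' intersect_accepted(list(c("A", "B"), c("B", "C")))
#' @export
intersect_accepted <- function(accepted_sets) {
  if (length(accepted_sets) == 0L) {
    return(list(estimated_set = character(0), status = "model_rejected"))
  }
  est <- Reduce(intersect, accepted_sets)
  list(estimated_set = sort(est),
       status = if (length(est)) "ok" else "empty_by_intersection")
}

# Shared computational core: one pooled fit + residual vector per subset
# (fits do not depend on the environment), then a Welch test per
# environment. Returns a long data.frame; alpha enters only afterwards.
subset_pvalue_table <- function(dataset, subsets, env_names,
                                residual_type = "response") {
  rows <- vector("list", length(subsets) * length(env_names))
  i <- 0L
  for (s in subsets) {
    fit <- fit_logistic(dataset, s)
    r <- stats::residuals(fit, type = residual_type)
    for (e in env_names) {
      lab <- dataset$env[[e]]
      keep <- !is.na(lab)
      w <- welch_t(r[keep][lab[keep] == 0], r[keep][lab[keep] == 1])
      i <- i + 1L
      rows[[i]] <- data.frame(subset = subset_key(s), size = length(s),
                              env = e, t = w$t, dof = w$dof, p = w$p,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

subsets_from_keys <- function(keys) {
  lapply(keys, function(k) if (k == "(empty)") character(0)
         else strsplit(k, "+", fixed = TRUE)[[1]])
}

#' Invariant causal prediction for a binary outcome
#'
#' The central estimator. Every candidate subset of predictors is fit by
#' pooled logistic regression; subsets whose response residuals have equal
#' means across the two environment levels (Welch t-test, `p >= alpha`)
#' are accepted, and the estimate is the intersection of all accepted
#' subsets — with high probability a subset of the true direct causes.
#' The `"lasso"` method first shrinks the candidate pool with
#' [lasso_screen()]; the `"full"` method enumerates subsets of every
#' predictor (optionally capped by `max_size`).
#'
#' @param data an [icp_dataset()], or a data.frame together with `outcome`
#'   and `env_cols`.
#' @param env name of the environment column to split on.
#' @param alpha significance level of the invariance test.
#' @param method `"full"` or `"lasso"`.
#' @param k_max lasso-screen retention cap (default 8, i.e. at most 256
#'   subsets).
#' @param max_size optional cap on subset size for the full method.
#' @param seed seed (used only by the lasso folds).
#' @param residual_type residual flavour for the test.
#' @param reverse_acceptance accept when `p < alpha` (sensitivity flag; see
#'   the methods vignette).
#' @param ... passed between methods.
#' @return An object of class `icp` with the accepted subsets, the
#'   estimated set and its status, and the per-subset p-value table.
#' @examples
#' d <- simulate_scm(scm_preset("strong"), 1000, seed = 3)
#' fit <- icp(d, env = "env", alpha = 0.05)
#' fit
#' @export
icp <- function(data, ...) UseMethod("icp")

#' @rdname icp
#' @param outcome,env_cols column roles when `data` is a plain data.frame.
#' @export
icp.data.frame <- function(data, env, outcome = "y",
                           env_cols = grep("^env_", names(data), value = TRUE),
                           ...) {
  preds <- setdiff(names(data), c(outcome, env_cols))
  ds <- icp_dataset(data[preds], data[[outcome]],
                    stats::setNames(data[env_cols],
                                    sub("^env_", "", env_cols)),
                    provenance = "data.frame")
  icp(ds, env = env, ...)
}

#' @rdname icp
#' @export
icp.icp_dataset <- function(data, env, alpha = 0.05,
                            method = c("full", "lasso"),
                            k_max = 8L, max_size = NULL, seed = 1L,
                            residual_type = "response",
                            reverse_acceptance = FALSE, ...) {
  method <- match.arg(method)
  if (!env %in% names(data$env)) {
    stopf("unknown environment '%s'", env, class = "icpbin_argument_error")
  }
  screened <- if (method == "lasso") {
    lasso_screen(data, k_max = k_max, seed = seed)
  } else {
    names(data$X)
  }
  subsets <- if (length(screened)) {
    enumerate_subsets(screened, max_size = max_size)
  } else {
    list(character(0))
  }
  ptab <- subset_pvalue_table(data, subsets, env, residual_type)
  icp_from_table(ptab, env, alpha, method, screened,
                 n_subsets = length(subsets),
                 reverse_acceptance = reverse_acceptance, seed = seed)
}

# materialize an ICP result for one (env, alpha) cell from the p-table
icp_from_table <- function(ptab, env, alpha, method, screened, n_subsets,
                           reverse_acceptance = FALSE, seed = NA_integer_) {
  tab <- ptab[ptab$env == env, , drop = FALSE]
  acc <- if (reverse_acceptance) tab$p < alpha else tab$p >= alpha
  accepted_sets <- subsets_from_keys(tab$subset[acc])
  inter <- intersect_accepted(accepted_sets)
  structure(
    list(env_name = env, alpha = alpha, method = method,
         screened_predictors = screened,
         accepted_sets = accepted_sets,
         estimated_set = inter$estimated_set,
         status = inter$status,
         any_accepted = length(accepted_sets) > 0L,
         n_subsets_tested = n_subsets,
         pvalues = tab[order(tab$size, tab$subset), ,
                       drop = FALSE],
         reverse_acceptance = reverse_acceptance,
         seed = seed),
    class = "icp"
  )
}

#' @export
print.icp <- function(x, ...) {
  cat(sprintf("<icp> method %s, environment '%s', alpha = %g\n",
              x$method, x$env_name, x$alpha))
  cat(sprintf("  %d/%d subsets accepted\n",
              length(x$accepted_sets), x$n_subsets_tested))
  est <- switch(x$status,
    model_rejected = "- (model rejected: no subset is invariant)",
    empty_by_intersection = "None (accepted subsets share no predictor)",
    paste(x$estimated_set, collapse = ", "))
  cat("  estimated causal predictors:", est, "\n")
  invisible(x)
}

#' @export
summary.icp <- function(object, max_rows = 10L, ...) {
  cat(sprintf("Invariant causal prediction (%s method)\n", object$method))
  cat(sprintf("Environment '%s', alpha = %g; %d predictors screened, %d subsets tested\n",
              object$env_name, object$alpha,
              length(object$screened_predictors), object$n_subsets_tested))
  print.icp(object)
  acc <- object$pvalues[order(-object$pvalues$p), , drop = FALSE]
  cat("\nMost invariant subsets:\n")
  print(utils::head(acc[c("subset", "t", "dof", "p")], max_rows),
        row.names = FALSE)
  invisible(object)
}

#' @export
plot.icp <- function(x, ...) {
  tab <- x$pvalues
  acc <- tab$p >= x$alpha
  graphics::plot(jitter(tab$size, amount = 0.1), -log10(pmax(tab$p, 1e-16)),
                 col = ifelse(acc, "forestgreen", "firebrick"),
                 pch = ifelse(acc, 19, 1),
                 xlab = "subset size", ylab = "-log10 p",
                 main = sprintf("Invariance evidence by subset ('%s', alpha = %g)",
                                x$env_name, x$alpha), ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  invisible(x)
}

#' Serialize an ICP result
#'
#' JSON for the result object; optionally a TSV audit trail of every
#' tested subset.
#'
#' @param fit an `icp` object.
#' @param path output JSON path.
#' @param tsv optional TSV path for the per-subset table.
#' @return `path`, invisibly.
#' @export
write_icp <- function(fit, path, tsv = NULL) {
  stopifnot(inherits(fit, "icp"))
  obj <- list(
    env = fit$env_name, alpha = fit$alpha, method = fit$method,
    screened_predictors = fit$screened_predictors,
    n_subsets_tested = fit$n_subsets_tested,
    any_accepted = fit$any_accepted,
    status = fit$status,
    estimated_set = fit$estimated_set,
    accepted_sets = lapply(fit$accepted_sets, subset_key)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv)) {
    utils::write.table(fit$pvalues, tsv, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
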