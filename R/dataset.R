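#' Assemble an analysis dataset
#'
#' Bundles a predictor matrix, a binary outcome and one or more binary
#' environment labels into the container used by every fitting and testing
#' function in the package. All components must share the same number of
#' rows; environment columns must carry both levels, because an environment
#' with a single observed level cannot define a two-sample comparison.
#'
#' @param X data frame or numeric matrix of predictors (named columns).
#' @param y binary outcome vector coded 0/1.
#' @param env data frame (or named list) of 0/1 environment label vectors.
#' @param provenance free-text origin tag (e.g. `"scm"`, `"study-schema"`,
#'   `"file"`).
#' @param seed integer seed recorded for reproducibility, or `NA`.
#' @return An object of class `icp_dataset`: a list with elements `X`
#'   (data.frame), `y` (integer vector), `env` (data.frame of 0/1 columns),
#'   `provenance` and `seed`.
#' @examples
#' d <- icp_dataset(data.frame(x1 = rnorm(8)),
#'                  y = rep(c(0, 1), 4),
#'                  env = data.frame(e = rep(c(0, 1), each = 4)))
#' d
#' @export
icp_dataset <- function(X, y, env, provenance = "user", seed = NA_integer_) {
  X <- as.data.frame(X)
  if (is.null(names(X)) || any(!nzchar(names(X))) || anyDuplicated(names(X))) {
    stopf("predictor columns must have unique non-empty names",
          class = "icpbin_data_error")
  }
  if (!is_binary01(y)) {
    stopf("outcome must be coded 0/1", class = "icpbin_data_error")
  }
  y <- as.integer(y)
  env <- as.data.frame(env)
  n <- nrow(X)
  if (length(y) != n || nrow(env) != n) {
    stopf("X (%d rows), y (%d) and env (%d rows) must align",
          nrow(X), length(y), nrow(env), class = "icpbin_data_error")
  }
  for (nm in names(env)) {
    v <- env[[nm]]
    if (!is_binary01(v)) {
      stopf("environment '%s' must be coded 0/1", nm,
            class = "icpbin_data_error")
    }
    if (length(unique(v[!is.na(v)])) < 2L) {
      stopf("environment '%s' has a single observed level", nm,
            class = "icpbin_invalid_environment")
    }
    env[[nm]] <- as.integer(v)
  }
  structure(
    list(X = X, y = y, env = env,
         provenance = provenance, seed = as.integer(seed)),
    class = "icp_dataset"
  )
}

#' @export
print.icp_dataset <- function(x, ...) {
  cat(sprintf("<icp_dataset> %d rows, %d predictors, %d environment(s)\n",
              nrow(x$X), ncol(x$X), ncol(x$env)))
  cat(sprintf("  outcome: %d events (%.2f%%)\n",
              sum(x$y), 100 * mean(x$y)))
  cat(sprintf("  environments: %s\n", paste(names(x$env), collapse = ", ")))
  cat(sprintf("  provenance: %s (seed %s)\n", x$provenance,
              ifelse(is.na(x$seed), "none", x$seed)))
  invisible(x)
}

#' @export
dim.icp_dataset <- function(x) c(nrow(x$X), ncol(x$X))

#' Write a dataset to CSV with a JSON provenance sidecar
#'
#' The CSV holds predictors under their own names, the outcome as `y` and
#' each environment as `env_<name>`. A `<path>.json` sidecar records the
#' provenance, seed and column roles so the file round-trips losslessly.
#'
#' @param dataset an [icp_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "icp_dataset"))
  env <- dataset$env
  names(env) <- paste0("env_", names(env))
  out <- cbind(dataset$X, y = dataset$y, env)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    provenance = dataset$provenance,
    seed = dataset$seed,
    outcome = "y",
    predictors = names(dataset$X),
    environments = names(dataset$env)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' Column roles come from the JSON sidecar when present; otherwise `y` is
#' the outcome and any `env_`-prefixed column an environment.
#'
#' @param path CSV path.
#' @return An [icp_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    env_cols <- paste0("env_", side$environments)
    ds <- icp_dataset(df[side$predictors], df[[side$outcome]],
                      stats::setNames(df[env_cols], side$environments),
                      provenance = side$provenance %||% "file",
                      seed = side$seed %||% NA_integer_)
  } else {
    env_cols <- grep("^env_", names(df), value = TRUE)
    pred_cols <- setdiff(names(df), c("y", env_cols))
    ds <- icp_dataset(df[pred_cols], df[["y"]],
                      stats::setNames(df[env_cols], sub("^env_", "", env_cols)),
                      provenance = "file")
  }
  ds
}
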