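# Applied study workflow: environment preparation and screening, the
# methods x environments x alpha grid, and Table-style reporting.

#' Dichotomize an environment variable
#'
#' Environments must be two-level. A numeric `rule` is a threshold: values
#' `<= rule` map to 1 (e.g. age at most 23 vs 24+). A named vector `rule`
#' maps observed values explicitly (e.g. `c(White = 1)` with `default = 0`
#' for White vs non-White). Values covered by neither map to `NA` and are
#' excluded from that environment's analysis only — never listwise — with
#' the count attached as an attribute.
#'
#' @param column vector to dichotomize.
#' @param rule numeric threshold or named value-to-0/1 mapping.
#' @param default label for values absent from a mapping rule; `NA` (the
#'   drop policy) by default.
#' @return Integer 0/1 vector with attribute `n_dropped`.
#' @examples
#' dichotomize_environment(c(18, 23, 24, 40), rule = 23)
#' dichotomize_environment(c("White", "Black", "Asian"),
#'                         rule = c(White = 1), default = 0)
#' @export
dichotomize_environment <- function(column, rule, default = NA) {
  if (is.numeric(rule) && is.null(names(rule)) && length(rule) == 1L) {
    out <- ifelse(is.na(column), NA_integer_, as.integer(column <= rule))
  } else {
    if (is.null(names(rule))) {
      stopf("mapping rule must be a named vector", class = "icpbin_argument_error")
    }
    idx <- match(as.character(column), names(rule))
    out <- ifelse(is.na(idx), as.integer(default), as.integer(rule[idx]))
  }
  dropped <- sum(is.na(out) & !is.na(column)) + sum(is.na(column))
  obs <- unique(out[!is.na(out)])
  if (length(obs) == 0L) {
    stopf("no rows mapped by the dichotomization rule",
          class = "icpbin_invalid_environment")
  }
  if (length(obs) < 2L) {
    stopf("dichotomized environment has a single level",
          class = "icpbin_invalid_environment")
  }
  structure(as.integer(out), n_dropped = dropped)
}

#' Screen an environment variable against the outcome
#'
#' A valid environment should be associated with the outcome — if the
#' outcome does not differ across levels, the environments are not
#' distinct from its perspective — yet must not be a descendant of it.
#' The screen runs a 2x2 chi-square test of independence (Fisher's exact
#' when any expected count falls below 5) and annotates: a high p-value
#' yields a warning note but `valid = TRUE`, because screening informs
#' rather than silently drops; a near-perfect association is flagged as a
#' possible descendant.
#'
#' @param dataset an [icp_dataset()].
#' @param env_name environment column name.
#' @return An object of class `env_screen` with `env_name`,
#'   `outcome_association_p`, `both_levels_present`, `valid`, `note`.
#' @export
screen_environment <- function(dataset, env_name) {
  stopifnot(inherits(dataset, "icp_dataset"))
  e <- dataset$env[[env_name]]
  keep <- !is.na(e)
  e <- e[keep]
  y <- dataset$y[keep]
  both <- length(unique(e)) == 2L
  if (!both) {
    return(structure(list(env_name = env_name,
                          outcome_association_p = NA_real_,
                          both_levels_present = FALSE, valid = FALSE,
                          note = "single observed level"),
                     class = "env_screen"))
  }
  tab <- table(factor(e, levels = 0:1), factor(y, levels = 0:1))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  p <- if (any(expected < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab)$p.value
  }
  v <- suppressWarnings(sqrt(stats::chisq.test(tab, correct = FALSE)$statistic / sum(tab)))
  note <- ""
  if (p > 0.05) {
    note <- sprintf("weak outcome association (p = %.3f); environment may not be sufficiently distinct", p)
  }
  if (is.finite(v) && v > 0.9) {
    note <- paste0(note, if (nzchar(note)) "; " else "",
                   "near-perfect association with outcome: possible causal descendant")
  }
  structure(list(env_name = env_name, outcome_association_p = p,
                 both_levels_present = TRUE, valid = TRUE, note = note),
            class = "env_screen")
}

#' @export
print.env_screen <- function(x, ...) {
  cat(sprintf("<env_screen> '%s': p = %.4g, valid = %s%s\n",
              x$env_name, x$outcome_association_p, x$valid,
              if (nzchar(x$note %||% "")) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

normalize_config <- function(config, dataset) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  config$alphas <- as.numeric(config$alphas %||% c(0.1, 0.05, 0.01))
  config$methods <- as.character(config$methods %||% c("full", "lasso"))
  config$environments <- as.character(config$environments %||% names(dataset$env))
  config$k_max <- as.integer(config$k_max %||% 8L)
  config$max_size <- config$max_size
  config$residual_type <- config$residual_type %||% "response"
  config$seed <- as.integer(config$seed %||% 1L)
  if (!all(config$methods %in% c("full", "lasso"))) {
    stopf("methods must be 'full' and/or 'lasso'", class = "icpbin_config_error")
  }
  miss <- setdiff(config$environments, names(dataset$env))
  if (length(miss)) {
    stopf("config environment(s) not in dataset: %s",
          paste(miss, collapse = ", "), class = "icpbin_config_error")
  }
  config
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full study analysis grid
#'
#' For every method, screened environment and significance level in the
#' configuration, runs the ICP estimator and assembles a report mirroring
#' the study's results table. Per-subset fits are shared across
#' environments and alpha levels (the pooled fit depends on neither), so
#' the grid costs one fit per candidate subset per method. Any per-cell
#' failure is recorded in place of its result rather than aborting the
#' grid. Environment screening annotates; it never drops an environment
#' with both levels present.
#'
#' @param dataset an [icp_dataset()].
#' @param config a list (or YAML file path) with optional fields `alphas`
#'   (default 0.1, 0.05, 0.01), `methods` (default full and lasso),
#'   `environments` (default all), `k_max`, `max_size`, `residual_type`,
#'   `seed`.
#' @return An object of class `icp_study`: `grid` (named list of `icp`
#'   results keyed `method|env|alpha`), `screening`, `config` (with hash),
#'   `version`, `seed`.
#' @examples
#' d <- generate_study_like(default_schema(), n = 600, seed = 11)
#' rep <- run_study_analysis(d, list(methods = "lasso", k_max = 3,
#'                                   alphas = c(0.1, 0.05)))
#' rep
#' @export
run_study_analysis <- function(dataset, config = list()) {
  stopifnot(inherits(dataset, "icp_dataset"))
  config <- normalize_config(config, dataset)
  screening <- lapply(config$environments, function(e) {
    screen_environment(dataset, e)
  })
  names(screening) <- config$environments
  valid_envs <- config$environments[vapply(screening, `[[`, TRUE, "valid")]
  grid <- list()
  for (method in config$methods) {
    cell_or_error <- function(expr) tryCatch(expr, error = function(e) {
      structure(list(error = conditionMessage(e)), class = "icp_cell_error")
    })
    prep <- cell_or_error({
      screened <- if (method == "lasso") {
        lasso_screen(dataset, k_max = config$k_max, seed = config$seed)
      } else {
        names(dataset$X)
      }
      subsets <- if (length(screened)) {
        enumerate_subsets(screened, max_size = config$max_size)
      } else {
        list(character(0))
      }
      ptab <- subset_pvalue_table(dataset, subsets, valid_envs,
                                  config$residual_type)
      list(screened = screened, n_subsets = length(subsets), ptab = ptab)
    })
    for (e in valid_envs) {
      for (a in config$alphas) {
        key <- paste(method, e, format(a), sep = "|")
        grid[[key]] <- if (inherits(prep, "icp_cell_error")) prep else {
          cell_or_error(icp_from_table(prep$ptab, e, a, method,
                                       prep$screened, prep$n_subsets,
                                       seed = config$seed))
        }
      }
    }
  }
  structure(
    list(grid = grid, screening = screening,
         config = c(config, list(hash = config_hash(config))),
         version = as.character(utils::packageVersion("icpbin")),
         seed = config$seed),
    class = "icp_study"
  )
}

report_cell_text <- function(cell) {
  if (inherits(cell, "icp_cell_error")) return("!")
  switch(cell$status,
    model_rejected = "-",
    empty_by_intersection = "None",
    paste(cell$estimated_set, collapse = ", "))
}

#' Render a study report
#'
#' `"markdown"` renders the method x environment x alpha matrix in the
#' style of the study's results table: a named set for a non-empty
#' estimate, `None` when subsets were accepted but intersect to the empty
#' set, and `-` when no subset was accepted (model rejected). `"tsv"`
#' gives the long-format grid; `"json"` the full structured report.
#' Output is deterministic byte-for-byte given the report.
#'
#' @param report an `icp_study`.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return A character scalar (single string) containing the serialized
#'   report.
#' @export
render_report <- function(report, format = c("tsv", "json", "markdown")) {
  stopifnot(inherits(report, "icp_study"))
  if (!is.character(format) || !all(format %in% c("tsv", "json", "markdown"))) {
    stopf("unknown format", class = "icpbin_argument_error")
  }
  format <- match.arg(format)
  cfg <- report$config
  keys <- expand.grid(alpha = cfg$alphas, env = unique(vapply(
    strsplit(names(report$grid), "|", fixed = TRUE), `[[`, "", 2)),
    method = cfg$methods, stringsAsFactors = FALSE)
  if (format == "tsv") {
    rows <- lapply(names(report$grid), function(k) {
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      cell <- report$grid[[k]]
      err <- inherits(cell, "icp_cell_error")
      data.frame(method = parts[1], env = parts[2], alpha = parts[3],
                 status = if (err) "error" else cell$status,
                 estimated_set = if (err) "" else
                   paste(cell$estimated_set, collapse = ","),
                 n_accepted = if (err) NA_integer_ else
                   length(cell$accepted_sets),
                 n_subsets = if (err) NA_integer_ else cell$n_subsets_tested,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  if (format == "json") {
    obj <- list(
      version = report$version, seed = report$seed,
      config = report$config,
      screening = lapply(report$screening, unclass),
      grid = lapply(report$grid, function(cell) {
        if (inherits(cell, "icp_cell_error")) return(list(error = cell$error))
        list(method = cell$method, env = cell$env_name, alpha = cell$alpha,
             status = cell$status, estimated_set = cell$estimated_set,
             n_accepted = length(cell$accepted_sets),
             n_subsets_tested = cell$n_subsets_tested)
      })
    )
    return(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  }
  # markdown
  envs <- unique(keys$env)
  acol <- paste0("alpha<", format(cfg$alphas))
  lines <- c(
    paste0("| Method | Environment | ", paste(acol, collapse = " | "), " |"),
    paste0(paste(rep("|---", 2 + length(cfg$alphas)), collapse = ""), "|")
  )
  for (m in cfg$methods) {
    for (e in envs) {
      cells <- vapply(cfg$alphas, function(a) {
        report_cell_text(report$grid[[paste(m, e, format(a), sep = "|")]])
      }, "")
      lines <- c(lines, paste0("| ", m, " | ", e, " | ",
                               paste(cells, collapse = " | "), " |"))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.icp_study <- function(x, ...) {
  cat(sprintf("<icp_study> %d grid cells (version %s, seed %d)\n",
              length(x$grid), x$version, x$seed))
  notes <- Filter(nzchar, vapply(x$screening, function(s) {
    if (nzchar(s$note %||% "")) sprintf("%s: %s", s$env_name, s$note) else ""
  }, ""))
  if (length(notes)) cat("  screening notes:\n",
                         paste0("   - ", notes, collapse = "\n"), "\n")
  cat(render_report(x, "markdown"))
  invisible(x)
}
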