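# Configuration files and result tables. Everything is plain text: YAML/JSON
# configs in, CSV tables out, byte-identical under identical inputs.

#' Load a study configuration from YAML or JSON
#'
#' Any key left out falls back to the package default: the shipped
#' population model, the nine-cell design grid, 1000 replications.
#' Recognized keys: `population_model` (inline, or a path to a model YAML),
#' `conditions` (list of `{ng, small, large}`), `replications`,
#' `root_seed`, `control` (`tol`, `maxit`, `restarts`).
#'
#' @param path File path, or `NULL` for the full default configuration.
#' @return A [study_config()].
#' @export
load_config <- function(path = NULL) {
  y <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    y <- if (grepl("\\.json$", path)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(y)) y <- list()
  }
  spec <- if (is.null(y$population_model)) {
    default_mlgm_spec()
  } else if (is.character(y$population_model)) {
    read_mlgm_spec(y$population_model)
  } else {
    pm <- y$population_model
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(pm, tf)
    tryCatch(read_mlgm_spec(tf), error = function(e) {
      stop("invalid `population_model`: ", conditionMessage(e), call. = FALSE)
    })
  }
  conditions <- if (is.null(y$conditions)) default_conditions() else {
    lapply(y$conditions, function(cc) {
      tryCatch(design_condition(cc$ng, cc$small, cc$large, cc$label),
               error = function(e) {
                 stop("invalid `conditions` entry: ", conditionMessage(e),
                      call. = FALSE)
               })
    })
  }
  ctrl <- y$control %||% list()
  study_config(
    spec = spec,
    conditions = conditions,
    replications = y$replications %||% 1000L,
    root_seed = y$root_seed %||% 20260101L,
    control = fit_control(
      tol = ctrl$tol %||% 1e-6,
      maxit = ctrl$maxit %||% 500L,
      restarts = ctrl$restarts %||% 1L
    )
  )
}

#' Save a study configuration
#'
#' Round-trips through [load_config()].
#'
#' @param config A [study_config()].
#' @param path Output path (`.yaml` or `.json`).
#' @export
save_config <- function(config, path) {
  lt <- function(m) as.numeric(m[lower.tri(m, diag = TRUE)])
  sp <- config$spec
  y <- list(
    population_model = list(
      time_codes = sp$basis$time_codes,
      degree = sp$basis$degree,
      alpha_between = sp$between$latent_mean,
      phi_between = lt(sp$between$latent_cov),
      theta_between = sp$between$residual_var,
      phi_within = lt(sp$within$latent_cov),
      theta_within = sp$within$residual_var
    ),
    conditions = lapply(config$conditions, function(cc) {
      list(ng = cc$n_groups, small = cc$small_size, large = cc$large_size,
           label = cc$label)
    }),
    replications = config$replications,
    root_seed = config$root_seed,
    control = config$control
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(y, path)
  }
  invisible(path)
}

#' Write descriptive and sensitivity tables
#'
#' Produces four CSVs in `out_dir`: `summary_table.csv` (rows = index x
#' {Mean, SD}, one column per design cell, chi-squares shown to 2 decimals
#' and all other indices to 3), `summary_table_full.csv` (same layout at
#' full precision), `eta_squared.csv` and `convergence.csv`.
#'
#' @param summary Output of [summarize_study()].
#' @param eta Output of [eta_squared_table()] (optional).
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written.
#' @export
write_summary_tables <- function(summary, eta = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary$summary
  cells <- unique(s$condition)
  cols <- index_names()
  missing <- setdiff(cells, s$condition)
  wide <- function(fmt) {
    rows <- list()
    for (ix in cols) {
      for (stat in c("Mean", "SD")) {
        vals <- vapply(cells, function(cc) {
          v <- s[s$index == ix & s$condition == cc, ]
          if (nrow(v) != 1L) stop("missing cell ", cc, " for ", ix, call. = FALSE)
          if (stat == "Mean") v$mean else v$sd
        }, 0)
        digits <- if (startsWith(ix, "chi2")) 2L else 3L
        rows[[length(rows) + 1L]] <- data.frame(
          fit_index = ix, stat = stat,
          t(if (fmt) round(vals, digits) else vals),
          check.names = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    names(out)[-(1:2)] <- cells
    out
  }
  paths <- character()
  f1 <- file.path(out_dir, "summary_table.csv")
  utils::write.csv(format(wide(TRUE), trim = TRUE, scientific = FALSE), f1,
                   row.names = FALSE, quote = FALSE)
  f2 <- file.path(out_dir, "summary_table_full.csv")
  utils::write.csv(wide(FALSE), f2, row.names = FALSE, quote = FALSE)
  f3 <- file.path(out_dir, "convergence.csv")
  utils::write.csv(summary$convergence, f3, row.names = FALSE, quote = FALSE)
  paths <- c(f1, f2, f3)
  if (!is.null(eta)) {
    f4 <- file.path(out_dir, "eta_squared.csv")
    utils::write.csv(eta, f4, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f4)
  }
  paths
}

#' Write the per-replication table
#'
#' @param tab Replication table from [run_study()].
#' @param path Output CSV path.
#' @export
write_replications_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
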