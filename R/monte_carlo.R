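# Seeded study driver: the 3 x 3 design grid with independent, reproducible
# replications, Table-style descriptive summaries and ANOVA eta-squared.

#' Study configuration
#'
#' @param spec Population model ([mlgm_spec()]); defaults to
#'   [default_mlgm_spec()].
#' @param conditions List of [design_condition()]s; defaults to the
#'   nine-cell grid of [default_conditions()].
#' @param replications Replications per cell.
#' @param root_seed Single root seed; every replication's seed is derived
#'   from it (see [spawn_seed()]).
#' @param control Optimizer settings ([fit_control()]).
#' @return A `study_config` list.
#' @export
study_config <- function(spec = default_mlgm_spec(),
                         conditions = default_conditions(),
                         replications = 1000L,
                         root_seed = 20260101L,
                         control = fit_control()) {
  stopifnot(inherits(spec, "mlgm_spec"), replications >= 1)
  for (cond in conditions) stopifnot(inherits(cond, "design_condition"))
  structure(
    list(spec = spec, conditions = conditions,
         replications = as.integer(replications),
         root_seed = as.integer(root_seed), control = control),
    class = "study_config"
  )
}

#' Deterministic child seed for one replication
#'
#' Counter-based spawn: mixes the root seed, the condition index and the
#' replication index through a multiplicative-congruential step modulo the
#' prime 2147483629, so every (condition, replication) pair gets a
#' reproducible seed below 2^31 independent of all the others.
#'
#' @param root_seed Root seed.
#' @param condition_index 1-based condition index.
#' @param replication 1-based replication index.
#' @return An integer seed.
#' @export
spawn_seed <- function(root_seed, condition_index, replication) {
  m <- 2147483629
  h <- as.numeric(root_seed) %% m
  h <- (h * 69069 + 1 + as.numeric(condition_index)) %% m
  h <- (h * 69069 + 1 + as.numeric(replication)) %% m
  as.integer(h + 1)
}

#' Run the Monte Carlo study
#'
#' For each condition and replication: simulate a dataset, compress it to
#' sufficient statistics, fit the template catalog, and record the 20 fit
#' indices. Fully deterministic given `config$root_seed`.
#'
#' @param config A [study_config()].
#' @param reps Optional override of `config$replications` (for scaled-down
#'   runs).
#' @param conditions Optional subset of condition labels to run.
#' @param progress If `TRUE`, prints one line per condition.
#' @return A long data.frame: `condition`, `ng`, `gs`, `replication`,
#'   `seed`, `converged`, `n_total`, then the 20 index columns of
#'   [index_names()].
#' @export
run_study <- function(config, reps = NULL, conditions = NULL, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  reps <- as.integer(reps %||% config$replications)
  conds <- config$conditions
  keep <- if (is.null(conditions)) seq_along(conds) else {
    match(conditions, vapply(conds, `[[`, "", "label"))
  }
  basis <- config$spec$basis
  cols <- index_names()
  rows <- vector("list", length(keep) * reps)
  k <- 0L
  for (ci in keep) {
    cond <- conds[[ci]]
    if (progress) {
      message(sprintf("condition %s: %d replications", cond$label, reps))
    }
    for (r in seq_len(reps)) {
      seed <- spawn_seed(config$root_seed, ci, r)
      ds <- simulate_dataset(config$spec, cond, seed)
      fis <- compute_fit_indices(ds, basis, config$control)
      k <- k + 1L
      rows[[k]] <- data.frame(
        condition = cond$label,
        ng = cond$n_groups,
        gs = sprintf("%d/%d", cond$small_size, cond$large_size),
        replication = r,
        seed = seed,
        converged = fis$converged_all,
        n_total = fis$n_total,
        as.data.frame(fis$indices[cols]),
        check.names = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Re-run a single replication in isolation
#'
#' Rebuilds the exact dataset of one study replication from the root seed
#' and returns its full [compute_fit_indices()] result, fitted models
#' included.
#'
#' @param config The [study_config()] of the original run.
#' @param condition Condition label.
#' @param replication Replication number.
#' @return A `fit_index_set`.
#' @export
replay_replication <- function(config, condition, replication) {
  labels <- vapply(config$conditions, `[[`, "", "label")
  ci <- match(condition, labels)
  if (is.na(ci)) stop("unknown condition label: ", condition, call. = FALSE)
  seed <- spawn_seed(config$root_seed, ci, replication)
  ds <- simulate_dataset(config$spec, config$conditions[[ci]], seed)
  compute_fit_indices(ds, config$spec$basis, config$control)
}

#' Descriptive summary of a study run
#'
#' Condition-wise means and sample standard deviations (divisor n - 1) of
#' every index over converged replications, plus per-condition convergence
#' rates.
#'
#' @param tab Replication table from [run_study()].
#' @return List with `summary` (condition, index, mean, sd, n_converged)
#'   and `convergence` (condition, rate, n).
#' @export
summarize_study <- function(tab) {
  cols <- index_names()
  conds <- unique(tab$condition)
  out <- list()
  conv <- data.frame(condition = conds, rate = NA_real_, n = NA_integer_)
  for (i in seq_along(conds)) {
    sub <- tab[tab$condition == conds[i], , drop = FALSE]
    conv$rate[i] <- mean(sub$converged)
    conv$n[i] <- nrow(sub)
    ok <- sub[sub$converged, , drop = FALSE]
    if (nrow(ok) < 2L) stop("fewer than two converged replications in cell ",
                            conds[i], call. = FALSE)
    out[[i]] <- data.frame(
      condition = conds[i],
      index = cols,
      mean = vapply(cols, function(cl) mean(ok[[cl]]), 0),
      sd = vapply(cols, function(cl) stats::sd(ok[[cl]]), 0),
      n_converged = nrow(ok),
      row.names = NULL
    )
  }
  list(summary = do.call(rbind, out), convergence = conv)
}

#' ANOVA eta-squared of the design factors
#'
#' Fixed-effects two-factor ANOVA of one index on number-of-groups and
#' group-size factors (with interaction); eta-squared for a term is its
#' sum of squares over the corrected total. With the balanced default grid
#' the sequential and Type III decompositions coincide; with unequal cell
#' counts a warning is issued and the sequential decomposition is reported.
#'
#' @param tab Replication table from [run_study()].
#' @param index_name One of [index_names()].
#' @return List with `eta2_ng`, `eta2_gs`, `eta2_interaction`.
#' @export
eta_squared <- function(tab, index_name) {
  stopifnot(index_name %in% names(tab))
  ok <- tab[tab$converged, , drop = FALSE]
  counts <- table(ok$ng, ok$gs)
  if (length(unique(as.vector(counts))) != 1L) {
    warning("unequal cell counts: sequential sums of squares are order-dependent")
  }
  d <- data.frame(
    y = ok[[index_name]],
    ng = factor(ok$ng),
    gs = factor(ok$gs)
  )
  ss <- summary(stats::aov(y ~ ng * gs, data = d))[[1]][["Sum Sq"]]
  total <- sum(ss)
  list(eta2_ng = ss[1] / total, eta2_gs = ss[2] / total,
       eta2_interaction = ss[3] / total)
}

#' Eta-squared table over all indices
#'
#' @param tab Replication table from [run_study()].
#' @return data.frame with one row per index: `eta2_ng`, `eta2_gs`,
#'   `eta2_interaction`.
#' @export
eta_squared_table <- function(tab) {
  cols <- index_names()
  rows <- lapply(cols, function(cl) {
    e <- eta_squared(tab, cl)
    data.frame(index = cl, eta2_ng = e$eta2_ng, eta2_gs = e$eta2_gs,
               eta2_interaction = e$eta2_interaction)
  })
  do.call(rbind, rows)
}

#' Flag practically influential design factors
#'
#' A factor is influential for an index when its eta-squared reaches the
#' moderate-effect threshold 0.0588 and the index actually varies: indices
#' whose pooled standard deviation (root mean square of the cell SDs) is
#' below `sd_floor` are exempt, because design factors cannot matter for a
#' quantity that is essentially constant.
#'
#' @param eta_tab Output of [eta_squared_table()].
#' @param summary Output of [summarize_study()].
#' @param threshold Eta-squared threshold (default 0.0588).
#' @param sd_floor Low-variability override (default 0.005).
#' @return data.frame with one row per index and factor:
#'   `eta2`, `pooled_sd`, `influential`.
#' @export
flag_influential <- function(eta_tab, summary, threshold = 0.0588,
                             sd_floor = 0.005) {
  s <- summary$summary
  pooled <- vapply(eta_tab$index, function(cl) {
    sqrt(mean(s$sd[s$index == cl]^2))
  }, 0)
  long <- rbind(
    data.frame(index = eta_tab$index, factor = "NG", eta2 = eta_tab$eta2_ng),
    data.frame(index = eta_tab$index, factor = "GS", eta2 = eta_tab$eta2_gs),
    data.frame(index = eta_tab$index, factor = "NG:GS",
               eta2 = eta_tab$eta2_interaction)
  )
  long$pooled_sd <- pooled[long$index]
  long$influential <- long$eta2 >= threshold & long$pooled_sd >= sd_floor
  rownames(long) <- NULL
  long
}
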