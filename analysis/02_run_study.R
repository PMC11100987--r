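#!/usr/bin/env Rscript
# Step 2 — the Monte Carlo study.
#
# Runs the full 3 (number of groups: 50/100/200) x 3 (unbalanced group
# size: 5/15, 10/30, 25/75) grid. Every replication simulates a dataset
# from the population model, compresses it to sufficient statistics, fits
# the eight-model catalog by maximum likelihood, and records the twenty
# level-specific and target-specific fit indices.
#
# The shipped run uses 100 replications per cell (a desk-scale pass; the
# full design uses 1,000) and takes a few minutes on one core. Change
# `reps` below or pass --reps. Everything is reproducible from the single
# root seed.

suppressPackageStartupMessages({
  library(optparse)
  library(mlgmsim)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--reps", type = "integer", default = 100L),
  make_option("--seed", type = "integer", default = 20260101L)
)))

dir.create("results", showWarnings = FALSE)

config <- study_config(root_seed = opts$seed)
cat(sprintf("Running %d conditions x %d replications (root seed %d)...\n",
            length(config$conditions), opts$reps, opts$seed))
t0 <- Sys.time()
tab <- run_study(config, reps = opts$reps, progress = TRUE)
cat(sprintf("done in %.1f min\n", as.numeric(Sys.time() - t0, units = "mins")))

write_replications_csv(tab, "results/replications.csv")

conv <- summarize_study(tab)$convergence
cat("\nConvergence rate by cell:\n")
print(conv)
if (all(conv$rate == 1)) {
  cat("\nEvery replication converged in every cell, matching the expectation\n")
  cat("that this correctly specified model poses no estimation problems even\n")
  cat("at 50 groups of size 5/15.\n")
}
cat("\nWrote results/replications.csv (", nrow(tab), "rows ).\n")
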