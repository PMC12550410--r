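#!/usr/bin/env Rscript
## Extended validation: qualitative trends of estimation accuracy and power
## across study conditions, on a grid of simulated datasets (40 by default).
## This is the long-running companion to scripts/acceptance.R: it checks
## that, across datasets,
##   * median RMSD decreases across terciles of the number of subjects N,
##   * mean p_pos increases with N and with the true effect size,
##   * quadratic gradients show higher RMSD and lower p_pos than
##     directional gradients.
## Expect a runtime of roughly half an hour to an hour at the default size.
##
## usage: Rscript scripts/extended_checks.R [--datasets 40] [--seed 1]
##        [--out results/extended_checks.json]

library(rnselect)

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
n_datasets <- as.integer(get_arg("--datasets", "40"))
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "results/extended_checks.json")
dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)

metrics <- run_validation_study(n_datasets, seed = seed,
                                control = rn_sampler(chains = 2,
                                                     warmup = 300,
                                                     iter = 300),
                                priors = rn_priors(lkj_eta = 5),
                                progress = TRUE)
cat(length(attr(metrics, "failures")), "dataset failures\n")

is_dir <- startsWith(metrics$gradient_name, "beta_")
tercile <- cut(metrics$N, quantile(metrics$N, c(0, 1/3, 2/3, 1)),
               include.lowest = TRUE, labels = c("low", "mid", "high"))
rmsd_by_N <- tapply(metrics$rmsd, tercile, median)
ppos_by_N <- tapply(metrics$p_pos, tercile, mean)
eff_ter <- cut(metrics$true_value,
               quantile(metrics$true_value, c(0, 1/3, 2/3, 1)),
               include.lowest = TRUE, labels = c("low", "mid", "high"))
ppos_by_eff <- tapply(metrics$p_pos, eff_ter, mean)

checks <- list(
  rmsd_decreases_in_N = unname(diff(rmsd_by_N) < 0),
  ppos_increases_in_N = unname(diff(ppos_by_N) > 0),
  ppos_increases_in_effect = unname(diff(ppos_by_eff) > 0),
  quadratic_rmsd_higher = mean(metrics$rmsd[!is_dir]) >
    mean(metrics$rmsd[is_dir]),
  quadratic_ppos_lower = mean(metrics$p_pos[!is_dir]) <
    mean(metrics$p_pos[is_dir]))

trends <- list(
  rmsd_vs_N = as.list(polynomial_trend_summary(metrics, "N", "rmsd")),
  ppos_vs_N = as.list(polynomial_trend_summary(metrics, "N", "p_pos")),
  ppos_vs_effect = as.list(polynomial_trend_summary(metrics, "true_value",
                                                    "p_pos")),
  bias_vs_N = as.list(polynomial_trend_summary(metrics, "N", "bias")))

res <- list(n_datasets = n_datasets, seed = seed,
            rmsd_by_N_tercile = as.list(rmsd_by_N),
            ppos_by_N_tercile = as.list(ppos_by_N),
            ppos_by_effect_tercile = as.list(ppos_by_eff),
            mean_bias_directional = mean(metrics$bias[is_dir]),
            mean_bias_quadratic = mean(metrics$bias[!is_dir]),
            checks = checks, trends = trends)
jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
cat("checks:\n")
for (nm in names(checks))
  cat(sprintf("  %-28s %s\n", nm,
              paste(checks[[nm]], collapse = " ")))
cat("written to", out, "\n")
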