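#!/usr/bin/env Rscript
# Step 3 of the analysis: compare the synthetic empirical SRT
# distributions with the simulated batches, step by step, using 6-ms
# binned histograms, CDFs, R^2, MSE, the first-order Wasserstein
# distance, quantile tables and rank-sum tests.  Reads the tables
# written by analysis steps 1 and 2.
#
#   Rscript analysis/03_compare_distributions.R

suppressPackageStartupMessages(library(sacfield))
dir.create("results", showWarnings = FALSE)

need <- c("results/synthetic_marmoset.csv", "results/synthetic_human.csv",
          "results/sim_marmoset_step1.csv")
if (!all(file.exists(need))) {
  stop("run analysis/01_simulate_species.R and 02_synthetic_behavior.R first")
}

observed <- list(marmoset = read_srt_table("results/synthetic_marmoset.csv"),
                 human = read_srt_table("results/synthetic_human.csv"))

# species contrast on the synthetic data (marmosets faster than humans)
rs <- rank_sum_test(observed$marmoset$srt_ms, observed$human$srt_ms)
cat(sprintf("synthetic marmoset vs human: medians %d vs %d ms, rank-sum p = %.3g\n",
            as.integer(stats::median(observed$marmoset$srt_ms)),
            as.integer(stats::median(observed$human$srt_ms)), rs$p_value))

steps <- list(marmoset = 1:3, human = 1:2)
for (species in names(steps)) {
  for (step in steps[[species]]) {
    path <- sprintf("results/sim_%s_step%d.csv", species, step)
    if (!file.exists(path)) next
    sim <- read_srt_table(path)
    rep <- compare_srt_distributions(observed[[species]]$srt_ms, sim$srt_ms)
    tag <- sprintf("%s_step%d", species, step)
    write_comparison_report(rep,
                            sprintf("results/compare_%s_bins.csv", tag),
                            sprintf("results/compare_%s_summary.cfg", tag))
    cat(sprintf("%-8s step %d vs synthetic: R^2 %6.3f  MSE %.6f  Wasserstein %6.2f ms\n",
                species, step, rep$r_squared, rep$mse, rep$wasserstein_ms))
  }
}

# headline contrast of the modification sequence: Wasserstein improvement
# from step 1 to the final marmoset step
s1 <- sprintf("results/compare_marmoset_step1_summary.cfg")
s3 <- sprintf("results/compare_marmoset_step3_summary.cfg")
if (file.exists(s1) && file.exists(s3)) {
  w1 <- read_config(s1)$wasserstein_ms
  w3 <- read_config(s3)$wasserstein_ms
  cat(sprintf("marmoset Wasserstein distance: step 1 %.1f ms -> step 3 %.1f ms (ratio %.2f)\n",
              w1, w3, w1 / w3))
}
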