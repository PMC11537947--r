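#!/usr/bin/env Rscript
# Step 2 of the analysis: generate the synthetic empirical-like SRT
# datasets (the stand-in for behavioral recordings), estimate the
# anticipatory boundary from landing points, classify saccades, and
# write the tables under results/.
#
#   Rscript analysis/02_synthetic_behavior.R [n] [seed]

suppressPackageStartupMessages(library(sacfield))
args <- commandArgs(trailingOnly = TRUE)
n <- if (length(args) >= 1) as.integer(args[1]) else 10000L
seed <- if (length(args) >= 2) as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

for (species in c("marmoset", "human")) {
  spec <- generator_spec(species, n = n)
  s <- generate_species_srts(spec, seed = seed)
  s$category <- as.character(classify_saccades(s$srt_ms, species))
  out <- sprintf("results/synthetic_%s.csv", species)
  write_srt_table(s, out)
  counts <- table(s$category)
  v <- s$srt_ms
  cat(sprintf("%s (n = %d): median %d ms, min %d ms, %.2f%% over 250 ms\n",
              species, n, as.integer(stats::median(v)), min(v),
              100 * fraction_exceeding(v, 250)))
  cat("  categories:",
      paste(sprintf("%s %d", names(counts), counts), collapse = ", "), "\n")
  write_manifest(sprintf("results/synthetic_%s_manifest.cfg", species),
                 command = "synthesize_srts", seed = seed, outputs = out,
                 extra = list(species = species, n = n))
}

# landing-point dataset and anticipatory-boundary estimate (marmoset)
land_spec <- generator_spec("marmoset", n = n,
                            anticipatory_boundary_ms = 60)
land <- generate_landing_data(land_spec, seed = seed + 1)
write_srt_table(land, "results/synthetic_marmoset_landing.csv")
est <- estimate_anticipatory_boundary(land$srt_ms, land$correct)
cat(sprintf("anticipatory boundary: configured 60 ms, estimated %d ms (%s)\n",
            as.integer(est$boundary_ms), est$flag))
write_manifest("results/synthetic_marmoset_landing_manifest.cfg",
               command = "synthesize_landing", seed = seed + 1,
               outputs = "results/synthetic_marmoset_landing.csv",
               extra = list(boundary_configured_ms = 60,
                            boundary_estimated_ms = est$boundary_ms))
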