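#!/usr/bin/env Rscript
# Step 1 — generate the synthetic docking benchmark.
#
# Emulates a repeated-run docking study: 300 ligand instances docked by a
# 12-configuration portfolio, 50 stochastic runs per (ligand, algorithm)
# pair, with four planted instance clusters whose best algorithms differ
# (the complementarity a per-instance selector exploits), descriptor-like
# features that encode cluster membership, and 881-bit fingerprints.

library(dockselect)

seed <- 1L
out <- "results/benchmark"
bench <- generate_benchmark(synthetic_config(run_noise_sd = 0.1, seed = seed))
write_benchmark(bench, out)

cat("instances:        ", bench$config$n_instances, "\n")
cat("algorithms:       ", bench$config$n_algorithms, "\n")
cat("runs per pair:    ", bench$config$n_runs, "\n")
cat("run records:      ", nrow(bench$run_records), "\n")
cat("descriptor table: ", paste(dim(bench$descriptor_features), collapse = " x "), "\n")
cat("fingerprint table:", paste(dim(bench$fingerprint_features), collapse = " x "), "\n")
cat("planted winners:  ",
    paste(unique(bench$truth$winner), collapse = ", "), "\n")
cat("written to", out, "\n")
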