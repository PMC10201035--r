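#!/usr/bin/env Rscript
# Step 3 — aggregate docking runs and rank the standalone algorithms.
#
# Builds the AVG (mean over runs) and BEST (minimum over runs) performance
# matrices, rank-transforms each row (rank 1 = lowest binding energy,
# average ties), and writes the per-algorithm mean +/- SD rank league
# table for both aggregation modes.

library(dockselect)

rec <- read_run_records("results/benchmark/run_records.tsv")

for (mode in c("AVG", "BEST")) {
  perf <- aggregate_runs(rec, mode)
  ranks <- rank_transform(perf)
  stopifnot(all(abs(rowSums(ranks) - ncol(ranks) * (ncol(ranks) + 1) / 2) < 1e-9))
  league <- summarize_mean_ranks(ranks)
  league <- league[order(league$mean_rank), ]
  write_matrix_csv(perf, sprintf("results/perf_%s.csv", tolower(mode)))
  write.csv(league, sprintf("results/standalone_ranks_%s.csv", tolower(mode)),
            row.names = FALSE)
  cat("\n", mode, " league table (top 5 of ", ncol(perf), "):\n", sep = "")
  print(head(league, 5), row.names = FALSE)
}
cat("\nwritten to results/perf_{avg,best}.csv and results/standalone_ranks_{avg,best}.csv\n")
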