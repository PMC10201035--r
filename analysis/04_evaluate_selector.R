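#!/usr/bin/env Rscript
# Step 4 — tenfold cross-validated selector evaluation.
#
# Fits the ALORS-style selector (rank-5 SVD of the rank matrix + a
# 100-tree random-forest regression from features to instance latent
# factors) fold by fold, selects one algorithm per held-out instance, and
# ranks every method — 12 standalone algorithms, the selector, the
# single-best solver, the virtual-best solver and a uniform-random picker
# — on a shared joint-rank scale. Repeats the evaluation for the AVG and
# BEST aggregation modes and compares descriptor, fingerprint and
# combined feature sets on AVG.

library(dockselect)

seed <- 1L
rec <- read_run_records("results/benchmark/run_records.tsv")
md <- read_feature_csv("results/benchmark/descriptors.csv", kind = "md")
sf <- read_feature_csv("results/benchmark/fingerprints.csv", kind = "sf")
truth <- read.csv("results/benchmark/truth.csv")
cfg <- selector_config(k = 5, n_trees = 100, seed = seed)

perf_avg <- aggregate_runs(rec, "AVG")
folds <- kfold_split(rownames(perf_avg), 10, seed = seed)

for (mode in c("AVG", "BEST")) {
  perf <- aggregate_runs(rec, mode)
  rep <- evaluate_selector(perf, md, cfg, folds)
  acc <- mean(rep$selections$chosen == truth$winner)
  s <- rep$summary
  cat("\n==", mode, "mode ==\n")
  cat("selection accuracy vs planted winners:", round(acc, 3), "\n")
  meta <- s[s$method %in% c("ALORS", "SBS", "VBS", "random"), ]
  print(meta, row.names = FALSE)
  write_evaluation_csv(rep, sprintf("results/evaluation_%s.csv", tolower(mode)))
}

# feature-set comparison (AVG mode, shared folds)
cat("\n== feature-set comparison (AVG) ==\n")
model_full <- local({
  feats <- apply_minmax(md, fit_minmax(md))
  fit_selector(feats, rank_transform(perf_avg), cfg)
})
imp <- feature_importance(model_full)
scores <- setNames(imp$gini, imp$feature)
sets <- list(
  md = md,
  md_top4 = select_top_features(md, scores, list(top_n = 4)),
  sf = sf,
  md_top4_plus_sf = combine_feature_sets(
    select_top_features(md, scores, list(top_n = 4)), sf)
)
cmp <- compare_feature_sets(perf_avg, sets, cfg, folds)
print(cmp, row.names = FALSE)
write.csv(cmp, "results/feature_set_comparison.csv", row.names = FALSE)
cat("\nwritten to results/evaluation_{avg,best}.csv and results/feature_set_comparison.csv\n")
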