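#!/usr/bin/env Rscript
# Step 5 — landscape analyses on the fitted selector.
#
# Post-hoc views of the algorithm and instance spaces: Gini feature
# importance of the selector's forests, hierarchical clustering of the
# algorithms in the SVD latent space (AVG mode) with similarity-based
# portfolio reduction, 2-D PCA/t-SNE instance embeddings, and a
# silhouette-guided k-means scan of the instance space with per-cluster
# feature profiles.

library(dockselect)

seed <- 1L
rec <- read_run_records("results/benchmark/run_records.tsv")
md <- read_feature_csv("results/benchmark/descriptors.csv", kind = "md")
perf <- aggregate_runs(rec, "AVG")
ranks <- rank_transform(perf)
feats <- apply_minmax(md, fit_minmax(md))
cfg <- selector_config(k = 5, n_trees = 100, seed = seed)
model <- fit_selector(feats, ranks, cfg)

## Gini importance
imp <- feature_importance(model)
write.csv(imp, "results/feature_importance.csv", row.names = FALSE)
cat("top features by Gini importance:\n")
print(head(imp, 9), row.names = FALSE)
n15 <- sum(imp$gini >= 0.15)
cat("features above the 0.15 cutoff:", n15, "\n")

## algorithm similarity and portfolio reduction
latent <- factorize(ranks, cfg$k)
hc <- cluster_algorithms(latent)
merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                     height = hc$height)
write.csv(merges, "results/algorithm_linkage.csv", row.names = FALSE)
mr <- setNames(colMeans(ranks), colnames(ranks))
sub19 <- reduce_portfolio(hc, mr, "lowest_pairs")
sub9 <- reduce_portfolio(hc, mr, "one_higher")
cat("\nportfolio reduction (", ncol(perf), "algorithms ):\n")
cat("  lowest-pair cut ->", length(sub19), "kept:",
    paste(sub19, collapse = ", "), "\n")
cat("  one level higher ->", length(sub9), "kept:",
    paste(sub9, collapse = ", "), "\n")

## instance-space embedding and clustering on the top informative features
top9 <- select_top_features(feats, setNames(imp$gini, imp$feature),
                            list(top_n = 9))
for (method in c("pca", "tsne")) {
  emb <- embed_instances(top9, method, seed = seed)
  write.csv(data.frame(instance_id = rownames(emb), emb),
            sprintf("results/embedding_%s.csv", method), row.names = FALSE)
}
clus <- cluster_instances(top9, 2:15, seed = seed)
cat("\nsilhouette scan over k in [2, 15]: best k =", clus$best_k, "\n")
write.csv(clus$silhouette, "results/silhouette_scan.csv", row.names = FALSE)
prof <- cluster_profiles(top9, clus$labels)
write.csv(prof, "results/cluster_profiles.csv", row.names = FALSE)
cat("cluster sizes:", paste(table(clus$labels), collapse = ", "), "\n")
cat("\nwritten landscape outputs under results/\n")
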