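test_that("importances are a normalized descending report and recover planted signal", {
  b <- cached_benchmark(small_cfg(seed = 5, run_noise_sd = 0.1))
  ranks <- rank_transform(aggregate_runs(b$run_records, "AVG"))
  feats <- apply_minmax(b$descriptor_features, fit_minmax(b$descriptor_features))
  model <- fit_selector(feats, ranks, selector_config(k = 4, n_trees = 50, seed = 5))
  imp <- feature_importance(model)
  expect_true(all(imp$gini >= 0))
  expect_equal(sum(imp$gini), 1)
  expect_true(all(diff(imp$gini) <= 1e-12))
  # the informative block dominates the top of the report
  expect_true(all(grepl("^inf", imp$feature[1:4])))
  expect_error(feature_importance(list()), "selector_model")
})

test_that("identical rank columns merge first in algorithm clustering", {
  vals <- cbind(A1 = c(-9, -8, -7, -6), A2 = c(-9, -8, -7, -6),
                A3 = c(-5, -4, -9.5, -3))
  rownames(vals) <- sprintf("i%d", 1:4)
  ranks <- rank_transform(performance_matrix(vals, "AVG"))
  lm <- factorize(ranks, 3)
  hc <- cluster_algorithms(lm)
  expect_s3_class(hc, "hclust")
  expect_equal(nrow(hc$merge), 2L)
  expect_true(all(diff(hc$height) >= -1e-12))
  # A1 and A2 have identical columns: factors coincide, first merge at 0
  expect_equal(sort(-hc$merge[1, ]), c(1, 2))
  expect_equal(hc$height[1], 0, tolerance = 1e-10)
  expect_error(cluster_algorithms(lm$algorithm_factors[1, , drop = FALSE]),
               "at least 2")
})

test_that("clustering is invariant to latent sign flips", {
  ranks <- rank_transform(random_perf(20, 6, seed = 31))
  lm <- factorize(ranks, 4)
  hc1 <- cluster_algorithms(lm)
  flipped <- lm
  flipped$algorithm_factors <- lm$algorithm_factors %*% diag(c(1, -1, 1, -1))
  flipped$instance_factors <- lm$instance_factors %*% diag(c(1, -1, 1, -1))
  hc2 <- cluster_algorithms(flipped)
  # distances (hence merge heights) are preserved under column sign flips
  expect_equal(hc1$height, hc2$height, tolerance = 1e-10)
})

test_that("portfolio reduction keeps one representative per similarity cluster", {
  vals <- cbind(A1 = c(-9, -8, -7), A2 = c(-9.001, -8.001, -7.001),
                A3 = c(-2, -9.5, -4), A4 = c(-2.01, -9.49, -4.02),
                A5 = c(-6, -2, -9.7))
  rownames(vals) <- sprintf("i%d", 1:3)
  ranks <- rank_transform(performance_matrix(vals, "AVG"))
  hc <- cluster_algorithms(factorize(ranks, 3))
  mr <- setNames(colMeans(ranks), colnames(ranks))
  kept <- reduce_portfolio(hc, mr, "lowest_pairs")
  # {A1,A2} and {A3,A4} are near-duplicates: one survivor each, plus A5
  expect_equal(length(kept), 3L)
  expect_true("A5" %in% kept)
  expect_equal(sum(c("A1", "A2") %in% kept), 1L)
  expect_equal(sum(c("A3", "A4") %in% kept), 1L)
  # representative has the lower mean rank within its pair
  pair1 <- intersect(kept, c("A1", "A2"))
  expect_equal(mr[pair1], min(mr[c("A1", "A2")]), ignore_attr = TRUE)

  # all-singleton case: identity
  far <- rank_transform(random_perf(10, 4, seed = 50))
  hc2 <- cluster_algorithms(factorize(far, 4))
  # force singletons by cutting nothing: heights all > 0 and not paired at 0;
  # lowest_pairs still pairs the two closest leaves, so instead check subset
  kept2 <- reduce_portfolio(hc2, setNames(colMeans(far), colnames(far)))
  expect_true(all(kept2 %in% colnames(far)))
  expect_equal(length(kept2),
               length(unique(dockselect:::linkage_partition(hc2, 1L))))
})

test_that("2-D PCA embedding preserves geometry and separates planted blobs", {
  blobs <- make_blobs(2, per_blob = 25, seed = 3)
  emb <- embed_instances(blobs$x, "pca")
  expect_equal(dim(emb), c(50L, 2L))
  # data already 2-D: PCA is a rigid rotation, distances preserved
  expect_equal(as.numeric(dist(emb)), as.numeric(dist(blobs$x)),
               tolerance = 1e-10)
  pc1 <- emb[, 1]
  between <- abs(mean(pc1[blobs$labels == 1]) - mean(pc1[blobs$labels == 2]))
  within <- max(tapply(pc1, blobs$labels, sd))
  expect_gt(between, 3 * within)
  expect_error(embed_instances(blobs$x[, 1, drop = FALSE], "pca"), "at least 2")
})

test_that("t-SNE embedding is seeded and separates planted blobs", {
  blobs <- make_blobs(2, per_blob = 20, seed = 4)
  e1 <- embed_instances(blobs$x, "tsne", seed = 9)
  e2 <- embed_instances(blobs$x, "tsne", seed = 9)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  d <- as.matrix(dist(e1))
  same <- outer(blobs$labels, blobs$labels, "==")
  diag(same) <- NA
  expect_gt(mean(d[!same & !is.na(same)]), mean(d[same & !is.na(same)]))
})

test_that("silhouette scan recovers planted cluster counts on blobs", {
  b2 <- make_blobs(2, per_blob = 20, seed = 12)
  r2 <- cluster_instances(b2$x, 2:8, seed = 1)
  expect_equal(r2$best_k, 2L)
  expect_gt(max(r2$silhouette$silhouette), 0.7)

  b4 <- make_blobs(4, per_blob = 15, seed = 13)
  r4 <- cluster_instances(b4$x, 2:8, seed = 1)
  expect_equal(r4$best_k, 4L)
  expect_error(cluster_instances(b2$x[1:6, ], 2:8, seed = 1), "more instances")
})

test_that("cluster profiles summarize per-cluster feature distributions", {
  x <- rbind(matrix(1, 5, 3), matrix(rnorm(15, 10), 5, 3))
  dimnames(x) <- list(sprintf("i%d", 1:10), c("f1", "f2", "f3"))
  labels <- rep(1:2, each = 5)
  prof <- cluster_profiles(x, labels)
  # identical rows: zero IQR everywhere in cluster 1
  c1 <- prof[prof$cluster == 1, ]
  expect_equal(c1$q3 - c1$q1, rep(0, 3))
  expect_equal(c1$median, rep(1, 3))

  # single cluster: summaries equal whole-table summaries
  whole <- cluster_profiles(x, rep(1, 10))
  expect_equal(whole$median[whole$feature == "f2"],
               median(x[, "f2"]))

  # medians match a sort-based oracle on random data
  set.seed(77)
  y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  rownames(y) <- sprintf("r%d", 1:20)
  lab <- rep(1:2, 10)
  p <- cluster_profiles(y, lab)
  for (cl in 1:2) for (f in c("a", "b", "c")) {
    v <- sort(y[lab == cl, f])
    med <- unname((v[5] + v[6]) / 2)
    expect_equal(p$median[p$cluster == cl & p$feature == f], med)
  }
})
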