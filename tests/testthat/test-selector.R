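test_that("full-rank factorization reconstructs the rank matrix exactly", {
  r <- rank_matrix_of(matrix(c(-9, -8, -8, -9), 2, byrow = TRUE,
                             dimnames = list(c("i1", "i2"), c("A1", "A2"))))
  lm <- factorize(r, 2)
  expect_equal(lm$instance_factors %*% t(lm$algorithm_factors),
               unclass(r), tolerance = 1e-12, ignore_attr = TRUE)

  ranks <- rank_transform(random_perf(12, 5, seed = 3))
  lmf <- factorize(ranks, 5)
  expect_equal(lmf$instance_factors %*% t(lmf$algorithm_factors),
               unclass(ranks), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(lmf$singular_values) <= 1e-12))
  expect_true(all(lmf$singular_values >= 0))
  expect_error(factorize(ranks, 6), "k must")
  expect_error(factorize(ranks, 0), "k must")
})

test_that("truncation error matches an eigenvalue-based oracle on random matrices", {
  for (s in 1:5) {
    ranks <- rank_transform(random_perf(30, 8, seed = 100 + s))
    k <- 3
    lm <- factorize(ranks, k)
    recon <- lm$instance_factors %*% t(lm$algorithm_factors)
    err <- sqrt(sum((unclass(ranks) - recon)^2))
    # independent oracle: tail eigenvalues of the Gram matrix
    ev <- sort(eigen(crossprod(unclass(ranks)), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    oracle <- sqrt(sum(pmax(ev[(k + 1):8], 0)))
    expect_equal(err, oracle, tolerance = 1e-8)
  }
})

test_that("factor sign flips leave the reconstruction product unchanged", {
  ranks <- rank_transform(random_perf(10, 4, seed = 7))
  lm <- factorize(ranks, 3)
  flip <- diag(c(1, -1, -1))
  prod1 <- lm$instance_factors %*% t(lm$algorithm_factors)
  prod2 <- (lm$instance_factors %*% flip) %*% t(lm$algorithm_factors %*% flip)
  expect_equal(prod1, prod2, tolerance = 1e-12)
})

test_that("an oracle lookup regressor reproduces true rank rows at full rank", {
  ranks <- rank_transform(random_perf(15, 6, seed = 21))
  lm <- factorize(ranks, 6)
  model <- structure(list(
    regressor = lookup_regressor(lm$instance_factors),
    algorithm_factors = lm$algorithm_factors,
    feature_names = c("f1", "f2"),
    algorithm_ids = colnames(ranks),
    train_mean_ranks = colMeans(ranks),
    config = selector_config(k = 6)
  ), class = "selector_model")
  x <- matrix(0, 15, 2, dimnames = list(rownames(ranks), c("f1", "f2")))
  sc <- predict_ranks(model, x)
  expect_equal(unname(sc), unname(unclass(ranks)), tolerance = 1e-10,
               ignore_attr = TRUE)
  sp <- sapply(seq_len(15), function(i)
    cor(sc[i, ], unclass(ranks)[i, ], method = "spearman"))
  expect_equal(unname(sp), rep(1, 15))
})

test_that("selection takes the argmin and breaks ties by train mean rank then order", {
  model <- structure(list(
    regressor = lookup_regressor(matrix(1, 1, 1, dimnames = list("i1", NULL))),
    algorithm_factors = matrix(c(2.1, 1.3, 3.0), 3, 1),
    feature_names = "f1",
    algorithm_ids = c("A1", "A2", "A3"),
    train_mean_ranks = c(A1 = 2, A2 = 2, A3 = 2),
    config = selector_config(k = 1)
  ), class = "selector_model")
  x <- matrix(0, 1, 1, dimnames = list("i1", "f1"))
  expect_equal(as.numeric(predict_ranks(model, x)), c(2.1, 1.3, 3.0))
  expect_equal(unname(select_algorithm(model, x)), "A2")

  # exact tie: lower train mean rank wins
  model$algorithm_factors <- matrix(c(1.0, 1.0, 3.0), 3, 1)
  model$train_mean_ranks <- c(A1 = 5.0, A2 = 3.0, A3 = 1.0)
  expect_equal(unname(select_algorithm(model, x)), "A2")
  # tie on mean rank too: portfolio order
  model$train_mean_ranks <- c(A1 = 3.0, A2 = 3.0, A3 = 1.0)
  expect_equal(unname(select_algorithm(model, x)), "A1")

  # selection invariant under positive rescaling of scores
  model2 <- model; model2$algorithm_factors <- model$algorithm_factors * 10
  expect_equal(select_algorithm(model2, x), select_algorithm(model, x))
})

test_that("fitted selector recovers training structure on low-noise data", {
  b <- cached_benchmark(small_cfg(seed = 2, run_noise_sd = 0.1))
  ranks <- rank_transform(aggregate_runs(b$run_records, "AVG"))
  feats <- apply_minmax(b$descriptor_features, fit_minmax(b$descriptor_features))
  model <- fit_selector(feats, ranks, selector_config(k = 5, n_trees = 50, seed = 3))
  sc <- predict_ranks(model, unclass(feats))
  sp <- sapply(seq_len(nrow(sc)), function(i)
    cor(sc[i, ], unclass(ranks)[i, ], method = "spearman"))
  expect_gte(mean(sp), 0.9)

  # identical feature rows => identical predictions
  same <- matrix(0.5, 4, ncol(feats),
                 dimnames = list(sprintf("s%d", 1:4), colnames(feats)))
  scs <- predict_ranks(model, same)
  expect_equal(scs[1, ], scs[2, ])
  expect_equal(scs[1, ], scs[4, ])
})

test_that("prediction beats a shuffled-feature control on held-out structure", {
  b <- cached_benchmark(small_cfg(seed = 2, run_noise_sd = 0.1))
  ranks <- rank_transform(aggregate_runs(b$run_records, "AVG"))
  feats <- apply_minmax(b$descriptor_features, fit_minmax(b$descriptor_features))
  cfg <- selector_config(k = 5, n_trees = 50, seed = 3)
  model <- fit_selector(feats, ranks, cfg)
  set.seed(99)
  shuf <- unclass(feats)[sample(nrow(feats)), , drop = FALSE]
  rownames(shuf) <- rownames(feats)
  model_shuf <- fit_selector(dockselect:::as_feature_table(shuf, feats), ranks, cfg)
  sp_of <- function(m) {
    sc <- predict_ranks(m, unclass(feats))
    mean(sapply(seq_len(nrow(feats)), function(i)
      cor(sc[i, ], unclass(ranks)[i, ], method = "spearman")))
  }
  expect_gt(sp_of(model), sp_of(model_shuf))
})

test_that("fixed seeds refit identically and models serialize round-trip", {
  b <- cached_benchmark(small_cfg(seed = 2, run_noise_sd = 0.1))
  ranks <- rank_transform(aggregate_runs(b$run_records, "AVG"))
  feats <- apply_minmax(b$descriptor_features, fit_minmax(b$descriptor_features))
  cfg <- selector_config(k = 3, n_trees = 30, seed = 11)
  m1 <- fit_selector(feats, ranks, cfg)
  m2 <- fit_selector(feats, ranks, cfg)
  x <- unclass(feats)[1:10, ]
  expect_identical(predict_ranks(m1, x), predict_ranks(m2, x))

  path <- withr::local_tempfile(fileext = ".rds")
  save_selector(m1, path)
  m3 <- load_selector(path)
  expect_identical(predict_ranks(m3, x), predict_ranks(m1, x))
  expect_identical(select_algorithm(m3, x), select_algorithm(m1, x))
})

test_that("malformed feature input fails loudly", {
  b <- cached_benchmark(small_cfg(seed = 2, run_noise_sd = 0.1))
  ranks <- rank_transform(aggregate_runs(b$run_records, "AVG"))
  model <- fit_selector(b$descriptor_features, ranks,
                        selector_config(k = 2, n_trees = 10, seed = 1))
  expect_error(predict_ranks(model, c(0.1, 0.2)), "does not match")
  wrong_rows <- b$descriptor_features[1:5, ]
  rownames(wrong_rows) <- letters[1:5]
  expect_error(fit_selector(dockselect:::as_feature_table(wrong_rows, b$descriptor_features),
                            ranks, selector_config()),
               "identical order")
  expect_error(fit_selector(b$descriptor_features, ranks,
                            selector_config(k = 50)), "k must")
})
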