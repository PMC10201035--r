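#' Selector configuration
#'
#' Bundles the selector hyperparameters: the latent rank `k` of the
#' truncated SVD (default 5), the size of the random-forest ensemble
#' (default 100 trees, the scikit-learn default the study protocol uses),
#' and the master seed from which all selector randomness derives.
#'
#' The tree-growing defaults mirror the scikit-learn regression forest the
#' protocol names: every feature is a split candidate (`mtry = NULL`, i.e.
#' all features) and trees are grown deep (`min_node_size = 2`).
#'
#' @param k latent rank of the factorization.
#' @param n_trees number of trees in the regression ensemble.
#' @param seed integer master seed.
#' @param mtry split candidates per node; `NULL` = all features.
#' @param min_node_size minimal node size to attempt a split.
#' @return A list of class `selector_config`.
#' @export
selector_config <- function(k = 5L, n_trees = 100L, seed = 1L, mtry = NULL,
                            min_node_size = 2L) {
  if (k < 1L) stop("k must be >= 1")
  if (n_trees < 1L) stop("n_trees must be >= 1")
  structure(list(k = as.integer(k), n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 min_node_size = as.integer(min_node_size)),
            class = "selector_config")
}

#' Factorize a rank matrix into latent factors
#'
#' Truncated singular value decomposition of the uncentered m x n rank
#' matrix R ~ U_k S_k V_k'. The singular-value scale is folded into the
#' instance factors (U_k S_k), leaving the algorithm factors V_k
#' orthonormal, so that a predicted rank row is the plain inner product
#' `instance_factors %*% t(algorithm_factors)`. At k = min(m, n) the
#' product reconstructs R to machine tolerance; at smaller k the
#' Frobenius reconstruction error is the optimal rank-k error.
#'
#' @param ranks a `rank_matrix` (any complete numeric matrix works).
#' @param k latent rank, 1 <= k <= min(m, n).
#' @return A list of class `latent_model` with `instance_factors` (m x k),
#'   `algorithm_factors` (n x k), `singular_values` (length k,
#'   non-increasing) and `source_mode`.
#' @export
factorize <- function(ranks, k) {
  vals <- unclass(ranks)
  if (any(!is.finite(vals))) stop("rank matrix has non-finite cells")
  kmax <- min(dim(vals))
  if (k < 1L || k > kmax)
    stop("k must lie in [1, ", kmax, "]")
  sv <- svd(vals, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  inst <- sv$u %*% diag(d, k, k)
  rownames(inst) <- rownames(vals)
  algf <- sv$v
  rownames(algf) <- colnames(vals)
  structure(list(instance_factors = inst, algorithm_factors = algf,
                 singular_values = d,
                 source_mode = attr(ranks, "mode")),
            class = "latent_model")
}

# Latent-factor regressors. Two kinds: a per-dimension random-forest
# ensemble (the fitted selector) and a lookup table (oracle used in tests
# and diagnostics, returning stored factors by instance id).
predict_latent <- function(regressor, x) UseMethod("predict_latent")

#' @export
predict_latent.per_dim_forest <- function(regressor, x) {
  z <- vapply(regressor$forests, function(f) {
    stats::predict(f, data = as.data.frame(x), num.threads = 1L,
                   verbose = FALSE)$predictions
  }, numeric(nrow(x)))
  matrix(z, nrow = nrow(x))
}

#' @export
predict_latent.lookup <- function(regressor, x) {
  idx <- match(rownames(x), rownames(regressor$factors))
  if (anyNA(idx)) stop("lookup regressor: unknown instance id")
  regressor$factors[idx, , drop = FALSE]
}

#' Oracle lookup regressor
#'
#' A regressor that ignores the feature values and returns the stored
#' latent factors of each instance (matched by row id). Useful as the
#' identity limit of the selector: with full-rank factors it reproduces
#' the training rank rows exactly.
#'
#' @param factors m x k matrix of instance latent factors with row names.
#' @return A regressor of class `lookup`.
#' @export
lookup_regressor <- function(factors) {
  structure(list(factors = factors), class = "lookup")
}

#' Fit the feature-to-latent-factor selector
#'
#' The ALORS-style selector: the rank matrix is factorized with a
#' truncated SVD (rank `config$k`), and a random-forest regression maps
#' each instance's feature vector to its k latent factors (one forest per
#' latent dimension, `config$n_trees` trees each, impurity importance
#' recorded). Prediction then scores every portfolio algorithm by the
#' inner product of the regressed factors with the algorithm factors.
#'
#' @param features a `feature_table`, normalized upstream, with the same
#'   instance ids as `ranks` in the same order.
#' @param ranks the training `rank_matrix`.
#' @param config a [selector_config()].
#' @return A list of class `selector_model` with the regressor, the
#'   algorithm factors, `feature_names`, `train_mean_ranks` (tie-break
#'   key), `algorithm_ids` and `config`.
#' @export
fit_selector <- function(features, ranks, config = selector_config()) {
  if (!identical(rownames(features), rownames(ranks)))
    stop("features and ranks must share instance ids in identical order")
  latent <- factorize(ranks, config$k)
  x <- as.data.frame(unclass(features))
  forests <- lapply(seq_len(config$k), function(j) {
    ranger::ranger(
      y = latent$instance_factors[, j],
      x = x,
      num.trees = config$n_trees,
      mtry = if (is.null(config$mtry)) ncol(x) else config$mtry,
      min.node.size = config$min_node_size,
      importance = "impurity",
      seed = config$seed + j - 1L,
      num.threads = 1L
    )
  })
  structure(list(
    regressor = structure(list(forests = forests), class = "per_dim_forest"),
    algorithm_factors = latent$algorithm_factors,
    singular_values = latent$singular_values,
    feature_names = colnames(features),
    algorithm_ids = colnames(ranks),
    train_mean_ranks = colMeans(ranks),
    source_mode = attr(ranks, "mode"),
    config = config
  ), class = "selector_model")
}

check_feature_input <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != length(model$feature_names))
      stop("feature vector length ", length(x), " does not match the ",
           length(model$feature_names), " features the model expects")
    x <- matrix(x, nrow = 1L, dimnames = list("x", model$feature_names))
  }
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names))
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         length(model$feature_names))
  if (!is.null(colnames(x)) && !identical(colnames(x), model$feature_names))
    x <- x[, model$feature_names, drop = FALSE]
  colnames(x) <- model$feature_names
  x
}

#' Predict per-instance rank scores for every portfolio algorithm
#'
#' Regresses the feature vector(s) onto the latent space and scores each
#' algorithm as the inner product with its latent factors. Lower score =
#' predicted better algorithm. Scores approximate rank values but need not
#' be integers or a permutation.
#'
#' @param model a fitted `selector_model`.
#' @param x a feature vector (ordered as `model$feature_names`) or a
#'   matrix/`feature_table` of such rows.
#' @return A numeric matrix (rows = inputs, columns = algorithms) of
#'   predicted rank scores; a single vector input yields a 1-row matrix.
#' @export
predict_ranks <- function(model, x) {
  x <- check_feature_input(model, x)
  z <- predict_latent(model$regressor, x)
  scores <- z %*% t(model$algorithm_factors)
  dimnames(scores) <- list(rownames(x), model$algorithm_ids)
  scores
}

#' Select the predicted best algorithm for each instance
#'
#' The argmin of the predicted rank scores. Exact score ties are broken by
#' the lower training mean rank, then by portfolio (column) order.
#'
#' @inheritParams predict_ranks
#' @return A character vector of algorithm ids, one per input row.
#' @export
select_algorithm <- function(model, x) {
  scores <- predict_ranks(model, x)
  apply(scores, 1L, function(s) {
    cand <- which(s == min(s))
    if (length(cand) > 1L) {
      key <- model$train_mean_ranks[cand]
      cand <- cand[order(key, cand)]
    }
    model$algorithm_ids[cand[1L]]
  })
}

#' Save / load a fitted selector
#'
#' Serializes the whole selector (config, feature names, algorithm ids,
#' latent factors and the fitted forests) into a single archive file.
#' Loading reproduces predictions bit-for-bit.
#'
#' @param model a `selector_model`.
#' @param path archive file path.
#' @export
save_selector <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_selector
#' @export
load_selector <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "selector_model"))
    stop("file does not contain a selector_model")
  model
}
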