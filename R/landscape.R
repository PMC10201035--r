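#' Gini feature importance of a fitted selector
#'
#' Aggregates the impurity-decrease (Gini) importances recorded while
#' growing the selector's random forests: raw impurity decreases are
#' summed across the k per-dimension forests — which weights each latent
#' dimension by the target variance it carries — and normalized to sum 1.
#' Features are reported in descending importance order; this is the
#' ordering behind importance-cutoff feature subsets (e.g. cutoff 0.15).
#'
#' @param model a fitted `selector_model`.
#' @return A data frame of class `importance_report` with columns
#'   `feature`, `gini`, sorted descending.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "selector_model") ||
      !inherits(model$regressor, "per_dim_forest"))
    stop("feature_importance needs a fitted forest-based selector_model")
  imp <- Reduce(`+`, lapply(model$regressor$forests,
                            function(f) f$variable.importance))
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), gini = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gini, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("importance_report", "data.frame")
  out
}

#' Hierarchical clustering of portfolio algorithms
#'
#' Agglomerative clustering of the algorithms in the latent space: each
#' algorithm is its row of latent factors, distances are Euclidean, and
#' merging uses average linkage. Algorithms whose rank columns coincide
#' have identical factors and merge at height 0. Latent factors from the
#' AVG-mode rank matrix are the conventional input.
#'
#' When a `latent_model` is supplied, latent dimensions whose singular
#' value is numerically zero are dropped first: their factor directions
#' are arbitrary (any basis of the null space is a valid SVD) and would
#' inject noise into the distances.
#'
#' @param latent a `latent_model` from [factorize()], or a bare n x k
#'   matrix of algorithm factors.
#' @param method linkage rule passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An `hclust` object over the n algorithms (n - 1 merges,
#'   non-decreasing heights), with algorithm ids as labels.
#' @export
cluster_algorithms <- function(latent, method = "average") {
  af <- if (inherits(latent, "latent_model")) {
    sv <- latent$singular_values
    keep <- sv > max(sv) * 1e-10
    latent$algorithm_factors[, keep, drop = FALSE]
  } else as.matrix(latent)
  if (nrow(af) < 2L) stop("need at least 2 algorithms to cluster")
  stats::hclust(stats::dist(af), method = method)
}

# Partition implied by accepting merges of the linkage tree in height
# order while every cluster stays within `max_size` members built from
# nodes of bounded depth: depth 1 = leaf pairs, depth 2 = merges of
# leaves/pairs.
linkage_partition <- function(hc, max_depth) {
  n <- length(hc$order)
  depth <- integer(n - 1L)            # depth of each merge node
  member <- as.list(seq_len(n))       # leaves of each accepted merge
  accepted <- logical(n - 1L)
  node_leaves <- vector("list", n - 1L)
  for (j in seq_len(n - 1L)) {
    ch <- hc$merge[j, ]
    leaves <- integer(0); d <- 1L; ok <- TRUE
    for (c in ch) {
      if (c < 0) {
        leaves <- c(leaves, -c)
      } else {
        if (!accepted[c]) ok <- FALSE
        d <- max(d, depth[c] + 1L)
        leaves <- c(leaves, node_leaves[[c]])
      }
    }
    if (ok && d <= max_depth) {
      accepted[j] <- TRUE
      depth[j] <- d
      node_leaves[[j]] <- leaves
    }
  }
  # largest accepted nodes become clusters; everything else stays singleton
  labels <- seq_len(n)
  for (j in seq_len(n - 1L)) {
    if (accepted[j]) {
      # skip nodes absorbed by a larger accepted ancestor
      parent <- which(hc$merge[, 1] == j | hc$merge[, 2] == j)
      if (length(parent) && accepted[parent]) next
      labels[node_leaves[[j]]] <- n + j
    }
  }
  match(labels, unique(labels))
}

#' Reduce a portfolio via algorithm similarity
#'
#' Collapses clusters of near-equivalent algorithms to a single
#' representative. At `level = "lowest_pairs"` only leaf-leaf merges of
#' the dendrogram form clusters (pairs of highly similar algorithms); at
#' `level = "one_higher"` merges one level up the hierarchy are also
#' accepted (clusters of up to four algorithms). The representative of
#' each cluster is the member with the lowest training mean rank, ties
#' broken by portfolio order.
#'
#' @param linkage an `hclust` over the algorithms (see
#'   [cluster_algorithms()]), with labels.
#' @param mean_ranks named numeric training mean ranks covering the
#'   clustered algorithms.
#' @param level `"lowest_pairs"` or `"one_higher"`.
#' @return Character vector of retained algorithm ids, in portfolio order.
#' @export
reduce_portfolio <- function(linkage, mean_ranks,
                             level = c("lowest_pairs", "one_higher")) {
  level <- match.arg(level)
  ids <- linkage$labels
  if (is.null(ids)) ids <- as.character(seq_along(linkage$order))
  part <- linkage_partition(linkage, if (level == "lowest_pairs") 1L else 2L)
  mr <- mean_ranks[ids]
  keep <- vapply(split(seq_along(ids), part), function(members) {
    members[order(mr[members], members)][1L]
  }, integer(1))
  ids[sort(keep)]
}

#' Embed instances in two dimensions
#'
#' Projects an instance feature table to 2-D for instance-space maps:
#' `"pca"` uses the first two principal components (deterministic);
#' `"tsne"` uses a seeded exact t-SNE (see the package's embedded
#' implementation) whose perplexity is recorded in the result's metadata.
#'
#' @param features a `feature_table` (or numeric matrix), d >= 2 columns.
#' @param method `"pca"` or `"tsne"`.
#' @param seed seed for the stochastic embedding.
#' @param perplexity t-SNE perplexity (capped at (m - 1)/3).
#' @return An m x 2 coordinate matrix with attributes `method` and, for
#'   t-SNE, `perplexity`.
#' @export
embed_instances <- function(features, method = c("pca", "tsne"), seed = 1L,
                            perplexity = 30) {
  method <- match.arg(method)
  x <- unclass(as.matrix(features))
  if (ncol(x) < 2L) stop("need at least 2 feature dimensions to embed")
  if (method == "pca") {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    y <- pc$x[, 1:2, drop = FALSE]
    colnames(y) <- c("dim1", "dim2")
  } else {
    y <- tsne_embed(x, perplexity = perplexity, seed = seed)
    attr(y, "perplexity") <- min(perplexity, floor((nrow(x) - 1) / 3))
  }
  attr(y, "method") <- method
  y
}

#' Silhouette-guided k-means clustering of instances
#'
#' Runs seeded k-means for every k in `k_range`, scores each clustering by
#' the mean silhouette coefficient over all instances, and returns the
#' full scan together with the best k (argmax silhouette) and its labels.
#'
#' @param features a `feature_table` or numeric matrix with more rows than
#'   `max(k_range)`.
#' @param k_range integer range of cluster counts to scan (default 2:15).
#' @param seed seed for the k-means initialisations.
#' @param nstart random restarts per k.
#' @return A list of class `clustering_report`: `silhouette` (data frame
#'   k, silhouette), `best_k`, `labels` (for `best_k`).
#' @export
cluster_instances <- function(features, k_range = 2:15, seed = 1L,
                              nstart = 10L) {
  x <- unclass(as.matrix(features))
  m <- nrow(x)
  if (m <= max(k_range)) stop("need more instances than the largest k")
  d <- stats::dist(x)
  sil <- numeric(length(k_range))
  labels <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(seed + k_range[i])
    km <- stats::kmeans(x, centers = k_range[i], nstart = nstart,
                        iter.max = 50L)
    labels[[i]] <- km$cluster
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  best <- which.max(sil)
  structure(list(
    silhouette = data.frame(k = k_range, silhouette = sil),
    best_k = k_range[best],
    labels = stats::setNames(labels[[best]], rownames(x))
  ), class = "clustering_report")
}

#' Per-cluster feature distribution summaries
#'
#' The numeric backbone of per-cluster boxplots: for every
#' (cluster, feature) pair, the median, quartiles, whisker ends
#' (Tukey 1.5 IQR rule) and outlier count.
#'
#' @param features a `feature_table` or numeric matrix.
#' @param labels cluster labels covering all instances (named or in row
#'   order).
#' @return A data frame with columns `cluster`, `feature`, `lower_whisker`,
#'   `q1`, `median`, `q3`, `upper_whisker`, `n_outliers`.
#' @export
cluster_profiles <- function(features, labels) {
  x <- unclass(as.matrix(features))
  if (length(labels) != nrow(x))
    stop("labels must cover all instances")
  if (!is.null(names(labels)) && !is.null(rownames(x)))
    labels <- labels[rownames(x)]
  out <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    do.call(rbind, lapply(colnames(xi), function(f) {
      bs <- grDevices::boxplot.stats(xi[, f])
      data.frame(cluster = cl, feature = f,
                 lower_whisker = bs$stats[1], q1 = bs$stats[2],
                 median = bs$stats[3], q3 = bs$stats[4],
                 upper_whisker = bs$stats[5],
                 n_outliers = length(bs$out),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
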