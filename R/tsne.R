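# Exact (dense) t-SNE, implemented here because the package needs a seeded
# 2-D stochastic neighbour embedding for instance-space maps. O(m^2) in the
# number of instances; intended for the few-hundred-to-few-thousand
# instance scale of docking benchmarks.

# Per-point conditional Gaussian affinities calibrated to a target
# perplexity by bisection on the precision beta.
tsne_affinities <- function(d2, perplexity, tol = 1e-5, max_iter = 50L) {
  m <- nrow(d2)
  P <- matrix(0, m, m)
  logU <- log(perplexity)
  for (i in seq_len(m)) {
    beta <- 1; beta_lo <- -Inf; beta_hi <- Inf
    di <- d2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(di * p) / sp
        p <- p / sp
      }
      if (abs(H - logU) < tol) break
      if (H > logU) { beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else { beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * m)
  pmax(P, .Machine$double.eps)
}

# Gradient-descent t-SNE with early exaggeration and momentum.
tsne_embed <- function(x, perplexity = 30, n_iter = 400L, seed = 1L,
                       learning_rate = 200) {
  x <- as.matrix(x)
  m <- nrow(x)
  perplexity <- min(perplexity, floor((m - 1) / 3))
  if (perplexity < 2) stop("too few points for t-SNE")
  sq <- rowSums(x^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(x), 0)
  P <- tsne_affinities(d2, perplexity)
  set.seed(seed)
  y <- matrix(stats::rnorm(m * 2, sd = 1e-4), m, 2)
  inc <- matrix(0, m, 2)
  exaggeration <- 4
  for (iter in seq_len(n_iter)) {
    Pe <- if (iter <= 100L) P * exaggeration else P
    sqy <- rowSums(y^2)
    num <- 1 / (1 + pmax(outer(sqy, sqy, "+") - 2 * tcrossprod(y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% y
    momentum <- if (iter <= 250L) 0.5 else 0.8
    inc <- momentum * inc - learning_rate * grad
    y <- y + inc
    y <- sweep(y, 2L, colMeans(y))
  }
  rownames(y) <- rownames(x)
  colnames(y) <- c("dim1", "dim2")
  y
}
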