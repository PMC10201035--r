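#' Synthetic docking-benchmark configuration
#'
#' Parameters of the generated instance x algorithm x run energy tensor
#' and its feature tables. Defaults emulate the statistical shape of a
#' repeated-run docking study at desk scale: 300 instances, a 12-algorithm
#' portfolio, 50 runs per pair, 4 planted instance clusters with
#' complementary winning algorithms, 9 informative + 110 noise descriptor
#' features (119 total, the size of a cleaned descriptor table) and
#' 881-bit fingerprints.
#'
#' @param n_instances,n_algorithms,n_clusters,n_runs tensor dimensions.
#' @param n_informative_features,n_noise_features descriptor-table split.
#' @param run_noise_sd per-run Gaussian noise, kcal/mol.
#' @param cluster_gap energy margin (kcal/mol) by which each cluster's
#'   planted winner beats every other algorithm on that cluster.
#' @param seed integer master seed for all draws.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_instances = 300L, n_algorithms = 12L,
                             n_clusters = 4L, n_runs = 50L,
                             n_informative_features = 9L,
                             n_noise_features = 110L,
                             run_noise_sd = 0.5, cluster_gap = 2.0,
                             seed = 1L) {
  cfg <- list(n_instances = as.integer(n_instances),
              n_algorithms = as.integer(n_algorithms),
              n_clusters = as.integer(n_clusters),
              n_runs = as.integer(n_runs),
              n_informative_features = as.integer(n_informative_features),
              n_noise_features = as.integer(n_noise_features),
              fingerprint_length = 881L,
              run_noise_sd = run_noise_sd,
              cluster_gap = cluster_gap,
              seed = as.integer(seed))
  counts <- c("n_instances", "n_algorithms", "n_clusters", "n_runs",
              "n_informative_features", "n_noise_features")
  for (f in counts)
    if (cfg[[f]] < 1L) stop(f, " must be >= 1")
  if (cfg$cluster_gap < 0) stop("cluster_gap must be >= 0")
  if (cfg$run_noise_sd < 0) stop("run_noise_sd must be >= 0")
  if (cfg$n_clusters > cfg$n_algorithms)
    stop("n_clusters must not exceed n_algorithms")
  if (cfg$n_clusters > cfg$n_instances)
    stop("n_clusters must not exceed n_instances")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic docking benchmark with planted complementarity
#'
#' Builds ground-truth data for every pipeline stage. Instances are
#' assigned to clusters round-robin; cluster c's planted winner is
#' algorithm c (winners are distinct across clusters, guaranteeing
#' complementarity). Cell means sit around a -7 kcal/mol baseline with a
#' uniform jitter per (cluster, algorithm), and the winner's mean lies
#' `cluster_gap` below every competitor on its cluster; run energies are
#' Normal(mean, `run_noise_sd`). Informative descriptor features are noisy
#' \[0, 1\] indicator encodings of cluster membership (feature j tags
#' cluster `(j - 1) %% n_clusters + 1`); noise features are Uniform(0, 1).
#' Fingerprints flip a cluster-specific 881-bit template with per-bit
#' probability 0.05.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_benchmark`: `run_records`,
#'   `descriptor_features` (kind `md`), `fingerprint_features` (kind `sf`,
#'   881 bits), `truth` (data frame instance_id, cluster, winner),
#'   `cell_means` (n_clusters x n_algorithms matrix), `config`.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  cfg <- config
  set.seed(cfg$seed)
  m <- cfg$n_instances; n <- cfg$n_algorithms
  inst <- sprintf("L%04d", seq_len(m))
  alg <- paste0("A", seq_len(n))
  cluster <- ((seq_len(m) - 1L) %% cfg$n_clusters) + 1L
  winner <- seq_len(cfg$n_clusters)          # distinct winners: complementarity

  base <- -7
  mu <- matrix(base + stats::runif(cfg$n_clusters * n, 0, 1),
               cfg$n_clusters, n, dimnames = list(NULL, alg))
  if (cfg$cluster_gap > 0) {
    # plant the winner cluster_gap below its best competitor; with gap 0
    # the winner label stays a pure null (unrelated to performance)
    for (c in winner) {
      mu[c, c] <- min(mu[c, -c]) - cfg$cluster_gap
    }
    stopifnot(all(apply(mu, 1L, which.min) == winner))
  }

  # run energies, instance-major then algorithm then run
  idx <- expand.grid(run = seq_len(cfg$n_runs), algorithm = seq_len(n),
                     instance = seq_len(m))
  means <- mu[cbind(cluster[idx$instance], idx$algorithm)]
  energy <- stats::rnorm(nrow(idx), mean = means, sd = cfg$run_noise_sd)
  rec <- run_records(instance_id = inst[idx$instance],
                     algorithm_id = alg[idx$algorithm],
                     run_index = idx$run, binding_energy = energy)

  # descriptor features: noisy cluster indicators squeezed into [0, 1]
  p_inf <- cfg$n_informative_features
  tag <- ((seq_len(p_inf) - 1L) %% cfg$n_clusters) + 1L
  inf <- vapply(seq_len(p_inf), function(j) {
    v <- as.numeric(cluster == tag[j]) * 0.8 + 0.1 +
      stats::rnorm(m, sd = 0.05)
    pmin(pmax(v, 0), 1)
  }, numeric(m))
  noise <- matrix(stats::runif(m * cfg$n_noise_features), m)
  md <- cbind(inf, noise)
  dimnames(md) <- list(inst, c(sprintf("inf%02d", seq_len(p_inf)),
                               sprintf("noise%03d", seq_len(cfg$n_noise_features))))

  # fingerprints: cluster templates with per-bit flips
  L <- cfg$fingerprint_length
  templates <- matrix(stats::rbinom(cfg$n_clusters * L, 1L, 0.5),
                      cfg$n_clusters, L)
  flips <- matrix(stats::rbinom(m * L, 1L, 0.05), m, L)
  fp <- (templates[cluster, , drop = FALSE] + flips) %% 2L
  dimnames(fp) <- list(inst, paste0("PubchemFP", seq_len(L)))

  structure(list(
    run_records = rec,
    descriptor_features = feature_table(md, kind = "md"),
    fingerprint_features = feature_table(fp, kind = "sf"),
    truth = data.frame(instance_id = inst, cluster = cluster,
                       winner = alg[winner[cluster]],
                       stringsAsFactors = FALSE),
    cell_means = mu,
    config = cfg
  ), class = "synthetic_benchmark")
}

#' Write a synthetic benchmark to plain-text files
#'
#' Emits the run-record TSV, descriptor CSV, fingerprint CSV and truth CSV
#' under `dir`.
#'
#' @param bench a `synthetic_benchmark`.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_records(bench$run_records, file.path(dir, "run_records.tsv"))
  write_feature_csv(bench$descriptor_features, file.path(dir, "descriptors.csv"))
  write_feature_csv(bench$fingerprint_features, file.path(dir, "fingerprints.csv"))
  utils::write.csv(bench$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' End-to-end recovery run on a synthetic benchmark
#'
#' The desk-scale stand-in for the full study: generate a benchmark,
#' aggregate runs (AVG), rank, and cross-validate the selector on the
#' descriptor features, then score how often the selector recovers each
#' held-out instance's planted winner and how its joint mean rank compares
#' with the virtual-best and single-best baselines.
#'
#' @param config a [synthetic_config()].
#' @param selector_cfg a [selector_config()].
#' @param n_folds cross-validation folds (default 10).
#' @param mode aggregation mode for the evaluated matrix.
#' @return A list of class `recovery_report`: `accuracy` (fraction of
#'   held-out instances whose selected algorithm equals the planted
#'   winner), `summary` (joint mean-rank table incl. ALORS/SBS/VBS/random),
#'   `report` (the full `evaluation_report`), `benchmark`.
#' @export
end_to_end_recovery <- function(config = synthetic_config(),
                                selector_cfg = selector_config(),
                                n_folds = 10L, mode = "AVG") {
  bench <- generate_benchmark(config)
  perf <- aggregate_runs(bench$run_records, mode = mode)
  folds <- kfold_split(rownames(perf), n_folds = n_folds,
                       seed = selector_cfg$seed)
  rep <- evaluate_selector(perf, bench$descriptor_features,
                           config = selector_cfg, folds = folds)
  acc <- mean(rep$selections$chosen == bench$truth$winner)
  structure(list(accuracy = acc, summary = rep$summary, report = rep,
                 benchmark = bench),
            class = "recovery_report")
}
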