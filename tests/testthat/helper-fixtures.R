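# Shared fixtures, all built in code.

# A miniature AutoDock 4-style docking log with one final docked
# conformation per run.
make_dlg_text <- function(energies) {
  unlist(lapply(seq_along(energies), function(i) c(
    sprintf("Run:   %d / %d", i, length(energies)),
    "DOCKED: MODEL        1",
    sprintf("DOCKED: USER    Estimated Free Energy of Binding    =  %+.2f kcal/mol  [=(1)+(2)+(3)-(4)]",
            energies[i]),
    sprintf("DOCKED: USER    Final Intermolecular Energy         =  %+.2f kcal/mol",
            energies[i] - 0.3),
    "DOCKED: ENDMDL"
  )))
}

# Small, fast synthetic-benchmark configuration for unit tests.
small_cfg <- function(seed = 1L, ...) {
  args <- list(n_instances = 120L, n_algorithms = 8L, n_clusters = 4L,
               n_runs = 10L, n_informative_features = 9L,
               n_noise_features = 30L, run_noise_sd = 0.3,
               cluster_gap = 2.0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# Benchmarks are deterministic in the config, so cache them across tests.
.bench_cache <- new.env(parent = emptyenv())
cached_benchmark <- function(cfg) {
  key <- paste(unlist(cfg), collapse = "|")
  if (is.null(.bench_cache[[key]]))
    .bench_cache[[key]] <- generate_benchmark(cfg)
  .bench_cache[[key]]
}

# Well-separated isotropic Gaussian blobs in 2-D.
make_blobs <- function(n_blobs, per_blob = 30L, sep = 8, sd = 0.5, seed = 1L) {
  set.seed(seed)
  centers <- cbind(sep * cos(2 * pi * seq_len(n_blobs) / n_blobs),
                   sep * sin(2 * pi * seq_len(n_blobs) / n_blobs))
  lab <- rep(seq_len(n_blobs), each = per_blob)
  x <- centers[lab, ] + matrix(rnorm(2 * length(lab), sd = sd),
                               ncol = 2)
  dimnames(x) <- list(sprintf("P%03d", seq_along(lab)), c("f1", "f2"))
  list(x = x, labels = lab)
}

# Brute-force average-tie ranks: 1 + (# strictly smaller) + (# ties - 1)/2.
brute_force_ranks <- function(row) {
  vapply(row, function(v) 1 + sum(row < v) + (sum(row == v) - 1) / 2,
         numeric(1))
}

rank_matrix_of <- function(vals) {
  rank_transform(performance_matrix(vals, mode = "AVG"))
}

random_perf <- function(m, n, seed) {
  set.seed(seed)
  vals <- matrix(rnorm(m * n, mean = -8), m, n,
                 dimnames = list(sprintf("I%03d", seq_len(m)),
                                 paste0("A", seq_len(n))))
  performance_matrix(vals, mode = "AVG")
}
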