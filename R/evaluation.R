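#' Seeded k-fold split of instances
#'
#' Shuffles the instance ids with the given seed and partitions them into
#' `n_folds` contiguous blocks whose sizes differ by at most one (the
#' first `m %% n_folds` folds take the extra instance).
#'
#' @param instance_ids character vector of instance labels.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return A list of class `fold_assignment` with `fold_of` (named integer
#'   vector instance -> fold), `n_folds` and `seed`.
#' @export
kfold_split <- function(instance_ids, n_folds = 10L, seed = 1L) {
  m <- length(instance_ids)
  if (n_folds > m) stop("n_folds exceeds the number of instances")
  set.seed(seed)
  perm <- sample.int(m)
  base <- m %/% n_folds
  extra <- m %% n_folds
  sizes <- rep(base, n_folds) + c(rep(1L, extra), rep(0L, n_folds - extra))
  fold <- integer(m)
  fold[perm] <- rep(seq_len(n_folds), times = sizes)
  names(fold) <- instance_ids
  structure(list(fold_of = fold, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Joint ranking of standalone algorithms and meta-methods
#'
#' For each instance, ranks the n standalone binding energies together
#' with one achieved-energy entry per meta-method (selector, baselines)
#' using average-rank ties, so a meta-method that picks algorithm j ties
#' with column j. This puts selectors on the same rank scale as the
#' standalone algorithms, the scale of the league-table comparison.
#'
#' @param perf m x n `performance_matrix`.
#' @param meta m x q matrix of achieved energies, one column per
#'   meta-method (may have 0 columns).
#' @return An m x (n + q) matrix of joint ranks.
#' @export
rank_with_meta <- function(perf, meta) {
  vals <- cbind(unclass(perf), meta)
  out <- t(apply(vals, 1L, rank))
  dimnames(out) <- dimnames(vals)
  out
}

# Average-tie rank that the value x would take if inserted into the fixed
# vector v (x is a duplicate of an existing entry when drawn from v).
insertion_rank <- function(v, x) {
  n_less <- vapply(x, function(xx) sum(v < xx), numeric(1))
  n_tied <- vapply(x, function(xx) sum(v == xx), numeric(1))
  n_less + (n_tied + 2) / 2
}

#' Tenfold cross-validated selector evaluation
#'
#' Reproduces the league-table protocol: for each fold the selector is
#' fitted on the remaining folds (min-max normalization fitted on training
#' rows only), one algorithm is selected per held-out instance, and the
#' chosen algorithm's true aggregated energy is recorded as the selector's
#' achieved performance. Each instance's n standalone energies are then
#' jointly ranked with one entry per meta-method (the selector plus the
#' requested baselines), and every method is summarised by its mean and
#' population SD joint rank over all instances.
#'
#' Baselines: `sbs` (single best solver — the algorithm with the best mean
#' training rank, re-determined per fold), `vbs` (virtual best solver —
#' the per-instance oracle argmin of true energies) and `random` (uniform
#' pick, averaged over `n_random_draws` seeded draws; its draws are ranked
#' by insertion into the fixed joint set and do not perturb the other
#' methods' ranks).
#'
#' @param perf m x n `performance_matrix`.
#' @param features `feature_table` aligned to `perf` rows (raw scale; set
#'   `normalize = FALSE` if already normalized).
#' @param config a [selector_config()].
#' @param folds a [kfold_split()] assignment over the instances of `perf`.
#' @param baselines subset of `c("sbs", "vbs", "random")`.
#' @param normalize fit min-max on training rows per fold (default `TRUE`).
#' @param sbs_scope `"fold"` (training folds only, default) or `"global"`
#'   (whole-data single best, the replication mode).
#' @param n_random_draws Monte-Carlo draws for the random baseline.
#' @return A list of class `evaluation_report`: `summary` (method,
#'   mean_rank, sd_rank over the joint ranking), `selections` (per-instance
#'   fold and chosen algorithm), `achieved` (per-instance achieved energy
#'   per meta-method), `joint_ranks`, `mode`, `n_entries`.
#' @export
evaluate_selector <- function(perf, features, config = selector_config(),
                              folds = NULL,
                              baselines = c("sbs", "vbs", "random"),
                              normalize = TRUE,
                              sbs_scope = c("fold", "global"),
                              n_random_draws = 1000L) {
  sbs_scope <- match.arg(sbs_scope)
  if (!identical(rownames(perf), rownames(features)))
    stop("perf and features must share instance ids in identical order")
  if (is.null(folds))
    folds <- kfold_split(rownames(perf), seed = config$seed)
  if (!setequal(names(folds$fold_of), rownames(perf)))
    stop("fold assignment does not cover the instances of perf")
  baselines <- match.arg(baselines, several.ok = TRUE)
  m <- nrow(perf); n <- ncol(perf)
  fold <- folds$fold_of[rownames(perf)]

  chosen <- character(m)
  sbs_pick <- character(m)
  ranks_all <- rank_transform(perf)
  global_sbs <- colnames(perf)[which.min(colMeans(ranks_all))]

  for (f in sort(unique(fold))) {
    tr <- which(fold != f); te <- which(fold == f)
    ftr <- as_feature_table(unclass(features)[tr, , drop = FALSE], features)
    fte <- as_feature_table(unclass(features)[te, , drop = FALSE], features)
    if (normalize) {
      p <- fit_minmax(ftr)
      ftr <- apply_minmax(ftr, p)
      fte <- apply_minmax(fte, p)
    }
    rtr <- rank_transform(performance_matrix(unclass(perf)[tr, , drop = FALSE],
                                             mode = attr(perf, "mode")))
    model <- fit_selector(ftr, rtr, config)
    chosen[te] <- select_algorithm(model, unclass(fte))
    sbs_pick[te] <- if (sbs_scope == "fold")
      colnames(perf)[which.min(colMeans(rtr))] else global_sbs
  }

  pv <- unclass(perf)
  achieved <- cbind(ALORS = pv[cbind(seq_len(m), match(chosen, colnames(pv)))])
  if ("sbs" %in% baselines)
    achieved <- cbind(achieved,
                      SBS = pv[cbind(seq_len(m), match(sbs_pick, colnames(pv)))])
  if ("vbs" %in% baselines)
    achieved <- cbind(achieved, VBS = apply(pv, 1L, min))
  rownames(achieved) <- rownames(pv)

  joint <- rank_with_meta(perf, achieved)
  n_entries <- ncol(joint)
  summ <- summarize_mean_ranks(
    structure(joint, class = c("rank_matrix", "matrix", "array")))
  names(summ)[1] <- "method"

  if ("random" %in% baselines) {
    # expected joint rank of a uniformly drawn column, by insertion into
    # the fixed joint set; seeded Monte-Carlo over draws
    ins <- matrix(unlist(lapply(seq_len(m), function(i) {
      v <- c(pv[i, ], achieved[i, ])
      insertion_rank(v, pv[i, ])
    })), nrow = m, byrow = TRUE)
    set.seed(config$seed + 104729L)
    picks <- matrix(sample.int(n, m * n_random_draws, replace = TRUE), m)
    rnd_inst <- rowMeans(matrix(ins[cbind(rep(seq_len(m), n_random_draws),
                                          as.vector(picks))], m))
    summ <- rbind(summ, data.frame(
      method = "random", mean_rank = mean(rnd_inst),
      sd_rank = sqrt(mean((rnd_inst - mean(rnd_inst))^2)),
      stringsAsFactors = FALSE))
  }

  structure(list(
    summary = summ,
    selections = data.frame(instance_id = rownames(pv), fold = unname(fold),
                            chosen = chosen, sbs = sbs_pick,
                            stringsAsFactors = FALSE),
    achieved = achieved,
    joint_ranks = joint,
    mode = attr(perf, "mode"),
    n_entries = n_entries
  ), class = "evaluation_report")
}

#' Portfolio baselines on a performance matrix
#'
#' Computes the three reference selectors on their own, without the
#' cross-validated model: the single best solver (best mean rank over the
#' training rows), the virtual best solver (per-instance argmin), and the
#' uniform-random selector (standalone mean rank estimated over seeded
#' Monte-Carlo draws; its expectation is (n + 1)/2).
#'
#' @param perf a `performance_matrix`.
#' @param train_ids optional instance ids on which the SBS is determined
#'   (default: all rows).
#' @param n_random_draws Monte-Carlo draws for the random baseline.
#' @param seed seed for the random baseline.
#' @return A list with `sbs_id`, `vbs_choice` (per-instance id),
#'   `achieved` (matrix of SBS/VBS achieved energies) and
#'   `random_mean_rank` (standalone scale, among the n algorithms only).
#' @export
baseline_metrics <- function(perf, train_ids = NULL, n_random_draws = 1000L,
                             seed = 1L) {
  pv <- unclass(perf)
  m <- nrow(pv); n <- ncol(pv)
  tr <- if (is.null(train_ids)) seq_len(m) else match(train_ids, rownames(pv))
  rtr <- rank_transform(performance_matrix(pv[tr, , drop = FALSE],
                                           mode = attr(perf, "mode")))
  sbs_id <- colnames(pv)[which.min(colMeans(rtr))]
  vbs_j <- apply(pv, 1L, which.min)
  ranks <- unclass(rank_transform(perf))
  set.seed(seed)
  picks <- matrix(sample.int(n, m * n_random_draws, replace = TRUE), m)
  rnd <- mean(ranks[cbind(rep(seq_len(m), n_random_draws), as.vector(picks))])
  list(
    sbs_id = sbs_id,
    vbs_choice = colnames(pv)[vbs_j],
    achieved = cbind(SBS = pv[, sbs_id],
                     VBS = pv[cbind(seq_len(m), vbs_j)]),
    random_mean_rank = rnd
  )
}

#' Compare selector performance across feature sets
#'
#' Runs [evaluate_selector()] once per named feature set with shared folds
#' and a shared config, and reports each set's selector mean and SD joint
#' rank — the feature-set league table.
#'
#' @param perf a `performance_matrix`.
#' @param feature_sets named list of `feature_table`s aligned to `perf`.
#' @param config a [selector_config()].
#' @param folds shared [kfold_split()] assignment.
#' @param ... passed to [evaluate_selector()].
#' @return A data frame with columns `feature_set`, `mean_rank`, `sd_rank`,
#'   plus a `reports` attribute holding the full per-set reports.
#' @export
compare_feature_sets <- function(perf, feature_sets, config = selector_config(),
                                 folds = NULL, ...) {
  if (is.null(names(feature_sets)) || any(!nzchar(names(feature_sets))))
    stop("feature_sets must be a named list")
  if (is.null(folds))
    folds <- kfold_split(rownames(perf), seed = config$seed)
  reports <- lapply(feature_sets, function(ft)
    evaluate_selector(perf, ft, config = config, folds = folds, ...))
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    s <- reports[[nm]]$summary
    row <- s[s$method == "ALORS", ]
    data.frame(feature_set = nm, mean_rank = row$mean_rank,
               sd_rank = row$sd_rank, stringsAsFactors = FALSE)
  }))
  attr(out, "reports") <- reports
  out
}

#' Write an evaluation report as CSV
#'
#' Writes the method summary table (method, mean_rank, sd_rank, mode) and,
#' alongside it, the per-instance selection log
#' (`<path base>_selections.csv`).
#'
#' @param report an `evaluation_report`.
#' @param path CSV path for the summary table.
#' @export
write_evaluation_csv <- function(report, path) {
  s <- report$summary
  s$mode <- report$mode
  utils::write.csv(s, path, row.names = FALSE, quote = FALSE)
  sel_path <- sub("\\.csv$", "_selections.csv", path)
  utils::write.csv(report$selections, sel_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
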