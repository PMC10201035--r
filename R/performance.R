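#' Construct an instance-by-algorithm performance matrix
#'
#' Container for aggregated docking performance P(A, I): rows are problem
#' instances (ligands), columns are portfolio algorithms, cells are
#' aggregated binding energies in kcal/mol (lower is better). The matrix
#' must be complete and finite; the aggregation mode is carried as an
#' attribute.
#'
#' @param values numeric matrix with instance row names and algorithm
#'   column names.
#' @param mode aggregation mode label, one of `"AVG"`, `"BEST"`, `"MEDIAN"`.
#' @return A matrix of class `performance_matrix`.
#' @export
performance_matrix <- function(values, mode = c("AVG", "BEST", "MEDIAN")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("performance matrix needs instance row names and algorithm column names")
  if (any(!is.finite(values)))
    stop("performance matrix has missing or non-finite cells")
  structure(values, mode = mode,
            class = c("performance_matrix", "matrix", "array"))
}

#' Aggregate repeated docking runs into a performance matrix
#'
#' Collapses a long table of run records into one cell per
#' (instance, algorithm): `AVG` takes the arithmetic mean over runs, `BEST`
#' the minimum energy (strongest predicted binding), `MEDIAN` the median.
#' Row/column order follows first appearance in `records` unless explicit
#' orderings are supplied; with explicit orderings the full grid must be
#' covered, and any absent pair is reported as a missing cell.
#'
#' @param records a `run_records` data frame (see [run_records()]).
#' @param mode `"AVG"`, `"BEST"` or `"MEDIAN"`.
#' @param instance_order,algorithm_order optional label vectors fixing the
#'   row/column order (e.g. portfolio order A1...A28).
#' @return A `performance_matrix`.
#' @export
aggregate_runs <- function(records, mode = c("AVG", "BEST", "MEDIAN"),
                           instance_order = NULL, algorithm_order = NULL) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) stop("no run records supplied")
  rows <- if (is.null(instance_order)) unique(records$instance_id) else as.character(instance_order)
  cols <- if (is.null(algorithm_order)) unique(records$algorithm_id) else as.character(algorithm_order)
  ri <- match(records$instance_id, rows)
  ci <- match(records$algorithm_id, cols)
  if (anyNA(ri) || anyNA(ci))
    stop("records contain instance/algorithm ids outside the supplied ordering")
  fun <- switch(mode, AVG = mean, BEST = min, MEDIAN = stats::median)
  cell <- (ci - 1L) * length(rows) + ri
  agg <- tapply(records$binding_energy, cell, fun)
  vals <- matrix(NA_real_, length(rows), length(cols),
                 dimnames = list(rows, cols))
  vals[as.integer(names(agg))] <- agg
  if (anyNA(vals)) {
    miss <- which(is.na(vals), arr.ind = TRUE)
    stop("missing cells (no runs) for pairs: ",
         paste(rows[miss[, 1]], cols[miss[, 2]], sep = "/", collapse = ", "))
  }
  performance_matrix(vals, mode = mode)
}

#' Rank algorithms within each instance
#'
#' Converts a performance matrix into the rank data the selector consumes:
#' within each row, the algorithm with the lowest (best) binding energy gets
#' rank 1, and tied energies receive the average of the ranks they span, so
#' every row sums to n(n+1)/2 for n algorithms.
#'
#' @param perf a `performance_matrix` (or any complete numeric matrix with
#'   dimnames).
#' @return A matrix of class `rank_matrix` carrying the source `mode`
#'   attribute.
#' @export
rank_transform <- function(perf) {
  vals <- unclass(perf)
  if (any(!is.finite(vals))) stop("performance matrix has non-finite cells")
  ranks <- t(apply(vals, 1L, rank))  # ties.method = "average"
  if (ncol(vals) == 1L) ranks <- t(ranks)  # apply() drops the 1-column case
  dimnames(ranks) <- dimnames(vals)
  structure(ranks, mode = attr(perf, "mode"),
            class = c("rank_matrix", "matrix", "array"))
}

#' Per-algorithm rank summary
#'
#' Mean and population standard deviation of each algorithm's rank across
#' instances — the per-column statistics behind a mean-rank league table.
#' The mean of the mean ranks over all n algorithms is identically
#' (n + 1)/2.
#'
#' @param ranks a `rank_matrix`.
#' @param sd_type `"population"` (divide by m, the default) or `"sample"`.
#' @return A data frame with columns `algorithm`, `mean_rank`, `sd_rank`,
#'   in column order of `ranks`.
#' @export
summarize_mean_ranks <- function(ranks, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  m <- nrow(ranks)
  if (is.null(m) || m < 1L) stop("empty rank matrix")
  mu <- colMeans(ranks)
  dev <- sweep(unclass(ranks), 2L, mu)
  denom <- if (sd_type == "population") m else max(m - 1L, 1L)
  sds <- sqrt(colSums(dev^2) / denom)
  data.frame(algorithm = colnames(ranks), mean_rank = as.numeric(mu),
             sd_rank = as.numeric(sds), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read / write performance and rank matrices as CSV
#'
#' The CSV layout is a header row of algorithm ids and a first column of
#' instance ids. The aggregation mode travels in a JSON sidecar
#' (`<path>.meta.json`) so matrices stay joinable across tools.
#'
#' @param x a `performance_matrix` or `rank_matrix`.
#' @param path CSV file path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns the matrix with its `mode` attribute restored (as a
#'   `performance_matrix` unless the sidecar marks it as ranks).
#' @export
write_matrix_csv <- function(x, path) {
  df <- data.frame(instance_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(mode = attr(x, "mode"),
               kind = if (inherits(x, "rank_matrix")) "rank" else "performance")
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  mode <- if (!is.null(meta$mode)) meta$mode else "AVG"
  if (identical(meta$kind, "rank")) {
    structure(vals, mode = mode, class = c("rank_matrix", "matrix", "array"))
  } else {
    performance_matrix(vals, mode = mode)
  }
}
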