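#' Parse an AutoDock DLG docking log
#'
#' Harvests one binding energy per completed LGA run from an AutoDock 4-style
#' docking log. Each run reports a single final docked conformation whose
#' "Estimated Free Energy of Binding" line is taken as the run's outcome, in
#' kcal/mol (lower is better). Runs are numbered in order of appearance.
#'
#' @param log a path to a DLG file, or a character vector of log lines.
#' @param instance_id label of the docked ligand/instance.
#' @param algorithm_id label of the portfolio configuration that produced
#'   the log.
#' @return A `run_records` data frame with columns `instance_id`,
#'   `algorithm_id`, `run_index`, `binding_energy`.
#' @export
parse_dlg <- function(log, instance_id, algorithm_id) {
  lines <- if (length(log) == 1L && file.exists(log)) readLines(log, warn = FALSE) else log
  hits <- grep("Estimated Free Energy of Binding", lines)
  if (length(hits) == 0L)
    stop("empty log: no 'Estimated Free Energy of Binding' lines found")
  energies <- vapply(hits, function(i) {
    txt <- sub(".*Estimated Free Energy of Binding\\s*=\\s*", "", lines[i])
    num <- regmatches(txt, regexpr("^[+-]?[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", txt))
    if (length(num) == 0L)
      stop("malformed energy field on line ", i, ": ", trimws(lines[i]))
    as.numeric(num)
  }, numeric(1))
  run_records(instance_id = instance_id, algorithm_id = algorithm_id,
              run_index = seq_along(energies), binding_energy = energies)
}

#' Construct a table of docking run records
#'
#' Long-format container for repeated docking runs: one row per
#' (instance, algorithm, run) with its binding energy in kcal/mol.
#' Recycles scalar ids and validates uniqueness and finiteness.
#'
#' @param instance_id,algorithm_id,run_index,binding_energy vectors of equal
#'   (or recyclable) length.
#' @return A data frame of class `run_records`.
#' @export
run_records <- function(instance_id, algorithm_id, run_index, binding_energy) {
  rec <- data.frame(
    instance_id = as.character(instance_id),
    algorithm_id = as.character(algorithm_id),
    run_index = as.integer(run_index),
    binding_energy = as.numeric(binding_energy),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(rec$binding_energy)))
    stop("binding_energy must be finite")
  if (any(rec$run_index < 1L))
    stop("run_index must be >= 1")
  key <- paste(rec$instance_id, rec$algorithm_id, rec$run_index, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (instance_id, algorithm_id, run_index) records")
  class(rec) <- c("run_records", "data.frame")
  rec
}

#' Read / write run records as tab-separated text
#'
#' @param path file path of a TSV with columns `instance_id`,
#'   `algorithm_id`, `run_index`, `binding_energy`.
#' @return `read_run_records` returns a `run_records` data frame;
#'   `write_run_records` returns `path` invisibly.
#' @export
read_run_records <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  run_records(df$instance_id, df$algorithm_id, df$run_index, df$binding_energy)
}

#' @rdname read_run_records
#' @param records a `run_records` data frame.
#' @export
write_run_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
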