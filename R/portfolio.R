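#' Canonical LGA docking-algorithm portfolio
#'
#' Builds the 28-configuration portfolio of Lamarckian Genetic Algorithm
#' (LGA) variants used throughout the package. Configurations A1--A27 span
#' the full 3x3x3 grid over population size \{50, 150, 200\}, mutation rate
#' \{0.02, 0.5, 0.8\} and energy-window size \{10, 30, 50\}, all with the
#' pseudo-Solis-and-Wets local searcher (`psw`). A28 repeats the AutoDock
#' default parameterisation (150, 0.02, 10) with the classical
#' Solis-and-Wets local searcher (`sw`).
#'
#' @return A data frame of class `algorithm_portfolio` with columns
#'   `id`, `population_size`, `mutation_rate`, `window_size`,
#'   `local_search`, one row per configuration, in A1...A28 order.
#' @examples
#' pf <- build_portfolio()
#' nrow(pf)            # 28
#' pf[pf$id == "A28", ]
#' @export
build_portfolio <- function() {
  grid <- rbind(
    c(50, 0.02, 10),  # A1
    c(150, 0.02, 10), # A2  (AutoDock default parameters)
    c(200, 0.02, 10), # A3
    c(150, 0.50, 10), # A4
    c(150, 0.80, 10), # A5
    c(150, 0.02, 30), # A6
    c(150, 0.02, 50), # A7
    c(50, 0.02, 30),  # A8
    c(50, 0.02, 50),  # A9
    c(200, 0.02, 30), # A10
    c(50, 0.50, 10),  # A11
    c(50, 0.50, 30),  # A12
    c(50, 0.50, 50),  # A13
    c(50, 0.80, 10),  # A14
    c(50, 0.80, 30),  # A15
    c(50, 0.80, 50),  # A16
    c(150, 0.50, 30), # A17
    c(150, 0.50, 50), # A18
    c(150, 0.80, 30), # A19
    c(150, 0.80, 50), # A20
    c(200, 0.02, 50), # A21
    c(200, 0.50, 10), # A22
    c(200, 0.50, 30), # A23
    c(200, 0.50, 50), # A24
    c(200, 0.80, 10), # A25
    c(200, 0.80, 30), # A26
    c(200, 0.80, 50), # A27
    c(150, 0.02, 10)  # A28 (sw local searcher)
  )
  pf <- data.frame(
    id = paste0("A", seq_len(28)),
    population_size = as.integer(grid[, 1]),
    mutation_rate = grid[, 2],
    window_size = as.integer(grid[, 3]),
    local_search = c(rep("psw", 27), "sw"),
    stringsAsFactors = FALSE
  )
  class(pf) <- c("algorithm_portfolio", "data.frame")
  validate_portfolio(pf)
  pf
}

#' Validate an algorithm portfolio
#'
#' Checks the structural invariants of a portfolio table: unique ids,
#' mutation rates in \[0, 1\], positive integer population and window sizes,
#' and a recognised local-search label.
#'
#' @param pf a portfolio data frame as returned by [build_portfolio()].
#' @return `pf`, invisibly, if valid; otherwise an error.
#' @export
validate_portfolio <- function(pf) {
  required <- c("id", "population_size", "mutation_rate", "window_size",
                "local_search")
  if (!all(required %in% names(pf)))
    stop("portfolio is missing columns: ",
         paste(setdiff(required, names(pf)), collapse = ", "))
  if (anyDuplicated(pf$id))
    stop("portfolio ids are not unique")
  if (any(pf$mutation_rate < 0 | pf$mutation_rate > 1))
    stop("mutation_rate must lie in [0, 1]")
  if (any(pf$population_size < 1) || any(pf$window_size < 1))
    stop("population_size and window_size must be >= 1")
  if (!all(pf$local_search %in% c("psw", "sw")))
    stop("local_search must be 'psw' or 'sw'")
  invisible(pf)
}
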