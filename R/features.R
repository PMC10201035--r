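#' Construct an instance feature table
#'
#' Instance-by-feature matrix F(I) used to characterise docking instances
#' (ligands). `kind = "md"` marks continuous molecular descriptors,
#' `kind = "sf"` marks substructure fingerprints — for the canonical PubChem
#' Substructure Fingerprint the raw table must be 881 binary columns —
#' and `kind = "mixed"` marks concatenations of both.
#'
#' @param values numeric matrix with instance row names and unique feature
#'   column names.
#' @param kind `"md"`, `"sf"` or `"mixed"`.
#' @param canonical_sf if `TRUE` (default) a `kind = "sf"` table is required
#'   to have exactly 881 columns; set `FALSE` for fingerprint subsets.
#' @return A matrix of class `feature_table` with a `kind` attribute.
#' @export
feature_table <- function(values, kind = c("md", "sf", "mixed"),
                          canonical_sf = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || (ncol(values) > 0L && is.null(colnames(values))))
    stop("feature table needs instance row names and feature column names")
  if (anyDuplicated(colnames(values)))
    stop("feature names must be unique")
  if (kind == "sf") {
    if (!all(values %in% c(0, 1)))
      stop("substructure fingerprint tables must be binary (0/1)")
    if (canonical_sf && ncol(values) != 881L)
      stop("canonical substructure fingerprint tables have 881 bits, got ",
           ncol(values))
  }
  structure(values, kind = kind,
            class = c("feature_table", "matrix", "array"))
}

as_feature_table <- function(values, template) {
  structure(as.matrix(values), kind = attr(template, "kind"),
            class = c("feature_table", "matrix", "array"))
}

#' Drop features that are zero on every instance
#'
#' First cleaning pass over a raw descriptor table: any feature whose value
#' is exactly 0 for all instances carries no information and is removed.
#' Surviving column order is preserved.
#'
#' @param t a `feature_table`.
#' @return The filtered `feature_table` (possibly with zero columns).
#' @export
drop_zero_features <- function(t) {
  keep <- colSums(unclass(t) != 0) > 0
  if (!any(keep)) message("drop_zero_features: no features survive")
  as_feature_table(unclass(t)[, keep, drop = FALSE], t)
}

#' Drop near-constant features
#'
#' Removes every feature whose single most frequent value occurs in at
#' least `dominance * m` of the m instances — the operational form of
#' discarding features with almost the same value on all ligands. Applied
#' after [drop_zero_features()] this reproduces the descriptor-table
#' shrinkage from 208 raw descriptors to the usable feature set.
#'
#' @param t a `feature_table`.
#' @param dominance dominant-value fraction threshold in (0.5, 1\];
#'   default 0.99.
#' @return The filtered `feature_table`; dropped names are attached as
#'   attribute `dropped`.
#' @export
drop_near_constant <- function(t, dominance = 0.99) {
  if (dominance <= 0.5 || dominance > 1)
    stop("dominance must lie in (0.5, 1]")
  m <- nrow(t)
  frac <- apply(unclass(t), 2L, function(x) max(tabulate(match(x, unique(x)))) / m)
  keep <- frac < dominance
  out <- as_feature_table(unclass(t)[, keep, drop = FALSE], t)
  attr(out, "dropped") <- colnames(t)[!keep]
  out
}

#' Fit and apply min-max normalization
#'
#' `fit_minmax` records the per-feature minimum and maximum of a table;
#' `apply_minmax` maps x to (x - min)/(max - min), which sends the fitted
#' table into \[0, 1\]. Constant features (max = min) map to 0. Values from
#' a different table (e.g. cross-validation test rows) may fall outside
#' \[0, 1\] and are deliberately not clipped.
#'
#' @param t a `feature_table`.
#' @return `fit_minmax` returns a `normalization_params` data frame with
#'   columns `feature`, `min`, `max`.
#' @export
fit_minmax <- function(t) {
  vals <- unclass(t)
  p <- data.frame(feature = colnames(vals),
                  min = apply(vals, 2L, min),
                  max = apply(vals, 2L, max),
                  row.names = NULL, stringsAsFactors = FALSE)
  class(p) <- c("normalization_params", "data.frame")
  p
}

#' @rdname fit_minmax
#' @param p a `normalization_params` object covering every feature of `t`.
#' @export
apply_minmax <- function(t, p) {
  vals <- unclass(t)
  idx <- match(colnames(vals), p$feature)
  if (anyNA(idx))
    stop("normalization parameters missing for feature(s): ",
         paste(colnames(vals)[is.na(idx)], collapse = ", "))
  lo <- p$min[idx]
  span <- p$max[idx] - p$min[idx]
  scaled <- sweep(vals, 2L, lo)
  scaled <- sweep(scaled, 2L, ifelse(span > 0, span, 1), "/")
  scaled[, span == 0] <- 0
  out <- as_feature_table(scaled, t)
  attr(out, "normalization") <- p
  out
}

#' Select features by importance score
#'
#' Subsets a feature table either by an importance cutoff (keep scores
#' >= `cutoff`, e.g. the Gini-importance cutoff 0.15) or by keeping the
#' `top_n` highest-scoring features (score ties broken by feature name
#' order). Survivors keep their original column order.
#'
#' @param t a `feature_table`.
#' @param importances named numeric scores covering all features of `t`.
#' @param rule a list with exactly one of `cutoff` or `top_n`.
#' @return The subset `feature_table`.
#' @export
select_top_features <- function(t, importances, rule) {
  feats <- colnames(t)
  idx <- match(feats, names(importances))
  if (anyNA(idx))
    stop("importances missing for feature(s): ",
         paste(feats[is.na(idx)], collapse = ", "))
  scores <- as.numeric(importances)[idx]
  if (!is.null(rule$cutoff)) {
    keep <- scores >= rule$cutoff
  } else if (!is.null(rule$top_n)) {
    n <- rule$top_n
    if (n > length(feats)) stop("top_n exceeds the number of features")
    ord <- order(-scores, feats)
    keep <- seq_along(feats) %in% ord[seq_len(n)]
  } else {
    stop("rule must supply either 'cutoff' or 'top_n'")
  }
  out <- as_feature_table(unclass(t)[, keep, drop = FALSE], t)
  if (attr(t, "kind") == "sf") attr(out, "kind") <- "sf"
  out
}

#' Concatenate two feature tables column-wise
#'
#' Joins descriptor and fingerprint tables for the same instances (same
#' row ids, same order) into one `mixed` table. Colliding feature names are
#' disambiguated with a `<kind>.` prefix.
#'
#' @param a,b `feature_table`s with identical `row_ids` in identical order.
#' @return A `feature_table` with `kind = "mixed"`.
#' @export
combine_feature_sets <- function(a, b) {
  if (!identical(rownames(a), rownames(b)))
    stop("feature tables must share identical instance ids in identical order")
  if (ncol(b) == 0L) {
    out <- as_feature_table(unclass(a), a)
    attr(out, "kind") <- "mixed"
    return(out)
  }
  na <- colnames(a); nb <- colnames(b)
  clash <- intersect(na, nb)
  if (length(clash)) {
    na[na %in% clash] <- paste(attr(a, "kind"), na[na %in% clash], sep = ".")
    nb[nb %in% clash] <- paste(attr(b, "kind"), nb[nb %in% clash], sep = ".")
  }
  vals <- cbind(unclass(a), unclass(b))
  colnames(vals) <- c(na, nb)
  structure(vals, kind = "mixed",
            class = c("feature_table", "matrix", "array"))
}

#' Read feature tables from CSV/TSV
#'
#' `read_feature_csv` expects instances x named features with the instance
#' id in the first column. `read_fingerprint_strings` reads the compact
#' fingerprint format: one line per instance, `id,<881-character 0/1
#' string>`, and expands it into an 881-column binary table with bit names
#' `PubchemFP1...PubchemFP881`.
#'
#' @param path input file.
#' @param kind feature kind for `read_feature_csv`.
#' @param sep field separator, `","` for CSV (default) or `"\t"` for TSV.
#' @return A `feature_table`.
#' @export
read_feature_csv <- function(path, kind = c("md", "sf", "mixed"), sep = ",") {
  kind <- match.arg(kind)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  feature_table(vals, kind = kind, canonical_sf = FALSE)
}

#' @rdname read_feature_csv
#' @export
read_fingerprint_strings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  bits <- vapply(parts, `[[`, character(1), 2L)
  if (any(nchar(bits) != 881L))
    stop("fingerprint strings must be 881 characters of 0/1")
  vals <- do.call(rbind, lapply(strsplit(bits, ""), as.integer))
  dimnames(vals) <- list(ids, paste0("PubchemFP", seq_len(881L)))
  feature_table(vals, kind = "sf")
}

#' @rdname read_feature_csv
#' @param t a `feature_table` to write.
#' @export
write_feature_csv <- function(t, path) {
  df <- data.frame(instance_id = rownames(t), unclass(t),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
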