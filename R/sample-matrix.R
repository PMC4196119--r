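#' Sample-by-feature matrix with feature provenance
#'
#' A light container for a numeric samples-x-features matrix where each feature
#' is tagged with its source assay (`"expression"` or `"copy_number"`). Row
#' names are sample ids, column names feature ids; both must be unique, values
#' must be finite.
#'
#' @param values Numeric matrix, samples as rows, with unique row and column
#'   names.
#' @param feature_source Character vector of length `ncol(values)` with entries
#'   `"expression"` or `"copy_number"`, or a single value recycled to all
#'   features.
#' @return An object of class `sample_matrix`.
#' @export
sample_matrix <- function(values, feature_source = "expression") {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (nrow(values) < 2L || ncol(values) < 1L)
    stopf("a sample matrix needs at least 2 samples and 1 feature")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate feature ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stopf("`values` contains non-finite entries; resolve or reject missing data at load")
  if (length(feature_source) == 1L)
    feature_source <- rep(feature_source, ncol(values))
  if (length(feature_source) != ncol(values))
    stopf("`feature_source` must have one tag per feature")
  if (!all(feature_source %in% c("expression", "copy_number")))
    stopf("feature_source tags must be 'expression' or 'copy_number'")
  structure(list(values = values, feature_source = feature_source),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  src <- table(x$feature_source)
  cat(sprintf("<sample_matrix> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(src), src), collapse = ", ")))
  invisible(x)
}

#' @export
dim.sample_matrix <- function(x) dim(x$values)

#' @export
as.matrix.sample_matrix <- function(x, ...) x$values

#' @export
as_tibble.sample_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = rownames(x$values)),
                   as_tibble(x$values, .name_repair = "minimal"))
}

sample_ids <- function(m) rownames(m$values)
feature_ids <- function(m) colnames(m$values)

as_values_matrix <- function(x) {
  if (inherits(x, "sample_matrix")) x$values else as.matrix(x)
}

#' Read a delimited sample-by-feature matrix
#'
#' Expects a header row of feature ids and sample ids in the first column.
#' Non-numeric cells and duplicate ids are rejected with informative errors.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, default tab.
#' @param feature_source Source tag applied to all features in the file.
#' @return A [sample_matrix()].
#' @export
read_sample_matrix <- function(path, delimiter = "\t", feature_source = "expression") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2L) stopf("expected sample ids in column 1 plus >= 1 feature column")
  ids <- raw[[1L]]
  feats <- colnames(raw)[-1L]
  if (anyDuplicated(feats))
    stopf("duplicate feature ids in header: %s",
          paste(unique(feats[duplicated(feats)]), collapse = ", "))
  if (anyDuplicated(ids))
    stopf("duplicate sample ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("non-numeric or missing cell at sample '%s', feature '%s' (value '%s')",
          ids[bad[1L, 1L]], feats[bad[1L, 2L]], vals[bad[1L, 1L], bad[1L, 2L]])
  dimnames(num) <- list(ids, feats)
  sample_matrix(num, feature_source)
}

#' Write a sample matrix in the same delimited dialect
#'
#' @param m A [sample_matrix()].
#' @param path Output path.
#' @param delimiter Field separator, default tab.
#' @export
write_sample_matrix <- function(m, path, delimiter = "\t") {
  df <- data.frame(sample_id = sample_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Robust linear scaling of each feature to quantile anchors
#'
#' Per feature, an affine map sends the `q_low` quantile to 0 and the `q_high`
#' quantile to 1 (quantiles by linear interpolation of order statistics, type
#' 7); values outside the anchors are clipped to \[0, 1\], which removes
#' outliers. Constant features map to all zeros with a warning.
#'
#' @param m A [sample_matrix()].
#' @param q_low,q_high Quantile anchors, defaults 0.02 and 0.98.
#' @return A scaled [sample_matrix()] with all entries in \[0, 1\].
#' @export
robust_scale <- function(m, q_low = 0.02, q_high = 0.98) {
  assert_scalar_num(q_low, "q_low", 0, 1)
  assert_scalar_num(q_high, "q_high", 0, 1)
  if (q_low >= q_high) stopf("q_low must be smaller than q_high")
  x <- m$values
  qs <- apply(x, 2L, quantile, probs = c(q_low, q_high), type = 7, names = FALSE)
  span <- qs[2L, ] - qs[1L, ]
  flat <- span <= 0
  span[flat] <- 1
  out <- sweep(sweep(x, 2L, qs[1L, ], "-"), 2L, span, "/")
  out[, flat] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (any(flat))
    warnf("%d constant feature(s) mapped to all zeros (e.g. %s)",
          sum(flat), colnames(x)[which(flat)[1L]])
  sample_matrix(out, m$feature_source)
}

#' Stack expression and copy-number matrices feature-wise
#'
#' Aligns the two blocks by sample id (order of `expr` wins), prefixes feature
#' ids with their source so shared gene symbols cannot collide, and preserves
#' per-feature source tags.
#'
#' @param expr Expression [sample_matrix()].
#' @param cna Copy-number [sample_matrix()].
#' @return A stacked [sample_matrix()] with `ncol(expr) + ncol(cna)` features.
#' @export
stack_features <- function(expr, cna) {
  ids_e <- sample_ids(expr)
  ids_c <- sample_ids(cna)
  if (!setequal(ids_e, ids_c)) {
    miss <- c(setdiff(ids_e, ids_c), setdiff(ids_c, ids_e))
    stopf("sample ids do not match between blocks; unmatched: %s",
          paste(miss, collapse = ", "))
  }
  cna_vals <- cna$values[match(ids_e, ids_c), , drop = FALSE]
  vals <- cbind(expr$values, cna_vals)
  colnames(vals) <- c(paste0("expr:", feature_ids(expr)),
                      paste0("cna:", colnames(cna$values)))
  sample_matrix(vals, c(expr$feature_source, cna$feature_source))
}

#' Slice a stacked matrix back into one source block
#'
#' Inverse of [stack_features()] for one block: selects the features with the
#' given source tag and strips the source prefix from their ids.
#'
#' @param m A stacked [sample_matrix()].
#' @param source `"expression"` or `"copy_number"`.
#' @return A [sample_matrix()] holding only that block.
#' @export
split_by_source <- function(m, source = c("expression", "copy_number")) {
  source <- match.arg(source)
  keep <- m$feature_source == source
  if (!any(keep)) stopf("no features with source '%s'", source)
  vals <- m$values[, keep, drop = FALSE]
  colnames(vals) <- sub("^(expr|cna):", "", colnames(vals))
  sample_matrix(vals, source)
}

#' Validate a clinical table
#'
#' Checks the survival columns of a clinical table: unique sample ids,
#' nonnegative times (years), event indicator in \{0 = censored, 1 = event\}.
#' Extra columns are carried along as covariates or display annotation.
#'
#' @param df A data frame with columns `sample_id`, `time`, `event` and
#'   optional covariate columns.
#' @return The validated table as a tibble.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("clinical table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- as_tibble(df)
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample ids in clinical table")
  if (any(!is.finite(df$time)) || any(df$time < 0))
    stopf("survival times must be finite and >= 0")
  if (!all(df$event %in% c(0, 1)))
    stopf("event indicator must be 0 (censored) or 1 (event)")
  df
}

#' Read a clinical table from a delimited file
#'
#' @param path File with header `sample_id,time,event,<covariates...>`.
#' @param delimiter Field separator, default tab.
#' @return A validated clinical tibble.
#' @export
read_clinical_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  clinical_table(utils::read.table(path, sep = delimiter, header = TRUE,
                                   check.names = FALSE, stringsAsFactors = FALSE))
}

#' Remove samples censored before a minimum follow-up
#'
#' Samples censored (`event == 0`) before `min_years` of follow-up carry little
#' information about long-term outcome and confound endpoint-based feature
#' selection, so they are removed. Samples with an observed event are retained
#' at any follow-up by default; `drop_all_short = TRUE` reproduces the stricter
#' rule of dropping every sample with follow-up below the threshold.
#'
#' @param m A [sample_matrix()].
#' @param clinical A clinical table covering all samples of `m`.
#' @param min_years Follow-up threshold in years, default 10.
#' @param drop_all_short Drop short-follow-up samples regardless of event
#'   status.
#' @return A list with the filtered `matrix` and `clinical` table (aligned).
#' @export
filter_short_followup <- function(m, clinical, min_years = 10, drop_all_short = FALSE) {
  clinical <- clinical_table(clinical)
  ids <- sample_ids(m)
  if (!all(ids %in% clinical$sample_id))
    stopf("clinical table lacks sample(s): %s",
          paste(setdiff(ids, clinical$sample_id), collapse = ", "))
  cl <- clinical[match(ids, clinical$sample_id), ]
  keep <- if (drop_all_short) cl$time >= min_years
          else cl$event == 1 | cl$time >= min_years
  if (!any(keep)) stopf("no samples survive censoring filter")
  message(sprintf("censoring filter removed %d of %d samples (min_years = %g)",
                  sum(!keep), length(keep), min_years))
  list(matrix = sample_matrix(m$values[keep, , drop = FALSE],
                              m$feature_source),
       clinical = cl[keep, ])
}

#' Per-sample copy-number alteration frequency
#'
#' The CNA frequency of a sample is the sum of the magnitudes of its copy-number
#' alterations (amplifications and deletions) across all genes, i.e. the row sum
#' of absolute values of the copy-number block (0 = neutral).
#'
#' @param cna A [sample_matrix()] whose features are all copy-number.
#' @return A tibble with `sample_id` and `cna_frequency`.
#' @export
cna_frequency <- function(cna) {
  if (!all(cna$feature_source == "copy_number"))
    stopf("cna_frequency expects a copy-number-only matrix")
  tibble(sample_id = sample_ids(cna),
         cna_frequency = unname(rowSums(abs(cna$values))))
}
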