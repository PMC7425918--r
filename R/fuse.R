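#' Collapse repetition blocks of a feature column by rank-1 SVD
#'
#' Each block of `block_size` consecutive same-configuration records is
#' reduced to the scalar representative of its rank-1 SVD: for a 1-column
#' block this is the block's root-mean-square (`sigma_1 / sqrt(b)`) with
#' the sign of the block mean (non-negative when the mean is exactly 0).
#' Under the default protocol (6750 tumor records, 50 repetitions) each
#' column collapses to 135 rows. Deterministic. A trailing partial block
#' is collapsed too, with a warning.
#'
#' @param column numeric per-record column.
#' @param block_size records per block (consecutive).
#' @param blocks optional explicit block index per record (overrides
#'   `block_size`); must label consecutive runs.
#' @return numeric vector, one representative per block
#'   (`ceiling(length(column) / block_size)` values).
#' @export
collapse_reps <- function(column, block_size = 50L, blocks = NULL) {
  assert_numeric_vector(column, "column")
  if (is.null(blocks)) {
    if (block_size < 1L) stopf("block_size must be >= 1")
    if (length(column) %% block_size != 0L) {
      warning("column length not divisible by block_size; trailing partial block",
              call. = FALSE)
    }
    blocks <- (seq_along(column) - 1L) %/% block_size + 1L
  }
  vapply(split(column, blocks), function(b) {
    rms <- sqrt(mean(b^2))
    if (mean(b) < 0) -rms else rms
  }, numeric(1), USE.NAMES = FALSE)
}

#' Assemble a hybrid dataset of the top-m ranked feature columns
#'
#' Takes the first `m` columns of the rank-ordered feature columns (rank =
#' descending selection F-value), keeps the per-record values for
#' classification, and evaluates the hybrid's matrix-level F on the
#' repetition-collapsed matrix (one row per acquisition configuration,
#' via [collapse_reps()]).
#'
#' @param ranked records x K numeric matrix whose columns are in rank
#'   order (named `FEATURE-METHOD`).
#' @param m hybrid width, `2 <= m <= ncol(ranked)`.
#' @param labels class factor per record; must be constant within each
#'   repetition block.
#' @param block_size repetitions per acquisition configuration.
#' @return A `hybrid_dataset`: list with `columns` (names), `values`
#'   (records x m), `m`, `eval_F`, `eval_p`, `labels`, `collapsed`
#'   (blocks x m), `collapsed_labels`.
#' @export
assemble_hybrid <- function(ranked, m, labels, block_size = 50L) {
  ranked <- as.matrix(ranked)
  if (m < 2L || m > ncol(ranked)) {
    stopf("m must be between 2 and %d", ncol(ranked))
  }
  labels <- droplevels(as.factor(labels))
  if (nrow(ranked) != length(labels)) stopf("labels must match rows")
  blocks <- (seq_len(nrow(ranked)) - 1L) %/% block_size + 1L
  if (any(tapply(as.integer(labels), blocks, function(l) length(unique(l))) > 1L)) {
    stopf("repetition blocks mix class labels; check record ordering")
  }
  values <- ranked[, seq_len(m), drop = FALSE]
  collapsed <- vapply(seq_len(m),
                      function(j) collapse_reps(values[, j], block_size),
                      numeric(length(unique(blocks))))
  collapsed <- matrix(collapsed, ncol = m,
                      dimnames = list(NULL, colnames(values)))
  collapsed_labels <- labels[!duplicated(blocks)]
  ev <- matrix_statistic(collapsed, collapsed_labels)
  structure(list(columns = colnames(values), values = values, m = as.integer(m),
                 eval_F = ev$F, eval_p = ev$p, labels = labels,
                 collapsed = collapsed, collapsed_labels = collapsed_labels),
            class = "hybrid_dataset")
}

#' @export
print.hybrid_dataset <- function(x, ...) {
  cat(sprintf("<hybrid_dataset> m = %d (%s), eval F = %.4g\n", x$m,
              paste(head(x$columns, 3), collapse = ", "), x$eval_F))
  invisible(x)
}

#' Scan hybrid widths and mark the top-3 by F-value
#'
#' Evaluates [assemble_hybrid()] for every width in `m_range` (default 10
#' down to 2) and marks the three widths with the highest matrix-level F
#' as the named hybrid datasets (`<m>-HybridFeature`).
#'
#' @inheritParams assemble_hybrid
#' @param m_range integer widths to scan, each within
#'   `[2, ncol(ranked)]`.
#' @return data.frame with columns `m`, `F`, `p`, `dataset_name`
#'   (`<m>-HybridFeature` for the top-3, `NA` otherwise), in `m_range`
#'   order, with the scanned `hybrid_dataset` objects in
#'   `attr(, "hybrids")`.
#' @export
scan_hybrid_widths <- function(ranked, m_range = 10:2, labels,
                               block_size = 50L) {
  if (any(m_range < 2L) || any(m_range > ncol(as.matrix(ranked)))) {
    stopf("m_range must lie within [2, %d]", ncol(as.matrix(ranked)))
  }
  hybrids <- lapply(m_range, assemble_hybrid, ranked = ranked, labels = labels,
                    block_size = block_size)
  res <- data.frame(m = as.integer(m_range),
                    F = vapply(hybrids, `[[`, numeric(1), "eval_F"),
                    p = vapply(hybrids, `[[`, numeric(1), "eval_p"))
  top3 <- order(-res$F)[seq_len(min(3L, nrow(res)))]
  res$dataset_name <- NA_character_
  res$dataset_name[top3] <- paste0(res$m[top3], "-HybridFeature")
  names(hybrids) <- res$m
  attr(res, "hybrids") <- hybrids
  res
}
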