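#' One-way ANOVA of a feature column across size classes
#'
#' Classical one-way fixed-effects ANOVA (equal-variance F test, via
#' [stats::oneway.test()]) of a numeric column against the tumor-size
#' class labels. This is the statistic behind every selection step of the
#' pipeline: a large F means the between-class variance dominates the
#' within-class variance.
#'
#' @param values numeric column, one value per record.
#' @param labels class factor (>= 2 classes, each with >= 2 members).
#' @return An `anova_result`: list with `F`, `p`, `df_between`,
#'   `df_within`.
#' @export
#' @examples
#' anova_column(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 3)))
anova_column <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  assert_numeric_vector(values, "values", min_len = 4L)
  if (length(values) != length(labels)) stopf("values/labels length mismatch")
  counts <- table(labels)
  if (length(counts) < 2L) stopf("need >= 2 classes")
  if (any(counts < 2L)) stopf("every class needs >= 2 members")
  ht <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  structure(list(F = unname(ht$statistic), p = unname(ht$p.value),
                 df_between = unname(ht$parameter[1]),
                 df_within = unname(ht$parameter[2])),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Matrix-level ANOVA statistic
#'
#' Collapses a records x features matrix to one (F, p) pair. The default
#' (`standardized_rowmean`) standardizes every column to zero mean and
#' unit (population) sd, drops constant columns with a warning, takes the
#' per-record mean across columns, and runs [anova_column()] on that
#' summary vector. The alternative (`mean_F`) reports the mean of the
#' column-wise F values; it has no exact null distribution, so its p is
#' `NA`.
#'
#' @param x records x features numeric matrix.
#' @param labels class factor per record.
#' @param method `"standardized_rowmean"` (default) or `"mean_F"`.
#' @return An `anova_result` (for `mean_F`, `p`, `df_*` are `NA`).
#' @export
matrix_statistic <- function(x, labels,
                             method = c("standardized_rowmean", "mean_F")) {
  x <- as.matrix(x)
  method <- match.arg(method)
  if (method == "mean_F") {
    f <- apply(x, 2L, function(col) anova_column(col, labels)$F)
    return(structure(list(F = mean(f), p = NA_real_, df_between = NA_integer_,
                          df_within = NA_integer_),
                     class = "anova_result"))
  }
  mu <- colMeans(x)
  sdev <- sqrt(pmax(colMeans(x^2) - mu^2, 0))
  keep <- sdev > 0
  if (!any(keep)) stopf("all columns are constant")
  if (!all(keep)) {
    warning(sprintf("%d constant column(s) dropped from the row mean",
                    sum(!keep)), call. = FALSE)
  }
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdev[keep], "/")
  anova_column(rowMeans(z), labels)
}

#' Select top candidates by significance then F-value
#'
#' The pipeline's two-criterion selection rule: keep candidates with
#' p < `alpha`, order them by descending F, and take the first `k`.
#' Ties on F keep the candidates' input order (candidates are enumerated
#' in the fixed feature-within-method order, so ties resolve the way the
#' ranking tables print them); the sort is stable.
#'
#' @param candidates data.frame with columns `name`, `F`, `p` (extra
#'   columns are carried through).
#' @param alpha significance level.
#' @param k number of candidates to keep.
#' @return A `selection_report`: list with `candidates`, `passed_alpha`
#'   (names), `selected` (data.frame, F non-increasing), `alpha`, `k`,
#'   `underfilled` (TRUE when fewer than `k` candidates pass `alpha`).
#' @export
select_top <- function(candidates, alpha = 0.05, k) {
  if (k < 1L) stopf("k must be >= 1")
  stopifnot(is.data.frame(candidates),
            all(c("name", "F", "p") %in% names(candidates)))
  passed <- candidates[candidates$p < alpha, , drop = FALSE]
  ord <- order(-passed$F)           # stable: ties keep input order
  selected <- head(passed[ord, , drop = FALSE], k)
  rownames(selected) <- NULL
  structure(list(candidates = candidates,
                 passed_alpha = passed$name,
                 selected = selected,
                 alpha = alpha, k = as.integer(k),
                 underfilled = nrow(passed) < k),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d/%d passed alpha = %g; selected %d%s\n",
              length(x$passed_alpha), nrow(x$candidates), x$alpha,
              nrow(x$selected), if (x$underfilled) " (underfilled)" else ""))
  if (nrow(x$selected)) {
    print(x$selected[, c("name", "F", "p")], row.names = FALSE)
  }
  invisible(x)
}
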