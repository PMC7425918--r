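#' Fit a centered principal-component model
#'
#' Standard centered PCA via the eigendecomposition of the (population)
#' covariance matrix. Components are ordered by non-increasing explained
#' variance; components with (numerically) zero variance are truncated, so
#' rank-deficient input yields fewer components than columns. Each
#' loading's sign is fixed by convention: the largest-magnitude element of
#' every loading vector is positive, making the fit deterministic.
#'
#' @param x numeric matrix, records x variables (>= 2 rows and columns).
#' @param var_tol relative eigenvalue tolerance below which a component is
#'   treated as zero-variance and truncated.
#' @return A `pca_model`: list with `loadings` (orthonormal columns),
#'   `explained_variance` (non-increasing), `center`.
#' @export
fit_pca <- function(x, var_tol = 1e-12) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stopf("fit_pca needs >= 2 rows and columns")
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  ev <- eigen(crossprod(xc) / nrow(x), symmetric = TRUE)
  keep <- ev$values > max(ev$values[1], 0) * var_tol & ev$values > 0
  if (!any(keep)) stopf("input has no variance")
  load <- ev$vectors[, keep, drop = FALSE]
  # sign convention: largest-|loading| element positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(loadings = load, explained_variance = ev$values[keep],
                 center = ctr),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, top variance ratios: %s\n",
              ncol(x$loadings),
              paste(signif(head(x$explained_variance, 3) /
                             sum(x$explained_variance), 3), collapse = ", ")))
  invisible(x)
}

#' Project data onto a fitted PCA basis
#'
#' @param model a [fit_pca()] model.
#' @param x records x variables matrix (same variables as the fit).
#' @return records x components score matrix.
#' @export
pca_scores <- function(model, x) {
  sweep(as.matrix(x), 2L, model$center) %*% model$loadings
}

#' Backward elimination of trailing principal components
#'
#' Stage-1 reduction rule: starting from all retained components
#' (variance-ordered), test the matrix-level ANOVA significance of the
#' current score matrix across the size classes; while it is not
#' significant (p >= `alpha`), drop the last (lowest-variance) retained
#' column and retest. Stops at the first width with p < `alpha`. If the
#' floor (`min_components`) is reached without significance the floor
#' configuration is returned flagged non-significant. The full
#' (width, F, p) trace of visited configurations is recorded.
#'
#' @param scores records x components score matrix (variance-ordered).
#' @param labels class factor, one per record.
#' @param alpha significance level (default 0.05).
#' @param min_components smallest width the elimination may reach.
#' @param statistic matrix-level statistic, see [matrix_statistic()].
#' @return A `reduced_matrix`: list with `scores` (a column-prefix of the
#'   input), `retained_count`, `p_trace` (data.frame: n_components, F, p),
#'   `significant`.
#' @export
reduce_by_significance <- function(scores, labels, alpha = 0.05,
                                   min_components = 1L,
                                   statistic = c("standardized_rowmean",
                                                 "mean_F")) {
  scores <- as.matrix(scores)
  statistic <- match.arg(statistic)
  labels <- droplevels(as.factor(labels))
  if (nrow(scores) != length(labels)) stopf("scores rows must match labels")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0, 1)")
  c_max <- ncol(scores)
  min_components <- max(1L, as.integer(min_components))

  # incremental row sums of column-standardized scores, so each visited
  # width costs O(records) instead of re-touching the whole prefix
  mu <- colMeans(scores)
  sdev <- sqrt(colMeans(scores^2) - mu^2)
  valid <- sdev > 0
  z <- sweep(scores[, valid, drop = FALSE], 2L,  mu[valid])
  z <- sweep(z, 2L, sdev[valid], "/")
  valid_cum <- cumsum(valid)

  width <- c_max
  rs <- rowSums(z[, seq_len(valid_cum[width]), drop = FALSE])
  trace <- list()
  repeat {
    n_valid <- valid_cum[width]
    res <- if (n_valid == 0L) {
      list(F = NA_real_, p = NA_real_)   # all-constant prefix: undecidable
    } else if (statistic == "standardized_rowmean") {
      anova_column(rs / n_valid, labels)
    } else {
      matrix_statistic(scores[, seq_len(width), drop = FALSE], labels,
                       method = statistic)
    }
    trace[[length(trace) + 1L]] <- data.frame(n_components = width,
                                              F = res$F, p = res$p)
    if (!is.na(res$p) && res$p < alpha) {
      significant <- TRUE
      break
    }
    if (width <= min_components) {
      significant <- FALSE
      break
    }
    if (valid[width]) rs <- rs - z[, valid_cum[width]]
    width <- width - 1L
  }
  structure(list(scores = scores[, seq_len(width), drop = FALSE],
                 retained_count = width,
                 p_trace = do.call(rbind, trace),
                 significant = significant),
            class = "reduced_matrix")
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(sprintf("<reduced_matrix> retained %d components (p = %.4g, %s)\n",
              x$retained_count, x$p_trace$p[nrow(x$p_trace)],
              if (x$significant) "significant" else "floor, non-significant"))
  invisible(x)
}
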