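#' @name features
#' @title The Stage-2 feature extractors
#'
#' @description
#' Ten extractors, each mapping one record to one scalar, assembled into
#' a records x 10 feature matrix in the fixed column order
#' `SD, M, V, S, SE, ICA, SU, PSD, MAX, MIN`:
#'
#' * `M`, `SD`, `V`, `S` - mean, population standard deviation, population
#'   variance and skewness (`m3 / m2^1.5`) of the record's vector.
#' * `SE` - Shannon entropy of the energy distribution:
#'   `-sum(p_i log p_i)` with `p_i = v_i^2 / sum(v^2)` (natural log; zero
#'   terms contribute 0).
#' * `SU` - sure entropy `sum(min(v_i^2, eps^2))` with the threshold `eps`
#'   selected by minimizing Stein's unbiased risk estimate of soft
#'   thresholding over the candidate set `|v|` (noise scale from the
#'   median absolute deviation).
#' * `ICA` - the first independent component of the whole record matrix
#'   (one-unit FastICA on the whitened matrix, seeded, sign fixed by the
#'   positive-skew convention), evaluated per record.
#' * `PSD` - mean Welch power-spectral-density level: Hamming-windowed
#'   overlapping segments, averaged periodograms, averaged over all bins.
#' * `MAX`, `MIN` - largest / smallest value of the one-sided magnitude
#'   spectrum ([to_frequency()]).
#'
#' Time-domain extractors run on the record's PCA-reduced score vector;
#' the frequency-domain extractors (`PSD`, `MAX`, `MIN`) run on the
#' record's normalized full-length signal, where a spectrum is meaningful.
NULL

#' Feature extraction parameters
#'
#' @param welch_window_length Welch segment length (samples); shortened to
#'   the record length when the record is shorter.
#' @param welch_overlap fractional segment overlap in `[0, 1)`.
#' @param hamming use a Hamming window (`FALSE` falls back to rectangular).
#' @param ica_seed seed for the FastICA starting vector.
#' @param ica_max_iter,ica_tol FastICA iteration cap and convergence
#'   tolerance.
#' @return list of parameters for [build_feature_matrix()] and friends.
#' @export
feature_params <- function(welch_window_length = 256L, welch_overlap = 0.5,
                           hamming = TRUE, ica_seed = 1L,
                           ica_max_iter = 200L, ica_tol = 1e-8) {
  stopifnot(welch_window_length >= 2L, welch_overlap >= 0, welch_overlap < 1)
  list(welch_window_length = as.integer(welch_window_length),
       welch_overlap = welch_overlap, hamming = isTRUE(hamming),
       ica_seed = as.integer(ica_seed),
       ica_max_iter = as.integer(ica_max_iter), ica_tol = ica_tol)
}

#' @rdname features
#' @param v numeric record vector.
#' @export
feat_mean <- function(v) {
  assert_numeric_vector(v)
  mean(v)
}

#' @rdname features
#' @export
feat_var <- function(v) {
  assert_numeric_vector(v, min_len = 2L)
  pop_var(v)
}

#' @rdname features
#' @export
feat_sd <- function(v) sqrt(feat_var(v))

#' @rdname features
#' @export
feat_skew <- function(v) {
  assert_numeric_vector(v, min_len = 2L)
  c2 <- pop_var(v)
  if (c2 == 0) {
    warning("zero variance; skewness set to 0", call. = FALSE)
    return(0)
  }
  mean((v - mean(v))^3) / c2^1.5
}

#' @rdname features
#' @export
feat_shannon <- function(v) {
  assert_numeric_vector(v)
  e <- v^2
  s <- sum(e)
  if (s == 0) {
    warning("all-zero vector; Shannon entropy set to 0", call. = FALSE)
    return(0)
  }
  p <- e / s
  p <- p[p > 0]
  -sum(p * log(p))
}

# Rigorous-SURE threshold: minimize the unbiased risk of soft
# thresholding over the candidate set of sorted |x| (unit-noise scale).
sure_threshold_unit <- function(x) {
  n <- length(x)
  a <- sort(abs(x))
  cum <- cumsum(a^2)
  i <- seq_len(n)
  risk <- n - 2 * i + cum + (n - i) * a^2
  a[which.min(risk)]
}

#' @rdname features
#' @param params a [feature_params()] list.
#' @export
feat_sure <- function(v, params = feature_params()) {
  assert_numeric_vector(v)
  sigma <- stats::mad(v)
  if (sigma == 0) {
    # degenerate scale: threshold at max|v|, so SU = sum(v^2)
    eps <- max(abs(v))
  } else {
    eps <- sigma * sure_threshold_unit(v / sigma)
  }
  sum(pmin(v^2, eps^2))
}

#' @rdname features
#' @export
feat_maxfft <- function(v) max(to_frequency(v))

#' @rdname features
#' @export
feat_minfft <- function(v) min(to_frequency(v))

#' @rdname features
#' @export
feat_psd <- function(v, params = feature_params()) {
  assert_numeric_vector(v, min_len = 2L)
  L <- min(params$welch_window_length, length(v))
  if (params$welch_window_length > length(v)) {
    warning("Welch segment shortened to the record length", call. = FALSE)
  }
  w <- welch_window(L, params$hamming)
  starts <- welch_starts(length(v), L, params$welch_overlap)
  u <- sum(w^2)
  p <- rowMeans(vapply(starts, function(s) {
    Mod(stats::fft(v[s:(s + L - 1L)] * w))^2 / u
  }, numeric(L)))
  mean(p)
}

welch_window <- function(L, hamming) {
  if (hamming) as.numeric(signal::hamming(L)) else rep(1, L)
}

welch_starts <- function(n, L, overlap) {
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq(1L, n - L + 1L, by = step)
  if (length(starts) == 0L) starts <- 1L
  starts
}

# One-unit FastICA (tanh nonlinearity) on a whitened matrix; returns the
# component values per record, sign fixed to positive skew.
#' @rdname features
#' @param x records x columns numeric matrix (>= 2 columns, >= 2 records).
#' @export
feat_ica <- function(x, params = feature_params()) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    # degenerate matrices fall back to the (centered) first column
    warning("ICA needs >= 2 records and columns; falling back to first column",
            call. = FALSE)
    s <- x[, 1L] - mean(x[, 1L])
    return(ica_fix_sign(s))
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  # whiten through PCA: uncorrelated, unit-variance columns
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  keep <- ev$values > max(ev$values[1], 0) * 1e-10 & ev$values > 0
  if (!any(keep)) {
    warning("ICA input has no variance; returning zeros", call. = FALSE)
    return(rep(0, nrow(x)))
  }
  z <- xc %*% sweep(ev$vectors[, keep, drop = FALSE], 2L,
                    sqrt(ev$values[keep]), "/")
  q <- ncol(z)
  w <- with_seed(params$ica_seed, rnorm(q))
  w <- w / sqrt(sum(w^2))
  converged <- FALSE
  for (it in seq_len(params$ica_max_iter)) {
    s <- drop(z %*% w)
    g <- tanh(s)
    w_new <- colMeans(z * g) - mean(1 - g^2) * w
    w_new <- w_new / sqrt(sum(w_new^2))
    if (abs(abs(sum(w_new * w)) - 1) < params$ica_tol) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
  }
  if (!converged) {
    warning("FastICA did not converge; falling back to the first principal component",
            call. = FALSE)
    return(ica_fix_sign(drop(z[, 1L])))
  }
  ica_fix_sign(drop(z %*% w))
}

ica_fix_sign <- function(s) {
  if (length(s) >= 2L && pop_sd(s) > 0) {
    sk <- mean((s - mean(s))^3) / pop_var(s)^1.5
    if (sk < 0) s <- -s
  }
  s
}

#' Assemble the Stage-2 feature matrix
#'
#' Applies the ten extractors to every record: the time-domain extractors
#' to the rows of `reduced` (the record's retained PCA scores), the ICA
#' column matrix-wise to `reduced`, and the frequency-domain extractors
#' (`PSD`, `MAX`, `MIN`) to the rows of `signals` (the record's normalized
#' full-length signal; defaults to `reduced` when not supplied). Rows with
#' any non-finite feature are dropped with a warning.
#'
#' @param reduced records x components matrix (or a `reduced_matrix`).
#' @param params a [feature_params()] list.
#' @param signals optional records x points matrix for the
#'   frequency-domain features.
#' @param labels class factor per record.
#' @param method_name normalization method the features derive from.
#' @return A `feature_matrix`: list with `values` (records x 10, columns
#'   `SD, M, V, S, SE, ICA, SU, PSD, MAX, MIN`), `labels`, `method`,
#'   `dropped` (row indices removed as non-finite).
#' @export
build_feature_matrix <- function(reduced, params = feature_params(),
                                 signals = NULL, labels = NULL,
                                 method_name = NA_character_) {
  if (inherits(reduced, "reduced_matrix")) reduced <- reduced$scores
  s <- as.matrix(reduced)
  if (nrow(s) < 1L) stopf("empty input")
  x <- if (is.null(signals)) s else as.matrix(signals)
  if (nrow(x) != nrow(s)) stopf("signals rows must match reduced rows")

  m <- rowMeans(s)
  cen <- s - m                       # recycles per row (column-major)
  v <- rowMeans(cen^2)
  sdv <- sqrt(v)
  skw <- ifelse(v > 0, rowMeans(cen^3) / ifelse(v > 0, v, 1)^1.5, 0)

  e <- s^2
  etot <- rowSums(e)
  pe <- e / ifelse(etot > 0, etot, 1)
  se <- -rowSums(ifelse(pe > 0, pe * log(pe), 0))

  su <- apply(s, 1L, feat_sure, params = params)
  ica <- feat_ica(s, params)

  fm <- fft_magnitude_rows(x)
  mx <- apply(fm, 1L, max)
  mn <- apply(fm, 1L, min)
  psd <- welch_mean_psd_rows(x, params)

  values <- cbind(SD = sdv, M = m, V = v, S = skw, SE = se, ICA = ica,
                  SU = su, PSD = psd, MAX = mx, MIN = mn)
  bad <- which(!apply(is.finite(values), 1L, all))
  if (length(bad)) {
    warning(sprintf("%d row(s) with non-finite features dropped: %s",
                    length(bad), paste(head(bad, 10L), collapse = ", ")),
            call. = FALSE)
    values <- values[-bad, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[-bad]
  }
  structure(list(values = values, labels = labels, method = method_name,
                 dropped = bad),
            class = "feature_matrix")
}

# one-sided magnitude spectra for all rows at once
fft_magnitude_rows <- function(x) {
  n <- ncol(x)
  f <- stats::mvfft(t(x))
  t(Mod(f[seq_len(n %/% 2 + 1L), , drop = FALSE]))
}

# mean Welch PSD level for all rows at once (same contract as feat_psd)
welch_mean_psd_rows <- function(x, params) {
  n <- ncol(x)
  L <- min(params$welch_window_length, n)
  w <- welch_window(L, params$hamming)
  starts <- welch_starts(n, L, params$welch_overlap)
  u <- sum(w^2)
  xt <- t(x)
  acc <- numeric(nrow(x))
  for (s in starts) {
    f <- stats::mvfft(xt[s:(s + L - 1L), , drop = FALSE] * w)
    acc <- acc + colMeans(Mod(f)^2) / u
  }
  acc / length(starts)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d x %d\n",
              if (is.na(x$method)) "?" else x$method,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' Header = feature names, preceded by the normalization method and label
#' columns.
#'
#' @param fm a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  dt <- data.table::data.table(
    method = fm$method,
    label = if (is.null(fm$labels)) NA_character_ else as.character(fm$labels),
    fm$values)
  data.table::fwrite(dt, path)
  invisible(path)
}
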