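#' @name normalize
#' @title The Stage-1 normalization bank
#'
#' @description
#' Ten data normalization methods, each acting element-wise or with
#' per-signal / dataset-level statistics, never changing the dimension of
#' a signal. Five are conventional rescalings; five are reference-based
#' "relative voltage" corrections designed to cancel baseline drift by
#' comparing each signal against a tumor-free reference:
#'
#' * `DS` decimal scaling: `v / 10^j`, smallest integer `j` with
#'   `max|v| / 10^j <= 1`.
#' * `ZS` z-score: `(v - mean(v)) / sd(v)` with per-signal population
#'   statistics.
#' * `LS` linear scaling: `v / max|v|`.
#' * `MM` min-max: `(v - min v) / (max v - min v)`.
#' * `MSD` mean/standard-deviation: `(v - mean) / sd` with dataset-global
#'   statistics (this is what distinguishes it from `ZS`).
#' * `RV` relative voltage: `v - v_ref`.
#' * `FVC` fractional voltage change: `(v - v_ref) / (|v_ref| + eps)`.
#' * `RLV` relative logarithmic voltage:
#'   `log10((|v| + eps) / (|v_ref| + eps))`.
#' * `RSSV` relative sum-squared voltage:
#'   `(v - v_ref) |v - v_ref| / sum(v_ref^2)` (sign-preserving squared
#'   change relative to the reference energy).
#' * `RLSSV` relative logarithmic sum-squared voltage:
#'   `log10(((v - v_ref)^2 + eps) / sum(v_ref^2))`.
#'
#' The five relative methods require a [compute_reference()] signal;
#' `MSD` requires dataset-global statistics. `eps` guards divisions and
#' logarithms (default 1e-12, negligible at signal amplitudes).
NULL

#' Names of the ten normalization methods
#' @return character vector of method codes.
#' @export
normalization_methods <- function() {
  c("DS", "ZS", "LS", "MM", "MSD", "RLSSV", "RLV", "RV", "FVC", "RSSV")
}

reference_methods <- function() c("RLSSV", "RLV", "RV", "FVC", "RSSV")

#' One-sided magnitude spectrum of a signal
#'
#' Magnitude of the discrete Fourier transform, one-sided: bins
#' `0 .. floor(n/2)` (length `floor(n/2) + 1`), DC first. Deterministic.
#'
#' @param v real signal vector.
#' @param window_ns optional acquisition window; when given, the returned
#'   vector carries a `freq_ghz` attribute with the bin frequencies.
#' @return numeric vector of magnitudes.
#' @export
to_frequency <- function(v, window_ns = NULL) {
  assert_numeric_vector(v, "signal")
  n <- length(v)
  m <- Mod(stats::fft(v))[seq_len(n %/% 2 + 1L)]
  if (!is.null(window_ns)) {
    attr(m, "freq_ghz") <- (seq_len(n %/% 2 + 1L) - 1L) / window_ns
  }
  m
}

#' Tumor-free reference signal
#'
#' Element-wise mean of the tumor-free amplitude vectors of a signal set;
#' the baseline the five relative normalization methods subtract or divide
#' out (it carries the deterministic drift, so reference-based methods
#' cancel it).
#'
#' @param set a `signal_set` with at least one tumor-free record.
#' @return numeric vector of length `n_points`.
#' @export
compute_reference <- function(set) {
  idx <- which(set$meta$size_mm == 0)
  if (length(idx) == 0L) stopf("signal set has no tumor-free records")
  colMeans(set$amplitude[idx, , drop = FALSE])
}

#' Apply one normalization method to a single signal
#'
#' @param v real signal vector.
#' @param method one of [normalization_methods()].
#' @param reference tumor-free reference vector; required for the five
#'   relative methods (`RLSSV`, `RLV`, `RV`, `FVC`, `RSSV`).
#' @param global_stats `c(mean, sd)` of the whole dataset; required for
#'   `MSD`.
#' @param eps guard added to divisors and log arguments.
#' @param degenerate what to do when a per-signal statistic degenerates
#'   (constant signal under `MM`/`ZS`/`LS`): `"zero"` returns the
#'   all-zero vector with a warning, `"error"` stops.
#' @return numeric vector, same length as `v`.
#' @export
#' @examples
#' normalize_signal(c(2, 4, 6), "MM")   # 0, 0.5, 1
normalize_signal <- function(v, method, reference = NULL, global_stats = NULL,
                             eps = 1e-12, degenerate = c("zero", "error")) {
  assert_numeric_vector(v, "signal")
  degenerate <- match.arg(degenerate)
  method <- match.arg(method, normalization_methods())
  if (method %in% reference_methods()) {
    if (is.null(reference)) stopf("method %s requires a reference signal", method)
    if (length(reference) != length(v)) stopf("reference length mismatch")
  }
  fail <- function(msg) {
    if (degenerate == "error") stopf("degenerate input for %s: %s", method, msg)
    warning(sprintf("degenerate input for %s (%s); returning zero vector",
                    method, msg), call. = FALSE)
    rep(0, length(v))
  }
  r <- reference
  switch(method,
    DS = {
      mx <- max(abs(v))
      j <- if (mx == 0) 0L else max(0L, ceiling(log10(mx)))
      v / 10^j
    },
    ZS = {
      s <- pop_sd(v)
      if (s == 0) fail("zero per-signal sd") else (v - mean(v)) / s
    },
    LS = {
      mx <- max(abs(v))
      if (mx == 0) fail("all-zero signal") else v / mx
    },
    MM = {
      rng <- range(v)
      if (diff(rng) == 0) fail("zero range") else (v - rng[1]) / diff(rng)
    },
    MSD = {
      if (is.null(global_stats)) stopf("MSD requires dataset-global (mean, sd)")
      if (global_stats[2] == 0) fail("zero global sd") else
        (v - global_stats[1]) / global_stats[2]
    },
    RV = v - r,
    FVC = (v - r) / (abs(r) + eps),
    RLV = log10((abs(v) + eps) / (abs(r) + eps)),
    RSSV = (v - r) * abs(v - r) / sum(r^2),
    RLSSV = log10(((v - r)^2 + eps) / sum(r^2))
  )
}

#' Normalize every record of a signal set with one method
#'
#' @param set a `signal_set` (or a plain records x points matrix plus
#'   `labels`).
#' @param method one of [normalization_methods()].
#' @param reference tumor-free reference; computed from `set` when omitted
#'   and the method needs one.
#' @param labels class factor per record; derived from `set` when omitted.
#' @inheritParams normalize_signal
#' @return A `normalized_set`: list with `matrix` (records x points),
#'   `method`, `labels`, `reference_used`.
#' @export
normalize_set <- function(set, method, reference = NULL, labels = NULL,
                          eps = 1e-12, degenerate = c("zero", "error")) {
  degenerate <- match.arg(degenerate)
  method <- match.arg(method, normalization_methods())
  if (inherits(set, "signal_set")) {
    x <- set$amplitude
    if (is.null(labels)) labels <- signal_labels(set)
    if (is.null(reference) && method %in% reference_methods()) {
      reference <- compute_reference(set)
    }
  } else {
    x <- as.matrix(set)
  }
  global_stats <- NULL
  if (method == "MSD") {
    global_stats <- c(mean(x), sqrt(mean((x - mean(x))^2)))
  }
  # Row-wise vectorized forms; semantics identical to normalize_signal().
  out <- switch(method,
    DS = {
      mx <- apply(abs(x), 1L, max)
      j <- ifelse(mx == 0, 0, pmax(0, ceiling(log10(mx))))
      x / 10^j
    },
    ZS = {
      mu <- rowMeans(x)
      s <- sqrt(rowMeans(x^2) - mu^2)
      s2 <- ifelse(s == 0, 1, s)
      r <- (x - mu) / s2
      if (any(s == 0)) {
        warning("degenerate rows under ZS; returning zero rows", call. = FALSE)
        r[s == 0, ] <- 0
      }
      r
    },
    LS = {
      mx <- apply(abs(x), 1L, max)
      r <- x / ifelse(mx == 0, 1, mx)
      if (any(mx == 0)) {
        warning("degenerate rows under LS; returning zero rows", call. = FALSE)
      }
      r
    },
    MM = {
      lo <- apply(x, 1L, min)
      hi <- apply(x, 1L, max)
      rng <- hi - lo
      r <- (x - lo) / ifelse(rng == 0, 1, rng)
      if (any(rng == 0)) {
        warning("degenerate rows under MM; returning zero rows", call. = FALSE)
        r[rng == 0, ] <- 0
      }
      r
    },
    MSD = (x - global_stats[1]) / global_stats[2],
    RV = sweep(x, 2L, reference),
    FVC = sweep(sweep(x, 2L, reference), 2L, abs(reference) + eps, "/"),
    RLV = sweep(log10(abs(x) + eps), 2L, log10(abs(reference) + eps)),
    RSSV = {
      d <- sweep(x, 2L, reference)
      d * abs(d) / sum(reference^2)
    },
    RLSSV = {
      d <- sweep(x, 2L, reference)
      log10((d^2 + eps) / sum(reference^2))
    }
  )
  if (method %in% c("DS", "ZS", "LS", "MM", "MSD") &&
      !is.null(global_stats) && global_stats[2] == 0) {
    stopf("degenerate dataset: zero global sd under MSD")
  }
  structure(list(matrix = out, method = method, labels = labels,
                 reference_used = method %in% reference_methods()),
            class = "normalized_set")
}

#' @export
print.normalized_set <- function(x, ...) {
  cat(sprintf("<normalized_set> %s: %d x %d%s\n", x$method, nrow(x$matrix),
              ncol(x$matrix), if (x$reference_used) " (reference-based)" else ""))
  invisible(x)
}

#' Write a normalized set as a wide CSV
#'
#' Same wide dialect as [write_signal_set()]: metadata columns (`method`,
#' `label`) then one column per sample.
#'
#' @param nset a `normalized_set`.
#' @param path output CSV path.
#' @export
write_normalized_set <- function(nset, path) {
  amp <- nset$matrix
  colnames(amp) <- paste0("a", seq_len(ncol(amp)))
  dt <- data.table::data.table(method = nset$method,
                               label = as.character(nset$labels), amp)
  data.table::fwrite(dt, path)
  invisible(path)
}
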