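# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Population (1/N) variance and standard deviation; the moment convention
# used throughout the feature extractors and normalizations.
pop_var <- function(v) mean((v - mean(v))^2)
pop_sd <- function(v) sqrt(pop_var(v))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_numeric_vector <- function(v, what = "input", min_len = 1L) {
  if (!is.numeric(v) || length(v) < min_len) {
    stopf("%s must be a numeric vector of length >= %d", what, min_len)
  }
  if (anyNA(v)) stopf("%s contains missing values", what)
  invisible(v)
}

# Coerce size labels (0 = tumor-free) to the class factor used everywhere.
size_factor <- function(size_mm, sizes_mm) {
  lev <- c(0, sort(sizes_mm))
  factor(size_mm, levels = lev,
         labels = c("none", paste0(sort(sizes_mm), "mm")))
}
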