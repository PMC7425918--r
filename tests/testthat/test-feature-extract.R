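test_that("moment features match closed forms and loop oracles", {
  expect_equal(feat_mean(c(1, 2, 3)), 2)
  expect_equal(feat_mean(rep(4.2, 9)), 4.2)
  expect_equal(feat_var(c(1, 2, 3)), 2 / 3)
  expect_equal(feat_sd(c(1, 2, 3)), 0.8165, tolerance = 1e-4)

  set.seed(31)
  for (i in 1:5) {
    v <- rnorm(101)
    expect_equal(feat_mean(v), sum(v) / length(v), tolerance = 1e-12)
    mu <- sum(v) / length(v)
    m2 <- sum((v - mu)^2) / length(v)
    m3 <- sum((v - mu)^3) / length(v)
    expect_equal(feat_var(v), m2, tolerance = 1e-12)
    expect_equal(feat_sd(v)^2, feat_var(v), tolerance = 1e-12)
    expect_equal(feat_skew(v), m3 / m2^1.5, tolerance = 1e-12)
  }
  # symmetric vectors have zero skewness
  v <- c(-3, -1, 0, 1, 3)
  expect_equal(feat_skew(v), 0, tolerance = 1e-12)
  expect_warning(s0 <- feat_skew(rep(1, 5)), "zero variance")
  expect_equal(s0, 0)
})

test_that("Shannon entropy follows the energy distribution", {
  expect_equal(feat_shannon(rep(2, 7)), log(7), tolerance = 1e-12)
  expect_equal(feat_shannon(c(0, 0, 5, 0)), 0)
  expect_warning(z <- feat_shannon(rep(0, 4)), "all-zero")
  expect_equal(z, 0)
  set.seed(32)
  v <- rnorm(50)
  p <- v^2 / sum(v^2)
  expect_equal(feat_shannon(v), -sum(p * log(p)), tolerance = 1e-12)
})

test_that("sure entropy saturates correctly and matches the risk scan", {
  # threshold from a Gaussian vector equals the exhaustive SURE minimizer
  set.seed(33)
  for (i in 1:5) {
    v <- rnorm(80)
    sigma <- mad(v)
    got <- feat_sure(v)
    eps <- sigma * oracle_sure_threshold(v / sigma)
    expect_equal(got, sum(pmin(v^2, eps^2)), tolerance = 1e-10)
  }
  # all |v| above the threshold: SU = n * eps^2; all below: SU = sum(v^2)
  v <- c(5, -6, 7, 8)               # MAD scale small vs spread
  sigma <- mad(v)
  eps <- sigma * oracle_sure_threshold(v / sigma)
  if (all(abs(v) >= eps)) {
    expect_equal(feat_sure(v), length(v) * eps^2, tolerance = 1e-10)
  }
  w <- c(0.1, -0.05, 0.08, 0.12)
  sigw <- mad(w)
  epsw <- sigw * oracle_sure_threshold(w / sigw)
  if (all(abs(w) < epsw)) {
    expect_equal(feat_sure(w), sum(w^2), tolerance = 1e-12)
  }
})

test_that("Welch PSD level is calibrated and matches the direct oracle", {
  set.seed(34)
  v <- rnorm(4096)
  got <- feat_psd(v, feature_params(welch_window_length = 256))
  expect_lt(abs(got - 1), 0.1)       # unit-variance white noise level 1

  # equality with an independently coded periodogram average
  for (i in 1:3) {
    u <- rnorm(600)
    expect_equal(feat_psd(u, feature_params(welch_window_length = 128)),
                 oracle_welch_mean(u, 128), tolerance = 1e-9)
  }

  # pure tone concentrates the averaged periodogram
  n <- 1024
  tone <- sin(2 * pi * 64 * (0:(n - 1)) / n)
  p <- feature_params(welch_window_length = 256)
  L <- 256
  w <- as.numeric(signal::hamming(L))
  seg <- tone[1:L] * w
  per <- Mod(fft(seg))^2 / sum(w^2)
  expect_gte(max(per), 100 * median(per))

  expect_warning(feat_psd(rnorm(50), feature_params(welch_window_length = 256)),
                 "shortened")
})

test_that("FFT extrema features agree with a sort-based oracle", {
  set.seed(35)
  for (i in 1:5) {
    v <- rnorm(90)
    mag <- sort(to_frequency(v))
    expect_identical(feat_maxfft(v), mag[length(mag)])
    expect_identical(feat_minfft(v), mag[1])
    expect_gte(feat_maxfft(v), feat_minfft(v))
  }
  z <- rep(0, 32)
  expect_identical(feat_maxfft(z), 0)
  expect_identical(feat_minfft(z), 0)
})

test_that("ICA recovers an independent source from a known mixture", {
  set.seed(36)
  n <- 5000
  s1 <- runif(n, -1, 1)
  s2 <- runif(n, -1, 1)
  x <- cbind(s1, s2) %*% matrix(c(0.8, 0.3, -0.4, 0.9), 2, 2)
  comp <- feat_ica(x, feature_params(ica_seed = 4))
  r <- max(abs(cor(comp, s1)), abs(cor(comp, s2)))
  expect_gte(r, 0.95)

  # non-Gaussianity principle: picks the non-Gaussian column
  s_ng <- sample(c(-1, 1), n, replace = TRUE) * rexp(n)  # heavy-tailed
  s_g <- rnorm(n)
  y <- cbind(s_ng, s_g)
  comp2 <- feat_ica(y, feature_params(ica_seed = 4))
  expect_gte(abs(cor(comp2, s_ng)), 0.9)

  # determinism under a fixed seed
  expect_identical(feat_ica(x, feature_params(ica_seed = 4)),
                   feat_ica(x, feature_params(ica_seed = 4)))
})

test_that("feature matrix assembly composes the individual extractors", {
  set.seed(37)
  s <- matrix(rnorm(6 * 40), 6, 40)
  sig <- matrix(rnorm(6 * 128), 6, 128)
  p <- feature_params(welch_window_length = 64)
  fm <- build_feature_matrix(s, p, signals = sig,
                             labels = factor(rep(c("a", "b"), 3)))
  expect_identical(colnames(fm$values),
                   c("SD", "M", "V", "S", "SE", "ICA", "SU", "PSD", "MAX",
                     "MIN"))
  expect_identical(dim(fm$values), c(6L, 10L))
  expect_true(all(is.finite(fm$values)))
  for (r in c(1L, 4L)) {
    row <- unname(fm$values[r, ])
    expect_equal(row[2], feat_mean(s[r, ]), tolerance = 1e-12)
    expect_equal(row[1], feat_sd(s[r, ]), tolerance = 1e-12)
    expect_equal(row[3], feat_var(s[r, ]), tolerance = 1e-12)
    expect_equal(row[4], feat_skew(s[r, ]), tolerance = 1e-12)
    expect_equal(row[5], feat_shannon(s[r, ]), tolerance = 1e-12)
    expect_equal(row[7], feat_sure(s[r, ], p), tolerance = 1e-12)
    expect_equal(row[8], feat_psd(sig[r, ], p), tolerance = 1e-9)
    expect_equal(row[9], feat_maxfft(sig[r, ]), tolerance = 1e-9)
    expect_equal(row[10], feat_minfft(sig[r, ]), tolerance = 1e-9)
  }
  expect_equal(fm$values[, "ICA"], feat_ica(s, p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("single-record assembly matches individual extractor calls", {
  set.seed(38)
  s <- matrix(rnorm(32), 1, 32)
  p <- feature_params(welch_window_length = 16)
  fm <- suppressWarnings(build_feature_matrix(s, p))
  expect_identical(dim(fm$values), c(1L, 10L))
  expect_equal(unname(fm$values[1, "M"]), feat_mean(s[1, ]))
  expect_equal(unname(fm$values[1, "SE"]), feat_shannon(s[1, ]))
  expect_equal(unname(fm$values[1, "MAX"]), feat_maxfft(s[1, ]))
  expect_equal(unname(fm$values[1, "ICA"]),
               suppressWarnings(feat_ica(s, p))[1])
})

test_that("row-wise extraction is permutation-equivariant", {
  set.seed(39)
  n <- 100
  # distinct source variances keep the whitening basis well-conditioned
  # and a single strongly skewed source keeps the first independent
  # component identifiable, so the iterative ICA column is row-order-
  # stable; the other nine extractors are exactly equivariant
  src <- cbind(3 * rexp(n), 2 * rnorm(n), 1.4 * rnorm(n), rnorm(n),
               0.7 * rnorm(n))
  s <- src %*% qr.Q(qr(matrix(rnorm(25), 5, 5)))
  sig <- matrix(rnorm(n * 64), n, 64)
  p <- feature_params(welch_window_length = 32, ica_seed = 9)
  perm <- sample(n)
  a <- build_feature_matrix(s, p, signals = sig)
  b <- build_feature_matrix(s[perm, ], p, signals = sig[perm, ])
  expect_equal(b$values[, -6], a$values[perm, -6], tolerance = 1e-9)
  expect_gte(abs(cor(b$values[, 6], a$values[perm, 6])), 0.999)
})
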