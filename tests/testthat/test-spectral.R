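test_that("min-max normalization maps rows to [0,1] and zeros constants", {
  ts <- trace_set(rbind(c(2, 4, 6), c(5, 5, 5), c(-1, 0, 3)), fs = 10)
  nn <- normalize_minmax(ts)
  expect_equal(nn$values[1, ], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(nn$values[2, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(min(nn$values[3, ]), 0)
  expect_equal(max(nn$values[3, ]), 1)
})

test_that("packed real DFT agrees with the transform definition", {
  for (n in c(16L, 17L)) {  # even and odd lengths
    set.seed(n)
    x <- rnorm(n)
    X <- dft_definition(x)
    p <- catrace:::pack_rfft(x)
    expect_equal(p[1], Re(X[1]), tolerance = 1e-10)
    nh <- (n - 1L) %/% 2L
    for (h in seq_len(nh)) {
      expect_equal(p[2 * h], Re(X[h + 1]), tolerance = 1e-8)
      expect_equal(p[2 * h + 1], Im(X[h + 1]), tolerance = 1e-8)
    }
    if (n %% 2L == 0L) expect_equal(p[n], Re(X[n / 2 + 1]), tolerance = 1e-8)
    expect_equal(catrace:::unpack_rfft(p), x, tolerance = 1e-10)
  }
})

test_that("log-magnitude features localize a pure sinusoid at its harmonic", {
  n <- 200L
  k <- 7L
  ts <- trace_set(rbind(0.5 + 0.5 * sin(2 * pi * k * (0:(n - 1)) / n)), fs = 10)
  sf <- dft_log_magnitude(normalize_minmax(ts), n)
  f <- sf$features[1, ]
  top <- order(f, decreasing = TRUE)[1:3]
  # dc (index 1) plus the two packed slots of harmonic k (0-based 2k-1, 2k)
  expect_setequal(top, c(1L, 2L * k, 2L * k + 1L))
})

test_that("feature width caps at n_frames and silent traces hit the log floor", {
  ts <- trace_set(rbind(rep(0, 50), runif(50)), fs = 10)
  sf <- dft_log_magnitude(ts, 1000L)
  expect_equal(ncol(sf$features), 50L)
  expect_equal(sf$cutoff_index, 50L)
  expect_true(all(abs(sf$features[1, ] - log(1e-12)) < 1e-9))
  expect_error(dft_log_magnitude(ts, 0), "parameter error")
})

test_that("features are invariant to a constant offset before normalization", {
  set.seed(3)
  m <- matrix(runif(200), 2)
  a <- dft_log_magnitude(normalize_minmax(trace_set(m, fs = 10)), 100)
  b <- dft_log_magnitude(normalize_minmax(trace_set(m + 7, fs = 10)), 100)
  expect_equal(a$features, b$features, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("packed index maps to the frequency of its owning harmonic", {
  expect_equal(round(rfft_index_to_frequency(1000, 3000, 10), 2), 1.67)
  expect_equal(rfft_index_to_frequency(0, 512, 30), 0)
  expect_equal(rfft_index_to_frequency(2, 3000, 10), 10 / 3000)
  expect_equal(rfft_index_to_frequency(1, 100, 10), 0.1)
  expect_error(rfft_index_to_frequency(3000, 3000, 10), "parameter error")
})

test_that("full-cutoff reconstruction is exact (inverse transform identity)", {
  set.seed(8)
  ts <- trace_set(matrix(runif(3 * 120), 3), fs = 10)
  rep <- select_frequency_cutoff(ts, candidates = c(10L, 60L, 120L), fraction = 1)
  expect_equal(rep$sosd_per_cutoff[3], 0, tolerance = 1e-18)
  expect_true(all(diff(rep$cumulative_fraction) >= -1e-12))
  expect_equal(rep$cumulative_fraction[3], 1)
  # with nonzero error everywhere, fraction 1 is reached only at the end
  rep2 <- select_frequency_cutoff(ts, candidates = c(10L, 60L, 110L),
                                  fraction = 1)
  expect_equal(rep2$selected_cutoff, 110L)
})

test_that("SOSD saturates beyond a slow sinusoid's harmonic", {
  n <- 300L
  x <- 0.5 + 0.5 * sin(2 * pi * 3 * (0:(n - 1)) / n)
  ts <- trace_set(rbind(x), fs = 10)
  rep <- select_frequency_cutoff(ts, candidates = c(3L, 50L, 150L, 300L),
                                 fraction = 0.945)
  # nearly all reconstruction error is gone once the harmonic (packed
  # index 6-7) is included; what remains past it is the small linear
  # interpolation floor of the coarse inverse grid
  expect_gt(rep$sosd_per_cutoff[1] / sum(rep$sosd_per_cutoff), 0.95)
  expect_lt(rep$sosd_per_cutoff[2], rep$sosd_per_cutoff[1] * 0.05)
  expect_lt(rep$sosd_per_cutoff[3], rep$sosd_per_cutoff[1] * 0.005)
  expect_gt(rep$cumulative_fraction[1], 0.945)
  expect_equal(rep$selected_cutoff, 3L)
})

test_that("SOSD decreases monotonically with the cutoff on white noise", {
  set.seed(21)
  ts <- trace_set(matrix(runif(4 * 256), 4), fs = 10)
  rep <- select_frequency_cutoff(ts, candidates = as.integer(seq(16, 256, 16)))
  expect_true(all(diff(rep$sosd_per_cutoff) < 0))
  expect_error(select_frequency_cutoff(ts, integer(0)), "parameter error")
  expect_error(select_frequency_cutoff(ts, c(10L, 5L)), "increasing")
})
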