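gauss_bump <- function(n, center, width, amp = 1) {
  amp * exp(-((seq_len(n) - center) / width)^2)
}

test_that("detect_peaks finds isolated bumps with correct apices", {
  x <- gauss_bump(100, 50, 6)
  pk <- detect_peaks(x, prominence = 0.1)
  expect_length(pk, 1L)
  expect_equal(pk[[1]]$apex_frame, 49L)  # 0-based
  expect_gte(pk[[1]]$half_width, 1)

  expect_equal(detect_peaks(rep(0.3, 80)), list())

  # two bumps separated by a deep dip are distinct peaks
  y <- gauss_bump(120, 35, 5) + gauss_bump(120, 85, 5, amp = 0.8)
  pk2 <- detect_peaks(y, prominence = 0.1)
  expect_length(pk2, 2L)
  # brute-force local maxima scan oracle
  locmax <- which(diff(sign(diff(y))) < 0) + 1L
  expect_setequal(vapply(pk2, `[[`, integer(1), "apex_frame") + 1L,
                  locmax[y[locmax] > 0.1])
  # a shallow shoulder below the prominence threshold is not a peak
  z <- gauss_bump(120, 50, 8) + gauss_bump(120, 62, 6, amp = 0.05)
  expect_length(detect_peaks(z, prominence = 0.1), 1L)
})

test_that("sbd is a bounded, scale-invariant shape metric with shift recovery", {
  set.seed(14)
  x <- rnorm(40)
  expect_equal(sbd(x, x), list(distance = 0, shift = 0L),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sbd(x, 5 * x)$distance, 0, tolerance = 1e-12)
  expect_equal(sbd(x, 5 * x)$shift, 0L)
  d1 <- numeric(20); d1[3] <- 1
  d2 <- numeric(20); d2[6] <- 1
  r <- sbd(d1, d2)
  expect_equal(r$shift, 3L)
  expect_lt(r$distance, 0.02)  # z-normalized impulses align almost exactly
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(30)
    da <- sbd(a, b); db <- sbd(b, a)
    expect_equal(da$distance, db$distance, tolerance = 1e-10)
    expect_gte(da$distance, 0); expect_lte(da$distance, 2)
  }
  expect_error(sbd(rep(1, 10), rnorm(10)), "degenerate-shape")
})

test_that("kshape_fit recovers two planted shape families", {
  set.seed(20)
  n_per <- 30L
  mk <- function(base) lapply(seq_len(n_per), function(i)
    base + rnorm(length(base), 0, 0.05))
  spike <- gauss_bump(50, 25, 2)
  wave <- gauss_bump(50, 25, 14)
  peaks <- c(mk(spike), mk(wave))
  planted <- rep(1:2, each = n_per)
  fit <- kshape_fit(peaks, 2, seed = 3)
  expect_gte(ari(fit$labels, planted), 0.99)
  # centroids match the planted base shapes under sbd
  for (base in list(spike, wave)) {
    bb <- approx(seq_along(base), base,
                 xout = seq(1, length(base), length.out = fit$resample_length))$y
    expect_lte(min(vapply(1:2, function(c)
      sbd(fit$centroids[c, ], bb)$distance, numeric(1))), 0.05)
  }
  # letters: sharper family gets 'a'
  expect_equal(fit$letters[which(fit$half_widths == min(fit$half_widths))], "a")
})

test_that("k = 1 yields a single centroid whose inertia is the sbd sum", {
  set.seed(25)
  peaks <- lapply(1:10, function(i) gauss_bump(40, 20, 5) + rnorm(40, 0, 0.02))
  fit <- kshape_fit(peaks, 1, seed = 1)
  expect_equal(fit$k, 1L)
  L <- fit$resample_length
  d <- vapply(peaks, function(p) {
    z <- (approx(seq_along(p), p, xout = seq(1, length(p), length.out = L))$y)
    sbd(fit$centroids[1, ], z)$distance
  }, numeric(1))
  expect_equal(fit$inertia, sum(d), tolerance = 1e-8)
})

test_that("inertia does not increase across iterations on separated families", {
  lib <- generate_peak_library(seed = 31)
  fit <- kshape_fit(lib$peaks, 3, seed = 7)
  expect_true(all(diff(fit$inertia_trace) <= 1e-8))
})

test_that("fit assignments are invariant to peak input order", {
  lib <- generate_peak_library(per_shape = 15L, seed = 40)
  fit <- kshape_fit(lib$peaks, 3, seed = 2)
  perm <- sample(length(lib$peaks))
  fit2 <- kshape_fit(lib$peaks[perm], 3, seed = 2)
  # seeding draws centroids from half-width partitions, so the models
  # coincide and permuted inputs get the same cluster structure
  expect_gte(ari(fit$labels[perm], fit2$labels), 0.99)
})

test_that("gridsearch picks the planted family count and is deterministic", {
  lib <- generate_peak_library(seed = 3)
  g1 <- kshape_gridsearch(lib$peaks, k_range = 2:6, restarts = 2L, seed = 11)
  expect_equal(g1$k, 3L)
  expect_gte(ari(g1$labels, lib$labels), 0.9)
  g2 <- kshape_gridsearch(lib$peaks, k_range = 2:6, restarts = 2L, seed = 11)
  expect_identical(g1$centroids, g2$centroids)
  expect_identical(g1$labels, g2$labels)
  g3 <- kshape_gridsearch(lib$peaks, k_range = 2L, restarts = 1L, seed = 5)
  expect_equal(g3$k, 2L)
  expect_s3_class(attr(g1, "gridsearch"), "data.frame")
})

test_that("letters order by half-peak width with index tie-break", {
  model <- structure(list(centroids = diag(3), labels = c(1L, 2L, 3L), k = 3L,
                          half_widths = c(5, 2, 9), letters = NULL,
                          inertia = 0, inertia_trace = numeric(0),
                          resample_length = 3L),
                     class = "motif_model")
  m <- assign_letters(model)
  expect_equal(m$letters, c("b", "a", "c"))
  model$half_widths <- c(4, 4, 1)
  m2 <- assign_letters(model)
  expect_equal(m2$letters, c("b", "c", "a"))  # tie broken by cluster index
  expect_setequal(m2$letters, letters[1:3])
})

test_that("discretize maps peaks to letter sequences in temporal order", {
  lib <- generate_peak_library(per_shape = 20L, seed = 8)
  fit <- kshape_fit(lib$peaks, 3, seed = 4)
  # build per-trace peak lists with controlled temporal order
  by_family <- split(seq_along(lib$labels), lib$labels)
  fam_letter <- vapply(names(by_family), function(f) {
    idx <- by_family[[f]][1]
    fit$letters[fit$labels[idx]]
  }, character(1))
  mk_peak <- function(i, t0) {
    p <- lib$peaks[[i]]; p$start_frame <- t0; p
  }
  aab <- list(mk_peak(by_family[[1]][2], 0),
              mk_peak(by_family[[1]][3], 100),
              mk_peak(by_family[[2]][2], 200))
  seqs <- discretize(list(aab, list()), fit)
  expect_equal(seqs[1], paste0(fam_letter[1], fam_letter[1], fam_letter[2]))
  expect_equal(seqs[2], "")
  # temporal order, not list order
  rev_seq <- discretize(list(rev(aab)), fit)
  expect_equal(rev_seq, seqs[1])
  # planted alternating shapes give alternating letters
  alt <- lapply(1:6, function(i)
    mk_peak(by_family[[(i %% 2) + 1]][i], i * 100))
  expect_equal(discretize(list(alt), fit),
               paste(fam_letter[c(2, 1, 2, 1, 2, 1)], collapse = ""))
})
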