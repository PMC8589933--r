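#' Min-max normalize each trace to [0, 1]
#'
#' Each row is mapped to `(x - min) / (max - min)`. A constant (silent)
#' trace has no dynamic range; it is mapped to all zeros (0/0 defined as 0)
#' so that silent cells yield a well-defined "no energy" spectrum rather
#' than an error.
#'
#' @param traces a [trace_set()].
#' @return a [trace_set()] with values in \[0, 1\].
#' @export
normalize_minmax <- function(traces) {
  stopifnot(inherits(traces, "trace_set"))
  v <- traces$values
  if (ncol(v) < 2L) stop("traces need at least 2 frames to normalize")
  lo <- apply(v, 1, min)
  hi <- apply(v, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- Inf  # constant rows -> zeros
  traces$values <- (v - lo) / rng
  traces
}

# Pack the complex DFT of a real series into the real-valued layout
# [X0, Re(X1), Im(X1), Re(X2), Im(X2), ...]; for even N the Nyquist term
# appears once as a real coefficient. One packed slot = one "frequency
# domain". pack_rfft and unpack_rfft are exact inverses.
pack_rfft <- function(x) {
  n <- length(x)
  X <- fft(x)
  nh <- (n - 1L) %/% 2L  # full complex harmonics
  out <- numeric(n)
  out[1] <- Re(X[1])
  if (nh > 0) {
    idx <- seq_len(nh)
    out[2 * idx] <- Re(X[idx + 1L])
    out[2 * idx + 1L] <- Im(X[idx + 1L])
  }
  if (n %% 2L == 0L) out[n] <- Re(X[n / 2L + 1L])
  out
}

unpack_rfft <- function(p) {
  n <- length(p)
  X <- complex(n)
  X[1] <- p[1]
  nh <- (n - 1L) %/% 2L
  if (nh > 0) {
    idx <- seq_len(nh)
    X[idx + 1L] <- complex(real = p[2 * idx], imaginary = p[2 * idx + 1L])
    X[n + 1L - idx] <- Conj(X[idx + 1L])
  }
  if (n %% 2L == 0L) X[n / 2L + 1L] <- p[n]
  Re(fft(X, inverse = TRUE)) / n
}

#' Log-magnitude packed-DFT spectral features
#'
#' Computes, per cell, the packed real DFT of the normalized trace
#' (index 0 the zero-frequency term, then alternating real/imaginary parts
#' of successive harmonics), takes `log(|.| + eps)` and truncates to the
#' first `cutoff_index` packed slots. These vectors are the inputs to
#' EMD / Euclidean distance computation.
#'
#' @param traces a [trace_set()], normally min-max normalized first.
#' @param cutoff_index number of packed frequency domains to keep
#'   (capped at the number of frames).
#' @param eps floor inside the logarithm; exact zeros occur for silent
#'   traces.
#' @return an object of class `spectral_features` with fields `features`
#'   (cells x domains matrix), `cutoff_index`, `fs`, `n_frames`,
#'   `cell_ids`.
#' @export
dft_log_magnitude <- function(traces, cutoff_index, eps = 1e-12) {
  stopifnot(inherits(traces, "trace_set"))
  cutoff_index <- as.integer(cutoff_index)
  if (length(cutoff_index) != 1L || is.na(cutoff_index) || cutoff_index < 1L)
    stop("parameter error: cutoff_index must be a single integer >= 1")
  n <- ncol(traces$values)
  k <- min(cutoff_index, n)
  feats <- t(apply(traces$values, 1, function(r) log(abs(pack_rfft(r))[1:k] + eps)))
  if (k == 1L) feats <- matrix(feats, ncol = 1L)
  rownames(feats) <- traces$cell_ids
  structure(list(features = feats, cutoff_index = k, fs = traces$fs,
                 n_frames = n, cell_ids = traces$cell_ids),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf(
    "<spectral_features> %d cells x %d packed domains (0 - %.4g Hz), N = %d, fs = %g Hz\n",
    nrow(x$features), x$cutoff_index,
    rfft_index_to_frequency(x$cutoff_index - 1L, x$n_frames, x$fs),
    x$n_frames, x$fs))
  invisible(x)
}

#' Frequency owning a packed real-DFT slot
#'
#' Packed index `j` belongs to harmonic `floor((j + 1) / 2)`, whose
#' frequency is `floor((j + 1) / 2) * fs / n_frames` Hz. For a 3000-frame
#' recording at 10 Hz, index 1000 maps to 1.67 Hz.
#'
#' @param index packed slot index, `0 <= index < n_frames` (vectorized).
#' @param n_frames series length.
#' @param fs sampling rate (Hz).
#' @return frequency in Hz.
#' @examples
#' rfft_index_to_frequency(1000, 3000, 10)  # 1.6667
#' @export
rfft_index_to_frequency <- function(index, n_frames, fs) {
  index <- as.integer(index)
  if (any(index < 0L) || any(index >= n_frames))
    stop("parameter error: index must satisfy 0 <= index < n_frames")
  (index + 1L) %/% 2L * fs / n_frames
}

#' Choose a frequency cutoff from reconstruction error
#'
#' For each candidate cutoff `k` the packed spectrum is truncated to its
#' first `k` slots, treated as the spectrum of a length-`k` series,
#' inverse-transformed and linearly interpolated back onto the original
#' frame grid; the sum of squared differences (SOSD) between each raw
#' trace and its reconstruction is averaged over cells. The selected
#' cutoff is the smallest candidate whose cumulative share of the total
#' mean SOSD reaches `fraction`.
#'
#' @param traces a [trace_set()] (normalized traces recommended).
#' @param candidates strictly increasing integer cutoffs to evaluate.
#' @param fraction target cumulative fraction of total mean SOSD in (0, 1].
#'   Default 0.945.
#' @return an object of class `cutoff_report` with `sosd_per_cutoff`,
#'   `cumulative_fraction`, `selected_cutoff` and the candidate grid.
#' @export
select_frequency_cutoff <- function(traces, candidates, fraction = 0.945) {
  stopifnot(inherits(traces, "trace_set"))
  candidates <- as.integer(candidates)
  if (length(candidates) == 0L)
    stop("parameter error: candidates must be a non-empty integer vector")
  if (any(diff(candidates) <= 0L))
    stop("parameter error: candidates must be strictly increasing")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("parameter error: fraction must be in (0, 1]")
  n <- ncol(traces$values)
  if (any(candidates < 1L) || any(candidates > n))
    stop("parameter error: candidates must lie in [1, n_frames]")
  v <- traces$values
  packed <- t(apply(v, 1, pack_rfft))
  grid <- seq_len(n)
  sosd <- vapply(candidates, function(k) {
    errs <- vapply(seq_len(nrow(v)), function(i) {
      short <- unpack_rfft(packed[i, 1:k] * k / n)  # preserve amplitude scale
      rec <- if (k == n) short else
        approx(seq(1, n, length.out = k), short, xout = grid)$y
      sum((v[i, ] - rec)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  cumfrac <- cumsum(sosd) / sum(sosd)
  sel <- candidates[which(cumfrac >= fraction)[1]]
  structure(list(candidates = candidates, sosd_per_cutoff = sosd,
                 cumulative_fraction = cumfrac, selected_cutoff = sel,
                 fraction = fraction),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf(
    "<cutoff_report> %d candidates; selected cutoff %d (cumulative SOSD fraction >= %.3f)\n",
    length(x$candidates), x$selected_cutoff, x$fraction))
  invisible(x)
}

#' @export
plot.cutoff_report <- function(x, ...) {
  plot(x$candidates, x$cumulative_fraction, type = "b", pch = 16,
       xlab = "frequency-domain cutoff (packed index)",
       ylab = "cumulative fraction of total mean SOSD", ...)
  abline(h = x$fraction, lty = 2)
  abline(v = x$selected_cutoff, lty = 3)
  invisible(x)
}
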