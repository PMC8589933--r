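#' Archetype specification for the synthetic trace generator
#'
#' An archetype describes a cell population by its calcium event
#' statistics: a homogeneous Poisson event rate, double-exponential
#' transient kinetics (rise and decay time constants), an amplitude
#' distribution and additive Gaussian noise. Populations with different
#' event rates produce distinct low-frequency spectral energy profiles,
#' which is what the fingerprinting pipeline clusters on.
#'
#' @param name archetype name.
#' @param event_rate events per second (> 0).
#' @param rise_tau,decay_tau transient rise / decay time constants in
#'   seconds (GCaMP6s-like defaults 0.1 and 1.5).
#' @param amplitude_mean,amplitude_sd normal amplitude distribution in
#'   normalized units (negative draws are clipped at 0).
#' @param noise_sd additive Gaussian noise SD in normalized units.
#' @return an object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, event_rate, rise_tau = 0.1, decay_tau = 1.5,
                           amplitude_mean = 1, amplitude_sd = 0.15,
                           noise_sd = 0.05) {
  stopifnot(event_rate > 0, rise_tau > 0, decay_tau > 0, noise_sd >= 0)
  structure(list(name = as.character(name), event_rate = event_rate,
                 rise_tau = rise_tau, decay_tau = decay_tau,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 noise_sd = noise_sd),
            class = "archetype_spec")
}

#' Default four-archetype activity gradient
#'
#' Four populations spanning a 35-fold range of event rate and a 30-fold
#' range of transient kinetics, from nearly silent cells with slow
#' calcium waves (non-neuronal-like) to highly active cells with fast
#' transients (spiking-neuron-like). Rate and kinetics vary together so
#' that each population has a distinct spectral energy profile with
#' comparable separation between neighboring archetypes; rate alone
#' would not separate them, because min-max normalization discards the
#' overall scale of the spectrum. The low noise SD emulates traces
#' produced by a deconvolution/matrix-factorization signal extractor,
#' which are largely denoised model reconstructions.
#'
#' @return list of four [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(archetype_spec("silent", 0.02, rise_tau = 0.5, decay_tau = 12,
                      noise_sd = 0.01),
       archetype_spec("sparse", 0.12, rise_tau = 0.12, decay_tau = 2.5,
                      noise_sd = 0.01),
       archetype_spec("moderate", 0.35, rise_tau = 0.06, decay_tau = 0.9,
                      noise_sd = 0.01),
       archetype_spec("active", 0.7, rise_tau = 0.03, decay_tau = 0.4,
                      noise_sd = 0.01))
}

# double-exponential calcium transient, normalized to unit peak
transient_kernel <- function(rise_tau, decay_tau, fs, dur = NULL) {
  if (is.null(dur)) dur <- 8 * decay_tau
  t <- seq(0, dur, by = 1 / fs)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k / max(k)
}

#' Generate synthetic calcium traces with planted archetype labels
#'
#' Per cell: homogeneous Poisson event times at the archetype rate, each
#' event contributing a double-exponential transient with a sampled
#' amplitude, summed, plus Gaussian noise. Fully reproducible from
#' `seed`.
#'
#' @param archetypes list of [archetype_spec()] objects (default
#'   [default_archetypes()]).
#' @param cells_per cells per archetype.
#' @param n_frames frames per trace (>= 100; default 3000).
#' @param fs sampling rate in Hz (default 10).
#' @param seed RNG seed.
#' @return list with `traces` (a [trace_set()] carrying an `archetype`
#'   annotation) and `labels` (planted archetype name per cell).
#' @export
generate_traces <- function(archetypes = default_archetypes(), cells_per = 25L,
                            n_frames = 3000L, fs = 10, seed = 1L) {
  stopifnot(n_frames >= 100L)
  set.seed(seed)
  dur <- n_frames / fs
  rows <- list(); labels <- character(0)
  for (a in archetypes) {
    stopifnot(inherits(a, "archetype_spec"))
    kern <- transient_kernel(a$rise_tau, a$decay_tau, fs)
    for (i in seq_len(cells_per)) {
      n_ev <- rpois(1, a$event_rate * dur)
      tr <- numeric(n_frames)
      if (n_ev > 0) {
        ev_frames <- sort(ceiling(runif(n_ev) * n_frames))
        amps <- pmax(rnorm(n_ev, a$amplitude_mean, a$amplitude_sd), 0)
        for (e in seq_len(n_ev)) {
          idx <- ev_frames[e]:min(n_frames, ev_frames[e] + length(kern) - 1L)
          tr[idx] <- tr[idx] + amps[e] * kern[seq_along(idx)]
        }
      }
      tr <- tr + rnorm(n_frames, 0, a$noise_sd)
      rows[[length(rows) + 1L]] <- tr
      labels <- c(labels, a$name)
    }
  }
  values <- do.call(rbind, rows)
  ts <- trace_set(values, fs = fs,
                  annotations = list(archetype = labels))
  list(traces = ts, labels = labels)
}

#' Generate a synthetic stimulus session with planted tuning
#'
#' Builds interleaved labeled stimulus intervals (each label repeated
#' `trials` times) over a noise background, assigns every cell a planted
#' preferred label, and adds a transient response scaled by
#' `response_gain` at the onset of each interval carrying the cell's
#' preferred label.
#'
#' @param n_cells number of cells.
#' @param labels stimulus labels (default the three-state heat-stimulus
#'   design `heat-on`, `heat-on-delayed`, `none`).
#' @param trials trials per label (>= 1).
#' @param response_gain amplitude of the planted response in units of the
#'   noise SD 0.05 (gain 10 means amplitude 0.5).
#' @param stim_frames frames per interval (default 50).
#' @param fs sampling rate in Hz (default 10).
#' @param seed RNG seed.
#' @return list with `traces` (a [trace_set()]), `stim` (a
#'   [stimulus_map()]) and `tuning` (planted preferred label per cell).
#' @export
generate_stimulus_session <- function(n_cells = 30L,
                                      labels = c("heat-on", "heat-on-delayed", "none"),
                                      trials = 3L, response_gain = 10,
                                      stim_frames = 50L, fs = 10, seed = 1L) {
  stopifnot(trials >= 1L, n_cells >= 1L, length(labels) >= 1L)
  set.seed(seed)
  noise_sd <- 0.05
  labels <- as.character(labels)
  seq_labels <- rep(labels, times = trials)
  n_int <- length(seq_labels)
  start <- (seq_len(n_int) - 1L) * stim_frames
  stim <- stimulus_map(seq_labels, start, start + stim_frames)
  n_frames <- n_int * stim_frames
  planted <- sample(labels, n_cells, replace = TRUE)
  kern <- transient_kernel(0.1, 1.5, fs, dur = (stim_frames - 1) / fs)
  v <- matrix(rnorm(n_cells * n_frames, 0, noise_sd), n_cells, n_frames)
  amp <- response_gain * noise_sd
  for (c in seq_len(n_cells)) {
    own <- which(seq_labels == planted[c])
    for (i in own) {
      idx <- (start[i] + 1L):(start[i] + stim_frames)
      v[c, idx] <- v[c, idx] + amp * kern[seq_along(idx)]
    }
  }
  ts <- trace_set(v, fs = fs, annotations = list(planted_tuning = planted))
  list(traces = ts, stim = stim, tuning = setNames(planted, ts$cell_ids))
}

#' Default peak-shape library for motif-recovery fixtures
#'
#' Three shape families with well-separated half-widths on a common
#' 60-frame support: a sharp spike, a medium asymmetric calcium-like
#' transient, and a broad slow wave.
#'
#' @return named list of numeric base shapes.
#' @export
default_peak_shapes <- function() {
  t <- seq(0, 1, length.out = 60L)
  list(spike = exp(-((t - 0.5) / 0.04)^2),
       transient = pmax(exp(-(t - 0.3) / 0.25) - exp(-(t - 0.3) / 0.03), 0),
       wave = exp(-((t - 0.5) / 0.28)^2))
}

#' Generate a jittered peak library with planted family labels
#'
#' Each instance is its base shape with multiplicative amplitude jitter,
#' horizontal width jitter (resampling by a random stretch factor) and
#' additive Gaussian noise.
#'
#' @param shapes named list of base shapes with distinct half-widths
#'   (default [default_peak_shapes()]).
#' @param per_shape instances per family.
#' @param jitter relative amplitude/width jitter (default 0.1).
#' @param noise_sd additive noise SD relative to unit peak (default 0.02).
#' @param seed RNG seed.
#' @return list with `peaks` (list of `peak_curve` objects) and `labels`
#'   (planted family name per peak).
#' @export
generate_peak_library <- function(shapes = default_peak_shapes(),
                                  per_shape = 30L, jitter = 0.1,
                                  noise_sd = 0.02, seed = 1L) {
  set.seed(seed)
  peaks <- list(); labs <- character(0)
  L <- length(shapes[[1]])
  for (nm in names(shapes)) {
    base <- as.numeric(shapes[[nm]])
    for (i in seq_len(per_shape)) {
      stretch <- 1 + runif(1, -jitter, jitter)
      amp <- 1 + runif(1, -jitter, jitter)
      src <- seq(1, length(base), length.out = round(length(base) * stretch))
      v <- approx(seq_along(base), base, xout = src)$y * amp
      v <- v + rnorm(length(v), 0, noise_sd)
      hw <- half_width_at(v, which.max(v), max(v) - min(v))
      peaks[[length(peaks) + 1L]] <- structure(
        list(values = v, parent_uuid = NA_character_, start_frame = 0L,
             apex_frame = which.max(v) - 1L, half_width = hw,
             prominence = max(v) - min(v)),
        class = "peak_curve")
      labs <- c(labs, nm)
    }
  }
  list(peaks = peaks, labels = labs)
}
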