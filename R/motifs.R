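#' Detect calcium peaks in a normalized trace
#'
#' Prominence-based local-maximum detection. A local maximum is kept when
#' its topographic prominence (height above the higher of the two saddles
#' separating it from taller terrain) reaches `prominence`. Each retained
#' peak's curve spans the flanking minima between it and its neighboring
#' retained peaks (or the trace edges), and its half-width is measured at
#' half-prominence by linear interpolation.
#'
#' @param trace numeric vector, normalized to \[0, 1\].
#' @param prominence minimum prominence in normalized units (default 0.1).
#' @param min_width minimum peak-curve length in frames (default 3).
#' @param parent_uuid identifier of the source trace, carried on each
#'   peak.
#' @return list of `peak_curve` objects (fields `values`, `parent_uuid`,
#'   `start_frame` 0-based, `apex_frame` 0-based, `half_width`,
#'   `prominence`); empty list for a flat trace.
#' @export
detect_peaks <- function(trace, prominence = 0.1, min_width = 3L,
                         parent_uuid = NA_character_) {
  x <- as.numeric(trace)
  n <- length(x)
  if (n < 3L) return(list())
  # strict local maxima; plateaus take their first index
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L]]
  if (!length(cand)) return(list())
  keep <- list()
  for (p in cand) {
    # walk left/right to the nearest strictly higher sample; the prominence
    # base is the higher of the two interval minima
    l <- p; lmin <- x[p]
    while (l > 1L && x[l - 1L] <= x[p]) { l <- l - 1L; lmin <- min(lmin, x[l]) }
    r <- p; rmin <- x[p]
    while (r < n && x[r + 1L] <= x[p]) { r <- r + 1L; rmin <- min(rmin, x[r]) }
    base <- max(if (l == 1L) min(x[1:p]) else lmin,
                if (r == n) min(x[p:n]) else rmin)
    prom <- x[p] - base
    if (prom >= prominence)
      keep[[length(keep) + 1L]] <- list(apex = p, prom = prom)
  }
  if (!length(keep)) return(list())
  apices <- vapply(keep, `[[`, integer(1), "apex")
  proms <- vapply(keep, `[[`, numeric(1), "prom")
  bounds_lo <- integer(length(apices))
  bounds_hi <- integer(length(apices))
  for (i in seq_along(apices)) {
    lo <- if (i == 1L) 1L else {
      seg <- apices[i - 1L]:apices[i]
      seg[which.min(x[seg])]
    }
    hi <- if (i == length(apices)) n else {
      seg <- apices[i]:apices[i + 1L]
      seg[which.min(x[seg])]
    }
    bounds_lo[i] <- lo; bounds_hi[i] <- hi
  }
  out <- list()
  for (i in seq_along(apices)) {
    lo <- bounds_lo[i]; hi <- bounds_hi[i]
    if (hi - lo + 1L < max(3L, min_width)) next
    if (apices[i] <= lo || apices[i] >= hi) next  # apex must be interior
    hw <- half_width_at(x, apices[i], proms[i])
    out[[length(out) + 1L]] <- structure(
      list(values = x[lo:hi], parent_uuid = parent_uuid,
           start_frame = lo - 1L, apex_frame = apices[i] - 1L,
           half_width = hw, prominence = proms[i]),
      class = "peak_curve")
  }
  out
}

# width (frames) of the region around the apex above
# height(apex) - prominence/2, linearly interpolated at the crossings
half_width_at <- function(x, apex, prom) {
  thr <- x[apex] - prom / 2
  n <- length(x)
  l <- apex
  while (l > 1L && x[l - 1L] >= thr) l <- l - 1L
  left <- if (l == 1L) 1 else (l - (thr - x[l - 1L]) / (x[l] - x[l - 1L]) + 1) - 1
  r <- apex
  while (r < n && x[r + 1L] >= thr) r <- r + 1L
  right <- if (r == n) n else r + (x[r] - thr) / (x[r] - x[r + 1L])
  max(right - left, 1)
}

#' @export
print.peak_curve <- function(x, ...) {
  cat(sprintf(
    "<peak_curve> %d frames from frame %d (apex %d), half-width %.2f, prominence %.3f\n",
    length(x$values), x$start_frame, x$apex_frame, x$half_width, x$prominence))
  invisible(x)
}

peak_values <- function(p) if (inherits(p, "peak_curve")) p$values else as.numeric(p)

znorm <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate-shape error: zero-variance shape")
  (x - mean(x)) / s
}

# full zero-padded cross-correlation of equal-length vectors, shifts
# -(L-1)..(L-1); returned in that order
cross_corr_full <- function(x, y) {
  L <- length(x)
  nf <- stats::nextn(2L * L - 1L, 2)
  cc <- Re(fft(fft(c(x, numeric(nf - L))) *
               Conj(fft(c(y, numeric(nf - L)))), inverse = TRUE)) / nf
  # cc[1] = shift 0, cc[2] = shift 1 (x leads), wrap-around for negative
  c(cc[(nf - L + 2L):nf], cc[1:L])
}

#' Shape-based distance between two shapes
#'
#' `1 - max_s NCC(x, y, s)`, where NCC is the zero-padded cross-correlation
#' normalized by the product of the vectors' norms (coefficient
#' normalization) and `s` ranges over all integer shifts. Both inputs are
#' z-normalized first, so the distance lies in \[0, 2\], is zero iff the
#' shapes are equal up to positive scaling and shift, and underlies the
#' k-Shape clustering procedure.
#'
#' @param x,y numeric vectors or `peak_curve` objects of equal length.
#' @return list with `distance` and the maximizing integer `shift`
#'   (positive: `y` is delayed relative to `x`).
#' @export
sbd <- function(x, y) {
  x <- znorm(peak_values(x)); y <- znorm(peak_values(y))
  if (length(x) != length(y)) stop("shapes must have equal length")
  cc <- cross_corr_full(y, x)  # cc at shift s: sum x_t * y_{t+s}
  denom <- sqrt(sum(x^2)) * sqrt(sum(y^2))
  ncc <- cc / denom
  L <- length(x)
  shifts <- -(L - 1L):(L - 1L)
  i <- which.max(ncc)
  list(distance = max(0, 1 - ncc[i]), shift = shifts[i])
}

shift_pad <- function(x, s) {
  L <- length(x)
  if (s == 0) x
  else if (s > 0) c(numeric(min(s, L)), x[seq_len(max(L - s, 0))])
  else c(x[(-s + 1L):L], numeric(min(-s, L)))
}

# k-Shape centroid ("shape") extraction: align members to the reference,
# then take the dominant eigenvector of the centered Gram matrix
# M = Q' S Q, S = sum of outer products of aligned members -- the shape
# maximizing the summed squared NCC to the members.
shape_extract <- function(rows, ref) {
  L <- ncol(rows)
  aligned <- t(apply(rows, 1, function(r) {
    s <- sbd(ref, r)$shift  # positive: r is delayed by s relative to ref
    shift_pad(r, -s)
  }))
  if (nrow(rows) == 1L) aligned <- matrix(aligned, nrow = 1L)
  S <- crossprod(aligned)
  Q <- diag(L) - matrix(1 / L, L, L)
  M <- Q %*% S %*% Q
  w <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (sum(aligned %*% w) < 0) w <- -w
  znorm(w)
}

#' Fit k-Shape clusters to a library of peak curves
#'
#' Iteratively assigns each (z-normalized, common-length) peak to its
#' nearest centroid under the shape-based distance and re-extracts each
#' centroid as the shape maximizing the within-cluster alignment
#' criterion, until the assignment stabilizes or `max_iter` is reached.
#' Peaks are linearly resampled to the median peak length beforehand. An
#' empty cluster arising during iteration is re-seeded with the
#' worst-fitting peak. Letters are assigned with [assign_letters()].
#'
#' @param peaks list of `peak_curve` objects or numeric vectors.
#' @param k number of clusters, `2 <= k <= length(peaks)` (k = 1 allowed
#'   for a single global shape).
#' @param initial integer vector of initial cluster labels, or a matrix of
#'   k initial centroid shapes (rows); defaults to a deterministic
#'   half-width-ordered partition seeding with `seed`.
#' @param max_iter iteration cap (default 100).
#' @param seed RNG seed used only when `initial` is NULL.
#' @return an object of class `motif_model`: `centroids` (k x L matrix of
#'   z-normalized shapes), `labels`, `letters`, `half_widths`, `inertia`
#'   (sum of within-cluster shape-based distances), `inertia_trace`,
#'   `resample_length`.
#' @export
kshape_fit <- function(peaks, k, initial = NULL, max_iter = 100L, seed = 1L) {
  vals <- lapply(peaks, peak_values)
  n <- length(vals)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("parameter error: k must lie in [1, n_peaks]")
  L <- max(3L, as.integer(round(median(lengths(vals)))))
  X <- t(vapply(vals, function(v)
    znorm(approx(seq_along(v), v, xout = seq(1, length(v), length.out = L))$y),
    numeric(L)))
  cent <- NULL
  lab <- NULL
  if (is.null(initial)) {
    cent <- seed_centroids_halfwidth(peaks, X, k, seed)
  } else if (is.matrix(initial)) {
    stopifnot(nrow(initial) == k, ncol(initial) == L)
    cent <- t(apply(initial, 1, znorm))
  } else {
    lab <- as.integer(initial)
    stopifnot(length(lab) == n, all(lab %in% seq_len(k)))
    cent <- t(vapply(seq_len(k), function(c) {
      rows <- X[lab == c, , drop = FALSE]
      if (nrow(rows) == 0L) X[sample.int(n, 1L), ] else
        shape_extract(rows, rows[1, ])
    }, numeric(L)))
  }
  dist_to <- function(cent) {
    d <- matrix(0, n, k)
    for (c in seq_len(k))
      for (i in seq_len(n)) d[i, c] <- sbd(cent[c, ], X[i, ])$distance
    d
  }
  inertia_trace <- numeric(0)
  lab <- max.col(-dist_to(cent), ties.method = "first")
  for (it in seq_len(max_iter)) {
    for (c in seq_len(k)) {
      rows <- which(lab == c)
      if (!length(rows)) {
        d <- dist_to(cent)
        worst <- which.max(vapply(seq_len(n), function(i) d[i, lab[i]], numeric(1)))
        lab[worst] <- c
        rows <- worst
      }
      cent[c, ] <- shape_extract(X[rows, , drop = FALSE], cent[c, ])
    }
    d <- dist_to(cent)
    new_lab <- max.col(-d, ties.method = "first")
    inertia_trace <- c(inertia_trace,
                       sum(d[cbind(seq_len(n), new_lab)]))
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  d <- dist_to(cent)
  inertia <- sum(d[cbind(seq_len(n), lab)])
  hw <- apply(cent, 1, function(w)
    half_width_at(w, which.max(w), max(w) - min(w)))
  model <- structure(list(centroids = cent, labels = lab, k = k,
                          half_widths = hw, letters = NULL,
                          inertia = inertia, inertia_trace = inertia_trace,
                          resample_length = L),
                     class = "motif_model")
  assign_letters(model)
}

# the seeding used by the gridsearch: order peaks by half-peak width,
# partition into k contiguous blocks, pick one random member per block
seed_centroids_halfwidth <- function(peaks, X, k, seed) {
  hw <- vapply(seq_along(peaks), function(i) {
    p <- peaks[[i]]
    if (inherits(p, "peak_curve")) p$half_width else {
      v <- peak_values(p)
      half_width_at(v, which.max(v), max(v) - min(v))
    }
  }, numeric(1))
  o <- order(hw, seq_along(hw))
  parts <- if (k == 1L) list(o) else
    split(o, cut(seq_along(o), breaks = k, labels = FALSE))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  idx <- vapply(parts, function(p) p[sample.int(length(p), 1L)], numeric(1))
  X[idx, , drop = FALSE]
}

#' Assign alphabetical motif labels by half-peak width
#'
#' Letters `a`, `b`, ... are assigned to centroids in ascending order of
#' centroid half-peak width; ties are broken by cluster index.
#'
#' @param model a [kshape_fit()] result.
#' @return the model with `letters` filled in (`letters[c]` is the letter
#'   of cluster `c`).
#' @export
assign_letters <- function(model) {
  stopifnot(inherits(model, "motif_model"))
  o <- order(model$half_widths, seq_len(model$k))
  lt <- character(model$k)
  lt[o] <- letters[seq_len(model$k)]
  model$letters <- lt
  model
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> k = %d motifs (length %d), inertia %.4f\n",
              x$k, x$resample_length, x$inertia))
  o <- order(x$letters)
  cat(sprintf("  %s: half-width %.2f frames, %d peaks\n",
              x$letters[o], x$half_widths[o],
              as.integer(table(factor(x$labels, levels = seq_len(x$k))))[o]),
      sep = "")
  invisible(x)
}

#' @export
plot.motif_model <- function(x, ...) {
  o <- order(x$letters)
  matplot(t(x$centroids[o, , drop = FALSE]), type = "l", lty = 1,
          xlab = "frame (resampled)", ylab = "z-normalized shape", ...)
  legend("topright", legend = x$letters[o], lty = 1,
         col = seq_len(x$k), bty = "n")
  invisible(x)
}

#' Gridsearch over the number of k-Shape clusters
#'
#' For each `k` in `k_range` and each restart, peaks are ordered by
#' half-peak width, partitioned into `k` blocks and one random centroid
#' seed drawn per block; the fit with minimal inertia per `k` is kept and
#' candidates that end with an empty cluster are discarded. Across `k`,
#' `k_select = "elbow"` (default) picks the smallest `k` whose inertia
#' improvement over `k - 1` falls below 10%, since raw inertia decreases
#' monotonically with `k`; `k_select = "min-inertia"` picks the global
#' minimum.
#'
#' @param peaks list of `peak_curve` objects or numeric vectors.
#' @param k_range candidate cluster counts (default `2:14`).
#' @param restarts random restarts per `k` (default 3).
#' @param seed master seed; per-(k, restart) streams are derived from it.
#' @param k_select `"elbow"` or `"min-inertia"`.
#' @param elbow_tol relative improvement threshold for the elbow rule.
#' @return the selected [kshape_fit()] model, with the per-k inertia table
#'   attached as attribute `"gridsearch"`.
#' @export
kshape_gridsearch <- function(peaks, k_range = 2:14, restarts = 3L, seed = 1L,
                              k_select = c("elbow", "min-inertia"),
                              elbow_tol = 0.1) {
  k_select <- match.arg(k_select)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1L & k_range <= length(peaks)]
  if (!length(k_range)) stop("parameter error: empty usable k_range")
  if (restarts < 1L) stop("parameter error: restarts must be >= 1")
  best_per_k <- vector("list", length(k_range))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    for (r in seq_len(restarts)) {
      sub_seed <- (seed * 1009L + k * 131L + r) %% .Machine$integer.max
      fit <- kshape_fit(peaks, k, seed = sub_seed)
      if (length(unique(fit$labels)) < k) next  # empty cluster: discard
      if (is.null(best_per_k[[ki]]) || fit$inertia < best_per_k[[ki]]$inertia)
        best_per_k[[ki]] <- fit
    }
  }
  ok <- !vapply(best_per_k, is.null, logical(1))
  if (!any(ok))
    stop("search-failure error: every candidate ended with an empty cluster")
  ks <- k_range[ok]
  fits <- best_per_k[ok]
  inert <- vapply(fits, `[[`, numeric(1), "inertia")
  pick <- if (k_select == "min-inertia" || length(ks) == 1L) {
    which.min(inert)
  } else {
    imp <- c(Inf, 1 - inert[-1] / pmax(inert[-length(inert)], .Machine$double.eps))
    flat <- which(imp < elbow_tol)
    if (length(flat)) max(1L, flat[1] - 1L) else length(ks)
  }
  model <- fits[[pick]]
  attr(model, "gridsearch") <- data.frame(k = ks, inertia = inert)
  model
}

#' Discretize traces into motif-letter sequences
#'
#' Maps each trace's detected peaks, in temporal order, to the letter of
#' the nearest model centroid under the shape-based distance. A trace
#' without peaks yields the empty string.
#'
#' @param trace_peaks list (one element per trace) of lists of
#'   `peak_curve` objects, e.g. from [detect_peaks()] per trace.
#' @param model a fitted, lettered [kshape_fit()] model.
#' @return character vector of letter sequences, one per trace.
#' @export
discretize <- function(trace_peaks, model) {
  stopifnot(inherits(model, "motif_model"), !is.null(model$letters))
  L <- model$resample_length
  vapply(trace_peaks, function(pl) {
    if (!length(pl)) return("")
    ord <- order(vapply(pl, function(p)
      if (inherits(p, "peak_curve")) p$start_frame else 0L, numeric(1)))
    lets <- vapply(pl[ord], function(p) {
      v <- peak_values(p)
      z <- znorm(approx(seq_along(v), v, xout = seq(1, length(v), length.out = L))$y)
      d <- vapply(seq_len(model$k), function(c)
        sbd(model$centroids[c, ], z)$distance, numeric(1))
      model$letters[which.min(d)]
    }, character(1))
    paste(lets, collapse = "")
  }, character(1))
}
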