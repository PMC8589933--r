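#' One-dimensional Earth Mover's Distance
#'
#' Minimum transportation work between two non-negative weight vectors on
#' the integer line (ground distance between bins `i` and `j` is
#' `|i - j|`), divided by the total flow. Partial matching is used for
#' unequal total masses: only `flow = min(sum(u), sum(v))` mass is moved
#' and the surplus of the heavier signature stays put, placed so as to
#' minimize the work. For equal masses this equals the closed form
#' `sum(abs(cumsum(u) - cumsum(v))) / sum(u)`.
#'
#' The minimization is exact: it is solved as a convex piecewise-linear
#' dynamic program over the cumulative surplus, compiled in C++.
#'
#' @param u,v non-negative numeric vectors of equal length with positive
#'   total mass.
#' @return non-negative scalar distance (work per unit flow).
#' @examples
#' emd_1d(c(1, 0, 0), c(0, 0, 1))        # one unit moved two bins -> 2
#' emd_1d(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # 1
#' @export
emd_1d <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("signatures must have equal length")
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("signatures must be finite")
  if (any(u < 0) || any(v < 0)) stop("signature weights must be non-negative")
  su <- sum(u); sv <- sum(v)
  if (su == 0 || sv == 0)
    stop("degenerate-input error: all-zero signature")
  emd1d_work(u, v) / min(su, sv)
}

# Convert a pair of log-magnitude feature rows into the non-negative bin
# masses the EMD transports. "magnitude" (default) exponentiates back to
# the linear DFT magnitude — the square-root-of-energy reading of the
# spectrum, which concentrates mass in the signal band. "shift" instead
# jointly shifts the pair by -min(both rows); it preserves relative
# structure but adds a flat pedestal that dominates the total mass and
# dilutes contrast, so it is not the default.
emd_features_pair <- function(x, y, weights = c("magnitude", "shift")) {
  weights <- match.arg(weights)
  if (weights == "magnitude") {
    emd_1d(exp(x), exp(y))
  } else {
    m <- min(x, y)
    emd_1d(x - m, y - m)
  }
}

#' Permutation sensitivity of EMD versus Euclidean distance
#'
#' Applies the same index permutation to both vectors and reports EMD and
#' Euclidean distance before and after. The Euclidean distance is exactly
#' invariant under any joint permutation, while the EMD generally changes:
#' it is the property that makes EMD order-aware, which is what a spectral
#' feature vector requires.
#'
#' @param u,v numeric vectors; non-negative vectors are used as masses
#'   directly, otherwise the pair is jointly shifted to non-negative
#'   weights (before and after permuting).
#' @param permutation an index permutation of `seq_along(u)`.
#' @return named list with `emd_before`, `emd_after`, `euclidean_before`,
#'   `euclidean_after`.
#' @export
shift_sensitivity_check <- function(u, v, permutation) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("vectors must have equal length")
  permutation <- as.integer(permutation)
  if (length(permutation) != length(u) ||
      !identical(sort(permutation), seq_along(u)))
    stop("parameter error: permutation must be a bijection on indices")
  up <- u[permutation]; vp <- v[permutation]
  emd <- function(a, b) {
    m <- min(a, b, 0)
    emd_1d(a - m, b - m)
  }
  list(emd_before = emd(u, v),
       emd_after = emd(up, vp),
       euclidean_before = sqrt(sum((u - v)^2)),
       euclidean_after = sqrt(sum((up - vp)^2)))
}

#' Pairwise distance matrix between spectral feature rows
#'
#' Computes the symmetric matrix of EMD or Euclidean distances between
#' feature rows. The EMD needs non-negative bin masses, while
#' log-magnitude spectra dip negative; `weights` selects the conversion:
#' `"magnitude"` (default) transports the linear DFT magnitude
#' (`exp` of the log feature — the square-root-of-energy profile), and
#' `"shift"` jointly shifts each pair of rows by the pair's minimum.
#' Partial matching handles unequal total masses. Euclidean distances are
#' computed on the feature rows exactly as given.
#'
#' @param features a [dft_log_magnitude()] result, or a plain numeric
#'   matrix with one feature row per item.
#' @param metric `"emd"` or `"euclidean"`.
#' @param weights non-negativity rule for EMD masses, `"magnitude"` or
#'   `"shift"` (ignored for Euclidean).
#' @return an object of class `trace_dist`: list with `values` (symmetric
#'   matrix, zero diagonal), `metric` and `item_uuids`.
#' @export
pairwise_distances <- function(features, metric = c("emd", "euclidean"),
                               weights = c("magnitude", "shift")) {
  metric <- match.arg(metric)
  weights <- match.arg(weights)
  if (inherits(features, "spectral_features")) {
    ids <- features$cell_ids
    m <- features$features
  } else {
    m <- as.matrix(features)
    ids <- rownames(m)
    if (is.null(ids)) ids <- new_uuid(nrow(m))
  }
  if (nrow(m) < 2L)
    stop("parameter error: need at least 2 feature rows")
  if (any(!is.finite(m))) stop("features must be finite")
  if (metric == "emd") {
    d <- if (weights == "magnitude") emd1d_pairwise(exp(m), joint_shift = FALSE)
         else emd1d_pairwise(m, joint_shift = TRUE)
  } else {
    d <- as.matrix(stats::dist(m, method = "euclidean"))
  }
  dimnames(d) <- list(ids, ids)
  structure(list(values = d, metric = metric, item_uuids = ids),
            class = "trace_dist")
}

#' Construct a trace_dist from a precomputed matrix
#'
#' @param values symmetric non-negative matrix with zero diagonal.
#' @param metric label for the metric used.
#' @param item_uuids item identifiers (row names used when omitted).
#' @return a `trace_dist`.
#' @export
trace_dist <- function(values, metric = "custom", item_uuids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("validation error: matrix must be square")
  if (any(!is.finite(values)) || any(values < 0))
    stop("validation error: distances must be finite and non-negative")
  if (max(abs(values - t(values))) > 1e-9)
    stop("validation error: matrix must be symmetric")
  if (any(abs(diag(values)) > 1e-12))
    stop("validation error: diagonal must be zero")
  values <- (values + t(values)) / 2
  if (is.null(item_uuids)) item_uuids <- rownames(values)
  if (is.null(item_uuids)) item_uuids <- new_uuid(n)
  dimnames(values) <- list(item_uuids, item_uuids)
  structure(list(values = values, metric = metric, item_uuids = item_uuids),
            class = "trace_dist")
}

#' @export
print.trace_dist <- function(x, ...) {
  cat(sprintf("<trace_dist> %d items, metric = %s, range [0, %.4g]\n",
              nrow(x$values), x$metric, max(x$values)))
  invisible(x)
}

#' Write / read a distance matrix as CSV (UUID header row and column)
#' @param x a `trace_dist`.
#' @param path file path.
#' @export
write_distances <- function(x, path) {
  stopifnot(inherits(x, "trace_dist"))
  df <- data.frame(uuid = x$item_uuids,
                   format(x$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("uuid", x$item_uuids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @param metric metric label recorded on the read object.
#' @export
read_distances <- function(path, metric = "custom") {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  trace_dist(m, metric = metric, item_uuids = ids)
}
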