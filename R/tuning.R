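#' Stimulus tuning curves and tuning labels
#'
#' For every cell and every stimulus label, averages the cell's response
#' over all frames of all intervals carrying that label (plain mean of the
#' supplied traces, no baseline subtraction). The cell's tuning is the
#' label with the highest mean response; exact ties go to the
#' lexicographically first label.
#'
#' @param traces a [trace_set()] (normalized traces recommended).
#' @param stim a [stimulus_map()]; every interval must lie within the
#'   trace length.
#' @return an object of class `tuning_result`: `mean_response` (cells x
#'   labels matrix), `tuned_label` (per cell), `cell_ids`.
#' @export
tuning_curves <- function(traces, stim) {
  stopifnot(inherits(traces, "trace_set"), inherits(stim, "stimulus_map"))
  nfr <- ncol(traces$values)
  if (any(stim$end_frame > nfr))
    stop(sprintf("bounds error: interval ending at frame %d exceeds trace length %d",
                 max(stim$end_frame), nfr))
  labs <- sort(unique(stim$label))
  mr <- vapply(labs, function(l) {
    rows <- stim[stim$label == l, , drop = FALSE]
    frames <- unlist(mapply(function(s, e) (s + 1L):e, rows$start_frame,
                            rows$end_frame, SIMPLIFY = FALSE))
    rowMeans(traces$values[, frames, drop = FALSE])
  }, numeric(nrow(traces$values)))
  if (nrow(traces$values) == 1L) mr <- matrix(mr, nrow = 1L)
  dimnames(mr) <- list(traces$cell_ids, labs)
  tuned <- labs[apply(mr, 1, which.max)]  # which.max: first max, labs sorted
  structure(list(mean_response = mr, tuned_label = setNames(tuned, traces$cell_ids),
                 cell_ids = traces$cell_ids),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  tb <- table(x$tuned_label)
  cat(sprintf("<tuning_result> %d cells x %d stimuli; tuning: %s\n",
              nrow(x$mean_response), ncol(x$mean_response),
              paste(sprintf("%s(%d)", names(tb), tb), collapse = " ")))
  invisible(x)
}

#' @export
plot.tuning_result <- function(x, cells = seq_len(min(nrow(x$mean_response), 8L)),
                               ...) {
  matplot(t(x$mean_response[cells, , drop = FALSE]), type = "b", pch = 16,
          lty = 1, xaxt = "n", xlab = "stimulus", ylab = "mean response", ...)
  axis(1, at = seq_len(ncol(x$mean_response)),
       labels = colnames(x$mean_response))
  invisible(x)
}

# frame-wise class labels from a stimulus map restricted to `classes`;
# NA outside the listed intervals
frame_classes <- function(stim, n_frames, classes) {
  y <- rep(NA_character_, n_frames)
  for (r in seq_len(nrow(stim))) {
    if (!(stim$label[r] %in% classes)) next
    y[(stim$start_frame[r] + 1L):stim$end_frame[r]] <- stim$label[r]
  }
  y
}

#' Linear-discriminant state projection of population activity
#'
#' Treats each timepoint as a feature vector of the intensity values of
#' every cell and fits a linear discriminant model on the frames falling
#' inside the stimulus intervals of the requested classes. The pooled
#' within-class covariance may be shrunk toward the identity scaled by the
#' average variance (`W <- (1 - shrinkage) W + shrinkage * mean(diag(W)) I`),
#' which keeps the fit defined when frames are scarce relative to cells;
#' shrinkage defaults on when the training frames number fewer than five
#' per cell. Timepoints are classified by the nearest projected class mean
#' (equal priors), and accuracy is reported on the training frames (no
#' held-out split).
#'
#' @param traces a [trace_set()].
#' @param stim a [stimulus_map()].
#' @param classes stimulus labels to use as classes (>= 2); defaults to
#'   all labels in `stim`.
#' @param shrinkage shrinkage intensity in \[0, 1\], or `NULL` for the
#'   automatic rule (0.1 when frames < 5 x cells, else 0).
#' @param n_components number of discriminant components to keep (at most
#'   `length(classes) - 1`).
#' @return an object of class `state_projection`: `coordinates`
#'   (timepoints x components, training frames only), `class_per_timepoint`,
#'   `frame_index` (0-based), `predicted`, `training_accuracy`, `scalings`,
#'   `class_means`.
#' @export
lda_states <- function(traces, stim, classes = NULL, shrinkage = NULL,
                       n_components = NULL) {
  stopifnot(inherits(traces, "trace_set"), inherits(stim, "stimulus_map"))
  if (is.null(classes)) classes <- sort(unique(stim$label))
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("parameter error: need >= 2 classes")
  nfr <- ncol(traces$values)
  y_all <- frame_classes(stim, nfr, classes)
  use <- which(!is.na(y_all))
  y <- factor(y_all[use], levels = classes)
  if (any(table(y) == 0L))
    stop("parameter error: class has no frames: ",
         paste(classes[table(y) == 0L], collapse = ", "))
  X <- t(traces$values[, use, drop = FALSE])  # frames x cells
  p <- ncol(X)
  if (is.null(shrinkage)) shrinkage <- if (nrow(X) < 5L * p) 0.1 else 0
  mu <- t(vapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(p)))
  Xc <- X - mu[as.integer(y), , drop = FALSE]
  W <- crossprod(Xc) / max(nrow(X) - length(classes), 1L)
  if (shrinkage > 0) {
    W <- (1 - shrinkage) * W + shrinkage * mean(diag(W)) * diag(p)
  }
  gm <- colMeans(X)
  B <- crossprod(sqrt(as.vector(table(y))) * (mu - rep(gm, each = nrow(mu))))
  Wi <- tryCatch(solve(W), error = function(e)
    stop("numerical error: singular within-class scatter; set a shrinkage > 0"))
  eg <- eigen(Wi %*% B)
  r <- min(length(classes) - 1L, p)
  if (!is.null(n_components)) r <- min(r, as.integer(n_components))
  V <- Re(eg$vectors[, seq_len(r), drop = FALSE])
  # scale discriminants to unit within-class variance
  for (j in seq_len(r)) {
    s <- sqrt(drop(t(V[, j]) %*% W %*% V[, j]))
    if (s > 0) V[, j] <- V[, j] / s
  }
  Z <- X %*% V
  M <- mu %*% V
  dmat <- vapply(seq_len(nrow(M)), function(c)
    rowSums((Z - rep(M[c, ], each = nrow(Z)))^2), numeric(nrow(Z)))
  pred <- factor(classes[max.col(-dmat, ties.method = "first")],
                 levels = classes)
  structure(list(coordinates = Z, class_per_timepoint = as.character(y),
                 frame_index = use - 1L, predicted = as.character(pred),
                 training_accuracy = mean(pred == y),
                 scalings = V, class_means = M, classes = classes,
                 shrinkage = shrinkage),
            class = "state_projection")
}

#' @export
print.state_projection <- function(x, ...) {
  cat(sprintf(
    "<state_projection> %d timepoints, %d classes (%s), %d components, training accuracy %.3f\n",
    nrow(x$coordinates), length(x$classes), paste(x$classes, collapse = ", "),
    ncol(x$coordinates), x$training_accuracy))
  invisible(x)
}

#' @export
plot.state_projection <- function(x, ...) {
  cl <- factor(x$class_per_timepoint, levels = x$classes)
  if (ncol(x$coordinates) >= 2L) {
    plot(x$coordinates[, 1], x$coordinates[, 2], col = as.integer(cl),
         pch = 16, xlab = "LD1", ylab = "LD2", ...)
  } else {
    plot(x$frame_index, x$coordinates[, 1], col = as.integer(cl), pch = 16,
         xlab = "frame", ylab = "LD1", ...)
  }
  legend("topright", legend = x$classes, col = seq_along(x$classes),
         pch = 16, bty = "n")
  invisible(x)
}
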