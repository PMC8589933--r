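#' Complete-linkage agglomerative clustering on a precomputed distance
#' matrix
#'
#' Standard agglomeration where the distance between two clusters is the
#' maximum pairwise distance between their members. Ties in the minimal
#' inter-cluster distance are broken toward the lowest (row, column) index
#' pair among the active clusters, which makes the merge sequence
#' deterministic across platforms. The merge matrix follows the
#' [stats::hclust()] encoding (negative entries are leaves, positive
#' entries earlier merges).
#'
#' The tree carries the agglomerative coefficient `alpha`: the mean over
#' leaves of `1 - h(i)/h_max`, where `h(i)` is the height at which leaf
#' `i` first merges and `h_max` the final merge height. Values near 1
#' indicate strong hierarchical structure.
#'
#' @param dist a [trace_dist()] (or symmetric matrix coercible to one).
#' @return an object of class `linkage_tree` with `merge`, `height`,
#'   `size`, `alpha`, `labels` (item UUIDs) and `metric`.
#' @export
hierarchical_complete <- function(dist) {
  if (!inherits(dist, "trace_dist")) dist <- trace_dist(dist)
  D <- dist$values
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items to cluster")
  active <- seq_len(n)           # positions into D of live clusters
  id <- -seq_len(n)              # hclust-style cluster codes
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  fmh <- rep(NA_real_, n)        # first-merge height per leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  diag(D) <- Inf
  for (m in seq_len(n - 1L)) {
    na <- length(active)
    sub <- D[active, active, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]        # positions within `active`
    pi <- active[i]; pj <- active[j]
    merge[m, ] <- sort(c(id[pi], id[pj]))
    height[m] <- mn
    msize[m] <- sizes[pi] + sizes[pj]
    if (sizes[pi] == 1L) fmh[members[[pi]]] <- mn
    if (sizes[pj] == 1L) fmh[members[[pj]]] <- mn
    # complete linkage update in place at position pi
    newd <- pmax(D[pi, ], D[pj, ])
    D[pi, ] <- newd
    D[, pi] <- newd
    D[pi, pi] <- Inf
    members[[pi]] <- c(members[[pi]], members[[pj]])
    sizes[pi] <- sizes[pi] + sizes[pj]
    id[pi] <- m
    active <- active[-j]
  }
  hmax <- height[n - 1L]
  alpha <- if (hmax == 0) 0 else mean(1 - fmh / hmax)
  structure(list(merge = merge, height = height, size = msize,
                 alpha = alpha, labels = dist$item_uuids,
                 metric = dist$metric, n = n),
            class = "linkage_tree")
}

#' Agglomerative coefficient of a linkage tree
#'
#' `alpha = mean_i (1 - h(i) / h_max)` over leaves; `h(i)` is the height
#' of the first merge containing leaf `i`. Defined as 0 when all items are
#' identical (`h_max = 0`). Always in \[0, 1\] and invariant to uniform
#' scaling of the distances.
#'
#' @param tree a [hierarchical_complete()] result.
#' @return scalar in \[0, 1\].
#' @export
agglomerative_coefficient <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  tree$alpha
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf(
    "<linkage_tree> %d leaves, complete linkage (%s), alpha = %.3f, top height %.4g\n",
    x$n, x$metric, x$alpha, x$height[x$n - 1L]))
  invisible(x)
}

#' Convert a linkage tree to a stats::hclust object
#' @param x a `linkage_tree`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  ord <- function(m) {
    out <- integer(0)
    for (v in x$merge[m, ])
      out <- c(out, if (v < 0) -v else ord(v))
    out
  }
  structure(list(merge = x$merge, height = x$height,
                 order = ord(x$n - 1L),
                 labels = x$labels, method = "complete",
                 dist.method = x$metric, call = match.call()),
            class = "hclust")
}

#' @export
plot.linkage_tree <- function(x, ...) {
  plot(as.hclust.linkage_tree(x), ...)
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' Removes the `k - 1` highest merges; cluster ids are assigned by order
#' of first appearance along the leaf index.
#'
#' @param tree a [hierarchical_complete()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return an object of class `cluster_assignment`: integer `labels`
#'   (length n, values `1..k`), `k` and the leaf `item_uuids`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- tree$n
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n)
    stop("parameter error: k must lie in [1, n]")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  comp_of_merge <- integer(n - 1L)
  nm <- n - k
  for (m in seq_len(nm)) {
    reps <- vapply(tree$merge[m, ], function(v)
      if (v < 0) find(-v) else find(comp_of_merge[v]), integer(1))
    parent[reps[2]] <- reps[1]
    comp_of_merge[m] <- reps[1]
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))  # first-appearance order
  structure(list(labels = labels, k = k, item_uuids = tree$labels),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<cluster_assignment> k = %d; sizes: %s\n", x$k,
              paste(as.integer(tb), collapse = ", ")))
  invisible(x)
}

as_labels <- function(labels) {
  if (inherits(labels, "cluster_assignment")) labels$labels else as.integer(labels)
}

#' Mean silhouette score from a precomputed distance matrix
#'
#' Standard silhouette: for item `i` with own-cluster mean distance `a(i)`
#' and smallest other-cluster mean distance `b(i)`,
#' `s(i) = (b - a) / max(a, b)`; members of singleton clusters contribute
#' 0. Returns the mean over items.
#'
#' @param dist a [trace_dist()].
#' @param labels a [cut_tree()] result or integer label vector.
#' @return scalar in \[-1, 1\].
#' @export
silhouette_precomputed <- function(dist, labels) {
  if (!inherits(dist, "trace_dist")) dist <- trace_dist(dist)
  lab <- as_labels(labels)
  n <- nrow(dist$values)
  if (length(lab) != n) stop("labels must have one entry per item")
  k <- length(unique(lab))
  if (k < 2L || k > n - 1L)
    stop("parameter error: silhouette requires 2 <= k <= n - 1")
  D <- dist$values
  sizes <- table(lab)
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[[as.character(lab[i])]] == 1L) { s[i] <- 0; next }
    means <- tapply(D[i, ], lab, sum)
    means[as.character(lab[i])] <-
      means[as.character(lab[i])] / (sizes[[as.character(lab[i])]] - 1L)
    other <- setdiff(names(means), as.character(lab[i]))
    means[other] <- means[other] / as.numeric(sizes[other])
    a <- means[[as.character(lab[i])]]
    b <- min(means[other])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Davies-Bouldin index with EMD (or Euclidean) geometry
#'
#' Adaptation of the Davies-Bouldin cluster-validity index to Earth
#' Mover's Distance on spectral features: each cluster centroid is the
#' elementwise mean of its members' feature rows, within-cluster scatter
#' `S_c` is the mean EMD from members to the centroid, and centroid
#' separation `M_cd` the EMD between centroids (rows are converted to
#' non-negative masses by the magnitude rule of [pairwise_distances()];
#' a mean of log features maps to a geometric-mean magnitude profile).
#' The index is
#' `mean_c max_{d != c} (S_c + S_d) / M_cd`; lower is better. With
#' `metric = "euclidean"` this reduces to the textbook index.
#'
#' @param features a [dft_log_magnitude()] result or numeric matrix.
#' @param labels a [cut_tree()] result or integer label vector.
#' @param metric `"emd"` or `"euclidean"`.
#' @return non-negative scalar.
#' @export
davies_bouldin_emd <- function(features, labels, metric = c("emd", "euclidean")) {
  metric <- match.arg(metric)
  m <- if (inherits(features, "spectral_features")) features$features else as.matrix(features)
  lab <- as_labels(labels)
  if (length(lab) != nrow(m)) stop("labels must have one entry per feature row")
  cl <- sort(unique(lab))
  k <- length(cl)
  if (k < 2L) stop("parameter error: need k >= 2 clusters")
  dfun <- if (metric == "emd") emd_features_pair else
    function(x, y) sqrt(sum((x - y)^2))
  cent <- t(vapply(cl, function(c) colMeans(m[lab == c, , drop = FALSE]),
                   numeric(ncol(m))))
  S <- vapply(seq_len(k), function(ci) {
    rows <- which(lab == cl[ci])
    mean(vapply(rows, function(r) dfun(m[r, ], cent[ci, ]), numeric(1)))
  }, numeric(1))
  db <- numeric(k)
  for (c in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), c), function(d) {
      M <- dfun(cent[c, ], cent[d, ])
      if (M == 0)
        stop("degenerate-clustering error: coincident cluster centroids")
      (S[c] + S[d]) / M
    }, numeric(1))
    db[c] <- max(ratios)
  }
  mean(db)
}

#' Select the number of clusters by silhouette maxima
#'
#' Cuts the tree at every `k` in `k_range`, scores each cut with
#' [silhouette_precomputed()], and returns the `k` with the highest score
#' (ties broken toward smaller `k`).
#'
#' @param tree a [hierarchical_complete()] result.
#' @param dist the [trace_dist()] the tree was built from.
#' @param k_range integer vector of candidate cluster counts within
#'   `[2, n - 1]`.
#' @return the selected integer `k`, with the per-k scores attached as
#'   attribute `"scores"`.
#' @export
select_k_silhouette <- function(tree, dist, k_range = 2:10) {
  stopifnot(inherits(tree, "linkage_tree"))
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("parameter error: empty k_range")
  n <- tree$n
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop("parameter error: k_range must lie within [2, n - 1]")
  scores <- vapply(k_range, function(k)
    silhouette_precomputed(dist, cut_tree(tree, k)), numeric(1))
  best <- k_range[which.max(scores)]  # which.max takes the first maximum
  structure(best, scores = setNames(scores, k_range))
}
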