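# Independent oracles used across the suite.

# Solve the 1-D partial-matching transportation problem as an explicit
# linear program with scipy.optimize.linprog (HiGHS), called through the
# system python. Takes a list of (u, v) pairs, returns work/flow values.
emd_lp_oracle <- function(pairs, strict = FALSE) {
  py <- Sys.which("python")
  if (py == "") {
    if (strict) stop("python not available for the LP oracle")
    skip("python not available for the LP oracle")
  }
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, json",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "pairs = json.load(open(sys.argv[1]))",
    "out = []",
    "for u, v in pairs:",
    "    u = np.array(u, float); v = np.array(v, float)",
    "    n = len(u); flow = min(u.sum(), v.sum())",
    "    c = np.abs(np.subtract.outer(np.arange(n), np.arange(n))).ravel()",
    "    A_ub, b_ub = [], []",
    "    for i in range(n):",
    "        a = np.zeros((n, n)); a[i, :] = 1",
    "        A_ub.append(a.ravel()); b_ub.append(u[i])",
    "    for j in range(n):",
    "        a = np.zeros((n, n)); a[:, j] = 1",
    "        A_ub.append(a.ravel()); b_ub.append(v[j])",
    "    r = linprog(c, A_ub=np.array(A_ub), b_ub=np.array(b_ub),",
    "                A_eq=[np.ones(n * n)], b_eq=[flow], method='highs')",
    "    assert r.status == 0, r.message",
    "    out.append(r.fun / flow)",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  jsonlite::write_json(pairs, fin, digits = NA)
  status <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  if (status != 0) {
    if (strict) stop("scipy LP oracle failed to run")
    skip("scipy LP oracle failed to run")
  }
  unlist(jsonlite::read_json(fout, simplifyVector = TRUE))
}

# Dense DFT straight from the definition X_k = sum_t x_t exp(-2*pi*i*k*t/N);
# independent of stats::fft.
dft_definition <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n)), complex(1))
}

# Textbook Davies-Bouldin with Euclidean geometry, written directly from
# the definition (centroids, mean within-cluster distances, pairwise max).
db_euclidean_textbook <- function(m, lab) {
  cl <- sort(unique(lab))
  cent <- t(sapply(cl, function(c) colMeans(m[lab == c, , drop = FALSE])))
  S <- sapply(seq_along(cl), function(ci)
    mean(sqrt(rowSums((m[lab == cl[ci], , drop = FALSE] -
                         matrix(cent[ci, ], sum(lab == cl[ci]),
                                ncol(m), byrow = TRUE))^2))))
  mean(sapply(seq_along(cl), function(c)
    max(sapply(setdiff(seq_along(cl), c), function(d)
      (S[c] + S[d]) / sqrt(sum((cent[c, ] - cent[d, ])^2))))))
}

# Adjusted Rand index between two labelings (mclust is the oracle).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# A tiny well-separated two-pair distance matrix used in several tests.
two_pairs_dist <- function(within = 0.1, between = 10) {
  d <- matrix(between, 4, 4)
  d[1, 2] <- d[2, 1] <- within
  d[3, 4] <- d[4, 3] <- within
  diag(d) <- 0
  trace_dist(d, "toy")
}
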