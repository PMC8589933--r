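#' Fit a first-order Markov chain to motif sequences
#'
#' Maximum-likelihood estimate: `counts[i, j]` is the number of adjacent
#' `i -> j` symbol pairs pooled across sequences (no transitions are
#' counted across sequence boundaries) and the transition matrix is the
#' row-normalized count matrix. States are the letters present in the
#' pooled sequences, in alphabetical order. A state with no outgoing
#' transitions keeps an all-zero row (no smoothing by default).
#'
#' @param sequences character vector of letter sequences (e.g. from
#'   [discretize()]); empty strings are ignored.
#' @param pseudocount added to every count cell before normalization
#'   (default 0, the raw empirical estimate).
#' @return an object of class `markov_chain`: `states`, `transition`
#'   (row-stochastic where a row has outgoing counts), `counts`,
#'   `n_transitions`.
#' @export
fit_markov <- function(sequences, pseudocount = 0) {
  chars <- lapply(sequences[nzchar(sequences)], function(s)
    strsplit(s, "")[[1]])
  states <- sort(unique(unlist(chars)))
  if (!any(lengths(chars) >= 2L))
    stop("fit error: no transitions (need at least one sequence of length >= 2)")
  k <- length(states)
  counts <- matrix(0, k, k, dimnames = list(states, states))
  for (s in chars) {
    if (length(s) < 2L) next
    from <- s[-length(s)]; to <- s[-1]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  cs <- counts + pseudocount
  rs <- rowSums(cs)
  transition <- cs
  nz <- rs > 0
  transition[nz, ] <- cs[nz, , drop = FALSE] / rs[nz]
  transition[!nz, ] <- 0
  structure(list(states = states, transition = transition, counts = counts,
                 n_transitions = sum(counts)),
            class = "markov_chain")
}

#' @export
print.markov_chain <- function(x, ...) {
  cat(sprintf("<markov_chain> %d states (%s), %d pooled transitions\n",
              length(x$states), paste(x$states, collapse = ""),
              x$n_transitions))
  print(round(x$transition, 3))
  invisible(x)
}

#' @export
plot.markov_chain <- function(x, ...) {
  k <- length(x$states)
  image(seq_len(k), seq_len(k), t(x$transition[k:1, , drop = FALSE]),
        axes = FALSE, xlab = "to", ylab = "from",
        zlim = c(0, 1), ...)
  axis(1, at = seq_len(k), labels = x$states)
  axis(2, at = seq_len(k), labels = rev(x$states))
  invisible(x)
}

#' Simulate letter sequences from a Markov chain
#'
#' @param object a [fit_markov()] result (or any `markov_chain`).
#' @param nsim number of sequences.
#' @param seed optional RNG seed.
#' @param length_each length of each simulated sequence.
#' @param init initial-state distribution (default uniform over states
#'   with outgoing transitions).
#' @param ... unused.
#' @return character vector of `nsim` sequences.
#' @export
simulate.markov_chain <- function(object, nsim = 1, seed = NULL,
                                  length_each = 10L, init = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  k <- length(object$states)
  live <- rowSums(object$transition) > 0
  if (is.null(init)) init <- as.numeric(live) / sum(live)
  vapply(seq_len(nsim), function(i) {
    s <- integer(length_each)
    s[1] <- sample.int(k, 1L, prob = init)
    for (t in seq_len(length_each - 1L)) {
      p <- object$transition[s[t], ]
      if (sum(p) == 0) { s <- s[1:t]; break }  # absorbing: stop early
      s[t + 1L] <- sample.int(k, 1L, prob = p)
    }
    paste(object$states[s], collapse = "")
  }, character(1))
}

#' Prune weak transitions for graph export
#'
#' Returns the edges with probability at least `threshold`, the rule used
#' to de-clutter transition graphs (probabilities below 0.1 are
#' conventionally dropped for display).
#'
#' @param chain a [fit_markov()] result.
#' @param threshold probability cutoff in \[0, 1\] (default 0.1).
#' @return data frame with columns `source`, `target`, `probability`,
#'   suitable for graph tools.
#' @export
prune_transitions <- function(chain, threshold = 0.1) {
  stopifnot(inherits(chain, "markov_chain"))
  if (threshold < 0 || threshold > 1)
    stop("parameter error: threshold must lie in [0, 1]")
  idx <- which(chain$transition >= threshold & chain$transition > 0,
               arr.ind = TRUE)
  out <- data.frame(source = chain$states[idx[, 1]],
                    target = chain$states[idx[, 2]],
                    probability = chain$transition[idx],
                    stringsAsFactors = FALSE)
  out[order(out$source, out$target), , drop = FALSE]
}

#' Write a Markov chain to JSON / read it back
#' @param chain a [fit_markov()] result.
#' @param path file path.
#' @export
write_markov <- function(chain, path) {
  stopifnot(inherits(chain, "markov_chain"))
  jsonlite::write_json(list(states = chain$states,
                            counts = unname(chain$counts)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_markov
#' @export
read_markov <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  counts <- matrix(as.numeric(x$counts), length(x$states), length(x$states),
                   dimnames = list(x$states, x$states), byrow = FALSE)
  rs <- rowSums(counts)
  transition <- counts
  transition[rs > 0, ] <- counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(states = x$states, transition = transition, counts = counts,
                 n_transitions = sum(counts)),
            class = "markov_chain")
}
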