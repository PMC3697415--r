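#' DUPLEX train/test partitioning
#'
#' Deterministic sample-set splitting for representative training and test
#' sets: the two mutually most distant remaining samples (Euclidean distance
#' in the spectral space) are assigned to the training set, the two most
#' distant of the remainder to the test set, and the alternation repeats
#' until the test set holds `n_test` samples; everything left then joins the
#' training set. This is the simplified pair-alternation variant (Snee's
#' original switches to farthest-point assignment after the seed pairs).
#'
#' Determinism rules where the description is silent: distance ties are
#' broken by the lexicographically smallest original index pair; if a full
#' pair would overshoot the test quota, only the lower-index member is
#' assigned; a training-step pair is skipped when taking it would leave too
#' few samples to fill the test quota.
#'
#' @param data a [spectra_set()] or numeric matrix (samples in rows).
#' @param n_test requested test-set size, `0 < n_test <= n - 2`.
#' @return an object of class `"duplex_split"`: list with integer vectors
#'   `train` and `test` (assignment order), partitioning `1:n`.
#' @export
duplex_split <- function(data, n_test) {
  X <- if (inherits(data, "spectra_set")) data$x else as.matrix(data)
  n <- nrow(X)
  if (n < 4L) stop("DUPLEX needs at least 4 samples", call. = FALSE)
  if (!is.numeric(n_test) || length(n_test) != 1L || n_test != round(n_test))
    stop("n_test must be a single integer", call. = FALSE)
  n_test <- as.integer(n_test)
  if (n_test < 1L || n_test > n - 2L)
    stop("n_test must satisfy 0 < n_test <= n - 2", call. = FALSE)

  D <- as.matrix(stats::dist(X))
  rem <- seq_len(n)
  train <- integer(); test <- integer()

  farthest <- function(rem) {
    sub <- D[rem, rem, drop = FALSE]
    ut <- upper.tri(sub)
    m <- max(sub[ut])
    hits <- which(sub == m & ut, arr.ind = TRUE)
    k <- order(hits[, 1L], hits[, 2L])[1L]
    c(rem[hits[k, 1L]], rem[hits[k, 2L]])
  }

  while (length(test) < n_test) {
    need <- n_test - length(test)
    if (length(rem) >= 2L && length(rem) - 2L >= need) {
      pr <- farthest(rem)
      train <- c(train, pr)
      rem <- setdiff(rem, pr)
    }
    need <- n_test - length(test)
    if (length(rem) == 1L) {
      test <- c(test, rem)
      rem <- integer()
    } else if (need >= 2L) {
      pr <- farthest(rem)
      test <- c(test, pr)
      rem <- setdiff(rem, pr)
    } else {
      pr <- farthest(rem)
      test <- c(test, min(pr))
      rem <- setdiff(rem, min(pr))
    }
  }
  train <- c(train, rem)
  structure(list(train = train, test = test, n = n,
                 distance_metric = "euclidean"),
            class = "duplex_split")
}

#' @export
print.duplex_split <- function(x, ...) {
  cat("DUPLEX split:", length(x$train), "training /", length(x$test),
      "test samples (of", x$n, ")\n")
  invisible(x)
}
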