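# Shared fixtures. The full-design study run is cached because several files
# assert properties of the same frozen-seed run.

small_grid <- function(n = 40) wn_grid(seq(4000, 8000, length.out = n))

toy_set <- function(x, wn = NULL, meta = NULL) {
  x <- as.matrix(x)
  if (is.null(wn)) wn <- small_grid(ncol(x))
  spectra_set(x, wn, meta)
}

adult_meta <- function(ids, adulterant, level, batch = "B1") {
  data.frame(sample_id = ids, class_label = "adulterated",
             adulterant = adulterant, doping_level = level, batch = batch,
             stringsAsFactors = FALSE)
}

# reduced-size generator config for cheap tests
tiny_config <- function(seed = 1,
                        adulterant_design = data.frame(
                          adulterant = c("A1", "A1", "A2", "A3"),
                          doping_level = c(0.01, 0.08, 0.02, 0.05),
                          n = c(5, 5, 5, 5), stringsAsFactors = FALSE),
                        ...) {
  generator_config(grid = small_grid(120), seed = seed,
                   n_pure_per_batch = c(6, 7, 7),
                   adulterant_design = adulterant_design, ...)
}

study_run_7 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_study(generator_config(seed = 7))
    cache
  }
})

# brute-force DUPLEX oracle: recomputes all pairwise distances with explicit
# loops at every step; same tie-break and quota rules as the contract
duplex_oracle <- function(X, n_test) {
  X <- as.matrix(X)
  n <- nrow(X)
  dist_ij <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  farthest <- function(rem) {
    best <- NULL; bd <- -Inf
    for (a in seq_along(rem)) {
      for (b in seq_along(rem)) {
        if (a < b) {
          d <- dist_ij(rem[a], rem[b])
          if (d > bd) { bd <- d; best <- c(rem[a], rem[b]) }
        }
      }
    }
    best
  }
  rem <- seq_len(n); train <- integer(); test <- integer()
  while (length(test) < n_test) {
    need <- n_test - length(test)
    if (length(rem) >= 2L && length(rem) - 2L >= need) {
      pr <- farthest(rem); train <- c(train, pr); rem <- setdiff(rem, pr)
    }
    need <- n_test - length(test)
    if (length(rem) == 1L) {
      test <- c(test, rem); rem <- integer()
    } else if (need >= 2L) {
      pr <- farthest(rem); test <- c(test, pr); rem <- setdiff(rem, pr)
    } else {
      pr <- farthest(rem); test <- c(test, min(pr)); rem <- setdiff(rem, min(pr))
    }
  }
  list(train = c(train, rem), test = test)
}

# independent PLS1 oracle: least squares of y on the Krylov basis
# {X'y, (X'X)X'y, ...}, built with step-wise re-orthogonalisation (raw
# Krylov powers are too ill-conditioned to hold the span in doubles)
krylov_fitted <- function(X, y, a) {
  X <- as.matrix(X)
  U <- matrix(0, ncol(X), a)
  v <- crossprod(X, y)
  U[, 1] <- v / sqrt(sum(v^2))
  if (a > 1) {
    for (k in 2:a) {
      v <- crossprod(X, X %*% U[, k - 1])
      v <- v - U[, 1:(k - 1), drop = FALSE] %*%
        crossprod(U[, 1:(k - 1), drop = FALSE], v)
      v <- v - U[, 1:(k - 1), drop = FALSE] %*%
        crossprod(U[, 1:(k - 1), drop = FALSE], v)   # second pass
      U[, k] <- v / sqrt(sum(v^2))
    }
  }
  qr.fitted(qr(X %*% U), y)
}
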