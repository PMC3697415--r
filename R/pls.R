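# Uncentered NIPALS PLS1 engine.
#
# The one-class model regresses the all-ones response on the raw (uncentered)
# spectral matrix; column-centering is forbidden because it would make every
# predictor orthogonal to the constant response. Deflation of X only
# (standard PLS1); no scaling.

pls1_engine <- function(X, y, ncomp) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n, p))
    stop("n_components must lie in 1..min(n, p) = ", min(n, p), call. = FALSE)
  if (any(rowSums(abs(X)) == 0))
    stop("training matrix contains an all-zero row", call. = FALSE)
  W <- matrix(0, p, ncomp)   # weights
  P <- matrix(0, p, ncomp)   # X loadings
  q <- numeric(ncomp)        # y loadings
  Xd <- X
  scale0 <- sqrt(sum(X * X) / max(1, n * p))
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, y)
    wn <- sqrt(sum(w * w))
    # only exact degeneracy stops the extraction: once the Krylov recursion
    # has converged, later weights are tiny but their y loadings shrink in
    # step, so the coefficients stay stable
    if (!is.finite(wn) || wn == 0)
      stop("rank exhausted at component ", a,
           ": weight vector norm underflows", call. = FALSE)
    w <- w / wn
    tt <- Xd %*% w
    t2 <- sum(tt * tt)
    # scores collapse (relative to the input scale) only when the deflated
    # matrix is numerically zero, i.e. the matrix rank is truly exhausted
    if (!is.finite(t2) || t2 <= n * (1e-12 * scale0)^2)
      stop("rank exhausted at component ", a,
           ": score vector norm underflows", call. = FALSE)
    pa <- crossprod(Xd, tt) / t2
    q[a] <- sum(y * tt) / t2
    Xd <- Xd - tcrossprod(tt, pa)
    W[, a] <- w
    P[, a] <- pa
  }
  # the extraction is sequential, so the a-component coefficient vector is
  # recovered from the leading blocks: b_a = W_a (P_a' W_a)^-1 q_a
  M <- crossprod(P, W)
  B <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp))
    B[, a] <- W[, seq_len(a), drop = FALSE] %*%
      solve(M[seq_len(a), seq_len(a), drop = FALSE], q[seq_len(a)])
  list(B = B, W = W, P = P, q = q)
}

#' Fit an uncentered PLS1 regression of the ones response
#'
#' NIPALS PLS1 run without centering or scaling of either the spectral
#' matrix or the constant response, returning the coefficient vector `b`
#' such that `y_hat = X %*% b` uses exactly `n_components` latent variables.
#' With all `min(n, p)` components (full rank) the fit coincides with
#' ordinary least squares.
#'
#' @param X numeric training matrix (n samples x p wavenumbers), no all-zero
#'   rows.
#' @param n_components number of latent variables, `1..min(n, p)`.
#' @return numeric coefficient vector of length `p`.
#' @export
fit_uncentered_pls <- function(X, n_components) {
  fit <- pls1_engine(X, rep(1, nrow(as.matrix(X))), n_components)
  fit$B[, n_components]
}

#' Monte-Carlo cross-validation of the one-class PLS model
#'
#' Repeatedly holds out a uniformly random subset (size
#' `round(n * leave_out_fraction)`, at least 1), refits the uncentered PLS1
#' model on the remainder for every component count `1..max_components`, and
#' accumulates held-out prediction errors `e = 1 - y_hat`. `PRESS(a)` is the
#' sum of squared held-out errors over all repeats at component count `a`;
#' the pooled errors also provide the mean and spread estimates behind the
#' acceptance interval.
#'
#' @param X numeric training matrix.
#' @param leave_out_fraction proportion held out per repeat, in (0, 0.5);
#'   default 0.10.
#' @param n_repeats number of Monte-Carlo repeats; default 100.
#' @param max_components largest latent-variable count scanned.
#' @param seed integer seed making the resampling reproducible.
#' @return list with `press` (length `max_components`), `errors`
#'   (pooled held-out errors, one column per component count), and the
#'   settings used.
#' @export
mccv <- function(X, leave_out_fraction = 0.10, n_repeats = 100,
                 max_components = 15, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!(leave_out_fraction > 0 && leave_out_fraction < 0.5))
    stop("leave_out_fraction must lie in (0, 0.5)", call. = FALSE)
  if (n_repeats < 1L) stop("n_repeats must be >= 1", call. = FALSE)
  m <- max(1L, as.integer(round(n * leave_out_fraction)))
  if (n - m < max_components + 1L)
    stop("training remainder (", n - m, ") too small for ",
         max_components, " components", call. = FALSE)
  errors <- matrix(NA_real_, n_repeats * m, max_components)
  held <- integer(n_repeats * m)
  y1 <- rep(1, n - m)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (r in seq_len(n_repeats)) {
    out <- sample.int(n, m)
    fit <- pls1_engine(X[-out, , drop = FALSE], y1, max_components)
    pred <- X[out, , drop = FALSE] %*% fit$B      # m x A
    rows <- (r - 1L) * m + seq_len(m)
    errors[rows, ] <- 1 - pred
    held[rows] <- out
  }
  list(press = colSums(errors^2), errors = errors, held_out = held,
       leave_out_fraction = leave_out_fraction, n_repeats = n_repeats,
       leave_out_size = m, max_components = max_components, seed = seed)
}

#' Choose the latent-variable count from a PRESS curve
#'
#' Operationalises "a low PRESS value that further components cannot reduce
#' significantly" as the smallest component count whose PRESS is within a
#' relative tolerance of the curve minimum.
#'
#' @param press numeric vector of PRESS values, index = component count.
#' @param rel_tol relative tolerance to the minimum; default 0.02.
#' @return the selected component count (integer).
#' @export
select_components <- function(press, rel_tol = 0.02) {
  press <- as.numeric(press)
  if (!length(press) || any(!is.finite(press)))
    stop("press curve must be non-empty and finite", call. = FALSE)
  which(press <= (1 + rel_tol) * min(press))[1L]
}
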