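#' One-class PLS class model for authentic-sample spectra
#'
#' Fits the one-class PLS (OCPLS) model: a PLS1 regression of a constant
#' all-ones response on the *uncentered* training spectra of the target
#' class (centering would make every predictor orthogonal to the response).
#' The latent-variable count is selected from the Monte-Carlo
#' cross-validation PRESS curve, the pooled held-out errors at that count
#' give the error mean `mu_e` and spread `sigma_e`, and a new sample with
#' predicted response `y_hat` is accepted when it falls in the normal-theory
#' interval
#' \deqn{(1 - \mu_e - z_{1-\alpha/2}\,\sigma_e,\; 1 - \mu_e + z_{1-\alpha/2}\,\sigma_e).}
#'
#' @param train a [spectra_set()] of target-class (pure) samples, or a bare
#'   numeric matrix already preprocessed as intended for prediction. A
#'   spectra set containing adulterated samples is refused.
#' @param alpha significance level of the acceptance interval (default 0.05,
#'   giving `z_crit = 1.959964`).
#' @param leave_out_fraction,n_repeats MCCV settings (defaults 0.10 and 100).
#' @param max_components largest latent-variable count scanned (default 15).
#' @param rel_tol PRESS flattening tolerance for [select_components()].
#' @param n_components optional fixed latent-variable count, bypassing PRESS
#'   selection (MCCV still runs to estimate the error distribution).
#' @param seed integer seed for the MCCV resampling.
#' @return an object of class `"ocpls"`: coefficients `b`, `n_components`,
#'   error estimates `mu_e`/`sigma_e`, `alpha`, `z_crit`, the closed
#'   acceptance `interval`, the `press` curve, and fitting metadata.
#' @seealso [predict.ocpls()], [mccv()], [preprocess_spectra()]
#' @examples
#' set.seed(1)
#' X <- matrix(1 + rnorm(40 * 60, sd = 0.05), 40, 60)
#' m <- ocpls(X, max_components = 5, seed = 3)
#' print(m)
#' @export
ocpls <- function(train, alpha = 0.05, leave_out_fraction = 0.10,
                  n_repeats = 100, max_components = 15, rel_tol = 0.02,
                  n_components = NULL, seed = 1) {
  wavenumbers <- NULL
  if (inherits(train, "spectra_set")) {
    if (any(train$meta$class_label != "pure"))
      stop("training set is contaminated: only pure-class samples may be ",
           "used to train the class model", call. = FALSE)
    wavenumbers <- train$wavenumbers
    X <- train$x
  } else {
    X <- as.matrix(train)
  }
  if (!(alpha > 0 && alpha < 0.5))
    stop("alpha must lie in (0, 0.5)", call. = FALSE)
  n <- nrow(X)
  if (n < 10L)
    stop("need at least 10 training samples", call. = FALSE)
  max_components <- min(max_components, ncol(X))
  cv <- mccv(X, leave_out_fraction = leave_out_fraction,
             n_repeats = n_repeats, max_components = max_components,
             seed = seed)
  a <- if (is.null(n_components)) select_components(cv$press, rel_tol)
       else as.integer(n_components)
  if (a < 1L || a > max_components)
    stop("n_components must lie in 1..", max_components, call. = FALSE)
  e <- cv$errors[, a]
  mu_e <- mean(e)
  sigma_e <- stats::sd(e)
  if (!is.finite(sigma_e) || sigma_e <= 0)
    stop("degenerate model: MCCV error spread is zero", call. = FALSE)
  z_crit <- stats::qnorm(1 - alpha / 2)
  b <- fit_uncentered_pls(X, a)
  fitted <- as.vector(X %*% b)
  structure(list(
    b = b,
    n_components = a,
    mu_e = mu_e,
    sigma_e = sigma_e,
    alpha = alpha,
    z_crit = z_crit,
    interval = c(lower = 1 - mu_e - z_crit * sigma_e,
                 upper = 1 - mu_e + z_crit * sigma_e),
    press = cv$press,
    mccv = cv[c("leave_out_fraction", "n_repeats", "leave_out_size", "seed")],
    wavenumbers = wavenumbers,
    n_train = n,
    fitted.values = fitted,
    call = match.call()
  ), class = "ocpls")
}

#' Predict acceptance of new spectra with a fitted OCPLS model
#'
#' Computes the predicted response `y_hat = x'b` per sample, the
#' standardised distance `z_score = (y_hat - (1 - mu_e)) / sigma_e` from the
#' interval centre, and the accept/reject decision against the closed
#' acceptance interval (a sample exactly on a bound is accepted). New
#' spectra must be on the model's grid and preprocessed identically to the
#' training spectra.
#'
#' @param object a fitted [ocpls()] model.
#' @param newdata a [spectra_set()] or numeric matrix.
#' @param ... ignored.
#' @return a data.frame with one row per sample: metadata columns when
#'   available, `y_hat`, `z_score`, `accepted`.
#' @export
predict.ocpls <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    if (!is.null(object$wavenumbers))
      check_same_grid(newdata$wavenumbers, object$wavenumbers)
    X <- newdata$x
    meta <- newdata$meta
  } else {
    X <- as.matrix(newdata)
    if (nrow(X) > 0) {
      meta <- data.frame(sample_id = if (!is.null(rownames(X))) rownames(X)
                         else paste0("S", seq_len(nrow(X))),
                         stringsAsFactors = FALSE)
    } else meta <- data.frame(sample_id = character())
  }
  if (ncol(X) != length(object$b))
    stop("new spectra have ", ncol(X), " points; model expects ",
         length(object$b), call. = FALSE)
  y_hat <- as.vector(X %*% object$b)
  z <- (y_hat - (1 - object$mu_e)) / object$sigma_e
  accepted <- y_hat >= object$interval[["lower"]] &
              y_hat <= object$interval[["upper"]]
  out <- cbind(meta,
               data.frame(y_hat = y_hat, z_score = z, accepted = accepted))
  rownames(out) <- NULL
  out
}

#' @export
print.ocpls <- function(x, digits = 4, ...) {
  cat("One-class PLS model (uncentered PLS1)\n")
  cat("  training samples:", x$n_train,
      " latent variables:", x$n_components, "\n")
  cat(sprintf("  MCCV error: mu_e = %.*g, sigma_e = %.*g  (%d repeats, %d held out)\n",
              digits, x$mu_e, digits, x$sigma_e,
              x$mccv$n_repeats, x$mccv$leave_out_size))
  cat(sprintf("  acceptance interval (alpha = %g): [%.*g, %.*g]\n",
              x$alpha, digits, x$interval[["lower"]],
              digits, x$interval[["upper"]]))
  invisible(x)
}

#' @export
summary.ocpls <- function(object, ...) {
  structure(list(model = object,
                 press = object$press,
                 train_acceptance = mean(
                   object$fitted.values >= object$interval[["lower"]] &
                   object$fitted.values <= object$interval[["upper"]])),
            class = "summary.ocpls")
}

#' @export
print.summary.ocpls <- function(x, ...) {
  print(x$model)
  cat("  PRESS curve:\n")
  print(signif(x$press, 4))
  cat(sprintf("  training-set acceptance rate: %.3f\n", x$train_acceptance))
  invisible(x)
}

#' @export
coef.ocpls <- function(object, ...) object$b

#' @export
fitted.ocpls <- function(object, ...) object$fitted.values

#' @export
residuals.ocpls <- function(object, ...) 1 - object$fitted.values

#' Plot the MCCV PRESS curve of a fitted OCPLS model
#'
#' @param x a fitted [ocpls()] model.
#' @param ... passed to [plot()].
#' @export
plot.ocpls <- function(x, ...) {
  plot(seq_along(x$press), x$press, type = "b", xlab = "latent variables",
       ylab = "PRESS (MCCV)", ...)
  graphics::abline(v = x$n_components, lty = 2)
  invisible(x)
}

#' Serialise / restore an OCPLS model as JSON
#'
#' Exact reload of the fitted model (coefficients at full double precision,
#' interval, settings, MCCV seed) for provenance and reuse outside the
#' fitting session.
#'
#' @param model a fitted [ocpls()] model.
#' @param path JSON file path.
#' @return `write_ocpls_json` returns `invisible(path)`; `read_ocpls_json`
#'   the restored `"ocpls"` object.
#' @export
write_ocpls_json <- function(model, path) {
  stopifnot(inherits(model, "ocpls"))
  keep <- model[setdiff(names(model), c("call", "fitted.values"))]
  keep$wavenumbers <- as.numeric(keep$wavenumbers)
  keep$interval <- as.list(keep$interval)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ocpls_json
#' @export
read_ocpls_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$b <- as.numeric(obj$b)
  obj$press <- as.numeric(obj$press)
  obj$interval <- c(lower = as.numeric(obj$interval[["lower"]]),
                    upper = as.numeric(obj$interval[["upper"]]))
  if (!is.null(obj$wavenumbers) && length(obj$wavenumbers))
    obj$wavenumbers <- wn_grid(obj$wavenumbers)
  else obj$wavenumbers <- NULL
  obj$fitted.values <- NULL
  structure(obj, class = "ocpls")
}
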