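#' Run the full untargeted-adulteration study end to end
#'
#' One call reproducing the study workflow on synthetic (or supplied) data:
#' generate the spectra, DUPLEX-split the pure samples once on the raw
#' spectra (the split is shared by all preprocessing variants), assign every
#' adulterated sample to the test set as a negative, then for each
#' preprocessing method fit an independent OCPLS model on the preprocessed
#' training spectra and evaluate it on the preprocessed test spectra.
#'
#' @param config a [generator_config()] for the synthetic study, or a
#'   ready-made [generate_study()] result (e.g. built from files read with
#'   [read_spectra_csv()]).
#' @param methods preprocessing variants to compare, subset of
#'   `c("raw", "snv", "op")`.
#' @param n_test pure test-set size requested from [duplex_split()].
#' @param alpha significance level of the acceptance interval.
#' @param leave_out_fraction,n_repeats MCCV settings.
#' @param max_components,rel_tol latent-variable scan and PRESS tolerance.
#' @param seed master seed; independent streams for generation and MCCV are
#'   derived from it, so changing the MCCV settings does not perturb the
#'   synthetic data.
#' @return an object of class `"ocpls_study"`: per-method list of `model`,
#'   `predictions` and `report`, plus the `split`, the data, and the seed.
#' @examples
#' \donttest{
#' st <- run_study(seed = 7)
#' print(st)
#' }
#' @export
run_study <- function(config = generator_config(), methods = c("raw", "snv", "op"),
                      n_test = 20, alpha = 0.05, leave_out_fraction = 0.10,
                      n_repeats = 100, max_components = 15, rel_tol = 0.02,
                      seed = NULL) {
  if (!length(methods)) stop("need at least one preprocessing method",
                             call. = FALSE)
  methods <- match.arg(methods, c("raw", "snv", "op"), several.ok = TRUE)
  if (inherits(config, "synthetic_study") || (is.list(config) &&
      all(c("pure", "adulterated", "reference") %in% names(config)))) {
    study <- config
    if (is.null(seed)) seed <- 1L
  } else {
    stopifnot(inherits(config, "generator_config"))
    if (!is.null(seed)) config$seed <- as.integer(seed) else seed <- config$seed
    study <- generate_study(config)
  }
  mccv_seed <- stage_seeds(as.integer(seed))[4L]

  split <- duplex_split(study$pure, n_test = n_test)
  train_pure <- study$pure[split$train]
  test_all <- bind_spectra(study$pure[split$test], study$adulterated)

  per_method <- lapply(methods, function(m) {
    tr <- preprocess_spectra(train_pure, m, study$reference)
    te <- preprocess_spectra(test_all, m, study$reference)
    model <- ocpls(tr, alpha = alpha,
                   leave_out_fraction = leave_out_fraction,
                   n_repeats = n_repeats, max_components = max_components,
                   rel_tol = rel_tol, seed = mccv_seed)
    pred <- predict(model, te)
    list(model = model, predictions = pred,
         report = evaluate_predictions(pred, model, method = m))
  })
  names(per_method) <- methods
  structure(list(results = per_method, split = split, study = study,
                 seed = as.integer(seed), alpha = alpha),
            class = "ocpls_study")
}

#' @export
print.ocpls_study <- function(x, ...) {
  cat("OCPLS untargeted-adulteration study (seed", x$seed, ")\n")
  cat(sprintf("  training: %d pure   test: %d pure + %d adulterated\n\n",
              length(x$split$train), length(x$split$test),
              nrow(x$study$adulterated$x)))
  for (m in names(x$results)) {
    print(x$results[[m]]$report)
    cat("\n")
  }
  invisible(x)
}

#' Plot predicted responses of a study run
#'
#' Acceptance-interval view of one preprocessing variant: test-set predicted
#' responses against sample index, adulterated samples ordered by ascending
#' doping level within adulterant, with the acceptance bounds drawn as
#' horizontal lines.
#'
#' @param x an [run_study()] result.
#' @param method which preprocessing variant to plot.
#' @param ... passed to [plot()].
#' @export
plot.ocpls_study <- function(x, method = names(x$results)[1L], ...) {
  res <- x$results[[method]]
  pred <- res$predictions
  ord <- order(pred$class_label != "pure", pred$adulterant,
               pred$doping_level)
  pred <- pred[ord, , drop = FALSE]
  cols <- ifelse(pred$class_label == "pure", 1L,
                 match(pred$adulterant, c("A1", "A2", "A3")) + 1L)
  plot(seq_len(nrow(pred)), pred$y_hat, col = cols,
       pch = ifelse(pred$accepted, 1, 4),
       xlab = "sample (adulterated ordered by doping level)",
       ylab = "predicted response", ...)
  graphics::abline(h = res$model$interval, lty = 2)
  invisible(x)
}
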