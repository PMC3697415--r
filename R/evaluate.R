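#' Confusion counts for a one-class prediction table
#'
#' Pure samples are the positive class, adulterated samples the negative
#' class: pure & accepted = TP, pure & rejected = FN, adulterated &
#' rejected = TN, adulterated & accepted = FP.
#'
#' @param results data.frame from [predict.ocpls()] carrying `class_label`
#'   and `accepted` columns.
#' @return named integer vector `c(TP, FN, TN, FP)`.
#' @export
confusion <- function(results) {
  if (!all(c("class_label", "accepted") %in% names(results)))
    stop("results must carry class_label and accepted columns", call. = FALSE)
  pure <- results$class_label == "pure"
  acc <- results$accepted
  c(TP = sum(pure & acc), FN = sum(pure & !acc),
    TN = sum(!pure & !acc), FP = sum(!pure & acc))
}

#' Sensitivity and specificity from confusion counts
#'
#' `Sens = TP / (TP + FN)` (fraction of pure samples accepted) and
#' `Spec = TN / (TN + FP)` (fraction of adulterated samples rejected).
#'
#' @param counts named vector with `TP`, `FN`, `TN`, `FP`.
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(counts) {
  counts <- counts[c("TP", "FN", "TN", "FP")]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be nonnegative TP, FN, TN, FP", call. = FALSE)
  if (counts[["TP"]] + counts[["FN"]] == 0)
    stop("no positive (pure) samples: sensitivity undefined", call. = FALSE)
  if (counts[["TN"]] + counts[["FP"]] == 0)
    stop("no negative (adulterated) samples: specificity undefined",
         call. = FALSE)
  c(sensitivity = counts[["TP"]] / (counts[["TP"]] + counts[["FN"]]),
    specificity = counts[["TN"]] / (counts[["TN"]] + counts[["FP"]]))
}

#' Per-adulterant acceptance table and detection levels
#'
#' Tabulates accepted counts per (adulterant, doping level), levels
#' ascending, and derives each adulterant's detection level: the smallest
#' doping level from which upward no sample is accepted ("safely
#' detected"). `NA` when even the highest designed level has accepted
#' samples.
#'
#' @param results prediction data.frame with metadata columns.
#' @return list with `per_group` (data.frame `adulterant`, `doping_level`,
#'   `n`, `n_accepted`) and `detection_levels` (named numeric vector).
#' @export
group_table <- function(results) {
  adu <- results[results$class_label == "adulterated", , drop = FALSE]
  if (!nrow(adu))
    stop("no adulterated samples in results", call. = FALSE)
  key <- interaction(adu$adulterant, adu$doping_level, drop = TRUE)
  agg <- do.call(rbind, lapply(split(adu, key), function(g)
    data.frame(adulterant = g$adulterant[1L],
               doping_level = g$doping_level[1L],
               n = nrow(g), n_accepted = sum(g$accepted),
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$adulterant, agg$doping_level), , drop = FALSE]
  rownames(agg) <- NULL
  det <- vapply(split(agg, agg$adulterant), function(g) {
    g <- g[order(g$doping_level), , drop = FALSE]
    rev_accept <- rev(cumsum(rev(g$n_accepted)))  # accepted at level >= L
    ok <- which(rev_accept == 0)
    if (length(ok)) g$doping_level[ok[1L]] else NA_real_
  }, numeric(1))
  list(per_group = agg, detection_levels = det)
}

#' Evaluate OCPLS predictions on a labelled test set
#'
#' Bundles confusion counts, sensitivity/specificity, the per-adulterant
#' acceptance breakdown and detection levels, with self-consistency checks
#' (per-group counts sum to the negative margin).
#'
#' @param results prediction data.frame from [predict.ocpls()] on a
#'   [spectra_set()] with metadata.
#' @param model optional fitted [ocpls()] model, echoed in the report.
#' @param method optional preprocessing label for printing.
#' @return an object of class `"ocpls_eval"`.
#' @export
evaluate_predictions <- function(results, model = NULL, method = NULL) {
  counts <- confusion(results)
  ss <- sens_spec(counts)
  gt <- group_table(results)
  stopifnot(sum(gt$per_group$n) == counts[["TN"]] + counts[["FP"]],
            sum(gt$per_group$n_accepted) == counts[["FP"]])
  structure(list(counts = counts, sensitivity = ss[["sensitivity"]],
                 specificity = ss[["specificity"]],
                 per_group = gt$per_group,
                 detection_levels = gt$detection_levels,
                 model_summary = if (!is.null(model))
                   list(n_components = model$n_components,
                        mu_e = model$mu_e, sigma_e = model$sigma_e),
                 method = method),
            class = "ocpls_eval")
}

#' @export
print.ocpls_eval <- function(x, ...) {
  if (!is.null(x$method)) cat("Preprocessing:", x$method, "\n")
  if (!is.null(x$model_summary))
    cat(sprintf("Model: %d LVs, mu_e = %.4g, sigma_e = %.4g\n",
                x$model_summary$n_components, x$model_summary$mu_e,
                x$model_summary$sigma_e))
  cat(sprintf("Sensitivity %.3f (%d/%d)   Specificity %.3f (%d/%d)\n",
              x$sensitivity, x$counts[["TP"]],
              x$counts[["TP"]] + x$counts[["FN"]],
              x$specificity, x$counts[["TN"]],
              x$counts[["TN"]] + x$counts[["FP"]]))
  fp <- tapply(x$per_group$n_accepted, x$per_group$adulterant, sum)
  cat("Falsely accepted per adulterant:",
      paste(names(fp), fp, sep = "=", collapse = ", "), "\n")
  det <- x$detection_levels
  cat("Detection levels (w/w):",
      paste(names(det), ifelse(is.na(det), "none",
                               paste0(det * 100, "%")),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' @param report an [evaluate_predictions()] result.
#' @param path output CSV path for the per-group table; summary metrics go
#'   into comment-free leading columns repeated per row.
#' @return `invisible(path)`.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "ocpls_eval"))
  df <- report$per_group
  df$method <- if (is.null(report$method)) NA_character_ else report$method
  df$sensitivity <- report$sensitivity
  df$specificity <- report$specificity
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
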