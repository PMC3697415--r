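ADULTERANTS <- c("A0", "A1", "A2", "A3")
META_COLS <- c("sample_id", "class_label", "adulterant", "doping_level", "batch")

#' Wavenumber grid
#'
#' Construct and validate a wavenumber grid in cm^-1. Grids are stored
#' ascending; all algebra in the package assumes this single convention, and
#' readers reorder descending instrument output on the way in.
#'
#' @param values numeric vector of wavenumbers (cm^-1), strictly ascending,
#'   all positive.
#' @return a numeric vector of class `"wn_grid"`.
#' @export
wn_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values) || any(!is.finite(values)))
    stop("wavenumber grid must be non-empty and finite", call. = FALSE)
  if (any(values <= 0))
    stop("wavenumbers must be positive (cm^-1)", call. = FALSE)
  if (length(values) > 1L && any(diff(values) <= 0))
    stop("wavenumber grid must be strictly ascending with no duplicates",
         call. = FALSE)
  structure(values, class = "wn_grid")
}

#' Default study grid
#'
#' 2074 points starting at 4000 cm^-1 with a 3.857 cm^-1 interval
#' (ending near 11995.6 cm^-1), the FT-NIR diffuse-reflectance grid the
#' analysis was designed around. The point count is the operative dimension
#' for all models, so it takes precedence over a nominal 12000 cm^-1
#' endpoint (inclusive endpoints and this interval are off by one point).
#'
#' @return a [wn_grid()] of length 2074.
#' @export
default_grid <- function() {
  wn_grid(4000 + 3.857 * (0:2073))
}

validate_meta <- function(meta, n) {
  if (!is.data.frame(meta))
    stop("meta must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols))
    stop("meta lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(meta) != n)
    stop("meta has ", nrow(meta), " rows but matrix has ", n, call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  meta$class_label <- as.character(meta$class_label)
  meta$adulterant <- as.character(meta$adulterant)
  meta$batch <- as.character(meta$batch)
  meta$doping_level <- as.numeric(meta$doping_level)
  if (!all(meta$class_label %in% c("pure", "adulterated")))
    stop("class_label must be 'pure' or 'adulterated'", call. = FALSE)
  if (!all(meta$adulterant %in% ADULTERANTS))
    stop("unknown adulterant code; expected ",
         paste(ADULTERANTS, collapse = ", "), call. = FALSE)
  if (anyNA(meta$doping_level) ||
      any(meta$doping_level < 0 | meta$doping_level >= 1))
    stop("doping_level must lie in [0, 1)", call. = FALSE)
  pure <- meta$class_label == "pure"
  a0 <- meta$adulterant == "A0"
  zero <- meta$doping_level == 0
  if (!all(pure == a0) || !all(pure == zero))
    stop("metadata invariant violated: adulterant A0, class 'pure' and ",
         "doping_level 0 must coincide", call. = FALSE)
  meta
}

#' Spectra set
#'
#' The central container of the analysis: a samples-by-wavenumbers absorbance
#' matrix on a shared grid, with one metadata record per row (sample id,
#' pure/adulterated class, adulterant code A0--A3, doping level w/w, batch).
#' Pure samples are exactly those with adulterant `"A0"` and doping level 0.
#'
#' @param x numeric matrix, samples in rows, one column per grid point.
#' @param wavenumbers a [wn_grid()] (or numeric vector coerced to one) with
#'   `ncol(x)` points.
#' @param meta data.frame with columns `sample_id`, `class_label`,
#'   `adulterant`, `doping_level`, `batch`. If `NULL`, default pure metadata
#'   is attached (ids `S1..Sn`, class `"pure"`, adulterant `"A0"`, level 0).
#' @return an object of class `"spectra_set"`.
#' @export
spectra_set <- function(x, wavenumbers, meta = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  grid <- wn_grid(wavenumbers)
  if (ncol(x) != length(grid))
    stop("matrix has ", ncol(x), " columns but grid has ", length(grid),
         " points", call. = FALSE)
  if (nrow(x) > 0 && any(!is.finite(x)))
    stop("absorbance values must all be finite", call. = FALSE)
  if (is.null(meta)) {
    meta <- data.frame(
      sample_id = if (nrow(x)) paste0("S", seq_len(nrow(x))) else character(),
      class_label = rep("pure", nrow(x)),
      adulterant = rep("A0", nrow(x)),
      doping_level = rep(0, nrow(x)),
      batch = rep("B1", nrow(x)),
      stringsAsFactors = FALSE
    )
  }
  meta <- validate_meta(meta, nrow(x))
  rownames(x) <- meta$sample_id
  dimnames(x)[[2]] <- NULL
  structure(list(x = x, wavenumbers = grid, meta = meta),
            class = "spectra_set")
}

#' Reference spectrum
#'
#' A single spectrum used as a nuisance direction for orthogonal projection —
#' in this study the averaged pure-water spectrum. Must be a nonzero vector
#' on exactly the grid of the spectra it will correct.
#'
#' @param wavenumbers a [wn_grid()] or numeric vector.
#' @param absorbance numeric vector, same length as the grid.
#' @return an object of class `"ref_spectrum"`.
#' @export
reference_spectrum <- function(wavenumbers, absorbance) {
  grid <- wn_grid(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(grid))
    stop("absorbance length does not match grid", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("reference spectrum must be finite", call. = FALSE)
  structure(list(wavenumbers = grid, absorbance = absorbance),
            class = "ref_spectrum")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("Spectra set:", nrow(x$x), "samples x", length(x$wavenumbers),
      "wavenumbers\n")
  cat(sprintf("  grid: %.3f - %.3f cm^-1\n",
              min(x$wavenumbers), max(x$wavenumbers)))
  if (nrow(x$x)) {
    tab <- table(x$meta$adulterant)
    cat("  samples by adulterant:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.ref_spectrum <- function(x, ...) {
  cat("Reference spectrum:", length(x$wavenumbers), "points,",
      sprintf("norm %.4g\n", sqrt(sum(x$absorbance^2))))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$x)

#' @export
as.matrix.spectra_set <- function(x, ...) x$x

#' Subset a spectra set by sample
#'
#' @param x a [spectra_set()].
#' @param i row (sample) index.
#' @param ... ignored.
#' @return a `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$x[i, , drop = FALSE], x$wavenumbers,
              x$meta[i, , drop = FALSE])
}

#' Combine spectra sets on a common grid
#'
#' @param ... spectra sets sharing an identical wavenumber grid.
#' @return the row-concatenated `spectra_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  grid <- sets[[1L]]$wavenumbers
  for (s in sets) {
    if (!inherits(s, "spectra_set"))
      stop("bind_spectra expects spectra_set objects", call. = FALSE)
    check_same_grid(s$wavenumbers, grid)
  }
  spectra_set(do.call(rbind, lapply(sets, `[[`, "x")), grid,
              do.call(rbind, lapply(sets, `[[`, "meta")))
}

check_same_grid <- function(a, b) {
  if (length(a) != length(b) || any(a != b))
    stop("wavenumber grids do not match exactly; interpolation between ",
         "grids is not supported", call. = FALSE)
  invisible(TRUE)
}
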