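#' Write a spectra set to wide CSV
#'
#' One sample per row; the first five columns are the metadata
#' (`sample_id`, `class_label`, `adulterant`, `doping_level`, `batch`) and
#' the remaining column names are the wavenumbers. Numbers are written with
#' 17 significant digits so that [read_spectra_csv()] round-trips every
#' finite double exactly.
#'
#' @param data a [spectra_set()].
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
write_spectra_csv <- function(data, path) {
  if (!inherits(data, "spectra_set"))
    stop("data must be a spectra_set", call. = FALSE)
  header <- c(META_COLS, sprintf("%.17g", as.numeric(data$wavenumbers)))
  lines <- paste(header, collapse = ",")
  n <- nrow(data$x)
  if (n > 0) {
    num <- matrix(sprintf("%.17g", data$x), nrow = n)
    body <- paste(data$meta$sample_id, data$meta$class_label,
                  data$meta$adulterant,
                  sprintf("%.17g", data$meta$doping_level),
                  data$meta$batch,
                  apply(num, 1L, paste, collapse = ","),
                  sep = ",")
    lines <- c(lines, body)
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a spectra set from wide CSV
#'
#' Inverse of [write_spectra_csv()]. The wavenumber header must parse to a
#' strictly ascending positive grid; metadata are validated (in particular
#' the pure/A0/doping-0 equivalence). Ragged rows are a format error.
#'
#' @param path CSV file written by [write_spectra_csv()] (or following the
#'   same layout).
#' @return a [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fill = FALSE,
                    colClasses = NA, stringsAsFactors = FALSE),
    error = function(e) stop("malformed spectra CSV (", conditionMessage(e),
                             ")", call. = FALSE))
  missing_cols <- setdiff(META_COLS, names(df))
  if (length(missing_cols))
    stop("spectra CSV lacks metadata columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  wn_names <- setdiff(names(df), META_COLS)
  wn <- suppressWarnings(as.numeric(wn_names))
  if (length(wn) == 0 || anyNA(wn))
    stop("spectral column headers must be numeric wavenumbers", call. = FALSE)
  x <- as.matrix(df[, wn_names, drop = FALSE])
  spectra_set(x, wn_grid(wn), df[, META_COLS, drop = FALSE])
}

#' Read a reference spectrum from JCAMP-DX
#'
#' Minimal reader for the two plain-numeric (AFFN) JCAMP-DX data records
#' used for single spectra: `##XYDATA=(X++(Y..Y))` (equally spaced abscissa
#' reconstructed from FIRSTX/LASTX/NPOINTS with XFACTOR/YFACTOR scaling) and
#' `##XYPOINTS=(XY..XY)` (explicit pairs). Descending files are reordered to
#' the ascending package convention. Compressed ordinate forms (SQZ/DIF/DUP)
#' are not supported.
#'
#' @param path JCAMP-DX file.
#' @return a [reference_spectrum()].
#' @export
read_reference_jcampdx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\$\\$.*$", "", lines)           # strip comments
  ldr <- grepl("^##", lines)
  get_field <- function(name) {
    pat <- paste0("^##", name, "=")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(trimws(sub(pat, "", hit[1L], ignore.case = TRUE)))
  }
  split_nums <- function(txt) {
    toks <- unlist(strsplit(txt, "[,;[:space:]]+"))
    as.numeric(toks[nzchar(toks)])
  }
  block_after <- function(start) {
    stop_at <- which(ldr & seq_along(lines) > start)
    end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
    if (end < start + 1L) character() else lines[(start + 1L):end]
  }

  i_xy <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  i_pts <- grep("^##XYPOINTS=", lines, ignore.case = TRUE)
  if (length(i_xy)) {
    xfac <- get_field("XFACTOR"); if (is.na(xfac)) xfac <- 1
    yfac <- get_field("YFACTOR"); if (is.na(yfac)) yfac <- 1
    firstx <- get_field("FIRSTX")
    lastx <- get_field("LASTX")
    npts <- get_field("NPOINTS")
    body <- block_after(i_xy[1L])
    rows <- lapply(body, split_nums)
    rows <- rows[vapply(rows, length, 1L) >= 2L]
    if (!length(rows))
      stop("JCAMP-DX XYDATA record contains no data lines", call. = FALSE)
    y <- unlist(lapply(rows, function(v) v[-1L])) * yfac
    if (!is.na(npts) && length(y) != npts)
      stop("JCAMP-DX NPOINTS (", npts, ") does not match ", length(y),
           " ordinates read", call. = FALSE)
    if (is.na(firstx) || is.na(lastx)) {
      # fall back on the per-line abscissas
      firstx <- rows[[1L]][1L] * xfac
      dx <- if (length(rows) > 1L)
        (rows[[2L]][1L] * xfac - firstx) / (length(rows[[1L]]) - 1L)
      else stop("JCAMP-DX file lacks FIRSTX/LASTX and abscissa spacing ",
                "cannot be inferred", call. = FALSE)
      xs <- firstx + dx * (seq_along(y) - 1L)
    } else {
      xs <- seq(firstx * xfac, lastx * xfac, length.out = length(y))
    }
  } else if (length(i_pts)) {
    body <- block_after(i_pts[1L])
    vals <- split_nums(paste(body, collapse = " "))
    if (!length(vals))
      stop("JCAMP-DX XYPOINTS record contains no data lines", call. = FALSE)
    if (length(vals) %% 2L)
      stop("JCAMP-DX XYPOINTS record has an odd number of values",
           call. = FALSE)
    xs <- vals[c(TRUE, FALSE)]
    y <- vals[c(FALSE, TRUE)]
  } else {
    stop("no ##XYDATA or ##XYPOINTS record found in ", path, call. = FALSE)
  }
  ord <- order(xs)
  reference_spectrum(wn_grid(xs[ord]), y[ord])
}
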