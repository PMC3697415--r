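# Synthetic NIR study generator.
#
# The study's spectra were never deposited, so the package ships a generator
# that emulates their statistical structure: a water-dominated absorbance
# profile over 4000-12000 cm^-1, within-class variation of pure yogurt
# (water content, multiplicative scatter, additive baseline and slope,
# measurement noise, per-lot shifts), and additive adulterant signatures
# scaling with doping level. All spectral components are Gaussian bands in
# wavenumber: smooth, parameterisable and standard for simulated spectra.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  code
}

gaussian_bands <- function(wn, bands) {
  stopifnot(length(bands$centers) == length(bands$widths),
            length(bands$centers) == length(bands$heights))
  if (!length(bands$centers))
    stop("band list must contain at least one band", call. = FALSE)
  if (any(bands$widths <= 0))
    stop("band widths must be positive", call. = FALSE)
  out <- numeric(length(wn))
  for (k in seq_along(bands$centers))
    out <- out + bands$heights[k] *
      exp(-0.5 * ((wn - bands$centers[k]) / bands$widths[k])^2)
  out
}

#' Configuration of the synthetic NIR study generator
#'
#' Defaults reproduce the study design: three pure-yogurt lots of
#' 17 + 25 + 18 = 60 samples, and 197 adulterated samples across three
#' protein adulterants (A1 edible gelatin at 1/2/3/4/6/8 % w/w; A2
#' industrial gelatin and A3 soy protein powder at 0.5/1/2/3/5 % w/w) with
#' the per-level sample sizes of the study table. Water absorbs in the
#' classic NIR combination/overtone regions (bands near 5150, 6900 and
#' 10300 cm^-1); yogurt solids contribute weak C-H/N-H bands; each
#' adulterant carries a protein-like signature of three bands, with the A2
#' and A3 signatures weaker per unit dose than A1 so their detection limits
#' fall qualitatively in the same order as the study's. Variation magnitudes
#' are calibrated once so that raw spectra overlap heavily between classes
#' while orthogonal projection against water separates them, and are frozen
#' here.
#'
#' @param grid wavenumber grid; default [default_grid()].
#' @param seed master integer seed; per-stage streams are derived from it.
#' @param n_pure_per_batch pure sample count per production lot.
#' @param adulterant_design data.frame with columns `adulterant`,
#'   `doping_level` (w/w fraction, in \[0, 0.5\]) and `n`.
#' @param water_bands,solids_bands,adulterant_bands Gaussian band lists
#'   (`centers`, `widths` in cm^-1, `heights` in absorbance units; adulterant
#'   heights are per unit w/w dose).
#' @param variation list of spread parameters: `water_scale_sd` (relative sd
#'   of the water-direction coefficient), `mult_scatter_sd` (sd of the
#'   multiplicative scatter factor around 1), `baseline_offset_sd` (AU),
#'   `baseline_slope_sd` (AU per cm^-1), `noise_sd` (AU per point),
#'   `batch_shift_sd` (AU, one additive draw per pure lot).
#' @param makeup_water_mean,makeup_water_sd water fraction of the adulterant
#'   solution (thickness is kept roughly constant by adding water).
#' @param signature_jitter_sd lognormal sd of the per-sample signature
#'   amplitude.
#' @param n_scans,scan_noise_sd replicate count and per-scan noise of the
#'   averaged water reference measurement.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(
    grid = default_grid(),
    seed = 1,
    n_pure_per_batch = c(17, 25, 18),
    adulterant_design = default_adulterant_design(),
    water_bands = list(centers = c(5150, 6900, 10300),
                       widths  = c(220, 280, 350),
                       heights = c(1.00, 0.85, 0.30)),
    solids_bands = list(centers = c(4300, 4750, 5600, 8300),
                        widths  = c(120, 150, 200, 300),
                        heights = c(0.060, 0.050, 0.040, 0.015)),
    adulterant_bands = list(
      A1 = list(centers = c(4480, 6150, 7100),
                widths  = c(70, 90, 110),
                heights = c(1.20, 0.80, 0.60)),
      A2 = list(centers = c(4640, 5950, 7050),
                widths  = c(80, 100, 120),
                heights = c(0.27, 0.18, 0.13)),
      A3 = list(centers = c(4660, 5970, 7080),
                widths  = c(85, 105, 125),
                heights = c(0.24, 0.16, 0.11))),
    variation = list(water_scale_sd = 0.02,
                     mult_scatter_sd = 0.003,
                     baseline_offset_sd = 0.003,
                     baseline_slope_sd = 5e-7,
                     noise_sd = 0.001,
                     batch_shift_sd = 0.002),
    makeup_water_mean = 1.0,
    makeup_water_sd = 0.05,
    signature_jitter_sd = 0.10,
    n_scans = 5,
    scan_noise_sd = 5e-4) {
  grid <- wn_grid(grid)
  if (any(n_pure_per_batch < 0))
    stop("pure batch counts must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(adulterant_design),
            all(c("adulterant", "doping_level", "n") %in%
                  names(adulterant_design)))
  if (any(adulterant_design$n < 0))
    stop("design sample counts must be >= 0", call. = FALSE)
  if (any(adulterant_design$doping_level < 0 |
          adulterant_design$doping_level > 0.5))
    stop("doping levels must lie in [0, 0.5]", call. = FALSE)
  if (!all(adulterant_design$adulterant %in% names(adulterant_bands)))
    stop("every designed adulterant needs a band list", call. = FALSE)
  sds <- unlist(variation)
  if (anyNA(sds) || any(sds < 0))
    stop("variation sds must all be >= 0", call. = FALSE)
  for (b in c(list(water_bands, solids_bands), adulterant_bands))
    if (any(b$widths <= 0))
      stop("band widths must be positive", call. = FALSE)
  structure(list(grid = grid, seed = as.integer(seed),
                 n_pure_per_batch = as.integer(n_pure_per_batch),
                 adulterant_design = adulterant_design,
                 water_bands = water_bands, solids_bands = solids_bands,
                 adulterant_bands = adulterant_bands, variation = variation,
                 makeup_water_mean = makeup_water_mean,
                 makeup_water_sd = makeup_water_sd,
                 signature_jitter_sd = signature_jitter_sd,
                 n_scans = as.integer(n_scans),
                 scan_noise_sd = scan_noise_sd),
            class = "generator_config")
}

#' Study adulteration design
#'
#' The per-adulterant doping levels and sample sizes of the study design
#' (totalling 197 adulterated samples).
#'
#' @return data.frame with columns `adulterant`, `doping_level`, `n`.
#' @export
default_adulterant_design <- function() {
  data.frame(
    adulterant = c(rep("A1", 6), rep("A2", 5), rep("A3", 5)),
    doping_level = c(0.01, 0.02, 0.03, 0.04, 0.06, 0.08,
                     0.005, 0.01, 0.02, 0.03, 0.05,
                     0.005, 0.01, 0.02, 0.03, 0.05),
    n = c(12, 14, 14, 15, 15, 13,
          14, 9, 12, 13, 15,
          10, 10, 10, 10, 11),
    stringsAsFactors = FALSE
  )
}

stage_seeds <- function(seed) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
}

#' Synthetic averaged water reference spectrum
#'
#' Builds the pure-water reference as a sum of Gaussian bands at the
#' configured water band positions, then emulates the study's measurement
#' protocol by averaging `n_scans` noisy replicate scans. Deterministic
#' given the seed.
#'
#' @param grid wavenumber grid, or a full [generator_config()] whose grid
#'   and water-band settings are used.
#' @param seed integer seed (ignored when `grid` is a config, which carries
#'   its own).
#' @return a [reference_spectrum()] with positive norm.
#' @export
make_water_reference <- function(grid = default_grid(), seed = 1) {
  cfg <- if (inherits(grid, "generator_config")) grid
         else generator_config(grid = grid, seed = seed)
  wn <- as.numeric(cfg$grid)
  base <- gaussian_bands(wn, cfg$water_bands)
  sref <- stage_seeds(cfg$seed)[1L]
  scans <- with_seed(sref, {
    replicate(cfg$n_scans,
              base + stats::rnorm(length(wn), sd = cfg$scan_noise_sd))
  })
  reference_spectrum(cfg$grid, rowMeans(scans))
}

pure_style_spectrum <- function(cfg, water, solids, shift) {
  v <- cfg$variation
  wn <- as.numeric(cfg$grid)
  mid <- (min(wn) + max(wn)) / 2
  cw <- stats::rnorm(1, 1, v$water_scale_sd)
  m <- stats::rnorm(1, 1, v$mult_scatter_sd)
  b0 <- stats::rnorm(1, 0, v$baseline_offset_sd)
  b1 <- stats::rnorm(1, 0, v$baseline_slope_sd)
  eps <- stats::rnorm(length(wn), 0, v$noise_sd)
  list(x = (cw * water + solids + shift) * m + b0 + b1 * (wn - mid) + eps,
       truth = data.frame(water_coef = cw, scatter = m,
                          baseline_offset = b0, baseline_slope = b1,
                          batch_shift = shift, signature_norm = 0))
}

#' Generate synthetic pure-yogurt spectra
#'
#' Each pure spectrum is
#' `(c_w * water + solids + lot shift) * m + b0 + b1 * (nu - mid) + noise`,
#' with `c_w` the water-content coefficient, `m` a multiplicative scatter
#' factor, `b0`/`b1` additive baseline offset and slope, one additive shift
#' per production lot, and i.i.d. Gaussian measurement noise. Batch counts
#' follow the config (default 17 + 25 + 18 = 60).
#'
#' @param config a [generator_config()].
#' @return list with `data` (a [spectra_set()], all pure/A0/level 0) and
#'   `truth` (per-sample latent draws).
#' @export
generate_pure <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  water <- make_water_reference(config)$absorbance
  solids <- gaussian_bands(as.numeric(config$grid), config$solids_bands)
  spure <- stage_seeds(config$seed)[2L]
  n_tot <- sum(config$n_pure_per_batch)
  X <- matrix(0, n_tot, length(config$grid))
  truth <- vector("list", n_tot)
  batch <- character(n_tot)
  with_seed(spure, {
    i <- 0L
    for (b in seq_along(config$n_pure_per_batch)) {
      shift <- stats::rnorm(1, 0, config$variation$batch_shift_sd)
      for (k in seq_len(config$n_pure_per_batch[b])) {
        i <- i + 1L
        smp <- pure_style_spectrum(config, water, solids, shift)
        X[i, ] <- smp$x
        truth[[i]] <- smp$truth
        batch[i] <- paste0("B", b)
      }
    }
  })
  ids <- sprintf("P%03d", seq_len(n_tot))
  meta <- data.frame(sample_id = ids, class_label = "pure",
                     adulterant = "A0", doping_level = 0, batch = batch,
                     stringsAsFactors = FALSE)
  truth <- do.call(rbind, truth)
  if (is.null(truth)) truth <- data.frame()
  else truth <- cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE),
                      truth)
  list(data = spectra_set(X, config$grid, meta), truth = truth)
}

#' Generate synthetic adulterated-yogurt spectra
#'
#' Each adulterated spectrum blends a randomly chosen pure-style base
#' spectrum with an adulterant solution:
#' `(1 - L) * x_pure + L * (g * signature + w * water) + noise`,
#' where `L` is the doping level, `g` a lognormal per-sample amplitude
#' jitter of the protein signature, and `w * water` the make-up water of
#' the solution (sample thickness is kept roughly constant by adding
#' water). Counts per (adulterant, level) follow the config design
#' (197 samples under the defaults).
#'
#' @param config a [generator_config()].
#' @param pure_base a [spectra_set()] of pure spectra on the config grid,
#'   typically from [generate_pure()].
#' @return list with `data` (a [spectra_set()]) and `truth` (per-sample
#'   latent draws, including the signature contribution norm).
#' @export
generate_adulterated <- function(config, pure_base) {
  stopifnot(inherits(config, "generator_config"),
            inherits(pure_base, "spectra_set"))
  check_same_grid(pure_base$wavenumbers, config$grid)
  if (nrow(pure_base$x) < 1L)
    stop("pure_base must contain at least one spectrum", call. = FALSE)
  water <- make_water_reference(config)$absorbance
  sadu <- stage_seeds(config$seed)[3L]
  design <- config$adulterant_design
  n_tot <- sum(design$n)
  p <- length(config$grid)
  X <- matrix(0, n_tot, p)
  ids <- character(n_tot); adu <- character(n_tot)
  lev <- numeric(n_tot); batch <- character(n_tot)
  sig_norm <- numeric(n_tot); base_id <- character(n_tot)
  sigs <- lapply(config$adulterant_bands, function(b)
    gaussian_bands(as.numeric(config$grid), b))
  with_seed(sadu, {
    i <- 0L
    for (r in seq_len(nrow(design))) {
      a <- design$adulterant[r]; L <- design$doping_level[r]
      for (k in seq_len(design$n[r])) {
        i <- i + 1L
        j <- sample.int(nrow(pure_base$x), 1L)
        g <- stats::rlnorm(1, 0, config$signature_jitter_sd)
        w <- stats::rnorm(1, config$makeup_water_mean, config$makeup_water_sd)
        eps <- stats::rnorm(p, 0, config$variation$noise_sd)
        contrib <- L * g * sigs[[a]]
        X[i, ] <- (1 - L) * pure_base$x[j, ] + contrib + L * w * water + eps
        ids[i] <- sprintf("%s-L%s-%02d", a, format(L * 100), k)
        adu[i] <- a; lev[i] <- L
        batch[i] <- pure_base$meta$batch[j]
        sig_norm[i] <- sqrt(sum(contrib^2))
        base_id[i] <- pure_base$meta$sample_id[j]
      }
    }
  })
  cls <- ifelse(lev > 0, "adulterated", "pure")
  adu[lev == 0] <- "A0"   # zero-dose design rows degenerate to pure
  meta <- data.frame(sample_id = ids, class_label = cls, adulterant = adu,
                     doping_level = lev, batch = batch,
                     stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, base_sample = base_id,
                      signature_norm = sig_norm, stringsAsFactors = FALSE)
  list(data = spectra_set(X, config$grid, meta), truth = truth)
}

#' Generate the full synthetic study
#'
#' One-call composition of the water reference, the pure set and the
#' adulterated set under a single master seed (per-stage streams are
#' derived from it, so e.g. changing only the adulteration design does not
#' perturb the pure spectra). Default totals: 60 pure, 197 adulterated.
#'
#' @param config a [generator_config()].
#' @return a list of class `"synthetic_study"`: `pure` and `adulterated`
#'   [spectra_set()]s, `reference` (the water [reference_spectrum()]), and
#'   `truth` (list of per-sample latent-draw tables).
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  reference <- make_water_reference(config)
  pure <- generate_pure(config)
  adulterated <- generate_adulterated(config, pure$data)
  structure(list(pure = pure$data, adulterated = adulterated$data,
                 reference = reference,
                 truth = list(pure = pure$truth,
                              adulterated = adulterated$truth),
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic NIR adulteration study\n")
  cat("  pure samples:       ", nrow(x$pure$x), "\n")
  cat("  adulterated samples:", nrow(x$adulterated$x), "\n")
  cat("  grid:", length(x$pure$wavenumbers), "points\n")
  invisible(x)
}
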