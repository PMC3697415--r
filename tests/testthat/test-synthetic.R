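test_that("water reference is deterministic, smooth and positive-normed", {
  cfg <- tiny_config(seed = 4)
  r1 <- make_water_reference(cfg)
  r2 <- make_water_reference(cfg)
  expect_identical(r1$absorbance, r2$absorbance)
  expect_gt(sqrt(sum(r1$absorbance^2)), 0)
  expect_gt(sum(r1$absorbance * diff(c(r1$wavenumbers[1], r1$wavenumbers))), 0)
  expect_error(generator_config(water_bands = list(centers = 5000, widths = 0,
                                                   heights = 1)),
               "widths must be positive")
})

test_that("pure generator follows the batch design and its spectral model", {
  cfg <- generator_config(seed = 3, grid = small_grid(80))
  g <- generate_pure(cfg)
  expect_equal(nrow(g$data$x), 60)
  expect_equal(as.vector(table(g$data$meta$batch)), c(17, 25, 18))
  expect_true(all(g$data$meta$class_label == "pure"))
  expect_true(all(g$data$meta$adulterant == "A0"))
  expect_true(all(g$data$meta$doping_level == 0))
  expect_equal(nrow(g$truth), 60)

  # determinism
  g2 <- generate_pure(cfg)
  expect_identical(g$data$x, g2$data$x)

  # degenerate variation: identical rows within (and here, across) batches
  cfg0 <- tiny_config(seed = 9,
                      variation = list(water_scale_sd = 0, mult_scatter_sd = 0,
                                       baseline_offset_sd = 0,
                                       baseline_slope_sd = 0, noise_sd = 0,
                                       batch_shift_sd = 0))
  p0 <- generate_pure(cfg0)$data
  expect_lt(max(apply(p0$x, 2, sd)), 1e-14)
  sn <- preprocess_spectra(p0, "snv")
  expect_lt(max(apply(sn$x, 2, sd)), 1e-12)
})

test_that("adulterated generator follows the dosing design", {
  cfg <- generator_config(seed = 3, grid = small_grid(80))
  pure <- generate_pure(cfg)$data
  a <- generate_adulterated(cfg, pure)
  expect_equal(nrow(a$data$x), 197)
  des <- default_adulterant_design()
  got <- aggregate(rep(1, nrow(a$data$meta)),
                   list(adulterant = a$data$meta$adulterant,
                        doping_level = a$data$meta$doping_level), sum)
  got <- got[order(got$adulterant, got$doping_level), ]
  des <- des[order(des$adulterant, des$doping_level), ]
  expect_equal(got$x, des$n)
  expect_true(all(a$data$meta$class_label == "adulterated"))

  # signature contribution norm grows with dose (A1: 8% vs 1%)
  m <- a$data$meta
  expect_gt(mean(a$truth$signature_norm[m$adulterant == "A1" &
                                          m$doping_level == 0.08]),
            mean(a$truth$signature_norm[m$adulterant == "A1" &
                                          m$doping_level == 0.01]))

  # grid mismatch is refused
  other <- spectra_set(pure$x[, 1:40], small_grid(40),
                       pure$meta)
  expect_error(generate_adulterated(cfg, other), "do not match")
})

test_that("zero-dose design rows degenerate to pure-style samples", {
  cfg <- tiny_config(seed = 5,
                     adulterant_design = data.frame(
                       adulterant = "A1", doping_level = 0, n = 4))
  pure <- generate_pure(cfg)$data
  a <- generate_adulterated(cfg, pure)
  expect_true(all(a$data$meta$class_label == "pure"))
  expect_true(all(a$truth$signature_norm == 0))
  # spectrum equals its pure base up to fresh measurement noise
  base <- pure$x[match(a$truth$base_sample, pure$meta$sample_id), ,
                 drop = FALSE]
  expect_lt(max(abs(a$data$x - base)),
            6 * cfg$variation$noise_sd)
})

test_that("signature orthogonal component grows strictly with dose (no noise)", {
  cfg <- generator_config(
    seed = 6, grid = small_grid(100),
    n_pure_per_batch = c(4, 4, 4),
    adulterant_design = data.frame(
      adulterant = rep(c("A1", "A2", "A3"), each = 4),
      doping_level = rep(c(0.005, 0.01, 0.03, 0.08), 3),
      n = rep(6, 12)),
    variation = list(water_scale_sd = 0, mult_scatter_sd = 0,
                     baseline_offset_sd = 0, baseline_slope_sd = 0,
                     noise_sd = 0, batch_shift_sd = 0),
    signature_jitter_sd = 0.05, scan_noise_sd = 0)
  st <- generate_study(cfg)
  ref <- st$reference
  opn <- apply(preprocess_spectra(st$adulterated, "op", ref)$x, 1,
               function(r) sqrt(sum(r^2)))
  base_op <- sqrt(sum(op_project(st$pure$x[1, ], ref$absorbance)^2))
  excess <- abs(opn - base_op)
  m <- st$adulterated$meta
  for (a in c("A1", "A2", "A3")) {
    lv <- sort(unique(m$doping_level[m$adulterant == a]))
    mu <- vapply(lv, function(L)
      mean(excess[m$adulterant == a & m$doping_level == L]), numeric(1))
    expect_true(all(diff(mu) > 0))
  }
})

test_that("study composition matches the design totals and is seed-stable", {
  st <- study_run_7()$study
  expect_equal(nrow(st$pure$x), 60)
  expect_equal(nrow(st$adulterated$x), 197)
  expect_equal(sum(default_adulterant_design()$n), 197)
  expect_equal(sum(generator_config()$n_pure_per_batch), 60)

  # different seed: same shapes, different values
  st2 <- generate_study(generator_config(seed = 8, grid = small_grid(60)))
  expect_equal(dim(st2$pure$x), c(60L, 60L))
  st3 <- generate_study(generator_config(seed = 9, grid = small_grid(60)))
  expect_false(identical(st2$pure$x, st3$pure$x))

  # every generated set passes CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(st2$adulterated, f)
  expect_identical(read_spectra_csv(f)$x, st2$adulterated$x)
})
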