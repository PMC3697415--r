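test_that("uncentered PLS1 matches the Krylov least-squares oracle", {
  set.seed(14)
  y1 <- rep(1, 8)
  for (rep in 1:8) {
    X <- matrix(rnorm(40, mean = rep), 8, 5)
    for (a in 1:5) {
      b <- fit_uncentered_pls(X, a)
      expect_equal(as.vector(X %*% b), as.vector(krylov_fitted(X, y1, a)),
                   tolerance = 1e-8)
    }
  }
})

test_that("full-component PLS equals the ordinary least-squares fit", {
  set.seed(15)
  X <- matrix(rnorm(40, mean = 1), 8, 5)
  b <- fit_uncentered_pls(X, 5)
  expect_equal(as.vector(X %*% b),
               as.vector(qr.fitted(qr(X), rep(1, 8))), tolerance = 1e-8)
})

test_that("a ones column in X is captured by the first latent variable", {
  set.seed(16)
  X <- cbind(1, matrix(rnorm(30, sd = 0.1), 10, 3))
  X[, 2:4] <- X[, 2:4] - outer(rep(1, 10), colMeans(X[, 2:4]))  # orthogonal noise
  b <- fit_uncentered_pls(X, 1)
  expect_equal(as.vector(X %*% b), rep(1, 10), tolerance = 1e-2)
})

test_that("column-centering makes predictors orthogonal to the ones response", {
  # the regression against silent centering: a centered fit can only return
  # coefficients whose predictions vanish
  set.seed(17)
  X <- matrix(rnorm(60, mean = 2), 12, 5)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  b <- fit_uncentered_pls(Xc, 2)
  expect_lt(max(abs(Xc %*% b)), 1e-8)
})

test_that("rank exhaustion on an exactly rank-deficient matrix is reported", {
  X <- outer(c(1, 2, 3, 4), c(1, 0.5, 2))   # rank 1, no noise
  expect_error(fit_uncentered_pls(X, 2), "component 2")
  expect_error(fit_uncentered_pls(rbind(c(0, 0), c(1, 1)), 1), "all-zero row")
})

test_that("MCCV accumulates the designed number of held-out errors", {
  set.seed(18)
  X <- matrix(rnorm(40 * 30, mean = 1), 40, 30)
  cv <- mccv(X, leave_out_fraction = 0.10, n_repeats = 100,
             max_components = 5, seed = 2)
  expect_equal(cv$leave_out_size, 4)
  expect_equal(nrow(cv$errors), 400)
  expect_equal(cv$press, colSums(cv$errors^2))
  # determinism under the seed
  cv2 <- mccv(X, leave_out_fraction = 0.10, n_repeats = 100,
              max_components = 5, seed = 2)
  expect_identical(cv$press, cv2$press)
  expect_false(identical(
    cv$press, mccv(X, max_components = 5, seed = 3)$press))
})

test_that("MCCV PRESS vanishes for noiseless single-factor data", {
  p <- rnorm(20)
  X <- outer(rep(2, 12), p)   # constant score: response exactly recoverable
  cv <- mccv(X, leave_out_fraction = 0.1, n_repeats = 20,
             max_components = 1, seed = 1)
  expect_lt(cv$press[1], 1e-20)
})

test_that("MCCV validates its configuration", {
  X <- matrix(rnorm(100), 10, 10)
  expect_error(mccv(X, leave_out_fraction = 0.6), "leave_out_fraction")
  expect_error(mccv(X, max_components = 12), "too small")
})

test_that("component selection implements the PRESS-flattening rule", {
  expect_equal(select_components(c(100, 50, 20, 10, 5.0, 4.99, 4.98)), 5L)
  expect_equal(select_components(c(3, 4, 5)), 1L)
  expect_equal(select_components(rep(2, 6)), 1L)
  expect_equal(select_components(c(10, 1, 0.9), rel_tol = 0.2), 2L)
  expect_error(select_components(numeric()), "non-empty")
  expect_error(select_components(c(1, Inf)), "finite")
})

test_that("the fitted model satisfies the acceptance-interval algebra", {
  set.seed(19)
  X <- matrix(1 + rnorm(40 * 50, sd = 0.03), 40, 50)
  m <- ocpls(X, alpha = 0.05, max_components = 8, seed = 4)
  expect_equal(m$z_crit, 1.959964, tolerance = 1e-6)
  expect_equal(unname(diff(m$interval)), 2 * m$z_crit * m$sigma_e)
  expect_equal(m$interval[["lower"]], 1 - m$mu_e - m$z_crit * m$sigma_e)
  expect_equal(m$interval[["upper"]], 1 - m$mu_e + m$z_crit * m$sigma_e)
  expect_gt(m$sigma_e, 0)
  expect_length(coef(m), 50)
  expect_equal(residuals(m), 1 - fitted(m))

  # a contaminated training set is refused
  st <- tiny_config(seed = 1)
  study <- generate_study(st)
  both <- bind_spectra(study$pure, study$adulterated)
  expect_error(ocpls(both), "contaminated")
  # degenerate spread is refused
  expect_error(ocpls(matrix(1, 20, 5), max_components = 1, seed = 1),
               "degenerate")
})

test_that("prediction standardises distances and respects the closed interval", {
  model <- structure(list(
    b = c(1, 0), mu_e = 0.01, sigma_e = 0.005, alpha = 0.05,
    z_crit = qnorm(0.975),
    interval = c(lower = 0.99 - qnorm(0.975) * 0.005,
                 upper = 0.99 + qnorm(0.975) * 0.005),
    wavenumbers = NULL), class = "ocpls")
  X <- rbind(centre = c(0.99, 5),
             upper  = c(model$interval[["upper"]], 0),
             out    = c(1.2, 0))
  pr <- predict(model, X)
  expect_equal(pr$z_score[1], 0)
  expect_true(pr$accepted[1])
  expect_true(pr$accepted[2])            # boundary is accepted (closed)
  expect_equal(pr$z_score[2], model$z_crit)
  expect_false(pr$accepted[3])
  expect_equal(pr$accepted, abs(pr$z_score) <= model$z_crit + 1e-9)

  # acceptance is invariant to sample order
  perm <- c(3, 1, 2)
  pr2 <- predict(model, X[perm, ])
  expect_equal(pr2$accepted, pr$accepted[perm])
  expect_error(predict(model, matrix(1, 1, 3)), "model expects")
})

test_that("JSON serialisation reloads a model that predicts identically", {
  set.seed(20)
  X <- matrix(1 + rnorm(30 * 20, sd = 0.05), 30, 20)
  m <- ocpls(X, max_components = 5, seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_ocpls_json(m, f)
  m2 <- read_ocpls_json(f)
  Xn <- matrix(1 + rnorm(5 * 20, sd = 0.05), 5, 20)
  expect_equal(predict(m2, Xn)$y_hat, predict(m, Xn)$y_hat)
  expect_equal(m2$interval, m$interval)
})

test_that("false-rejection rate of in-class samples is near the nominal level", {
  # pooled over a few replicates of the synthetic study at alpha = 0.05;
  # the band reflects replicate-to-replicate model variability
  rej <- vapply(1:4, function(r) {
    cfg <- generator_config(seed = 200 + r, grid = small_grid(150),
                            n_pure_per_batch = c(47, 47, 46))
    pure <- generate_pure(cfg)$data
    ref <- make_water_reference(cfg)
    set.seed(300 + r)
    idx <- sample.int(140, 40)
    tr <- preprocess_spectra(pure[idx], "op", ref)
    te <- preprocess_spectra(pure[-idx], "op", ref)
    m <- ocpls(tr, alpha = 0.05, seed = 400 + r)
    mean(!predict(m, te)$accepted)
  }, numeric(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.12)
})
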