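test_that("synthetic trajectories are reproducible with the right noise", {
  p <- opt_params()
  tt <- default_times(120)
  clean <- synth_trajectory(p, glucose_level(0), tt, noise_model(1e-15), 1)
  expect_equal(clean$values, signal_0d(p, glucose_level(0), tt)$values,
               tolerance = 1e-10)
  a <- synth_trajectory(p, mgdl_to_mM(100), tt, seed = 42)
  b <- synth_trajectory(p, mgdl_to_mM(100), tt, seed = 42)
  expect_identical(a$values, b$values)
  # residual mean over many draws vanishes within 3 standard errors
  resid <- unlist(lapply(1:100, function(s) {
    synth_trajectory(p, mgdl_to_mM(100), seq(0, 100, by = 1),
                     noise_model(0.02), seed = s)$values -
      signal_0d(p, mgdl_to_mM(100), seq(0, 100, by = 1))$values
  }))
  expect_lt(abs(mean(resid)), 3 * 0.02 / sqrt(length(resid)))
})

test_that("basal fit inverts the decay exactly in the noiseless limit", {
  p <- opt_params()
  tt <- seq(0, 480, by = 8)
  clean <- signal_0d(p, glucose_level(0), tt)
  fit <- fit_basal(clean, beta_fixed = 1.5)
  expect_equal(fit$k0_hat, p$k0, tolerance = 1e-10)
  expect_equal(fit$method, "loglinear")
  expect_error(fit_basal(trajectory(c(0, 1), c(1, 0.9))), "at least 3")
})

test_that("joint basal fit pins the rate product and reports the ridge", {
  p <- opt_params()
  tt <- seq(0, 480, by = 8)
  clean <- signal_0d(p, glucose_level(0), tt)
  fit <- fit_basal(clean, beta_fixed = NULL)
  # beta and k0 enter only through their product: only that is determined
  expect_equal(fit$rate_hat, p$beta * p$k0, tolerance = 1e-6)
  expect_equal(fit$method, "joint_ridge")
  expect_true(is.na(fit$correlation) || abs(fit$correlation) > 0.99)
  noisy <- synth_trajectory(p, glucose_level(0), tt, noise_model(0.02), 1)
  fit_n <- fit_basal(noisy)
  expect_gt(abs(fit_n$correlation), 0.99)
})

test_that("basal rate recovery stays within 5% under 2% noise", {
  p <- opt_params()
  tt <- seq(0, 480, length.out = 60)  # one basal half-life, 60 points
  rel_err <- vapply(1:200, function(s) {
    noisy <- synth_trajectory(p, glucose_level(0), tt, noise_model(0.02), s)
    abs(fit_basal(noisy, beta_fixed = 1.5)$k0_hat / p$k0 - 1)
  }, 0)
  expect_lt(median(rel_err), 0.05)
})

test_that("reference fit recovers the glucose coupling", {
  p <- opt_params()
  G_ref <- mgdl_to_mM(200)
  tt <- seq(0, 120, by = 2)
  clean <- signal_0d(p, G_ref, tt)
  fit <- fit_reference(clean, G_ref, p$k0, 1.5)
  expect_equal(fit$kG_hat, p$kG, tolerance = 1e-10)
  expect_true(fit$responsive)
  # the closed-form identity: (ln2/30 - ln2/480) / 11.101 mM
  expect_equal(fit$kG_hat, 1.951e-3, tolerance = 1e-3)
  # non-responsive sensor (decay no faster than basal) warns
  flat_traj <- trajectory(tt, exp(-1.5 * 0.999 * p$k0 * tt))
  expect_warning(f0 <- fit_reference(flat_traj, G_ref, p$k0, 1.5),
                 "non-responsive")
  expect_lte(f0$kG_hat, 0)
})

test_that("quadratic refinement captures saturating glucose response", {
  p <- opt_params()
  tt <- seq(0, 120, by = 2)
  # decay rates saturating in G: k = k0 + kG G - c G^2
  G_mM <- c(3, 6, 12)
  kG2_true <- -4e-5
  trajs <- lapply(G_mM, function(g) {
    k <- p$k0 + p$kG * g + kG2_true * g^2
    trajectory(tt, exp(-p$beta * k * tt))
  })
  fit <- fit_reference(trajs, G_mM, p$k0, p$beta, quadratic = TRUE)
  expect_equal(fit$kG_hat, p$kG, tolerance = 1e-6)
  expect_equal(fit$kG2_hat, kG2_true, tolerance = 1e-6)
  expect_error(fit_reference(trajs[1:2], G_mM[1:2], p$k0, p$beta,
                             quadratic = TRUE), ">= 3")
})

test_that("full pipeline inverts the half-life parameterisation", {
  p <- opt_params()
  tt <- seq(0, 480, by = 5)
  basal <- synth_trajectory(p, glucose_level(0), tt, noise_model(1e-15), 1)
  ref <- synth_trajectory(p, mgdl_to_mM(200), seq(0, 120, by = 2),
                          noise_model(1e-15), 2)
  res <- calibrate_sensor(basal, ref, mgdl_to_mM(200), beta_fixed = 1.5)
  expect_equal(res$k0_hat, log(2) / 480, tolerance = 1e-8)
  expect_equal(res$kG_hat, p$kG, tolerance = 1e-8)
  expect_equal(half_life(res$params, glucose_level(0)), 480, tolerance = 1e-6)
  expect_equal(half_life(res$params, mgdl_to_mM(200)), 30, tolerance = 1e-6)
})

test_that("parameter recovery is accurate and unbiased across 200 datasets", {
  p <- opt_params()
  tt_basal <- seq(0, 480, length.out = 60)
  tt_ref <- seq(0, 90, length.out = 45)
  ests <- t(vapply(1:200, function(s) {
    basal <- synth_trajectory(p, glucose_level(0), tt_basal,
                              noise_model(0.02), 2 * s)
    ref <- synth_trajectory(p, mgdl_to_mM(200), tt_ref,
                            noise_model(0.02), 2 * s + 1)
    res <- calibrate_sensor(basal, ref, mgdl_to_mM(200), beta_fixed = 1.5)
    c(res$k0_hat, res$kG_hat)
  }, c(0, 0)))
  rel_k0 <- abs(ests[, 1] / p$k0 - 1)
  rel_kG <- abs(ests[, 2] / p$kG - 1)
  expect_lt(median(rel_k0), 0.10)
  expect_lt(median(rel_kG), 0.10)
  # unbiased within 3 standard errors of the estimate means
  expect_lt(abs(mean(ests[, 1]) - p$k0), 3 * sd(ests[, 1]) / sqrt(200))
  expect_lt(abs(mean(ests[, 2]) - p$kG), 3 * sd(ests[, 2]) / sqrt(200))
})

test_that("held-out validation sits at the noise floor and flags mismatch", {
  p <- opt_params()
  tt <- seq(0, 90, length.out = 45)
  basal <- signal_0d(p, glucose_level(0), seq(0, 480, by = 8))
  ref <- signal_0d(p, mgdl_to_mM(200), tt)
  res <- calibrate_sensor(basal, ref, mgdl_to_mM(200), beta_fixed = 1.5)
  # noiseless held-out data from the fitted model: essentially zero misfit
  held0 <- list(list(G = 140, traj = signal_0d(p, mgdl_to_mM(140), tt)))
  v0 <- validate_calibration(res, held0)
  expect_lt(v0$rms, 1e-8)
  expect_false(v0$flagged)
  # noisy held-out data: RMS near sigma_S
  heldn <- list(list(G = 140,
                     traj = synth_trajectory(p, mgdl_to_mM(140), tt,
                                             noise_model(0.02), 77)))
  vn <- validate_calibration(res, heldn)
  expect_equal(vn$rms, 0.02, tolerance = 0.2)
  expect_false(vn$flagged)
  # strongly saturating truth against the linear calibration: flagged
  k_sat <- res$params$k0 + res$params$kG * 11.101 * 0.45  # compressed response
  mis <- trajectory(tt, exp(-res$params$beta * k_sat * tt))
  vm <- validate_calibration(res, list(list(G = 200, traj = mis)))
  expect_true(vm$flagged)
  expect_error(validate_calibration(res, list()), "length")
})
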