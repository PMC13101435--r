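test_that("Michaelis-Menten production saturates and linearises", {
  enz <- enzyme_params()
  expect_equal(mm_rate(enz, glucose_level(8.8)), enz$Vmax / 2)
  expect_equal(mm_rate(enz, glucose_level(1e9)), enz$Vmax, tolerance = 1e-7)
  G <- enz$KM / 100
  expect_equal(mm_rate(enz, glucose_level(G)), enz$Vmax / enz$KM * G,
               tolerance = 0.01)
  g <- seq(0, 50, by = 1)
  v <- mm_rate(enz, g)
  expect_true(all(diff(v) > 0))          # strictly increasing
  expect_true(all(diff(diff(v)) < 0))    # concave
})

test_that("surface peroxide matches an independent ODE solve", {
  enz <- enzyme_params(k_cons = 0.02)
  G <- mgdl_to_mM(200)
  tt <- default_times(120)
  Hs <- surface_peroxide(enz, G, tt)
  v <- mm_rate(enz, G)
  sol <- deSolve::ode(c(H = 0), tt,
                      function(t, y, p) list(v - enz$k_cons * y),
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(Hs$values, unname(sol[, "H"]), tolerance = 1e-7)
  expect_true(all(diff(Hs$values) > 0))
  expect_equal(tail(Hs$values, 1), v / enz$k_cons, tolerance = 0.1)
  # no substrate, no peroxide; no consumption, linear accumulation
  expect_equal(surface_peroxide(enz, glucose_level(0), tt)$values,
               rep(0, length(tt)))
  enz0 <- enzyme_params(k_cons = 0)
  expect_equal(surface_peroxide(enz0, G, tt)$values, mm_rate(enz0, G) * tt)
})

test_that("transient rate builds from the basal rate to the plateau", {
  kin <- opt_params()
  enz <- anchored_enzyme(kin)
  G <- mgdl_to_mM(200)
  prof <- transient_rate(enz, kin, G, default_times(600))
  expect_equal(prof$k_values[1], kin$k0)
  expect_true(all(diff(prof$k_values) > 0))
  plateau <- kin$k0 + enz$alpha_H * mm_rate(enz, G) / enz$k_cons
  expect_equal(tail(prof$k_values, 1), plateau, tolerance = 1e-5)
  # alpha_H = 0 leaves the rate constant
  enz0 <- enzyme_params(alpha_H = 0)
  prof0 <- transient_rate(enz0, kin, G, default_times(60))
  expect_equal(prof0$k_values, rep(kin$k0, length(prof0$times)))
})

test_that("alpha_H anchoring hits the reference rate at steady state", {
  kin <- opt_params()
  enz <- enzyme_params(k_cons = 0.02)
  aH <- calibrate_alpha_H(enz, kin, target_spec())
  plateau <- kin$k0 + aH * mm_rate(enz, target_spec()$G_ref) / enz$k_cons
  expect_equal(plateau, log(2) / 30, tolerance = 1e-12)
  # proportionality in k_cons
  enz2 <- enzyme_params(k_cons = 0.04)
  expect_equal(calibrate_alpha_H(enz2, kin, target_spec()), 2 * aH)
  # saturated reference level: alpha_H -> (k_ref - k0) k_cons / Vmax
  enz_sat <- enzyme_params(KM = 1e-6, k_cons = 0.02)
  expect_equal(calibrate_alpha_H(enz_sat, kin, target_spec()),
               (log(2) / 30 - kin$k0) * enz_sat$k_cons / enz_sat$Vmax,
               tolerance = 1e-6)
  expect_error(calibrate_alpha_H(enzyme_params(k_cons = 0), kin, target_spec()),
               "k_cons > 0")
})

test_that("exposure matching equalises the end-point exactly", {
  kin <- opt_params()
  enz <- anchored_enzyme(kin)
  G <- mgdl_to_mM(200)
  tt <- default_times(120)
  k_const <- k_deg(kin, G)
  prof <- transient_rate(enz, kin, G, tt)
  matched <- exposure_match(prof, k_const, 120)
  # integral identity by construction (same trapezoid rule)
  expo <- perosense:::cumulative_exposure(matched$times, matched$k_values)
  expect_equal(exp(-tail(expo, 1)), exp(-k_const * 120), tolerance = 1e-13)
  # matched rate starts below k_const and crosses it at an interior time
  expect_lt(matched$k_values[1], k_const)
  expect_gt(tail(matched$k_values, 1), k_const)
  crossings <- which(diff(sign(matched$k_values - k_const)) != 0)
  expect_true(length(crossings) >= 1 &&
              tt[crossings[1]] > 0 && tt[crossings[1]] < 120)
  # constant profile at k_const is left untouched (lambda = 1)
  const_prof <- rate_profile(tt, rep(k_const, length(tt)), k0 = kin$k0)
  same <- exposure_match(const_prof, k_const, 120)
  expect_equal(attr(same, "lambda"), 1, tolerance = 1e-12)
  expect_equal(same$k_values, const_prof$k_values)
  # total-scaling alternative also matches the integral
  m2 <- exposure_match(prof, k_const, 120, scale_total = TRUE)
  expect_equal(perosense:::rate_exposure(m2, 120), k_const * 120,
               tolerance = 1e-12)
})

test_that("GOx integration reduces to the constant-k model without coupling", {
  kin <- opt_params()
  enz0 <- enzyme_params(alpha_H = 0)
  G <- mgdl_to_mM(200)
  tt <- default_times(120)
  base <- trajectory(tt, exp(-kin$beta * kin$k0 * tt))
  for (m in c("quadrature", "ode")) {
    s <- integrate_gox_signal(enz0, kin, G, tt, method = m)
    expect_equal(s$values, base$values, tolerance = 1e-6)
  }
})

test_that("quadrature and ODE routes agree as mutual oracles", {
  kin <- opt_params()
  enz <- anchored_enzyme(kin)
  for (G in c(70, 140, 300)) {
    tt <- default_times(120)
    sq <- integrate_gox_signal(enz, kin, mgdl_to_mM(G), tt, "quadrature")
    so <- integrate_gox_signal(enz, kin, mgdl_to_mM(G), tt, "ode")
    expect_lt(max(abs(sq$values - so$values)), 1e-5)
  }
})

test_that("GOx signal lags the constant-k surrogate before and after matching", {
  kin <- opt_params()
  enz <- anchored_enzyme(kin)
  cmp <- gox_compare(enz, kin, mgdl_to_mM(200))
  early <- cmp$S_const$times > 0 & cmp$S_const$times <= 20
  expect_true(all(cmp$S_gox_raw$values[early] > cmp$S_const$values[early]))
  expect_true(all(cmp$S_gox_matched$values[early] > cmp$S_const$values[early]))
  # end-point signals near-identical, transient RMS difference nonzero
  expect_lt(abs(tail(cmp$S_gox_matched$values, 1) / tail(cmp$S_const$values, 1) - 1),
            1e-8)
  rms <- sqrt(mean((cmp$S_gox_matched$values - cmp$S_const$values)^2))
  expect_gt(rms, 1e-4)
  # signal bounded and non-increasing
  expect_true(all(diff(cmp$S_gox_raw$values) < 0))
  expect_true(all(cmp$S_gox_raw$values > 0 & cmp$S_gox_raw$values <= kin$S0))
})

test_that("fast peroxide turnover recovers the constant-k limit", {
  kin <- opt_params()
  G <- mgdl_to_mM(200)
  tt <- default_times(120)
  target <- signal_0d(kin, G, tt)
  sup <- vapply(c(0.1, 1, 10), function(kc) {
    enz <- enzyme_params(k_cons = kc)
    enz$alpha_H <- calibrate_alpha_H(enz, kin, target_spec())
    s <- integrate_gox_signal(enz, kin, G, tt)
    max(abs(s$values - target$values))
  }, 0)
  expect_true(all(diff(sup) < 0))
  expect_lt(sup[3], 5e-3)
})
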