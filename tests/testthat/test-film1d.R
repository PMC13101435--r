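test_that("CFL-stable step follows dx^2/(2 D_H) with the safety factor", {
  cfg <- film_config(L = 200e-9, Nx = 101, D_H = 1e-18, safety = 0.5)
  expect_equal(stable_dt(cfg), 1.0)  # 0.5 * (2e-9)^2 / (2e-18) by hand
  cfg2 <- film_config(L = 200e-9, Nx = 101, D_H = 2e-18, safety = 0.5)
  expect_equal(stable_dt(cfg2), 0.5)
  cfg3 <- film_config(L = 200e-9, Nx = 101, D_H = 1e-18, safety = 1)
  expect_equal(stable_dt(cfg3), 2.0)
  expect_equal(stable_dt(cfg, output_interval_s = 0.25), 0.25)
})

test_that("single peroxide steps behave at equilibria and decoupled limits", {
  cfg <- film_config(Nx = 11, k_cons = 0)
  st <- film_state(cfg)
  st$H <- rep(0.3, 11)
  st2 <- step_peroxide(st, 0.3, cfg, stable_dt(cfg))
  expect_equal(st2$H, rep(0.3, 11))
  # vanishing diffusion: pure exponential consumption per node
  cfg_d <- film_config(Nx = 11, D_H = 1e-30, k_cons = 0.06)
  st$H <- seq(0.1, 1, length.out = 11)
  dt <- 1  # seconds
  st3 <- step_peroxide(st, st$H[1], cfg_d, dt)
  expect_equal(st3$H[-1], st$H[-1] * (1 - cfg_d$k_cons * dt / 60),
               tolerance = 1e-9)
  # unstable step is rejected with a diagnostic
  cfg_u <- film_config(Nx = 101)
  stu <- film_state(cfg_u)
  stu$H <- c(1, rep(0, 99), 1)
  expect_error(step_peroxide(stu, 1, cfg_u, 50 * stable_dt(cfg_u)),
               "stability")
})

test_that("integrity update is the exact exponential and tracks peroxide", {
  cfg <- film_config(Nx = 21, alpha_H = 0.01)
  kin <- opt_params()
  st <- film_state(cfg)
  st$H <- seq(1, 0, length.out = 21)  # more peroxide at the surface
  dt <- 30
  st2 <- update_integrity(st, cfg, kin, dt)
  expect_equal(st2$C, exp(-(kin$k0 + 0.01 * st$H) * dt / 60))
  expect_true(all(diff(st2$C) > 0))  # surface degrades fastest
  cfg0 <- film_config(Nx = 21, alpha_H = 0)
  st3 <- update_integrity(film_state(cfg0), cfg0, kin, 60)
  expect_equal(st3$C, rep(exp(-kin$k0), 21))
})

test_that("R step functions and the compiled kernel implement one scheme", {
  cfg <- film_config(Nx = 41, k_cons = 0.02, alpha_H = 0.01)
  kin <- opt_params()
  dt <- stable_dt(cfg)
  st <- film_state(cfg)
  Hs <- seq(0.01, 0.1, length.out = 25)
  for (s in seq_along(Hs)) {
    st <- step_peroxide(st, Hs[s], cfg, dt)
    st <- update_integrity(st, cfg, kin, dt)
  }
  ker <- perosense:::film_advance(rep(0, 41), rep(1, 41), Hs, dt / 60,
                                  cfg$L / 40, cfg$D_H * 60, cfg$k_cons,
                                  kin$k0, cfg$alpha_H)
  expect_equal(st$H, ker$H, tolerance = 1e-13)
  expect_equal(st$C, ker$C, tolerance = 1e-13)
})

test_that("repeated stepping reaches the analytic cosh steady profile", {
  cfg <- film_config(L = 200e-9, Nx = 201, D_H = 1e-18, k_cons = 0.02)
  kin <- opt_params()
  dt <- stable_dt(cfg)
  n <- ceiling(450 * 60 / dt)  # ~9 consumption time constants
  r <- perosense:::film_advance(rep(0, 201), rep(1, 201), rep(0.5, n),
                                dt / 60, cfg$L / 200, cfg$D_H * 60,
                                cfg$k_cons, kin$k0, 0)
  exact <- steady_peroxide_profile(cfg, 0.5)
  expect_lt(max(abs(r$H - exact) / exact), 0.01)
})

test_that("film reduces to the homogeneous basal decay without coupling", {
  cfg <- film_config(Nx = 31, alpha_H = 0)
  kin <- opt_params()
  res <- simulate_film(cfg, enzyme_params(), kin, mgdl_to_mM(200), T_min = 60)
  expect_equal(res$mean_signal, exp(-kin$beta * kin$k0 * res$times),
               tolerance = 1e-12)
  expect_equal(res$surface_C, res$substrate_C, tolerance = 1e-12)
})

test_that("degradation is surface-initiated with interior maximum principle", {
  kin <- opt_params()
  res <- simulate_film(film_config(), anchored_enzyme(kin), kin,
                       mgdl_to_mM(200), T_min = 120,
                       snapshot_times = c(10, 60, 120))
  idx <- -1  # exclude t = 0
  expect_true(all(res$surface_C[idx] < res$substrate_C[idx]))
  expect_true(all(res$surface_C[idx] <= res$mean_C[idx]))
  expect_true(all(res$mean_C[idx] <= res$substrate_C[idx]))
  expect_true(all(diff(res$mean_signal) < 0))
  H_cap <- mm_rate(anchored_enzyme(kin), mgdl_to_mM(200)) / 0.02
  for (snap in res$snapshots) {
    expect_true(all(snap$H >= 0 & snap$H <= H_cap + 1e-12))
    expect_true(all(diff(snap$H) <= 1e-12))   # monotone into the film
    expect_true(all(diff(snap$C) >= -1e-12))  # integrity mirrors peroxide
  }
})

test_that("averaged signal stays ordered across glucose and converges in dx", {
  kin <- opt_params()
  enz <- anchored_enzyme(kin)
  runs <- lapply(c(100, 200, 300), function(G) {
    simulate_film(film_config(Nx = 51), enz, kin, mgdl_to_mM(G), T_min = 60)
  })
  for (i in 1:2) {
    expect_true(all(runs[[i]]$mean_signal[-1] > runs[[i + 1]]$mean_signal[-1]))
  }
  fine <- simulate_film(film_config(Nx = 101), enz, kin, mgdl_to_mM(200),
                        T_min = 60)
  coarse <- runs[[2]]
  expect_lt(abs(tail(fine$mean_signal, 1) / tail(coarse$mean_signal, 1) - 1),
            0.005)
})

test_that("well-mixed fast-diffusion limit recovers the 0D GOx model", {
  kin <- opt_params()
  aH <- calibrate_alpha_H(enzyme_params(k_cons = 0.02), kin, target_spec())
  # diffusion scaled up 1e6 from the reference 1e-18 m^2/s; no consumption
  cfg <- film_config(D_H = 1e-12, k_cons = 0, Nx = 5, alpha_H = aH)
  enz0 <- enzyme_params(k_cons = 0, alpha_H = aH)
  res <- simulate_film(cfg, enz0, kin, mgdl_to_mM(200), T_min = 30)
  s0d <- integrate_gox_signal(enz0, kin, mgdl_to_mM(200), res$times)
  expect_lt(max(abs(res$mean_signal - s0d$values)), 1e-3)
})

test_that("consistency metrics quantify end-point match and transient gap", {
  kin <- opt_params()
  res <- simulate_film(film_config(Nx = 51), anchored_enzyme(kin), kin,
                       mgdl_to_mM(200), T_min = 60)
  self <- trajectory(res$times, res$mean_signal)
  chk <- consistency_check(res, self)
  expect_equal(chk$endpoint_diff, 0)
  expect_equal(chk$rms_diff, 0)
  # end-point-matched 0D surrogate: same final signal, different transient
  k_eff <- -log(tail(res$mean_signal, 1)) / (kin$beta * 60)
  surro <- trajectory(res$times, exp(-kin$beta * k_eff * res$times))
  chk2 <- consistency_check(res, surro)
  expect_lt(chk2$endpoint_diff, 1e-12)
  expect_gt(chk2$rms_diff, 1e-4)
  bad <- trajectory(c(0, 10), c(1, 0.9))
  expect_error(consistency_check(res, bad), "cover")
})
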