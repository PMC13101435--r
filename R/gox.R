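# Transient enzyme-driven degradation pathway. Glucose oxidase converts
# glucose to gluconolactone + H2O2 at the Michaelis-Menten rate
#   v(G) = Vmax * G / (KM + G)                       [mM/min]
# Peroxide at the exposed surface balances production and first-order
# consumption,
#   dHs/dt = v(G) - k_cons * Hs,   Hs(0) = 0
# whose solution Hs(t) = (v/k_cons) (1 - exp(-k_cons t)) rises from zero to
# the plateau v/k_cons. The degradation rate then becomes time dependent,
#   k(t) = k0 + alpha_H * Hs(t)
# so the GOx model degrades slower than the constant-k surrogate at early
# times (peroxide lag) and can be compared like-for-like by rescaling the
# glucose-driven exposure integral ("exposure matching").

#' GOx / peroxide pathway constants
#'
#' @param Vmax Maximum enzymatic turnover rate, mM/min (> 0). Default 0.067,
#'   representative of GOx covalently immobilised on pHEMA membranes.
#' @param KM Michaelis constant, mM (> 0). Default 8.8 for the same system.
#' @param k_cons First-order peroxide consumption rate, min^-1 (>= 0).
#' @param alpha_H Peroxide-to-degradation coupling, min^-1 mM^-1 (>= 0).
#' @param alpha Optional lumped peroxide-per-glucose ratio of the linear
#'   surrogate; documentation only, never used in computation.
#' @return An object of class `enzyme_params`.
#' @export
enzyme_params <- function(Vmax = 0.067, KM = 8.8, k_cons = 0.02,
                          alpha_H = 0, alpha = NULL) {
  stopifnot(is.numeric(Vmax), Vmax > 0, is.numeric(KM), KM > 0,
            is.numeric(k_cons), k_cons >= 0,
            is.numeric(alpha_H), alpha_H >= 0)
  structure(list(Vmax = as.numeric(Vmax), KM = as.numeric(KM),
                 k_cons = as.numeric(k_cons), alpha_H = as.numeric(alpha_H),
                 alpha = alpha),
            class = "enzyme_params")
}

#' @export
print.enzyme_params <- function(x, ...) {
  cat(sprintf(paste0("<enzyme_params> Vmax = %.4g mM/min, KM = %.4g mM, ",
                     "k_cons = %.4g /min, alpha_H = %.4g /min/mM\n"),
              x$Vmax, x$KM, x$k_cons, x$alpha_H))
  invisible(x)
}

#' Michaelis-Menten peroxide production rate
#'
#' @param enz An [enzyme_params].
#' @param G A [glucose_level] or numeric vector in mM.
#' @return v(G) = Vmax G / (KM + G), mM/min (vectorised).
#' @export
mm_rate <- function(enz, G) {
  stopifnot(inherits(enz, "enzyme_params"))
  G <- as_glucose_mM(G, scalar = FALSE)
  enz$Vmax * G / (enz$KM + G)
}

#' Surface peroxide build-up
#'
#' Solves dHs/dt = v(G) - k_cons Hs from Hs(0) = 0. The balance is linear,
#' so the exact solution is used: Hs(t) = (v/k_cons)(1 - exp(-k_cons t))
#' for k_cons > 0, and pure accumulation v t when k_cons = 0.
#'
#' @param enz An [enzyme_params].
#' @param G Glucose level.
#' @param times Time grid, minutes.
#' @return A `trajectory` of surface peroxide in mM.
#' @export
surface_peroxide <- function(enz, G, times = default_times()) {
  v <- mm_rate(enz, as_glucose_mM(G))
  H <- if (enz$k_cons > 0) {
    (v / enz$k_cons) * (1 - exp(-enz$k_cons * times))
  } else {
    v * times
  }
  trajectory(times, H, glucose_mgdl = mM_to_mgdl(as_glucose_mM(G)),
             kind = "peroxide_mM")
}

#' Time-dependent degradation-rate profile
#'
#' @param times Time grid, minutes, starting at 0.
#' @param k_values Degradation rate at each time, min^-1.
#' @param k0 Basal rate the profile is anchored to; every k value must be
#'   >= k0.
#' @return An object of class `rate_profile`.
#' @export
rate_profile <- function(times, k_values, k0) {
  stopifnot(is.numeric(times), is.numeric(k_values),
            length(times) == length(k_values), length(times) >= 2L,
            times[1] == 0, all(diff(times) > 0),
            is.numeric(k0), length(k0) == 1L, k0 > 0)
  if (any(k_values < k0 - 1e-12)) {
    stop("rate profile dips below the basal rate k0")
  }
  structure(list(times = as.numeric(times), k_values = as.numeric(k_values),
                 k0 = as.numeric(k0)),
            class = "rate_profile")
}

#' @export
print.rate_profile <- function(x, ...) {
  cat(sprintf("<rate_profile> %d points over [0, %.4g] min; k in [%.4g, %.4g] /min (k0 = %.4g)\n",
              length(x$times), max(x$times), min(x$k_values), max(x$k_values), x$k0))
  invisible(x)
}

#' GOx-driven transient degradation rate
#'
#' k(t) = k0 + alpha_H Hs(t): starts at the basal rate and builds towards
#' the plateau k0 + alpha_H v(G)/k_cons as peroxide accumulates.
#'
#' @param enz An [enzyme_params] (its `alpha_H` is used).
#' @param kin A [kinetic_params] (its `k0` is used).
#' @param G Glucose level.
#' @param times Time grid, minutes.
#' @return A [rate_profile].
#' @export
transient_rate <- function(enz, kin, G, times = default_times()) {
  stopifnot(inherits(kin, "kinetic_params"))
  Hs <- surface_peroxide(enz, G, times)
  rate_profile(times, kin$k0 + enz$alpha_H * Hs$values, k0 = kin$k0)
}

#' Anchor the peroxide pathway to the half-life design targets
#'
#' Chooses alpha_H so that the steady-state transient rate at the reference
#' glucose level equals the constant-k reference rate ln 2 / t_half_ref:
#' alpha_H = (ln 2 / t_half_ref - k0) / (v(G_ref) / k_cons).
#'
#' @param enz An [enzyme_params] with k_cons > 0.
#' @param kin A [kinetic_params].
#' @param spec A [halflife_spec].
#' @return The calibrated alpha_H (min^-1 mM^-1).
#' @export
calibrate_alpha_H <- function(enz, kin, spec) {
  stopifnot(inherits(enz, "enzyme_params"), inherits(kin, "kinetic_params"),
            inherits(spec, "halflife_spec"))
  if (enz$k_cons <= 0) {
    stop("calibrate_alpha_H requires k_cons > 0: without consumption the ",
         "peroxide level has no steady state")
  }
  H_inf <- mm_rate(enz, spec$G_ref) / enz$k_cons
  k_ref <- log(2) / spec$t_half_ref
  (k_ref - kin$k0) / H_inf
}

# Trapezoidal exposure integral of a rate profile over [0, T]; T may fall
# between grid points (linear interpolation of k at T).
rate_exposure <- function(profile, T_end = max(profile$times)) {
  stopifnot(inherits(profile, "rate_profile"),
            T_end > 0, T_end <= max(profile$times) + 1e-9)
  tt <- profile$times
  kk <- profile$k_values
  keep <- tt < T_end - 1e-12
  kT <- approx(tt, kk, xout = min(T_end, max(tt)))$y
  tt <- c(tt[keep], T_end)
  kk <- c(kk[keep], kT)
  sum(diff(tt) * (head(kk, -1) + kk[-1]) / 2)
}

# Cumulative trapezoidal exposure at every grid point.
cumulative_exposure <- function(times, k_values) {
  c(0, cumsum(diff(times) * (head(k_values, -1) + k_values[-1]) / 2))
}

#' Match the integrated degradation exposure of a rate profile
#'
#' Rescales a time-dependent rate history so that its integral over the
#' observation window equals that of a constant-rate surrogate,
#' int_0^T k dt = k_const T, guaranteeing identical end-point intact
#' fractions while preserving the transient shape. By default only the
#' glucose-driven component k(t) - k0 is scaled, leaving the basal pathway
#' untouched; `scale_total = TRUE` scales the whole profile instead.
#'
#' @param profile A [rate_profile].
#' @param k_const Constant surrogate rate, min^-1.
#' @param T_end Observation window end, minutes (within the profile grid).
#' @param scale_total Scale the full rate rather than the glucose-driven
#'   component.
#' @return A [rate_profile] with attribute `"lambda"` (the applied scale).
#' @export
exposure_match <- function(profile, k_const, T_end = max(profile$times),
                           scale_total = FALSE) {
  stopifnot(inherits(profile, "rate_profile"),
            is.numeric(k_const), k_const > 0)
  total <- rate_exposure(profile, T_end)
  if (total <= 0) stop("rate profile has zero integrated exposure")
  if (scale_total) {
    lambda <- k_const * T_end / total
    k_new <- lambda * profile$k_values
    k0_new <- lambda * profile$k0
  } else {
    excess <- total - profile$k0 * T_end
    target <- (k_const - profile$k0) * T_end
    if (excess <= 0) {
      stop("profile has no glucose-driven exposure above k0 to rescale; ",
           "use scale_total = TRUE")
    }
    lambda <- target / excess
    k_new <- profile$k0 + lambda * (profile$k_values - profile$k0)
    k0_new <- profile$k0
  }
  out <- rate_profile(profile$times, k_new, k0 = k0_new)
  attr(out, "lambda") <- lambda
  out
}

#' Integrate the GOx-model optical signal
#'
#' Computes C(t) = exp(-int_0^t k(s) ds) with k(t) from [transient_rate()]
#' (or any supplied [rate_profile], e.g. an exposure-matched one) and
#' S(t) = S0 C(t)^beta.
#'
#' Two routes are available: `"quadrature"` evaluates the exposure integral
#' of the closed-form rate (exact for the enzyme-derived profile, cumulative
#' trapezoid for a supplied profile); `"ode"` integrates dC/dt = -k(t) C
#' with an adaptive solver at relative and absolute tolerance 1e-6.
#'
#' @param enz An [enzyme_params].
#' @param kin A [kinetic_params].
#' @param G Glucose level.
#' @param times Time grid, minutes.
#' @param method `"quadrature"` (default) or `"ode"`.
#' @param profile Optional [rate_profile] overriding the enzyme-derived
#'   rate; must share `times`.
#' @return A signal `trajectory`.
#' @export
integrate_gox_signal <- function(enz, kin, G, times = default_times(),
                                 method = c("quadrature", "ode"),
                                 profile = NULL) {
  method <- match.arg(method)
  G_mM <- as_glucose_mM(G)
  if (!is.null(profile)) {
    stopifnot(inherits(profile, "rate_profile"))
    if (length(profile$times) != length(times) ||
        any(abs(profile$times - times) > 1e-9)) {
      stop("supplied rate profile must share the requested time grid")
    }
  }
  if (method == "quadrature") {
    if (is.null(profile)) {
      expo <- exact_gox_exposure(enz, kin, G_mM, times)
    } else {
      expo <- cumulative_exposure(profile$times, profile$k_values)
    }
    C <- exp(-expo)
  } else {
    k_fun <- if (is.null(profile)) {
      v <- mm_rate(enz, G_mM)
      function(t) {
        Hs <- if (enz$k_cons > 0) (v / enz$k_cons) * (1 - exp(-enz$k_cons * t))
              else v * t
        kin$k0 + enz$alpha_H * Hs
      }
    } else {
      function(t) approx(profile$times, profile$k_values, xout = t,
                         rule = 2)$y
    }
    sol <- deSolve::ode(y = c(C = 1), times = times,
                        func = function(t, y, p) list(-k_fun(t) * y),
                        rtol = 1e-6, atol = 1e-6)
    if (attr(sol, "istate")[1] < 0) {
      stop("GOx signal ODE integration failed to converge (istate = ",
           attr(sol, "istate")[1], ") for G = ", G_mM, " mM over [0, ",
           max(times), "] min")
    }
    C <- sol[, "C"]
  }
  trajectory(times, kin$S0 * pmax(C, 0)^kin$beta,
             glucose_mgdl = mM_to_mgdl(G_mM), kind = "signal")
}

# Closed-form exposure integral int_0^t (k0 + alpha_H Hs(s)) ds for the
# enzyme-derived rate.
exact_gox_exposure <- function(enz, kin, G_mM, times) {
  v <- mm_rate(enz, G_mM)
  if (enz$k_cons > 0) {
    H_inf <- v / enz$k_cons
    kin$k0 * times + enz$alpha_H * H_inf *
      (times - (1 - exp(-enz$k_cons * times)) / enz$k_cons)
  } else {
    kin$k0 * times + enz$alpha_H * v * times^2 / 2
  }
}

#' Side-by-side GOx vs constant-rate comparison
#'
#' Convenience wrapper producing the matched comparison: the constant-k
#' surrogate at glucose G, the raw GOx trajectory, and the exposure-matched
#' GOx trajectory, together with both rate profiles.
#'
#' @param enz An [enzyme_params].
#' @param kin A [kinetic_params].
#' @param G Glucose level.
#' @param times Time grid, minutes.
#' @param scale_total Passed to [exposure_match()].
#' @return A list with elements `S_const`, `S_gox_raw`, `S_gox_matched`
#'   (trajectories), `k_const` (scalar), `profile_raw`, `profile_matched`
#'   (rate profiles) and `lambda`.
#' @export
gox_compare <- function(enz, kin, G, times = default_times(),
                        scale_total = FALSE) {
  G_mM <- as_glucose_mM(G)
  k_const <- k_deg(kin, G_mM)
  prof <- transient_rate(enz, kin, G_mM, times)
  matched <- exposure_match(prof, k_const, max(times), scale_total = scale_total)
  list(S_const = signal_0d(kin, G_mM, times),
       S_gox_raw = integrate_gox_signal(enz, kin, G_mM, times),
       S_gox_matched = integrate_gox_signal(enz, kin, G_mM, times,
                                            profile = matched),
       k_const = k_const,
       profile_raw = prof,
       profile_matched = matched,
       lambda = attr(matched, "lambda"))
}
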