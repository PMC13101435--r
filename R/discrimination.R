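# Signal-detection analysis of pairwise glucose discrimination. Two glucose
# levels produce diverging signal trajectories; with additive Gaussian
# measurement noise of standard deviation sigma_S on each reading, the
# inter-class separation Delta S has uncertainty sqrt(2) sigma_S, giving the
# sensitivity index
#   d'(t) = |S1(t) - S2(t)| / (sqrt(2) sigma_S)
# and, for an optimally placed midpoint threshold between two equal-variance
# Gaussians, the theoretical misclassification probability
#   P_error(t) = Phi(-d'(t)/2).
# The read-out time minimising P_error is the recommended measurement time.

#' Additive Gaussian measurement-noise model
#'
#' @param sigma_S Noise standard deviation on the normalised signal (> 0).
#'   Default 0.02, i.e. 2% of full scale.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_S = 0.02) {
  stopifnot(is.numeric(sigma_S), length(sigma_S) == 1L, sigma_S > 0)
  structure(list(sigma_S = as.numeric(sigma_S)), class = "noise_model")
}

#' Read-out window specification
#'
#' @param t_read Nominal single-shot read-out time, minutes.
#' @param window_max Upper bound of the practical read-out window searched
#'   for the optimum, minutes (default 60).
#' @return An object of class `readout_spec`.
#' @export
readout_spec <- function(t_read = 30, window_max = 60) {
  stopifnot(is.numeric(t_read), t_read > 0, is.numeric(window_max),
            window_max > 0, t_read <= window_max)
  structure(list(t_read = as.numeric(t_read),
                 window_max = as.numeric(window_max)),
            class = "readout_spec")
}

#' Absolute signal difference between two glucose levels
#'
#' Delta S(t) = |S(t; G1) - S(t; G2)|: zero at t = 0, growing while the
#' kinetic contrast accumulates, then decaying as both signals vanish —
#' unimodal for the constant-rate model.
#'
#' @param params A [kinetic_params].
#' @param G1,G2 Glucose levels in mg/dL.
#' @param times Time grid, minutes.
#' @return A `trajectory` of Delta S.
#' @export
delta_S <- function(params, G1, G2, times = default_times()) {
  g1 <- as_glucose_mM(mgdl_to_mM(G1))
  g2 <- as_glucose_mM(mgdl_to_mM(G2))
  dS <- abs(signal_at(params, g1, times) - signal_at(params, g2, times))
  trajectory(times, dS, kind = "delta_S")
}

#' Closed-form maximiser of the signal difference
#'
#' For rates k1 = k_deg(G1), k2 = k_deg(G2) the difference of the two
#' exponentials S0 exp(-beta k t) peaks at
#'   t* = ln(k2/k1) / (beta (k2 - k1)).
#' Serves as the analytic oracle for the grid search in
#' [optimal_readout()].
#'
#' @param params A [kinetic_params].
#' @param G1,G2 Distinct glucose levels in mg/dL.
#' @return Peak time, minutes.
#' @export
peak_time_closed_form <- function(params, G1, G2) {
  k1 <- k_deg(params, mgdl_to_mM(G1))
  k2 <- k_deg(params, mgdl_to_mM(G2))
  if (abs(k1 - k2) < .Machine$double.eps * max(k1, k2)) {
    stop("equal degradation rates: the signal difference has no peak")
  }
  log(k2 / k1) / (params$beta * (k2 - k1))
}

#' Sensitivity index d'
#'
#' @param deltaS Signal separation(s), dimensionless.
#' @param noise A [noise_model].
#' @return d' = deltaS / (sqrt(2) sigma_S), vectorised.
#' @export
d_prime <- function(deltaS, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"), is.numeric(deltaS),
            all(deltaS >= 0))
  deltaS / (sqrt(2) * noise$sigma_S)
}

#' Theoretical two-class error under optimal threshold placement
#'
#' For two equal-variance Gaussian signal distributions separated by
#' d' noise units, the midpoint threshold misclassifies with probability
#' Phi(-d'/2); chance level (0.5) at d' = 0.
#'
#' @param d_prime Sensitivity index (>= 0), vectorised.
#' @return Misclassification probability.
#' @export
p_error <- function(d_prime) {
  stopifnot(is.numeric(d_prime), all(d_prime >= 0))
  pnorm(-d_prime / 2)
}

#' Error-minimising read-out time and discrimination summary
#'
#' Scans a fine time grid over `(0, window_max]` for the minimum of
#' P_error(t) = Phi(-d'(t)/2); with time-independent noise this coincides
#' with the Delta S maximiser, so the closed-form peak time is used to
#' cross-check (and is returned when it falls inside the window).
#'
#' @param params A [kinetic_params].
#' @param G1,G2 Distinct glucose levels in mg/dL.
#' @param noise A [noise_model].
#' @param spec A [readout_spec]; only `window_max` is used.
#' @param grid_dt Search-grid resolution, minutes.
#' @return An object of class `pair_metrics`: `G1`, `G2` (mg/dL),
#'   `deltaS_max`, `t_opt` (min), `d_prime_at_opt`, `error_pct`,
#'   `accuracy_pct`.
#' @examples
#' optimal_readout(optimal_config(), 100, 200)
#' @export
optimal_readout <- function(params, G1, G2, noise = noise_model(),
                            spec = readout_spec(), grid_dt = 0.1) {
  stopifnot(inherits(spec, "readout_spec"), grid_dt > 0)
  t_star <- peak_time_closed_form(params, G1, G2)  # rejects degenerate pairs
  tt <- seq(grid_dt, spec$window_max, by = grid_dt)
  dS <- delta_S(params, G1, G2, c(0, tt))$values[-1]
  err <- p_error(d_prime(dS, noise))
  i <- which.min(err)
  t_opt <- tt[i]
  # the analytic peak is exact; snap to it when it lies inside the window
  if (t_star > 0 && t_star <= spec$window_max) t_opt <- t_star
  dS_opt <- delta_S(params, G1, G2, c(0, t_opt))$values[2]
  dp <- d_prime(dS_opt, noise)
  err_opt <- p_error(dp)
  structure(list(G1 = as.numeric(G1), G2 = as.numeric(G2),
                 deltaS_max = dS_opt, t_opt = t_opt, d_prime_at_opt = dp,
                 error_pct = 100 * err_opt,
                 accuracy_pct = 100 * (1 - err_opt)),
            class = "pair_metrics")
}

#' @export
print.pair_metrics <- function(x, ...) {
  cat(sprintf(paste0("<pair_metrics> %g vs %g mg/dL: dS_max = %.3f at ",
                     "t_opt = %.1f min, d' = %.2f, error = %.4g%% ",
                     "(accuracy %.4g%%)\n"),
              x$G1, x$G2, x$deltaS_max, x$t_opt, x$d_prime_at_opt,
              x$error_pct, x$accuracy_pct))
  invisible(x)
}

#' @export
as.data.frame.pair_metrics <- function(x, ...) {
  data.frame(G1_mgdl = x$G1, G2_mgdl = x$G2, deltaS_max = x$deltaS_max,
             t_opt_min = x$t_opt, d_prime = x$d_prime_at_opt,
             error_pct = x$error_pct, accuracy_pct = x$accuracy_pct)
}

#' Monte Carlo validation of threshold classification
#'
#' Draws `N` noisy signal readings per glucose class at the read-out time,
#' classifies each by the midpoint between the two class means, and reports
#' the empirical accuracy. Per-class noise streams are derived
#' deterministically from the single seed.
#'
#' @param params A [kinetic_params].
#' @param G1,G2 Glucose levels in mg/dL.
#' @param t_read Read-out time, minutes.
#' @param noise A [noise_model].
#' @param N Samples per class.
#' @param seed Integer seed for reproducibility.
#' @return A list with `accuracy` (fraction), `threshold`, the analytic
#'   expectation `accuracy_theory = 1 - Phi(-dS/(2 sigma))`, per-class
#'   sample means, and `N`, `seed`.
#' @export
monte_carlo_classify <- function(params, G1, G2, t_read = 30,
                                 noise = noise_model(), N = 2000,
                                 seed = 1L) {
  stopifnot(N >= 1, is.numeric(seed), length(seed) == 1L)
  g1 <- as_glucose_mM(mgdl_to_mM(G1))
  g2 <- as_glucose_mM(mgdl_to_mM(G2))
  mu1 <- signal_at(params, g1, t_read)
  mu2 <- signal_at(params, g2, t_read)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, 2)
  set.seed(sub_seeds[1])
  s1 <- mu1 + rnorm(N, 0, noise$sigma_S)
  set.seed(sub_seeds[2])
  s2 <- mu2 + rnorm(N, 0, noise$sigma_S)
  thr <- (mu1 + mu2) / 2
  # class 1 has the higher mean iff G1 < G2 (signal decreases with glucose)
  hi_is_1 <- mu1 >= mu2
  correct1 <- if (hi_is_1) s1 > thr else s1 <= thr
  correct2 <- if (hi_is_1) s2 <= thr else s2 > thr
  acc <- mean(c(correct1, correct2))
  dS <- abs(mu1 - mu2)
  list(accuracy = acc, threshold = thr,
       accuracy_theory = 1 - pnorm(-dS / (2 * noise$sigma_S)),
       mean_class1 = mean(s1), mean_class2 = mean(s2),
       N = N, seed = as.integer(seed))
}
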