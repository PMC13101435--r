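# Closed-form 0D constant-rate model. The intact fraction decays as
#   C(t) = exp(-k_deg(G) * t)
# and the optical signal follows the power law S(t) = S0 * C(t)^beta.
# Everything here is evaluated analytically; numerical integration is
# reserved for the transient GOx pathway (see gox.R).

#' Intact fraction of the sensing layer over time
#'
#' @param params A [kinetic_params].
#' @param G A [glucose_level] (or numeric mM scalar).
#' @param times Time grid, minutes, starting at 0.
#' @return A `trajectory` of C(t) = exp(-k_deg(G) t), starting at 1.
#' @export
intact_fraction <- function(params, G, times = default_times()) {
  k <- k_deg(params, as_glucose_mM(G))
  trajectory(times, exp(-k * times),
             glucose_mgdl = mM_to_mgdl(as_glucose_mM(G)), kind = "integrity")
}

#' Optical signal over time
#'
#' @inheritParams intact_fraction
#' @return A `trajectory` of S(t) = S0 * exp(-beta * k_deg(G) * t).
#' @examples
#' sig <- signal_0d(optimal_config(), mgdl_to_mM(100))
#' head(as.data.frame(sig))
#' @export
signal_0d <- function(params, G, times = default_times()) {
  k <- k_deg(params, as_glucose_mM(G))
  trajectory(times, params$S0 * exp(-params$beta * k * times),
             glucose_mgdl = mM_to_mgdl(as_glucose_mM(G)), kind = "signal")
}

# Scalar fast path used heavily by the discrimination and design modules.
signal_at <- function(params, G_mM, t) {
  params$S0 * exp(-params$beta * (params$k0 + params$kG * G_mM) * t)
}

#' Dimensionless state of the degradation model
#'
#' In scaled time tau = k0 t and sensitivity ratio g = kG G / k0 the intact
#' fraction collapses to the universal curve C(tau) = exp(-(1 + g) tau):
#' every material, enzyme and environment effect enters through g alone.
#'
#' @param tau Dimensionless time(s), >= 0.
#' @param g Dimensionless sensitivity ratio(s), >= 0.
#' @return An object of class `dimensionless_state`.
#' @export
dimensionless_state <- function(tau, g) {
  stopifnot(is.numeric(tau), is.numeric(g), all(tau >= 0), all(g >= 0),
            all(is.finite(tau)), all(is.finite(g)))
  structure(list(tau = as.numeric(tau), g = as.numeric(g)),
            class = "dimensionless_state")
}

#' Universal dimensionless intact fraction
#'
#' @param state A [dimensionless_state].
#' @return exp(-(1 + g) * tau), vectorised.
#' @export
dimensionless_signal <- function(state) {
  stopifnot(inherits(state, "dimensionless_state"))
  exp(-(1 + state$g) * state$tau)
}

#' Map a dimensional operating point to the dimensionless state
#'
#' @param params A [kinetic_params].
#' @param G Glucose level.
#' @param times Times in minutes.
#' @return A [dimensionless_state] with tau = k0 t, g = kG G / k0.
#' @export
to_dimensionless <- function(params, G, times) {
  dimensionless_state(tau = params$k0 * times,
                      g = params$kG * as_glucose_mM(G) / params$k0)
}

#' Signal trajectories across a glucose panel
#'
#' One closed-form signal trajectory per glucose level. For kG > 0 the
#' curves are strictly ordered at every t > 0: higher glucose degrades
#' faster and yields the lower signal.
#'
#' @param params A [kinetic_params].
#' @param G_list Glucose levels in mg/dL.
#' @param times Time grid, minutes.
#' @return A list of `trajectory` objects, one per glucose level.
#' @export
glucose_sweep <- function(params, G_list = default_glucose_panel(),
                          times = default_times()) {
  stopifnot(is.numeric(G_list), length(G_list) >= 1L)
  lapply(G_list, function(g) signal_0d(params, mgdl_to_mM(g), times))
}

#' Single-time read-out across a glucose panel
#'
#' Emulates a one-shot measurement: the signal at a fixed read-out time as
#' a function of glucose. Strictly decreasing in G whenever kG > 0.
#'
#' @param params A [kinetic_params].
#' @param G_list Glucose levels in mg/dL.
#' @param t_read Read-out time, minutes (>= 0).
#' @return A data.frame with columns `glucose_mgdl`, `glucose_mM`, `signal`.
#' @export
single_time_readout <- function(params, G_list = default_glucose_panel(),
                                t_read = 30) {
  stopifnot(is.numeric(t_read), length(t_read) == 1L, t_read >= 0)
  G_mM <- mgdl_to_mM(as.numeric(G_list))
  if (inherits(G_mM, "glucose_level")) G_mM <- G_mM$value_mM
  data.frame(glucose_mgdl = as.numeric(G_list),
             glucose_mM = G_mM,
             signal = signal_at(params, G_mM, t_read))
}
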