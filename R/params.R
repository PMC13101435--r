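# Half-life-based parameterisation of the pseudo-first-order degradation
# model. The effective degradation rate is
#   k_deg(G) = k0 + kG * G        [min^-1, G in mM]
# with k0 the basal pathway and kG the lumped glucose-to-degradation
# coupling (the identifiable product of the peroxide susceptibility and the
# peroxide-per-glucose ratio). Rates are fixed by two design-target
# half-lives: a basal one at G = 0 and an accelerated one at a reference
# glucose level, via t_half = ln 2 / k_deg.

#' Half-life design targets
#'
#' A pair of prescribed half-lives that parameterise the degradation model:
#' the basal half-life of the film in the absence of glucose and the
#' accelerated half-life at a reference glucose level.
#'
#' @param t_half_base Basal half-life at G = 0, minutes.
#' @param t_half_ref Accelerated half-life at `G_ref`, minutes; must be
#'   strictly smaller than `t_half_base`.
#' @param G_ref Reference glucose level: a [glucose_level], or a number
#'   interpreted in mM unless `units = "mgdl"`.
#' @param units Units of a bare-numeric `G_ref` (`"mM"` or `"mgdl"`).
#' @return An object of class `halflife_spec`.
#' @examples
#' halflife_spec(480, 30, 200, units = "mgdl")
#' @export
halflife_spec <- function(t_half_base, t_half_ref, G_ref, units = c("mM", "mgdl")) {
  units <- match.arg(units)
  stopifnot(is.numeric(t_half_base), length(t_half_base) == 1L, t_half_base > 0,
            is.numeric(t_half_ref), length(t_half_ref) == 1L, t_half_ref > 0)
  if (!inherits(G_ref, "glucose_level")) {
    G_ref <- if (units == "mgdl") mgdl_to_mM(G_ref) else glucose_level(G_ref)
  }
  if (G_ref$value_mM <= 0) stop("G_ref must be strictly positive")
  if (t_half_ref >= t_half_base) {
    stop("t_half_ref (", t_half_ref, " min) must be strictly smaller than ",
         "t_half_base (", t_half_base, " min): the accelerated half-life ",
         "defines the glucose-driven contrast")
  }
  structure(list(t_half_base = as.numeric(t_half_base),
                 t_half_ref = as.numeric(t_half_ref),
                 G_ref = G_ref),
            class = "halflife_spec")
}

#' Kinetic parameters of the 0D degradation model
#'
#' @param k0 Basal degradation rate, min^-1 (> 0).
#' @param kG Glucose-to-degradation coupling, min^-1 mM^-1 (>= 0).
#' @param beta Optical nonlinearity exponent in S = S0 * C^beta (> 0).
#' @param S0 Initial signal, arbitrary units (> 0, default 1).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k0, kG, beta = 1.5, S0 = 1) {
  stopifnot(is.numeric(k0), length(k0) == 1L, k0 > 0,
            is.numeric(kG), length(kG) == 1L, kG >= 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(S0), length(S0) == 1L, S0 > 0)
  structure(list(k0 = as.numeric(k0), kG = as.numeric(kG),
                 beta = as.numeric(beta), S0 = as.numeric(S0)),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(paste0("<kinetic_params> k0 = %.6g /min (basal t1/2 = %.4g min), ",
                     "kG = %.6g /min/mM, beta = %.3g, S0 = %.3g\n"),
              x$k0, log(2) / x$k0, x$kG, x$beta, x$S0))
  invisible(x)
}

#' Derive kinetic rates from half-life design targets
#'
#' Inverts t_half = ln 2 / k_deg at G = 0 and at the reference glucose level:
#' k0 = ln 2 / t_half_base and kG = (ln 2 / t_half_ref - k0) / G_ref.
#'
#' @param spec A [halflife_spec].
#' @param beta,S0 Optical model parameters, see [kinetic_params()].
#' @return A [kinetic_params] whose half-lives at G = 0 and G = G_ref
#'   reproduce the targets exactly.
#' @examples
#' params_from_halflives(halflife_spec(480, 30, 200, units = "mgdl"))
#' @export
params_from_halflives <- function(spec, beta = 1.5, S0 = 1) {
  stopifnot(inherits(spec, "halflife_spec"))
  k0 <- log(2) / spec$t_half_base
  k_ref <- log(2) / spec$t_half_ref
  kG <- (k_ref - k0) / spec$G_ref$value_mM
  if (kG <= 0) stop("half-life targets give non-positive kG")
  kinetic_params(k0 = k0, kG = kG, beta = beta, S0 = S0)
}

#' Effective degradation rate at a glucose level
#'
#' @param params A [kinetic_params].
#' @param G A [glucose_level] or numeric vector in mM.
#' @return k0 + kG * G, min^-1 (vectorised over G).
#' @export
k_deg <- function(params, G) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k0 + params$kG * as_glucose_mM(G, scalar = FALSE)
}

#' Degradation half-life at a glucose level
#'
#' @inheritParams k_deg
#' @return ln 2 / k_deg, minutes (vectorised over G).
#' @examples
#' opt <- params_from_halflives(halflife_spec(480, 30, 200, units = "mgdl"))
#' half_life(opt, mgdl_to_mM(70))   # ~77 min
#' half_life(opt, mgdl_to_mM(300))  # ~20 min
#' @export
half_life <- function(params, G) {
  log(2) / k_deg(params, G)
}

#' Document a decomposition of the lumped coupling kG
#'
#' The coupling kG is the product of the film's peroxide susceptibility k1
#' and the effective peroxide-per-glucose ratio alpha; the two factors are
#' not independently identifiable, so the model stores only kG. This helper
#' exists purely to express a chosen split for documentation or reporting.
#'
#' @param params A [kinetic_params].
#' @param alpha Assumed peroxide-per-glucose ratio (dimensionless, > 0).
#' @return A list with `k1 = kG / alpha`, `alpha`, and their product `kG`.
#' @export
decompose_kG <- function(params, alpha) {
  stopifnot(inherits(params, "kinetic_params"),
            is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  list(k1 = params$kG / alpha, alpha = alpha, kG = params$kG)
}

#' The worked-example sensor configuration
#'
#' The operating point used throughout the examples: basal half-life
#' 480 min, accelerated half-life 30 min at 200 mg/dL, optical exponent
#' beta = 1.5, unit initial signal.
#'
#' @param beta,S0 Overrides for the optical parameters.
#' @return A [kinetic_params].
#' @export
optimal_config <- function(beta = 1.5, S0 = 1) {
  params_from_halflives(halflife_spec(480, 30, 200, units = "mgdl"),
                        beta = beta, S0 = S0)
}

#' Serialise kinetic parameters with their half-life targets
#'
#' @param spec A [halflife_spec].
#' @param beta,S0 Optical parameters.
#' @return A plain named list with keys `t_half_base_min`, `t_half_ref_min`,
#'   `G_ref_mgdl`, `beta`, `S0`, suitable for YAML/JSON round trips.
#' @export
halflife_spec_to_list <- function(spec, beta = 1.5, S0 = 1) {
  stopifnot(inherits(spec, "halflife_spec"))
  list(t_half_base_min = spec$t_half_base,
       t_half_ref_min = spec$t_half_ref,
       G_ref_mgdl = mM_to_mgdl(spec$G_ref),
       beta = beta, S0 = S0)
}

#' @rdname halflife_spec_to_list
#' @param x A named list as produced by [halflife_spec_to_list()].
#' @return `halflife_spec_from_list()` returns a list with elements `spec`
#'   ([halflife_spec]), `beta` and `S0`.
#' @export
halflife_spec_from_list <- function(x) {
  need <- c("t_half_base_min", "t_half_ref_min", "G_ref_mgdl")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("missing config keys: ", paste(missing, collapse = ", "))
  list(spec = halflife_spec(x$t_half_base_min, x$t_half_ref_min,
                            x$G_ref_mgdl, units = "mgdl"),
       beta = if (is.null(x$beta)) 1.5 else x$beta,
       S0 = if (is.null(x$S0)) 1 else x$S0)
}
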