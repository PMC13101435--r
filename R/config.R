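# Structured scenario configuration shared by the CLI and scripted runs.
# Defaults are the worked-example operating point (half-lives 480/30 min at
# 200 mg/dL, beta = 1.5, sigma_S = 0.02) and the reference film
# (L = 200 nm, D_H = 1e-18 m^2/s, k_cons = 0.02 /min).

default_config_list <- function() {
  list(
    model = list(t_half_base_min = 480, t_half_ref_min = 30,
                 G_ref_mgdl = 200, beta = 1.5, S0 = 1),
    enzyme = list(Vmax_mM_min = 0.067, KM_mM = 8.8, k_cons_per_min = 0.02,
                  alpha_H = NULL),
    film = list(L_nm = 200, Nx = 101, D_H_m2s = 1e-18,
                k_cons_per_min = 0.02, safety = 0.5),
    readout = list(sigma_S = 0.02, t_read_min = 30, window_max_min = 60),
    run = list(t_max_min = 120, dt_min = 0.5,
               glucose_mgdl = c(70, 100, 126, 140, 200, 300),
               mc_samples = 2000, seed = 1, out_dir = ".")
  )
}

# Merge user values over defaults, rejecting unknown keys loudly.
merge_config <- function(user, defaults = default_config_list(), path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]],
                                     paste0(path, ".", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Build a validated scenario configuration
#'
#' Resolves a (possibly partial) named list of settings against the package
#' defaults and constructs the typed parameter objects of every module,
#' validating all invariants up front.
#'
#' @param x Named list with any of the sections `model`, `enzyme`, `film`,
#'   `readout`, `run` (missing entries take defaults; unknown keys are
#'   rejected with their key path).
#' @return An object of class `scenario_config` with elements `kin`
#'   ([kinetic_params]), `spec` ([halflife_spec]), `enz` ([enzyme_params]),
#'   `film` ([film_config]), `noise` ([noise_model]), `readout`
#'   ([readout_spec]), `run` (list) and `raw` (the resolved list).
#' @export
scenario_config <- function(x = list()) {
  cfg <- merge_config(x)
  spec <- halflife_spec(cfg$model$t_half_base_min, cfg$model$t_half_ref_min,
                        cfg$model$G_ref_mgdl, units = "mgdl")
  kin <- params_from_halflives(spec, beta = cfg$model$beta, S0 = cfg$model$S0)
  enz <- enzyme_params(Vmax = cfg$enzyme$Vmax_mM_min, KM = cfg$enzyme$KM_mM,
                       k_cons = cfg$enzyme$k_cons_per_min,
                       alpha_H = if (is.null(cfg$enzyme$alpha_H)) 0
                                 else cfg$enzyme$alpha_H)
  if (is.null(cfg$enzyme$alpha_H)) {
    enz$alpha_H <- calibrate_alpha_H(enz, kin, spec)
  }
  film <- film_config(L = cfg$film$L_nm * 1e-9, Nx = cfg$film$Nx,
                      D_H = cfg$film$D_H_m2s,
                      k_cons = cfg$film$k_cons_per_min,
                      alpha_H = enz$alpha_H, safety = cfg$film$safety)
  noise <- noise_model(cfg$readout$sigma_S)
  readout <- readout_spec(cfg$readout$t_read_min, cfg$readout$window_max_min)
  structure(list(kin = kin, spec = spec, enz = enz, film = film,
                 noise = noise, readout = readout, run = cfg$run, raw = cfg),
            class = "scenario_config")
}

#' Load a scenario configuration from a YAML file
#'
#' An empty file yields the all-defaults configuration. Validation errors
#' name the offending key.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("failed to parse config '", path, "': ", conditionMessage(e))
  })
  if (is.null(user)) user <- list()
  scenario_config(user)
}

#' Save a scenario configuration to YAML
#'
#' Round trip: `load_config(save_config(cfg, f))` resolves to the same
#' configuration.
#'
#' @param config A [scenario_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(config$raw, path)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  print(x$kin)
  print(x$enz)
  print(x$film)
  cat(sprintf("  noise sigma_S = %g; read-out %g min (window <= %g min); seed %d\n",
              x$noise$sigma_S, x$readout$t_read, x$readout$window_max,
              as.integer(x$run$seed)))
  invisible(x)
}

# Apply --set key.path=value overrides (values parsed as YAML scalars).
apply_overrides <- function(raw, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("override must be key.path=value, got: ", ov)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(kv[2])
    raw <- modifyList(raw, Reduce(function(v, k) stats::setNames(list(v), k),
                                  rev(keys), init = value))
  }
  raw
}
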