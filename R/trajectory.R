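# The universal exchange object: a time grid (minutes) plus one value per
# time point (dimensionless signal or intact fraction).

#' Construct a trajectory
#'
#' @param times Time grid in minutes: strictly increasing, starting at 0,
#'   length >= 2.
#' @param values Signal or integrity values, same length as `times`.
#' @param glucose_mgdl Optional glucose annotation in mg/dL, carried through
#'   to exports.
#' @param kind Free-text label (`"signal"`, `"integrity"`, ...).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, values, glucose_mgdl = NA_real_, kind = "signal") {
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values), length(times) >= 2L,
            all(is.finite(times)), all(is.finite(values)))
  if (times[1] != 0) stop("trajectory must start at t = 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 glucose_mgdl = glucose_mgdl, kind = kind),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory:%s> %d points over [0, %.4g] min", x$kind,
              length(x$times), max(x$times)))
  if (is.finite(x$glucose_mgdl)) cat(sprintf(" at G = %.4g mg/dL", x$glucose_mgdl))
  cat(sprintf("; value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_min = x$times, value = x$values,
             glucose_mgdl = x$glucose_mgdl)
}

#' Write one or more trajectories to CSV
#'
#' Long format with columns `time_min`, `value`, `glucose_mgdl`.
#'
#' @param traj A `trajectory` or list of trajectories.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  if (inherits(traj, "trajectory")) traj <- list(traj)
  df <- do.call(rbind, lapply(traj, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Default time grid for simulations and figures
#'
#' 0 to 120 minutes at 0.5-minute resolution.
#'
#' @param t_max End time, minutes.
#' @param dt Grid spacing, minutes.
#' @return Numeric vector of times.
#' @export
default_times <- function(t_max = 120, dt = 0.5) {
  stopifnot(t_max > 0, dt > 0, dt <= t_max)
  seq(0, t_max, by = dt)
}

#' Default glucose panel in clinical units
#'
#' Covers the 70-300 mg/dL range and the clinical thresholds at 70, 100
#' and 126 mg/dL (hypoglycemic / normal / prediabetic boundaries).
#'
#' @return Numeric vector of glucose levels in mg/dL.
#' @export
default_glucose_panel <- function() c(70, 100, 126, 140, 200, 300)
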