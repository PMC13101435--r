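# Glucose unit conversion. Internally everything is mM; the clinical unit
# mg/dL is accepted only at interfaces. Glucose molar mass 180.16 g/mol,
# so 1 mM = 18.016 mg/dL.

#' Glucose molar-mass conversion factor
#'
#' Number of mg/dL per mM of glucose (molar mass 180.16 g/mol).
#' @export
GLUCOSE_MGDL_PER_MM <- 18.016

#' Construct a glucose level
#'
#' A glucose concentration in millimolar (mM), the governing unit of all
#' kinetic expressions in this package.
#'
#' @param value_mM Concentration in mM; must be a single non-negative number.
#' @return An object of class `glucose_level`.
#' @examples
#' glucose_level(5.55)
#' @export
glucose_level <- function(value_mM) {
  stopifnot(is.numeric(value_mM), length(value_mM) == 1L, is.finite(value_mM))
  if (value_mM < 0) {
    stop("glucose concentration must be non-negative, got ", value_mM)
  }
  structure(list(value_mM = as.numeric(value_mM)), class = "glucose_level")
}

#' @export
print.glucose_level <- function(x, ...) {
  cat(sprintf("<glucose> %.4g mM (%.4g mg/dL)\n",
              x$value_mM, mM_to_mgdl(x)))
  invisible(x)
}

#' Convert clinical glucose units to millimolar
#'
#' @param g Concentration in mg/dL (vectorised, non-negative).
#' @return For scalar input, a [glucose_level]; for vector input, a numeric
#'   vector in mM.
#' @examples
#' mgdl_to_mM(100)   # 5.55 mM
#' mgdl_to_mM(c(70, 100, 126))
#' @export
mgdl_to_mM <- function(g) {
  stopifnot(is.numeric(g), all(is.finite(g)))
  if (any(g < 0)) stop("glucose concentration in mg/dL must be non-negative")
  mM <- g / GLUCOSE_MGDL_PER_MM
  if (length(g) == 1L) glucose_level(mM) else mM
}

#' Convert millimolar glucose to clinical units
#'
#' Inverse of [mgdl_to_mM()]; the round trip is the identity to floating
#' precision.
#'
#' @param g A [glucose_level] or numeric vector in mM.
#' @return Concentration(s) in mg/dL.
#' @examples
#' mM_to_mgdl(mgdl_to_mM(100))  # 100
#' @export
mM_to_mgdl <- function(g) {
  g <- as_glucose_mM(g, scalar = FALSE)
  g * GLUCOSE_MGDL_PER_MM
}

# Coerce a glucose_level or bare numeric (interpreted as mM) to numeric mM.
as_glucose_mM <- function(g, scalar = TRUE) {
  if (inherits(g, "glucose_level")) return(g$value_mM)
  stopifnot(is.numeric(g), all(is.finite(g)), all(g >= 0))
  if (scalar) stopifnot(length(g) == 1L)
  as.numeric(g)
}
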