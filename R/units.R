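# Physical constants and unit conversions used across the package.
# Coordinates are always Angstrom, angles in the public API are degrees
# (radians internally), energies are kcal/mol for nonbonded terms and
# kJ/mol for torsional / free-energy profiles -- stated on every function.

#' Physical constants used by dockfit
#'
#' Centralised constants: the Coulomb prefactor in kcal A / (mol e^2), the
#' molar gas constant in kcal/(mol K) and kJ/(mol K), and the exact
#' thermochemical calorie conversion.
#'
#' @return Named list with elements `coulomb` (332.0636 kcal A mol^-1 e^-2),
#'   `R_kcal` (1.98720e-3 kcal mol^-1 K^-1), `R_kJ` (8.31446e-3
#'   kJ mol^-1 K^-1) and `kJ_per_kcal` (4.184).
#' @examples
#' dockfit_constants()$R_kcal
#' @export
dockfit_constants <- function() {
  list(
    coulomb     = 332.0636,
    R_kcal      = 1.98720e-3,
    R_kJ        = 8.31446e-3,
    kJ_per_kcal = 4.184
  )
}

#' Convert energies between kJ/mol and kcal/mol
#'
#' Uses the exact thermochemical factor 1 kcal = 4.184 kJ (so
#' 1 kJ/mol = 0.239006 kcal/mol); rounded display factors sometimes seen in
#' figure captions are never used internally.
#'
#' @param x Numeric vector of energies.
#' @return Numeric vector in the target unit.
#' @examples
#' kcal_to_kj(1)    # 4.184
#' kj_to_kcal(4.184) # 1
#' @export
kj_to_kcal <- function(x) x / 4.184

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * 4.184

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles; exactly -180 maps to 180.
#' @examples
#' wrap_angle(c(190, -180, 360))
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}
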