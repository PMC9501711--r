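# Dihedral distributions from trajectory samples and their Boltzmann
# inversion into Helmholtz free-energy profiles, Delta A(theta) =
# -kT ln(rho(theta)/rho0).

#' Bin dihedral samples into a periodic density
#'
#' Histograms angles on a periodic grid over (-180, 180] and normalizes to
#' a probability density per degree (`sum(density * bin_width) == 1`).
#' Bin centers sit at multiples of `bin_width`, so one bin straddles the
#' +/-180 degree seam and mass wrapping across it is never lost.
#'
#' @param angles Numeric vector of angles in degrees (any range; wrapped).
#' @param bin_width Bin width in degrees; must divide 360.
#' @return Tibble with columns `center` (degrees), `count`, `density`
#'   (per degree), and attribute `bin_width`.
#' @examples
#' dihedral_distribution(c(-179, 179, 180), bin_width = 5)
#' @export
dihedral_distribution <- function(angles, bin_width = 5) {
  if (360 %% bin_width != 0) abort("bin_width must divide 360")
  k <- 360 / bin_width
  a <- wrap_angle(angles)
  # centers at -180 + bin_width * (1..k); index by rounding to nearest center
  idx <- round((a + 180) / bin_width)
  idx[idx == 0L] <- k  # wrap: angles just above -180 share the +/-180 bin
  counts <- tabulate(idx, nbins = k)
  centers <- -180 + bin_width * seq_len(k)
  tibble(center = centers, count = counts,
         density = counts / (length(a) * bin_width)) |>
    structure(bin_width = bin_width)
}

#' Boltzmann inversion of a dihedral density
#'
#' Converts a binned probability density rho(theta) into a Helmholtz
#' free-energy profile `Delta A(theta) = -kT ln(rho(theta)/rho0)` where
#' rho0 is the maximum binned density, so the profile is zero at the modal
#' bin and nonnegative elsewhere.  Bins with zero counts are reported as
#' `NA` ("no sampling found for that geometry"), never imputed.
#'
#' @param density Tibble from [dihedral_distribution()] (columns `center`,
#'   `density`, optionally `count`).
#' @param temperature Temperature in K.
#' @return Object of class `free_energy_profile`: tibble with columns
#'   `center` (degrees), `delta_A` (kJ/mol or NA), `density`; attributes
#'   `temperature`, `rho0`, `bin_width`.
#' @examples
#' d <- dihedral_distribution(runif(1000, -180, 180), 10)
#' boltzmann_invert(d, 300)
#' @export
boltzmann_invert <- function(density, temperature) {
  if (temperature <= 0) abort("temperature must be positive")
  rho <- density$density
  if (all(rho == 0)) abort("all-zero density cannot be inverted")
  rho0 <- max(rho)
  kT <- dockfit_constants()$R_kJ * temperature  # kJ/mol
  dA <- ifelse(rho > 0, -kT * log(rho / rho0), NA_real_)
  out <- tibble(center = density$center, delta_A = dA, density = rho)
  structure(out, temperature = temperature, rho0 = rho0,
            bin_width = attr(density, "bin_width"),
            class = c("free_energy_profile", class(out)))
}

#' @describeIn boltzmann_invert One-row summary: temperature, number of
#'   defined bins, modal angle, barrier height (max defined `delta_A`).
#' @param x A `free_energy_profile`.
#' @param ... Unused.
#' @export
glance.free_energy_profile <- function(x, ...) {
  ok <- !is.na(x$delta_A)
  tibble(temperature = attr(x, "temperature"),
         n_bins = nrow(x), n_defined = sum(ok),
         modal_angle = x$center[which.max(x$density)],
         barrier = max(x$delta_A[ok]))
}

#' @describeIn boltzmann_invert Free-energy profile with undefined bins
#'   shown as gaps.
#' @param object A `free_energy_profile`.
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$center, y = .data$delta_A)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "dihedral angle (deg)",
                  y = expression(Delta * A ~ "(kJ/mol)"))
}

#' Compare an inverted free-energy profile with a torsional potential
#'
#' Evaluates the potential at the profile's bin centers, shifts it so its
#' minimum over the defined bins is zero, and reports maximum absolute
#' difference and RMSE over defined bins only (undefined bins are excluded,
#' never imputed).
#'
#' @param profile A [boltzmann_invert()] result.
#' @param term A [fourier_torsion()].
#' @return A `profile_comparison` (same shape as [profile_comparison()]).
#' @export
profile_vs_potential <- function(profile, term) {
  ok <- !is.na(profile$delta_A)
  v <- evaluate_torsion(term, profile$center[ok])
  v <- v - min(v)
  ref <- profile$delta_A[ok]
  delta <- v - ref
  structure(
    list(max_abs = max(abs(delta)), rmse = sqrt(mean(delta^2)),
         table = tibble(angle = profile$center[ok], reference = ref,
                        fitted = v, delta = delta)),
    class = "profile_comparison")
}
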