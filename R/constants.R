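#' Physical constants bundle for electrostatic calculations
#'
#' Collects the scalar constants used throughout the Poisson-Boltzmann
#' machinery: the Boltzmann scaling factor \eqn{k_B T}, the Coulomb constant
#' in kcal A / (mol e^2), and the bulk ionic strength entering the
#' linearized screening term.
#'
#' @param temperature Simulation temperature in Kelvin. Default 310 K.
#' @param ionic_strength Bulk 1:1 electrolyte concentration in mol/L
#'   (default 0.15 M).
#' @param coulomb_constant Coulomb prefactor in kcal A / (mol e^2);
#'   default 332.06.
#' @param kbt Boltzmann scaling factor in kcal/mol. Defaults to
#'   \code{0.0019872 * temperature}; pass an explicit value (e.g. 0.593 for
#'   ambient-temperature worked examples) to override.
#'
#' @return An object of class \code{pb_constants}: a list with elements
#'   \code{temperature}, \code{kbt}, \code{kbt_mv} (thermal voltage
#'   \eqn{k_B T / e} in millivolts), \code{coulomb_constant} and
#'   \code{ionic_strength}.
#'
#' @details \code{kbt_mv} converts via 1 kcal/(mol e) = 1000/23.0605 mV.
#'   At 310 K, \code{kbt} is 0.616 kcal/mol (rounding to 0.62) and
#'   \code{kbt_mv} is 26.7 mV (rounding to 27 mV), the scale below which
#'   the linearization of the Boltzmann factor is accurate.
#'
#' @examples
#' cst <- pb_constants()
#' round(cst$kbt, 2)    # 0.62 kcal/mol
#' round(cst$kbt_mv)    # 27 mV
#' @export
pb_constants <- function(temperature = 310, ionic_strength = 0.15,
                         coulomb_constant = 332.06, kbt = NULL) {
  stopifnot(temperature > 0, ionic_strength >= 0, coulomb_constant > 0)
  if (is.null(kbt)) kbt <- 0.0019872 * temperature
  structure(list(
    temperature      = temperature,
    kbt              = kbt,
    kbt_mv           = kbt * 1000 / 23.0605,
    coulomb_constant = coulomb_constant,
    ionic_strength   = ionic_strength
  ), class = "pb_constants")
}

#' @export
print.pb_constants <- function(x, ...) {
  cat(sprintf("Poisson-Boltzmann constants: T = %g K, kBT = %.4g kcal/mol (%.3g mV), ",
              x$temperature, x$kbt, x$kbt_mv))
  cat(sprintf("C = %g kcal*A/(mol*e^2), I = %g M\n",
              x$coulomb_constant, x$ionic_strength))
  invisible(x)
}

# mobile-ion screening coefficient kappa_bar^2 [A^-2 * eps units] such that
# the linearized PB reads  div(eps grad phi) - kappa_bar^2 phi = -4 pi C rho.
# For a z:z electrolyte at molarity I:  sum_i z_i^2 n_i with n in A^-3.
screening_coefficient <- function(constants) {
  n_per_A3 <- constants$ionic_strength * 6.02214076e23 / 1e27
  sum_z2n <- 2 * n_per_A3            # 1:1 electrolyte, z^2 = 1 both species
  4 * pi * constants$coulomb_constant * sum_z2n / constants$kbt
}
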