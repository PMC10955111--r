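#' Physical constants used throughout the package
#'
#' Single authority for unit conversions in the pipeline: every other module
#' obtains its conversion factors from here. Energies are carried in
#' kcal/mol, trajectory times in ps, rate constants in 1/s, and spectroscopic
#' frequencies in 1/cm.
#'
#' @return A list with components:
#'   \describe{
#'     \item{kB}{Boltzmann constant, kcal/mol/K.}
#'     \item{h}{Planck constant, kcal/mol * s (per-mole convention, so that
#'       `kB * T / h` is the Eyring prefactor in 1/s).}
#'     \item{c_cm_per_ps}{Speed of light in cm/ps.}
#'     \item{kcal_to_amuA2ps2}{1 kcal/mol expressed in amu * Angstrom^2 / ps^2
#'       (= 418.4), the internal dynamical energy unit.}
#'     \item{ps_to_s}{1 ps in seconds (1e-12); applied exactly once, at the
#'       rate-assembly boundary.}
#'   }
#' @examples
#' const <- lk_constants()
#' const$kB * 300 / const$h   # Eyring prefactor at 300 K, about 6.25e12 1/s
#' @export
lk_constants <- function() {
  list(
    kB = 1.987204259e-3,
    h = 6.62607015e-34 * 6.02214076e23 / 4184,
    c_cm_per_ps = 0.0299792458,
    kcal_to_amuA2ps2 = 418.4,
    ps_to_s = 1e-12
  )
}

#' Validate a temperature in kelvin
#'
#' @param temperature Temperature in K; must be a single strictly positive,
#'   finite number.
#' @return The temperature, invisibly, after validation.
#' @keywords internal
check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single finite value > 0 (kelvin)",
         call. = FALSE)
  }
  invisible(temperature)
}

#' Thermal energy kB*T in both energy unit systems
#'
#' @param temperature Temperature, K.
#' @return List with `kcal` (kcal/mol) and `amu` (amu * Angstrom^2 / ps^2),
#'   consistent under the package conversion factor.
#' @examples
#' thermal_energy(300)$kcal   # 0.59616 kcal/mol
#' @export
thermal_energy <- function(temperature) {
  check_temperature(temperature)
  const <- lk_constants()
  kcal <- const$kB * temperature
  list(kcal = kcal, amu = kcal * const$kcal_to_amuA2ps2)
}

#' Convert an angular frequency to a spectroscopic wavenumber
#'
#' Reactive and equilibrium barrier frequencies are reported in 1/cm, the
#' convention used for barrier and friction amplitudes (for example an
#' equilibrium barrier frequency of 409 1/cm). The conversion is
#' `omega / (2 * pi * c)` with `c` in cm/ps.
#'
#' @param omega Angular frequency, rad/ps; must be >= 0.
#' @return Wavenumber in 1/cm.
#' @seealso [wavenumber_to_omega()] for the inverse.
#' @examples
#' omega_to_wavenumber(2 * pi * 0.0299792458)  # 1 cm^-1
#' wavenumber_to_omega(409)                    # 77.04 rad/ps
#' @export
omega_to_wavenumber <- function(omega) {
  stopifnot(is.numeric(omega))
  if (any(omega < 0)) stop("angular frequency must be >= 0", call. = FALSE)
  const <- lk_constants()
  omega / (2 * pi * const$c_cm_per_ps)
}

#' Convert a spectroscopic wavenumber to an angular frequency
#'
#' @param nu Wavenumber, 1/cm; must be >= 0.
#' @return Angular frequency in rad/ps.
#' @export
wavenumber_to_omega <- function(nu) {
  stopifnot(is.numeric(nu))
  if (any(nu < 0)) stop("wavenumber must be >= 0", call. = FALSE)
  const <- lk_constants()
  nu * 2 * pi * const$c_cm_per_ps
}
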