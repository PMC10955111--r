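# Boltzmann-weighted integral of a profile over a sub-range, trapezoidal on
# the profile grid with an interpolated endpoint at the range boundary.
# Returns the integral of C_s^-1 exp(-G/kBT) ds.
.boltzmann_integral <- function(profile, lo, hi, kT) {
  g <- profile$grid
  sel <- g > lo & g < hi
  if (!any(sel)) stop("empty integration range", call. = FALSE)
  if (anyNA(profile$G[sel])) {
    stop("unvisited bins inside the integration range [", signif(lo, 4),
         ", ", signif(hi, 4), "]; no extrapolation is performed",
         call. = FALSE)
  }
  s <- g[sel]
  y <- exp(-profile$G[sel] / kT)
  # close the range with interpolated boundary points where possible
  gfun <- stats::approxfun(g[!is.na(profile$G)], profile$G[!is.na(profile$G)])
  if (lo > min(g) && !is.na(gfun(lo))) {
    s <- c(lo, s)
    y <- c(exp(-gfun(lo) / kT), y)
  }
  if (hi < max(g) && !is.na(gfun(hi))) {
    s <- c(s, hi)
    y <- c(y, exp(-gfun(hi) / kT))
  }
  pracma::trapz(s, y) / profile$C_s
}

#' Equilibrium constant from a free-energy profile
#'
#' `K_eq = Z_open / Z_closed` with each state partition function obtained by
#' integrating `C_s^-1 exp(-G/kBT)` over its side of the dividing surface
#' (open: s > s_star; closed: s < s_star). Bounds are configurable for
#' state definitions narrower than a full side.
#'
#' @param profile An `lk_fep` (or [path_energy_profile()] output).
#' @param s_star Dividing surface position on s.
#' @param temperature Temperature, K (default: the profile's own).
#' @param closed_range,open_range Optional integration bounds
#'   `c(lo, hi)` overriding the default split at `s_star`.
#' @return Dimensionless K_eq (open over closed).
#' @export
equilibrium_constant <- function(profile, s_star, temperature = NULL,
                                 closed_range = NULL, open_range = NULL) {
  temperature <- temperature %||% profile$temperature
  check_temperature(temperature)
  g <- profile$grid
  if (s_star <= min(g) || s_star >= max(g)) {
    stop("s_star must lie strictly inside the profile grid", call. = FALSE)
  }
  kT <- thermal_energy(temperature)$kcal
  closed_range <- closed_range %||% c(min(g) - 1, s_star)
  open_range <- open_range %||% c(s_star, max(g) + 1)
  z_closed <- .boltzmann_integral(profile, closed_range[1], closed_range[2],
                                  kT)
  z_open <- .boltzmann_integral(profile, open_range[1], open_range[2], kT)
  z_open / z_closed
}

#' Mean absolute thermal velocity of the path coordinate
#'
#' One-dimensional Maxwell-Boltzmann mean speed
#' `sqrt(2 kBT / (pi * mu))` with kBT in dynamical units, so the result is
#' in amu^1/2 * Angstrom / ps.
#'
#' @param mu Reduced mass of the reaction coordinate at the TS
#'   (dimensionless in weighted-CV units).
#' @param temperature Temperature, K.
#' @return Mean |ds/dt|, amu^1/2 * A / ps.
#' @export
mean_abs_velocity <- function(mu, temperature = 300) {
  stopifnot(mu > 0)
  check_temperature(temperature)
  sqrt(2 * thermal_energy(temperature)$amu / (pi * mu))
}

#' Transition-state-theory rate constant from the profile
#'
#' Equilibrium flux across the dividing surface at `s_star`:
#' `k_TST = 0.5 * <|ds/dt|> * C_s^-1 * exp(-dG_act / kBT)` with the
#' activation free energy measured from the reactant-side ensemble,
#' `dG_act = G(s_star) + kBT * ln( C_s^-1 * integral_reactant
#' exp(-G/kBT) ds )`. The reactant side is the full side of the dividing
#' surface selected by `direction` ("opening": reactants closed, s <
#' s_star). The ps -> s conversion is applied here, once.
#'
#' @inheritParams equilibrium_constant
#' @param mu Reduced mass of the reaction coordinate at the TS.
#' @param direction "opening" (closed -> open) or "closing".
#' @param reactant_range Optional override of the reactant integration
#'   bounds.
#' @return List: `k_TST` (1/s), `dG_act` (kcal/mol), `prefactor_ps`
#'   (1/ps), `mean_abs_velocity`.
#' @export
tst_rate <- function(profile, s_star, mu, temperature = NULL,
                     direction = c("opening", "closing"),
                     reactant_range = NULL) {
  direction <- match.arg(direction)
  temperature <- temperature %||% profile$temperature
  check_temperature(temperature)
  stopifnot(mu > 0)
  g <- profile$grid
  if (s_star <= min(g) || s_star >= max(g)) {
    stop("s_star must lie strictly inside the profile grid", call. = FALSE)
  }
  kT <- thermal_energy(temperature)$kcal
  # sanity: s_star should top the profile locally
  win <- abs(g - s_star) <= max(4 * profile$bin_width, 0.1)
  if (any(win) && !anyNA(profile$G[win])) {
    if (max(profile$G[win]) > stats::approx(g[!is.na(profile$G)],
                                            profile$G[!is.na(profile$G)],
                                            xout = s_star)$y + 1e-4) {
      warning("s_star is not the local maximum of G within the TS window")
    }
  }
  reactant_range <- reactant_range %||%
    (if (direction == "opening") c(min(g) - 1, s_star) else
       c(s_star, max(g) + 1))
  z_r <- .boltzmann_integral(profile, reactant_range[1], reactant_range[2],
                             kT)
  gfun <- stats::approxfun(g[!is.na(profile$G)],
                           profile$G[!is.na(profile$G)])
  g_ts <- gfun(s_star)
  dG_act <- g_ts + kT * log(z_r)
  const <- lk_constants()
  vbar <- mean_abs_velocity(mu, temperature)
  pref_ps <- 0.5 * vbar / profile$C_s
  k <- pref_ps / const$ps_to_s * exp(-dG_act / kT)
  list(k_TST = k, dG_act = dG_act, prefactor_ps = pref_ps,
       mean_abs_velocity = vbar)
}

#' Reaction and activation free energies from constants
#'
#' `dG_eq = -kBT ln K_eq`; the phenomenological activation free energy via
#' the Eyring form `dG_act = -kBT ln( k h / kBT )`; and the friction
#' contribution `dG_kappa = -kBT ln kappa`. Note the Eyring prefactor
#' kBT/h used here is definitional and differs from the flux prefactor of
#' [tst_rate()].
#'
#' @param k Rate constant, 1/s (optional).
#' @param kappa Transmission coefficient in (0, 1] (optional).
#' @param K_eq Equilibrium constant (optional).
#' @param temperature Temperature, K.
#' @return List with `dG_eq`, `dG_act`, `dG_kappa` (kcal/mol; NA for
#'   quantities whose input was not given).
#' @export
free_energies <- function(k = NULL, kappa = NULL, K_eq = NULL,
                          temperature = 300) {
  check_temperature(temperature)
  const <- lk_constants()
  kT <- const$kB * temperature
  dG_eq <- dG_act <- dG_kappa <- NA_real_
  if (!is.null(K_eq)) {
    stopifnot(K_eq > 0)
    dG_eq <- -kT * log(K_eq)
  }
  if (!is.null(k)) {
    stopifnot(k > 0)
    dG_act <- -kT * log(k * const$h / kT)
  }
  if (!is.null(kappa)) {
    if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
    if (kappa > 1) stop("kappa > 1 is unphysical for a transmission ",
                        "coefficient", call. = FALSE)
    dG_kappa <- -kT * log(kappa)
  }
  list(dG_eq = dG_eq, dG_act = dG_act, dG_kappa = dG_kappa)
}

#' Combine serial (sequential) rate processes
#'
#' Overall rate of two processes in series (for loop opening: diffusive
#' displacement and activated conformational change):
#' `1/k = 1/k_dis + 1/k_conf`.
#'
#' @param k_dis,k_conf Rates, 1/s (> 0).
#' @return Combined rate, 1/s; never exceeds the slower input.
#' @export
combine_serial_rates <- function(k_dis, k_conf) {
  if (any(c(k_dis, k_conf) <= 0)) {
    stop("rates must be strictly positive", call. = FALSE)
  }
  1 / (1 / k_dis + 1 / k_conf)
}

#' Full rate/equilibrium bookkeeping for a loop transition
#'
#' Computes the equilibrium constant, both TST rates, the friction-corrected
#' rates `k = kappa * k_TST` and all derived free energies from one profile.
#' Opening and closing rates are built from the same state integrals, so
#' detailed balance `K_eq = k_opening / k_closing` holds to rounding.
#'
#' @inheritParams tst_rate
#' @param kappa Transmission coefficient in (0, 1] (default 1 = pure TST).
#' @return A `lk_rates` list: `K_eq`, `k_TST_opening`, `k_TST_closing`,
#'   `k_opening`, `k_closing`, `mean_abs_velocity`, `dG_eq`,
#'   `dG_act_opening`, `dG_act_closing`, `dG_kappa`, `temperature`, `mu`,
#'   `s_star`.
#' @export
loop_rates <- function(profile, s_star, mu, temperature = NULL, kappa = 1) {
  temperature <- temperature %||% profile$temperature
  if (kappa <= 0 || kappa > 1) {
    stop("kappa must be in (0, 1]", call. = FALSE)
  }
  opening <- tst_rate(profile, s_star, mu, temperature, "opening")
  closing <- tst_rate(profile, s_star, mu, temperature, "closing")
  kT <- thermal_energy(temperature)$kcal
  # same integrals as the rates, so K_eq = k_opening / k_closing exactly
  K_eq <- exp((closing$dG_act - opening$dG_act) / kT)
  k_op <- kappa * opening$k_TST
  k_cl <- kappa * closing$k_TST
  fe_op <- free_energies(k = k_op, kappa = kappa, K_eq = K_eq,
                         temperature = temperature)
  fe_cl <- free_energies(k = k_cl, temperature = temperature)
  structure(list(K_eq = K_eq,
                 k_TST_opening = opening$k_TST,
                 k_TST_closing = closing$k_TST,
                 k_opening = k_op, k_closing = k_cl,
                 kappa = kappa,
                 mean_abs_velocity = opening$mean_abs_velocity,
                 dG_eq = fe_op$dG_eq,
                 dG_act_opening = fe_op$dG_act,
                 dG_act_closing = fe_cl$dG_act,
                 dG_act_s_opening = opening$dG_act,
                 dG_act_s_closing = closing$dG_act,
                 dG_kappa = fe_op$dG_kappa,
                 temperature = temperature, mu = mu, s_star = s_star),
            class = "lk_rates")
}

#' @export
print.lk_rates <- function(x, ...) {
  cat("Loop kinetics: K_eq =", signif(x$K_eq, 4),
      "| k_opening =", signif(x$k_opening, 4), "1/s",
      "| k_closing =", signif(x$k_closing, 4), "1/s",
      "| kappa =", signif(x$kappa, 4), "\n")
  invisible(x)
}
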