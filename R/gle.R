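#' Exponential memory-bath component
#'
#' One component of the friction kernel: contributes
#' `xi_i(t) = coupling * exp(-t / tau)` (ps^-2) to the total memory kernel
#' felt by the path coordinate. Labels name the physical origin of the
#' component (for example `"backbone_torsion"` or `"solvent"`), mirroring
#' the decomposition of friction into force-field contributions.
#'
#' @param label Unique component name.
#' @param coupling Kernel amplitude A, ps^-2 (>= 0).
#' @param tau Relaxation time, ps (> 0).
#' @return A `lk_bath` object.
#' @export
bath_mode <- function(label, coupling, tau) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.numeric(coupling), length(coupling) == 1L, coupling >= 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(label = label, coupling = coupling, tau = tau),
            class = "lk_bath")
}

#' Generalized Langevin model of loop dynamics along the path coordinate
#'
#' Couples one-dimensional motion on a free-energy profile G(s) to a set of
#' exponential memory baths (realized exactly through auxiliary
#' Ornstein-Uhlenbeck variables) and, optionally, a memoryless white-noise
#' friction. This is the synthetic stand-in for the all-atom dynamics of a
#' loop: the profile carries the torsional barrier and basin structure, the
#' baths carry the time-dependent friction.
#'
#' @param profile The free-energy profile along s: an analytic
#'   [double_well_1d()] object, a WHAM [wham()] profile, or a plain function
#'   `G(s)` in kcal/mol.
#' @param baths List of [bath_mode()] components (possibly empty).
#' @param mass Reduced mass of the path coordinate in weighted-CV units
#'   (dimensionless, near 1; e.g. 0.917 for the PTP1B-like configuration).
#' @param dt Integration timestep, ps. Must resolve the fastest bath:
#'   `dt < 0.1 * min(tau)` is enforced.
#' @param temperature Temperature, K.
#' @param seed Master seed; per-trajectory seeds are derived
#'   deterministically from it.
#' @param gamma0 Optional memoryless friction, ps^-1 (plain Langevin term).
#' @param s_range Simulation range of s; defaults to the profile's own.
#' @param n_grid Resolution of the internal force table.
#' @return A `lk_gle_model` object.
#' @export
gle_model <- function(profile, baths = list(), mass = 1, dt = 0.002,
                      temperature = 300, seed = 1, gamma0 = 0,
                      s_range = NULL, n_grid = 4001) {
  check_temperature(temperature)
  stopifnot(is.numeric(mass), mass > 0, is.numeric(dt), dt > 0,
            is.numeric(gamma0), gamma0 >= 0, n_grid >= 2)
  if (inherits(baths, "lk_bath")) baths <- list(baths)
  labels <- vapply(baths, function(b) b$label, character(1))
  if (anyDuplicated(labels)) stop("bath labels must be unique", call. = FALSE)
  taus <- vapply(baths, function(b) b$tau, numeric(1))
  if (length(taus) && dt >= 0.1 * min(taus)) {
    stop("dt = ", dt, " ps does not resolve the fastest bath (tau = ",
         min(taus), " ps); require dt < 0.1 * min(tau)", call. = FALSE)
  }
  if (is.null(s_range)) {
    if (inherits(profile, "lk_profile_fun")) {
      s_range <- profile$s_range
    } else if (inherits(profile, "lk_fep")) {
      s_range <- range(profile$grid)
    } else {
      stop("`s_range` must be given for a plain-function profile",
           call. = FALSE)
    }
  }
  stopifnot(length(s_range) == 2, s_range[1] < s_range[2])

  const <- lk_constants()
  grid <- seq(s_range[1], s_range[2], length.out = n_grid)
  if (inherits(profile, "lk_profile_fun")) {
    g_kcal <- profile_energy(profile, grid)
    f_amu <- -profile_force(profile, grid) * const$kcal_to_amuA2ps2
  } else {
    if (inherits(profile, "lk_fep")) {
      sp <- stats::splinefun(profile$grid, profile$G, method = "natural")
      gfun <- sp
    } else if (is.function(profile)) {
      gfun <- profile
    } else {
      stop("unsupported profile type", call. = FALSE)
    }
    g_kcal <- gfun(grid)
    h <- grid[2] - grid[1]
    dg <- (gfun(grid + h / 2) - gfun(grid - h / 2)) / h
    f_amu <- -dg * const$kcal_to_amuA2ps2
  }

  structure(list(profile = profile, baths = baths, labels = labels,
                 mass = mass, dt = dt, temperature = temperature,
                 seed = seed, gamma0 = gamma0, s_range = s_range,
                 grid = grid, g_kcal = g_kcal, force_amu = f_amu),
            class = "lk_gle_model")
}

#' @export
print.lk_gle_model <- function(x, ...) {
  cat("GLE loop model: mass", x$mass, "| dt", x$dt, "ps | T",
      x$temperature, "K |", length(x$baths), "bath(s)")
  if (length(x$baths)) {
    xi0 <- sum(vapply(x$baths, function(b) b$coupling, numeric(1)))
    cat(" | xi(0) =", signif(xi0, 4), "ps^-2")
  }
  cat("\n")
  invisible(x)
}

#' Deterministic per-trajectory seed derivation
#'
#' @param master Master seed (integer-like).
#' @param i Trajectory index.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.double(master) %% 2147483647 * 48271 + i * 69621) %%
               2147483647)
}

#' Draw an equilibrium initial state for a GLE model
#'
#' Velocity from the Maxwell-Boltzmann distribution, auxiliary bath
#' variables from their stationary Gaussians.
#'
#' @param model A [gle_model()].
#' @param s Initial position (defaults to the profile minimum).
#' @return List with `s`, `v`, `z` (uses the current R RNG stream).
#' @export
draw_initial_state <- function(model, s = NULL) {
  kT <- thermal_energy(model$temperature)$amu
  if (is.null(s)) s <- model$grid[which.min(model$g_kcal)]
  v <- stats::rnorm(1, 0, sqrt(kT / model$mass))
  z <- vapply(model$baths, function(b) {
    stats::rnorm(1, 0, sqrt(kT * b$coupling / model$mass))
  }, numeric(1))
  list(s = s, v = v, z = as.numeric(z))
}

.model_AB <- function(model) {
  list(A = vapply(model$baths, function(b) b$coupling, numeric(1)),
       tau = vapply(model$baths, function(b) b$tau, numeric(1)))
}

.make_trajectory <- function(model, raw, sample_every, bias, n_equil_samp = 0) {
  keep <- seq.int(n_equil_samp + 1L, length(raw$s))
  nb <- length(model$baths)
  fb <- if (nb > 0) {
    matrix(raw$z, ncol = nb)[keep, , drop = FALSE] * model$mass
  } else {
    matrix(numeric(0), nrow = length(keep), ncol = 0)
  }
  cols <- data.frame(s = raw$s[keep], v = raw$v[keep],
                     f_landscape = raw$f_pot[keep])
  if (nb > 0) {
    colnames(fb) <- paste0("f_", model$labels)
    cols <- cbind(cols, as.data.frame(fb))
  }
  if (!is.null(bias) && bias$type == "harmonic") {
    cols$f_bias <- -bias$k_amu * (cols$s - bias$center)
  }
  fsum <- cols$f_landscape
  if (nb > 0) fsum <- fsum + rowSums(fb)
  if (!is.null(cols$f_bias)) fsum <- fsum + cols$f_bias
  cols$f_total <- fsum
  structure(list(
    dt = model$dt * sample_every,
    time = (seq_along(keep) - 1) * model$dt * sample_every,
    columns = cols,
    length = length(keep),
    metadata = list(temperature = model$temperature, mass = model$mass,
                    seed = raw$seed_used, dt_integration = model$dt,
                    bias = if (is.null(bias)) list(type = "none") else bias,
                    bath_labels = model$labels),
    final_state = raw$state
  ), class = "lk_trajectory")
}

#' @export
print.lk_trajectory <- function(x, ...) {
  cat("GLE trajectory:", x$length, "samples @", x$dt, "ps | bias:",
      x$metadata$bias$type, "\n")
  invisible(x)
}

.probe_stability <- function(model, init) {
  # 1000-step frictionless probe: energy drift beyond 0.5 kBT flags an
  # unstable timestep for this landscape
  kT <- thermal_energy(model$temperature)$amu
  raw <- .gle_integrate_cpp(model$grid, model$force_amu, model$mass, kT,
                            numeric(0), numeric(0), 0,
                            model$dt, 1000L, 1L,
                            init$s, init$v, numeric(0),
                            0, 0, FALSE, 1)
  gfun <- stats::approxfun(model$grid, model$g_kcal, rule = 2)
  const <- lk_constants()
  e <- 0.5 * model$mass * raw$v^2 + gfun(raw$s) * const$kcal_to_amuA2ps2
  drift <- max(abs(e - e[1]))
  if (!is.finite(drift) || drift > 0.5 * kT) {
    stop("unstable integration: energy drift ", signif(drift / kT, 3),
         " kBT over a 1000-step probe; reduce dt (currently ", model$dt,
         " ps)", call. = FALSE)
  }
  invisible(drift)
}

#' Simulate a GLE trajectory
#'
#' Integrates the generalized Langevin dynamics of the path coordinate with
#' a symmetric splitting: velocity-Verlet for the deterministic part and the
#' exact Ornstein-Uhlenbeck propagator for each bath substep. A fixed seed
#' gives bit-identical output. A short frictionless probe aborts with a
#' diagnostic if the timestep is unstable on the given landscape.
#'
#' @param model A [gle_model()].
#' @param n_steps Number of integration steps.
#' @param init Initial state `list(s, v, z)`; default drawn by
#'   [draw_initial_state()] under the model seed.
#' @param sample_every Record every this many steps.
#' @param seed Integration seed; defaults to the model seed.
#' @param check_stability Run the 1000-step energy-drift probe first.
#' @return An `lk_trajectory` whose `columns` hold `s`, `v` (s-velocity,
#'   amu^1/2 A/ps), the landscape force, one force column per bath label
#'   (internal amu A/ps^2 units, mass-weighted frame) and their exact sum
#'   `f_total`.
#' @export
simulate_gle <- function(model, n_steps, init = NULL, sample_every = 1L,
                         seed = NULL, check_stability = TRUE) {
  stopifnot(inherits(model, "lk_gle_model"))
  if (is.null(seed)) seed <- model$seed
  if (is.null(init)) {
    set.seed(derive_seed(seed, 0L))
    init <- draw_initial_state(model)
  }
  if (init$s < model$s_range[1] || init$s > model$s_range[2]) {
    stop("initial s outside the model range", call. = FALSE)
  }
  if (check_stability) .probe_stability(model, init)
  kT <- thermal_energy(model$temperature)$amu
  ab <- .model_AB(model)
  raw <- .gle_integrate_cpp(model$grid, model$force_amu, model$mass, kT,
                            ab$A, ab$tau, model$gamma0,
                            model$dt, as.integer(n_steps),
                            as.integer(sample_every),
                            init$s, init$v, init$z,
                            0, 0, FALSE, derive_seed(seed, 1L))
  raw$seed_used <- seed
  .make_trajectory(model, raw, sample_every, NULL)
}

#' Sample an umbrella window along the path coordinate
#'
#' Adds a harmonic bias `0.5 * k_umb * (s - center)^2` to the model forces
#' and records the biased s series after an equilibration stretch.
#'
#' @param model A [gle_model()].
#' @param center Window center on s.
#' @param k_umb Bias stiffness, kcal/mol per s-unit^2 (> 0).
#' @param n_steps Production steps.
#' @param n_equil Discarded equilibration steps.
#' @param sample_every Record every this many steps.
#' @param seed Window seed; defaults to the model seed.
#' @param bin_width Used only to warn when the bias is so stiff that the
#'   window variance falls below one histogram bin.
#' @return An `lk_trajectory` with bias metadata.
#' @export
sample_biased_window <- function(model, center, k_umb, n_steps,
                                 n_equil = 2000L, sample_every = 1L,
                                 seed = NULL, bin_width = 0.05) {
  stopifnot(inherits(model, "lk_gle_model"), k_umb > 0)
  if (center < model$s_range[1] || center > model$s_range[2]) {
    stop("window center ", center, " outside the path range [",
         model$s_range[1], ", ", model$s_range[2], "]", call. = FALSE)
  }
  kT_kcal <- thermal_energy(model$temperature)$kcal
  if (kT_kcal / k_umb < bin_width^2) {
    warning("stiff bias: window variance kBT/k_umb = ",
            signif(kT_kcal / k_umb, 3), " below bin_width^2; ",
            "sampling is degenerate at this bin width")
  }
  if (is.null(seed)) seed <- model$seed
  const <- lk_constants()
  kT <- thermal_energy(model$temperature)$amu
  ab <- .model_AB(model)
  set.seed(derive_seed(seed, 2L))
  init <- draw_initial_state(model, s = center)
  bias <- list(type = "harmonic", k_umb = k_umb, center = center,
               k_amu = k_umb * const$kcal_to_amuA2ps2)
  n_tot <- as.integer(n_equil + n_steps)
  raw <- .gle_integrate_cpp(model$grid, model$force_amu, model$mass, kT,
                            ab$A, ab$tau, model$gamma0,
                            model$dt, n_tot, as.integer(sample_every),
                            init$s, init$v, init$z,
                            bias$k_amu, center, FALSE, derive_seed(seed, 3L))
  raw$seed_used <- seed
  .make_trajectory(model, raw, sample_every, bias,
                   n_equil_samp = as.integer(n_equil) %/%
                     as.integer(sample_every))
}

#' Sample the transition-state ensemble with s constrained
#'
#' Holds the path coordinate fixed on the dividing surface and records the
#' fluctuating projected force exerted by each bath component, the input of
#' the friction-kernel estimator. With s constrained the auxiliary bath
#' variables evolve as free Ornstein-Uhlenbeck processes, so the projected
#' force autocorrelation of component i is exactly
#' `m * kBT * A_i * exp(-t/tau_i)`.
#'
#' @param model A [gle_model()].
#' @param s_star Constrained value of s (the TS position).
#' @param n_trajectories Number of independent TS trajectories (default 60).
#' @param n_steps Steps per trajectory.
#' @param sample_every Record every this many steps.
#' @param seed Ensemble seed; defaults to the model seed.
#' @return List of `lk_trajectory` objects, each with `bias$type =
#'   "ts_constraint"`.
#' @export
sample_ts_constrained <- function(model, s_star, n_trajectories = 60L,
                                  n_steps = 50000L, sample_every = 1L,
                                  seed = NULL) {
  stopifnot(inherits(model, "lk_gle_model"), n_trajectories >= 1)
  if (s_star < model$s_range[1] || s_star > model$s_range[2]) {
    stop("s_star outside the path range", call. = FALSE)
  }
  if (is.null(seed)) seed <- model$seed
  kT <- thermal_energy(model$temperature)$amu
  ab <- .model_AB(model)
  lapply(seq_len(n_trajectories), function(i) {
    set.seed(derive_seed(seed, 10L + 2L * i))
    init <- draw_initial_state(model, s = s_star)
    raw <- .gle_integrate_cpp(model$grid, model$force_amu, model$mass, kT,
                              ab$A, ab$tau, 0,
                              model$dt, as.integer(n_steps),
                              as.integer(sample_every),
                              s_star, 0, init$z,
                              0, 0, TRUE, derive_seed(seed, 11L + 2L * i))
    drift <- max(abs(raw$s - s_star))
    if (drift > 1e-6) {
      stop("TS constraint drift ", drift, " exceeds 1e-6", call. = FALSE)
    }
    raw$seed_used <- derive_seed(seed, 10L + 2L * i)
    .make_trajectory(model, raw, sample_every,
                     list(type = "ts_constraint", s_star = s_star))
  })
}
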