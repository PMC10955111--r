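#' Wrap angles into the principal branch (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Wrapped angles in degrees.
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 to -180; convention here is (-180, 180]
  w[w == -180] <- 180
  w
}

#' Periodic difference a - b wrapped into (-180, 180]
#'
#' @param a,b Angles in degrees.
#' @return Wrapped difference in degrees.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# Smooth periodic squared-displacement surrogate, in deg^2:
# q(delta) = 2 (180/pi)^2 (1 - cos(delta * pi/180)), with q ~ delta^2 near 0,
# smooth everywhere and 360-periodic. Its derivative wrt delta (deg) is
# 2 (180/pi) sin(delta * pi/180).
.q_per <- function(delta_deg) {
  r <- delta_deg * pi / 180
  2 * (180 / pi)^2 * (1 - cos(r))
}
.dq_per <- function(delta_deg) {
  r <- delta_deg * pi / 180
  2 * (180 / pi) * sin(r)
}

#' Model free-energy landscape for a loop open/close transition
#'
#' Builds an analytic, 360-degree-periodic free-energy surface over the two
#' backbone torsions that flip when the key peptide group rotates (a psi-like
#' and a phi-like angle), emulating the structure seen in loop transitions:
#' two basins (closed, open) separated by a sharp torsional barrier, an open
#' basin wider than the closed one, optional torsion-torsion coupling, an
#' optional high-energy intermediate (three-state variant, as for the DHFR
#' M20 loop), and optional diffusive distance coordinates with mild
#' ruggedness (salt-bridge making/breaking, at most a couple of kcal/mol).
#'
#' Basins are smooth periodic harmonic wells combined through a soft-min
#' (log-sum-exp) so the surface and its gradient are analytic everywhere;
#' the torsional barrier is a periodic Gaussian bump on the saddle.
#'
#' @param torsion_barrier_height Barrier height of the torsional flip,
#'   kcal/mol. Default 12, the sharp-barrier regime.
#' @param basin_centers List with `closed` and `open`, each c(psi, phi) in
#'   degrees.
#' @param well_stiffness Curvature of the closed basin, kcal/mol/deg^2.
#' @param open_basin_width_scale Ratio of open to closed basin widths
#'   (dimensionless, >= 1); the open valley is entropically wider.
#' @param barrier_width Width (degrees) of the Gaussian barrier bump.
#' @param coupling_strength Torsion-torsion coupling at the barrier,
#'   kcal/mol/deg^2 (bilinear in the displacements from the saddle).
#' @param n_states 2 or 3; 3 inserts a high-energy intermediate basin
#'   between the barrier and the open state, guarded by a second bump.
#' @param intermediate_offset Free energy of the intermediate minimum above
#'   the main basins, kcal/mol (three-state only).
#' @param distance_roughness_amplitude Amplitude of the sinusoidal
#'   ruggedness on distance coordinates, kcal/mol (<= ~2).
#' @param n_distances Number of distance coordinates appended (default 0).
#' @param distance_center,distance_stiffness,distance_period Confinement
#'   center (Angstrom), stiffness (kcal/mol/A^2) and ruggedness period (A)
#'   of each distance coordinate.
#' @param softmin_gamma Smoothing (kcal/mol) of the soft-min combination.
#' @return An object of class `lk_landscape`.
#' @examples
#' ls2 <- landscape_spec()
#' landscape_energy(ls2, c(-40, -60))   # closed basin floor
#' @export
landscape_spec <- function(torsion_barrier_height = 12,
                           basin_centers = list(closed = c(-40, -60),
                                                open = c(130, 110)),
                           well_stiffness = 0.004,
                           open_basin_width_scale = 3,
                           barrier_width = 35,
                           coupling_strength = 0,
                           n_states = 2,
                           intermediate_offset = 4,
                           distance_roughness_amplitude = 0,
                           n_distances = 0,
                           distance_center = 8,
                           distance_stiffness = 0.02,
                           distance_period = 2,
                           softmin_gamma = 0.5) {
  stopifnot(torsion_barrier_height > 0, well_stiffness > 0,
            open_basin_width_scale >= 1, barrier_width > 0,
            n_states %in% c(2L, 3L), n_distances >= 0, softmin_gamma > 0,
            distance_roughness_amplitude >= 0)
  if (distance_roughness_amplitude > 2) {
    warning("distance ruggedness above ~2 kcal/mol is outside the ",
            "diffusive regime this landscape emulates")
  }
  cc <- wrap_angle(basin_centers$closed)
  co <- wrap_angle(basin_centers$open)
  stopifnot(length(cc) == 2, length(co) == 2)

  k_closed <- well_stiffness
  k_open <- well_stiffness / open_basin_width_scale^2
  # midpoint along the shortest periodic displacement closed -> open
  delta <- angle_diff(co, cc)
  saddle <- wrap_angle(cc + delta / 2)

  wells <- list(
    list(name = "closed", center = cc, k = k_closed, offset = 0),
    list(name = "open", center = co, k = k_open, offset = 0)
  )
  # compensate the well-arm energy at the saddle so the realized barrier
  # (relative to the basin floors) matches the requested height
  u_saddle_wells <- {
    gam <- softmin_gamma
    uw <- vapply(wells, function(w) {
      0.5 * w$k * (.q_per(saddle[1] - w$center[1]) +
                     .q_per(saddle[2] - w$center[2])) + w$offset
    }, numeric(1))
    m0 <- min(uw)
    m0 - gam * log(sum(exp(-(uw - m0) / gam)))
  }
  bump_height <- torsion_barrier_height - u_saddle_wells
  if (bump_height <= 0) {
    stop("torsion_barrier_height is below the well-arm energy at the ",
         "saddle; increase the barrier or soften the wells", call. = FALSE)
  }
  bumps <- list(
    list(center = saddle, height = bump_height, width = barrier_width)
  )
  if (n_states == 3L) {
    # high-energy intermediate past the main barrier, guarded by a second,
    # lower torsional barrier; both bumps are narrowed so their tails do
    # not fill the intermediate dip
    bumps[[1]]$center <- wrap_angle(cc + 0.45 * delta)
    bumps[[1]]$width <- barrier_width / 2
    ci <- wrap_angle(cc + 0.65 * delta)
    wells[[3]] <- list(name = "intermediate", center = ci, k = k_closed,
                       offset = intermediate_offset)
    b2 <- wrap_angle(cc + 0.85 * delta)
    bumps[[2]] <- list(center = b2,
                       height = intermediate_offset +
                         torsion_barrier_height / 3,
                       width = barrier_width / 2)
  }

  structure(list(
    angular_names = c("psi", "phi"),
    wells = wells,
    bumps = bumps,
    coupling_strength = coupling_strength,
    coupling_center = saddle,
    softmin_gamma = softmin_gamma,
    n_states = as.integer(n_states),
    n_distances = as.integer(n_distances),
    distance = list(amplitude = distance_roughness_amplitude,
                    center = distance_center,
                    stiffness = distance_stiffness,
                    period = distance_period),
    barrier_height = torsion_barrier_height,
    basin_centers = list(closed = cc, open = co)
  ), class = "lk_landscape")
}

#' @export
print.lk_landscape <- function(x, ...) {
  cat("Model loop landscape:", x$n_states, "states,",
      x$barrier_height, "kcal/mol torsional barrier,",
      length(x$wells), "wells,", x$n_distances, "distance coordinate(s)\n")
  invisible(x)
}

.landscape_dim <- function(landscape) 2L + landscape$n_distances

.as_points <- function(landscape, x) {
  d <- .landscape_dim(landscape)
  if (is.null(dim(x))) x <- matrix(x, ncol = d, byrow = FALSE)
  if (ncol(x) != d) {
    stop("point dimension ", ncol(x), " does not match landscape dimension ",
         d, call. = FALSE)
  }
  x
}

#' Evaluate the landscape free energy
#'
#' @param landscape An `lk_landscape`.
#' @param x A point `c(psi, phi, d...)` (degrees, then Angstrom) or a matrix
#'   with one point per row.
#' @return Energy in kcal/mol (vector over rows).
#' @export
landscape_energy <- function(landscape, x) {
  x <- .as_points(landscape, x)
  n <- nrow(x)
  gam <- landscape$softmin_gamma

  uw <- vapply(landscape$wells, function(w) {
    0.5 * w$k * (.q_per(x[, 1] - w$center[1]) +
                   .q_per(x[, 2] - w$center[2])) + w$offset
  }, numeric(n))
  uw <- matrix(uw, nrow = n)
  m <- apply(uw, 1, min)
  u <- m - gam * log(rowSums(exp(-(uw - m) / gam)))

  for (b in landscape$bumps) {
    r2 <- .q_per(x[, 1] - b$center[1]) + .q_per(x[, 2] - b$center[2])
    u <- u + b$height * exp(-r2 / (2 * b$width^2))
  }

  if (landscape$coupling_strength != 0) {
    cs <- landscape$coupling_center
    u <- u + landscape$coupling_strength * (180 / pi)^2 *
      sin((x[, 1] - cs[1]) * pi / 180) * sin((x[, 2] - cs[2]) * pi / 180)
  }

  if (landscape$n_distances > 0) {
    dl <- landscape$distance
    for (j in seq_len(landscape$n_distances)) {
      d <- x[, 2 + j]
      u <- u + dl$amplitude * sin(2 * pi * d / dl$period) +
        0.5 * dl$stiffness * (d - dl$center)^2
    }
  }
  u
}

#' Analytic gradient of the landscape free energy
#'
#' @inheritParams landscape_energy
#' @return Gradient matrix (kcal/mol per degree or per Angstrom), one row
#'   per point.
#' @export
landscape_gradient <- function(landscape, x) {
  x <- .as_points(landscape, x)
  n <- nrow(x)
  d <- .landscape_dim(landscape)
  gam <- landscape$softmin_gamma
  g <- matrix(0, n, d)

  uw <- vapply(landscape$wells, function(w) {
    0.5 * w$k * (.q_per(x[, 1] - w$center[1]) +
                   .q_per(x[, 2] - w$center[2])) + w$offset
  }, numeric(n))
  uw <- matrix(uw, nrow = n)
  m <- apply(uw, 1, min)
  wts <- exp(-(uw - m) / gam)
  wts <- wts / rowSums(wts)
  for (i in seq_along(landscape$wells)) {
    w <- landscape$wells[[i]]
    g[, 1] <- g[, 1] + wts[, i] * 0.5 * w$k * .dq_per(x[, 1] - w$center[1])
    g[, 2] <- g[, 2] + wts[, i] * 0.5 * w$k * .dq_per(x[, 2] - w$center[2])
  }

  for (b in landscape$bumps) {
    q1 <- .q_per(x[, 1] - b$center[1])
    q2 <- .q_per(x[, 2] - b$center[2])
    amp <- b$height * exp(-(q1 + q2) / (2 * b$width^2))
    g[, 1] <- g[, 1] - amp * .dq_per(x[, 1] - b$center[1]) / (2 * b$width^2)
    g[, 2] <- g[, 2] - amp * .dq_per(x[, 2] - b$center[2]) / (2 * b$width^2)
  }

  if (landscape$coupling_strength != 0) {
    cs <- landscape$coupling_center
    r1 <- (x[, 1] - cs[1]) * pi / 180
    r2 <- (x[, 2] - cs[2]) * pi / 180
    fac <- landscape$coupling_strength * (180 / pi)^2 * pi / 180
    g[, 1] <- g[, 1] + fac * cos(r1) * sin(r2)
    g[, 2] <- g[, 2] + fac * sin(r1) * cos(r2)
  }

  if (landscape$n_distances > 0) {
    dl <- landscape$distance
    for (j in seq_len(landscape$n_distances)) {
      dd <- x[, 2 + j]
      g[, 2 + j] <- dl$amplitude * (2 * pi / dl$period) *
        cos(2 * pi * dd / dl$period) + dl$stiffness * (dd - dl$center)
    }
  }
  g
}

#' Analytic one-dimensional double-well free-energy profile
#'
#' The effective free energy along the path coordinate s used by the
#' generalized Langevin simulator: two soft-min-combined harmonic wells
#' (the open one wider than the closed one) plus a Gaussian barrier bump
#' whose height and width set the barrier top curvature, hence the
#' equilibrium barrier frequency. An optional third well yields a
#' three-state profile with a high-energy intermediate.
#'
#' The barrier is a raised-cosine bump with compact support
#' (`|s - s_barrier| < barrier_width`), so the basins are exactly
#' harmonic outside it: the top curvature is
#' `barrier_height * pi^2 / (2 * barrier_width^2)`; the default geometry
#' gives an equilibrium barrier frequency near 409 1/cm at reduced mass
#' 0.917.
#'
#' @param barrier_height Barrier bump height, kcal/mol.
#' @param s_closed,s_open Well centers on the s axis (amu^1/2 * Angstrom).
#' @param k_closed Closed-well curvature, kcal/mol per s-unit^2.
#' @param open_width_scale sigma_open / sigma_closed (>= 1).
#' @param barrier_width Half-support of the raised-cosine bump, s-units.
#' @param s_barrier Bump center; defaults to the midpoint.
#' @param open_offset Free energy of the open minimum relative to the
#'   closed one, kcal/mol (negative stabilizes the open state).
#' @param intermediate Optional list(center, k, offset, guard_height,
#'   guard_center, guard_width) adding a three-state intermediate.
#' @param softmin_gamma Soft-min smoothing, kcal/mol.
#' @return Object of class `lk_profile_fun` with analytic `G(s)` and
#'   `dG(s)` accessors (see [profile_energy()], [profile_force()]).
#' @export
double_well_1d <- function(barrier_height = 12,
                           s_closed = -2.2, s_open = 2.2,
                           k_closed = 2.39, open_width_scale = 3,
                           barrier_width = 2.13, s_barrier = NULL,
                           open_offset = 0,
                           intermediate = NULL,
                           softmin_gamma = 0.5) {
  stopifnot(barrier_height >= 0, k_closed > 0, open_width_scale >= 1,
            barrier_width > 0, softmin_gamma > 0, s_closed < s_open)
  if (is.null(s_barrier)) s_barrier <- (s_closed + s_open) / 2
  wells <- list(
    list(center = s_closed, k = k_closed, offset = 0),
    list(center = s_open, k = k_closed / open_width_scale^2,
         offset = open_offset)
  )
  bumps <- list(list(center = s_barrier, height = barrier_height,
                     width = barrier_width))
  if (!is.null(intermediate)) {
    wells[[3]] <- list(center = intermediate$center,
                       k = intermediate$k %||% k_closed,
                       offset = intermediate$offset %||% 4)
    bumps[[2]] <- list(center = intermediate$guard_center,
                       height = intermediate$guard_height %||%
                         (barrier_height / 2),
                       width = intermediate$guard_width %||% barrier_width)
  }
  structure(list(wells = wells, bumps = bumps, gamma = softmin_gamma,
                 s_range = c(s_closed - 6 / sqrt(k_closed),
                             s_open + 6 * open_width_scale / sqrt(k_closed))),
            class = "lk_profile_fun")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an analytic profile G(s)
#'
#' @param profile An `lk_profile_fun`.
#' @param s Path-coordinate values.
#' @return Free energy, kcal/mol.
#' @export
profile_energy <- function(profile, s) {
  gam <- profile$gamma
  u <- numeric(length(s))
  if (length(profile$wells)) {
    uw <- vapply(profile$wells,
                 function(w) 0.5 * w$k * (s - w$center)^2 + w$offset,
                 numeric(length(s)))
    uw <- matrix(uw, nrow = length(s))
    m <- apply(uw, 1, min)
    u <- m - gam * log(rowSums(exp(-(uw - m) / gam)))
  }
  for (b in profile$bumps) {
    x <- (s - b$center) / b$width
    inside <- abs(x) < 1
    u[inside] <- u[inside] +
      b$height * 0.5 * (1 + cos(pi * x[inside]))
  }
  u
}

#' Analytic derivative dG/ds of a profile
#'
#' @inheritParams profile_energy
#' @return dG/ds in kcal/mol per s-unit.
#' @export
profile_force <- function(profile, s) {
  gam <- profile$gamma
  g <- numeric(length(s))
  if (length(profile$wells)) {
    uw <- vapply(profile$wells,
                 function(w) 0.5 * w$k * (s - w$center)^2 + w$offset,
                 numeric(length(s)))
    uw <- matrix(uw, nrow = length(s))
    m <- apply(uw, 1, min)
    wts <- exp(-(uw - m) / gam)
    wts <- wts / rowSums(wts)
    for (i in seq_along(profile$wells)) {
      w <- profile$wells[[i]]
      g <- g + wts[, i] * w$k * (s - w$center)
    }
  }
  for (b in profile$bumps) {
    x <- (s - b$center) / b$width
    inside <- abs(x) < 1
    g[inside] <- g[inside] -
      b$height * 0.5 * pi / b$width * sin(pi * x[inside])
  }
  g
}
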