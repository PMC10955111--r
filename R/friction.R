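#' Analytic multi-exponential friction kernel
#'
#' `xi(t) = sum_i A_i exp(-t / tau_i)` with a closed-form Laplace
#' transform, used both as a reference object in tests and as the kernel
#' implied by a GLE bath specification.
#'
#' @param A Amplitudes, ps^-2 (>= 0).
#' @param tau Relaxation times, ps (> 0).
#' @param labels Optional component labels.
#' @return An `lk_kernel_exp`.
#' @export
exp_kernel <- function(A, tau, labels = NULL) {
  stopifnot(length(A) == length(tau), all(A >= 0), all(tau > 0))
  structure(list(A = A, tau = tau,
                 labels = labels %||% paste0("component", seq_along(A)),
                 xi0 = sum(A), zeta = sum(A * tau)),
            class = "lk_kernel_exp")
}

#' Kernel implied by a GLE model's baths
#'
#' @param model A [gle_model()].
#' @return The analytic [exp_kernel()] of the model's bath specification.
#' @export
model_kernel <- function(model) {
  stopifnot(inherits(model, "lk_gle_model"))
  exp_kernel(vapply(model$baths, function(b) b$coupling, numeric(1)),
             vapply(model$baths, function(b) b$tau, numeric(1)),
             labels = model$labels)
}

# one-sided autocorrelation / symmetrized cross-correlation via FFT,
# time-origin averaged with unbiased (n - lag) normalization
.xcorr_fft <- function(x, y, n_lag) {
  n <- length(x)
  np <- stats::nextn(2 * n, 2)
  fx <- stats::fft(c(x, rep(0, np - n)))
  fy <- stats::fft(c(y, rep(0, np - n)))
  cc <- Re(stats::fft(fx * Conj(fy), inverse = TRUE)) / np
  fwd <- cc[1:n_lag]                      # <x(t+lag) y(t)>
  bwd <- c(cc[1], rev(cc[(np - n_lag + 2):np]))  # <x(t) y(t+lag)>
  (fwd + bwd) / 2 / (n - (0:(n_lag - 1)))
}

#' Time-dependent friction kernel from TS-constrained trajectories
#'
#' Estimates `xi(t) = <F_s(0) F_s(t)>_TS / (kBT * m)` (mass-weighted
#' coordinates) from the fluctuating forces projected on the reaction
#' coordinate, recorded while s is constrained at the transition state.
#' The estimate is averaged over time origins and over the trajectory
#' ensemble (the conventional 60 TS trajectories). Component kernels are
#' returned in the requested decomposition mode:
#' \describe{
#'   \item{pure}{autocorrelation of each labeled component with itself
#'     (the zeroed-force-field recomputation style); components need not
#'     sum to the total - the difference is the cross-correlation term,
#'     reported as `cross_term`.}
#'   \item{projected}{symmetrized cross-correlation of each component with
#'     the total force; exactly additive.}
#' }
#'
#' @param trajectories List of `lk_trajectory` from
#'   [sample_ts_constrained()] (equal dt).
#' @param max_lag Maximum kernel lag, ps.
#' @param mode Decomposition mode, "pure" (default) or "projected".
#' @param components Force column labels to use (default: the trajectory's
#'   bath labels).
#' @return An `lk_kernel`: `t` (ps), `xi_total` (ps^-2), `xi_by_component`
#'   (matrix), `cross_term`, `zeta` (integral of xi, 1/ps),
#'   `xi0_wavenumber` (sqrt(xi(0)) in 1/cm), `dt`, `mode`.
#' @export
friction_kernel <- function(trajectories, max_lag = 5, mode = c("pure",
                                                                "projected"),
                            components = NULL) {
  mode <- match.arg(mode)
  if (inherits(trajectories, "lk_trajectory")) {
    trajectories <- list(trajectories)
  }
  dts <- vapply(trajectories, function(tr) tr$dt, numeric(1))
  if (diff(range(dts)) > 1e-12) {
    stop("trajectories must share the same sampling interval",
         call. = FALSE)
  }
  dt <- dts[1]
  tr1 <- trajectories[[1]]
  components <- components %||% tr1$metadata$bath_labels
  cols <- paste0("f_", components)
  missing_cols <- setdiff(cols, names(tr1$columns))
  if (length(missing_cols)) {
    stop("force columns missing labels: ",
         paste(sub("^f_", "", missing_cols), collapse = ", "),
         call. = FALSE)
  }
  n <- tr1$length
  n_lag <- floor(max_lag / dt) + 1L
  if (n_lag > n / 2) {
    stop("max_lag exceeds half the trajectory length", call. = FALSE)
  }
  kT_m <- thermal_energy(tr1$metadata$temperature)$amu *
    tr1$metadata$mass

  # demean with the ensemble mean (the conditional mean force at the
  # constrained TS), not per trajectory: per-trajectory demeaning of a
  # slowly decorrelating force biases the kernel tail downward
  ens_mean <- Reduce(`+`, lapply(trajectories, function(tr) {
    colMeans(as.matrix(tr$columns[cols]))
  })) / length(trajectories)

  acc_tot <- numeric(n_lag)
  acc_comp <- matrix(0, n_lag, length(cols))
  for (tr in trajectories) {
    fmat <- as.matrix(tr$columns[cols])
    fmat <- sweep(fmat, 2, ens_mean)
    ftot <- rowSums(fmat)
    acc_tot <- acc_tot + .xcorr_fft(ftot, ftot, n_lag)
    for (j in seq_along(cols)) {
      acc_comp[, j] <- acc_comp[, j] +
        if (mode == "pure") .xcorr_fft(fmat[, j], fmat[, j], n_lag) else
          .xcorr_fft(fmat[, j], ftot, n_lag)
    }
  }
  m <- length(trajectories)
  xi_total <- acc_tot / m / kT_m
  xi_comp <- acc_comp / m / kT_m
  colnames(xi_comp) <- components
  tgrid <- (0:(n_lag - 1)) * dt
  structure(list(t = tgrid, xi_total = xi_total,
                 xi_by_component = xi_comp,
                 cross_term = xi_total - rowSums(xi_comp),
                 zeta = pracma::trapz(tgrid, xi_total),
                 xi0_wavenumber = omega_to_wavenumber(
                   sqrt(max(xi_total[1], 0))),
                 dt = dt, mode = mode, n_trajectories = m),
            class = "lk_kernel")
}

#' @export
print.lk_kernel <- function(x, ...) {
  cat("Friction kernel (", x$mode, " mode, ", x$n_trajectories,
      " trajectories): xi(0) = ", signif(x$xi_total[1], 4),
      " ps^-2 (sqrt = ", signif(x$xi0_wavenumber, 4),
      " cm^-1) | zeta = ", signif(x$zeta, 4), " 1/ps\n", sep = "")
  invisible(x)
}

#' Fit a single-exponential model to an estimated kernel
#'
#' @param kernel An `lk_kernel` (or one column of it via `component`).
#' @param component Optional component label to fit instead of the total.
#' @param t_max Fit range, ps (default: full stored range).
#' @return List with `A` (ps^-2) and `tau` (ps).
#' @export
fit_exp_kernel <- function(kernel, component = NULL, t_max = NULL) {
  y <- if (is.null(component)) kernel$xi_total else
    kernel$xi_by_component[, component]
  t <- kernel$t
  if (!is.null(t_max)) {
    keep <- t <= t_max
    t <- t[keep]
    y <- y[keep]
  }
  a0 <- max(y[1], 1e-12)
  tau0 <- max(pracma::trapz(t, pmax(y, 0)) / a0, kernel$dt)
  fit <- minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                           start = list(A = a0, tau = tau0),
                           lower = c(0, kernel$dt / 10),
                           data = data.frame(t = t, y = y))
  as.list(stats::coef(fit))
}

#' Friction power spectrum
#'
#' One-sided cosine transform of the kernel,
#' `J(omega) = integral xi(t) w(t) cos(omega t) dt`, on a wavenumber grid.
#' The default Hann taper `w` suppresses truncation ringing. For a
#' sufficiently long stored kernel the transform satisfies the Parseval-type
#' identity `integral J(omega) d omega = pi * xi(0) / 2`.
#'
#' @param kernel An `lk_kernel` on a uniform time grid.
#' @param taper "hann" (default) or "none".
#' @param wavenumber_max Upper edge of the output grid, 1/cm.
#' @param n_freq Number of frequency points.
#' @param component Optional component label (default: total kernel).
#' @return Data frame with `wavenumber` (1/cm), `omega` (rad/ps) and
#'   `density` (ps^-1).
#' @export
power_spectrum <- function(kernel, taper = c("hann", "none"),
                           wavenumber_max = 1500, n_freq = 600L,
                           component = NULL) {
  taper <- match.arg(taper)
  t <- kernel$t
  if (length(t) > 2 && diff(range(diff(t))) > 1e-9 * kernel$dt) {
    stop("kernel grid must be uniform", call. = FALSE)
  }
  y <- if (is.null(component)) kernel$xi_total else
    kernel$xi_by_component[, component]
  w <- if (taper == "hann") {
    0.5 * (1 + cos(pi * t / max(t)))
  } else {
    rep(1, length(t))
  }
  nu <- seq(0, wavenumber_max, length.out = n_freq)
  omega <- wavenumber_to_omega(nu)
  dens <- vapply(omega, function(om) {
    pracma::trapz(t, y * w * cos(om * t))
  }, numeric(1))
  data.frame(wavenumber = nu, omega = omega, density = dens)
}

#' Equilibrium barrier frequency from the profile top
#'
#' Least-squares parabola on G(s) over `[s_star - window, s_star + window]`;
#' `omega_eq = sqrt(|curvature| / mu)` converted to dynamical units. The
#' barrier must be concave (negative curvature) at the top.
#'
#' @param profile An `lk_fep`.
#' @param s_star TS position (profile maximum in the window).
#' @param mu Reduced mass of the reaction coordinate.
#' @param window Half-width of the fit window, s-units.
#' @return List: `omega_eq` (rad/ps), `omega_eq_wavenumber` (1/cm),
#'   `curvature` (kcal/mol per s-unit^2).
#' @export
barrier_frequency <- function(profile, s_star, mu, window = 0.3) {
  stopifnot(mu > 0, window > 0)
  sel <- abs(profile$grid - s_star) <= window & !is.na(profile$G)
  if (sum(sel) < 5) {
    stop("too few profile points in the TS window", call. = FALSE)
  }
  x <- profile$grid[sel] - s_star
  fit <- stats::lm(profile$G[sel] ~ x + I(x^2))
  curv <- 2 * stats::coef(fit)[[3]]
  if (curv >= 0) {
    stop("non-negative curvature at s_star: the profile top is flat or ",
         "convex in the fit window", call. = FALSE)
  }
  const <- lk_constants()
  omega <- sqrt(-curv * const$kcal_to_amuA2ps2 / mu)
  list(omega_eq = omega, omega_eq_wavenumber = omega_to_wavenumber(omega),
       curvature = curv)
}

#' Memoryless (Markovian) friction kernel
#'
#' The delta-correlated limit `xi(t) = 2 * zeta * delta(t)`: the Laplace
#' transform is the constant static friction `zeta` at every frequency,
#' for which Grote-Hynes reduces exactly to Kramers.
#'
#' @param zeta Static friction, 1/ps (>= 0).
#' @return An `lk_kernel_delta`.
#' @export
memoryless_kernel <- function(zeta) {
  stopifnot(zeta >= 0)
  structure(list(zeta = zeta), class = "lk_kernel_delta")
}

# Laplace transform of a kernel at frequency om (rad/ps)
.kernel_laplace <- function(kernel, om) {
  if (inherits(kernel, "lk_kernel_exp")) {
    sum(kernel$A * kernel$tau / (1 + om * kernel$tau))
  } else if (inherits(kernel, "lk_kernel_delta")) {
    kernel$zeta
  } else {
    pracma::trapz(kernel$t, kernel$xi_total * exp(-om * kernel$t))
  }
}

#' Kramers transmission coefficient (spatial-diffusion regime)
#'
#' `kappa_Kr = sqrt(1 + (zeta / (2 omega_eq))^2) - zeta / (2 omega_eq)`,
#' the memoryless limit using only the static friction
#' `zeta = integral xi dt`.
#'
#' @param zeta Static friction, 1/ps.
#' @param omega_eq Barrier frequency, rad/ps.
#' @return kappa in (0, 1].
#' @export
kramers_kappa <- function(zeta, omega_eq) {
  stopifnot(zeta >= 0, omega_eq > 0)
  x <- zeta / (2 * omega_eq)
  sqrt(1 + x^2) - x
}

#' Grote-Hynes reactive frequency and transmission coefficient
#'
#' Solves the self-consistent equation
#' `omega_r^2 - omega_eq^2 + omega_r * L[xi](omega_r) = 0`
#' where `L[xi]` is the Laplace transform of the friction kernel over its
#' full support, by bracketed root search on `(0, omega_eq]`; then
#' `kappa_GH = omega_r / omega_eq`. Also reports the Kramers estimate from
#' the static friction and a friction-regime label: polarization caging
#' when the initial friction exceeds the barrier frequency
#' (`sqrt(xi(0)) > omega_eq`), nonadiabatic when friction barely bites
#' (`kappa_GH > 0.9`), intermediate otherwise.
#'
#' @param kernel An `lk_kernel` (tabulated; must have decayed below 1% of
#'   xi(0) before its last stored lag) or an analytic [exp_kernel()].
#' @param omega_eq Barrier frequency, in 1/cm by default.
#' @param unit Unit of `omega_eq`: "cm-1" (default) or "rad_ps".
#' @param tol Relative root tolerance.
#' @return A `lk_gh` list: `omega_eq`, `omega_r` (rad/ps and 1/cm),
#'   `kappa_GH`, `kappa_Kramers`, `zeta`, `xi0`, `regime`.
#' @export
grote_hynes <- function(kernel, omega_eq, unit = c("cm-1", "rad_ps"),
                        tol = 1e-12) {
  unit <- match.arg(unit)
  om_eq <- if (unit == "cm-1") wavenumber_to_omega(omega_eq) else omega_eq
  stopifnot(om_eq > 0)
  if (inherits(kernel, "lk_kernel")) {
    xi0 <- kernel$xi_total[1]
    # averaged tail: pointwise noise cancels, an undecayed kernel does not
    tail_mean <- abs(mean(kernel$xi_total[kernel$t >=
                                            0.9 * max(kernel$t)]))
    if (xi0 > 0 && tail_mean > 0.01 * xi0) {
      stop("kernel has not decayed below 1% of xi(0) within the stored ",
           "lag range; the truncated Laplace transform would be unsafe. ",
           "Increase max_lag.", call. = FALSE)
    }
  } else if (inherits(kernel, "lk_kernel_exp")) {
    xi0 <- kernel$xi0
  } else if (inherits(kernel, "lk_kernel_delta")) {
    xi0 <- NA_real_  # delta kernel: xi(0) undefined, regime from kappa
  } else {
    stop("unsupported kernel type", call. = FALSE)
  }

  f <- function(om) om^2 - om_eq^2 + om * .kernel_laplace(kernel, om)
  frictionless <- if (is.na(xi0)) kernel$zeta <= 0 else xi0 <= 0
  if (frictionless) {
    om_r <- om_eq
  } else {
    f_up <- f(om_eq)
    if (f_up < 0) {
      om_r <- om_eq  # frictionless within numerical noise
    } else {
      root <- stats::uniroot(f, lower = 1e-12 * om_eq, upper = om_eq,
                             tol = tol * om_eq)
      om_r <- root$root
    }
  }
  kappa <- om_r / om_eq
  zeta <- .kernel_laplace(kernel, 0)
  kKr <- kramers_kappa(zeta, om_eq)
  regime <- if (!is.na(xi0) && sqrt(max(xi0, 0)) > om_eq) {
    "polarization_caging"
  } else if (kappa > 0.9) {
    "nonadiabatic"
  } else {
    "intermediate"
  }
  structure(list(omega_eq = om_eq,
                 omega_eq_wavenumber = omega_to_wavenumber(om_eq),
                 omega_r = om_r,
                 omega_r_wavenumber = omega_to_wavenumber(om_r),
                 kappa_GH = kappa, kappa_Kramers = kKr,
                 zeta = zeta, xi0 = xi0, regime = regime),
            class = "lk_gh")
}

#' @export
print.lk_gh <- function(x, ...) {
  cat("Grote-Hynes solution: omega_eq = ",
      signif(x$omega_eq_wavenumber, 4), " cm^-1 | omega_r = ",
      signif(x$omega_r_wavenumber, 4), " cm^-1 | kappa_GH = ",
      signif(x$kappa_GH, 4), " | kappa_Kramers = ",
      signif(x$kappa_Kramers, 4), " | regime: ", x$regime, "\n", sep = "")
  invisible(x)
}
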