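#' Classify a CV point into a basin of a state partition
#'
#' Periodic-aware rectangular box membership on the angular CVs. Box
#' boundaries are closed: a point on an edge is a member.
#'
#' @param cv_point Numeric `c(psi, phi, ...)` in degrees (extra
#'   coordinates are ignored).
#' @param partition A [state_partition()].
#' @return The state name, or "indeterminate" if the point lies in no box.
#' @export
classify_state <- function(cv_point, partition) {
  stopifnot(inherits(partition, "lk_partition"))
  for (nm in names(partition$boxes)) {
    b <- partition$boxes[[nm]]
    if (.in_box(cv_point[1], b$psi) && .in_box(cv_point[2], b$phi)) {
      return(nm)
    }
  }
  "indeterminate"
}

# classify a 1D endpoint on s when no angular partition is available
.classify_s <- function(s_end, s_star, capture) {
  if (s_end <= s_star - capture) "closed"
  else if (s_end >= s_star + capture) "open"
  else "indeterminate"
}

#' Draw transition-state configurations for shooting
#'
#' Positions are rejection-sampled from the Boltzmann weight of the
#' profile restricted to `|s - s_star| <= ts_window`; bath variables from
#' their stationary distribution (the bath state is part of the TS
#' configuration).
#'
#' @param model A [gle_model()].
#' @param s_star TS position.
#' @param n Number of configurations.
#' @param ts_window Half-width of the TS window on s (default 0.1).
#' @return List of `list(s, z)` configurations.
#' @export
ts_configurations <- function(model, s_star, n, ts_window = 0.1) {
  kTk <- thermal_energy(model$temperature)$kcal
  gfun <- stats::approxfun(model$grid, model$g_kcal, rule = 2)
  g_ref <- min(gfun(seq(s_star - ts_window, s_star + ts_window,
                        length.out = 101)))
  kT <- thermal_energy(model$temperature)$amu
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    s_try <- stats::runif(1, s_star - ts_window, s_star + ts_window)
    if (stats::runif(1) <= exp(-(gfun(s_try) - g_ref) / kTk)) {
      i <- i + 1L
      z <- vapply(model$baths, function(b) {
        stats::rnorm(1, 0, sqrt(kT * b$coupling / model$mass))
      }, numeric(1))
      out[[i]] <- list(s = s_try, z = as.numeric(z))
    }
  }
  out
}

#' Shoot trajectories from the transition-state ensemble
#'
#' For each TS configuration a Maxwell-Boltzmann velocity is drawn once;
#' the system is propagated forward with that velocity and backward with
#' the reversed velocity (sharing the position and bath state) for `t_max`
#' each. A trajectory is reactive when its backward and forward endpoints
#' lie in different basins (committor-style definition); trajectories whose
#' two ends fall on the same side are nonreactive even if they recross.
#' Endpoints outside every basin are "indeterminate" and are excluded from
#' the reactive fraction (counts reported so totals reconcile).
#'
#' @param model A [gle_model()].
#' @param s_star TS position on s.
#' @param n_shots Number of shots (default 60).
#' @param t_max Propagation time per direction, ps (default 100).
#' @param ts_window TS window half-width on s; configurations must satisfy
#'   `|s - s_star| <= ts_window` (default 0.1).
#' @param configs Optional list of `list(s, z)` configurations (default:
#'   drawn by [ts_configurations()]).
#' @param partition Optional [state_partition()]; requires `path`.
#' @param path Optional `lk_path` used to map endpoint s values to CV
#'   points for classification; without it endpoints are classified on s
#'   directly with `capture_distance`.
#' @param capture_distance s distance from `s_star` beyond which an
#'   endpoint is committed (default 1).
#' @param sample_every Recording stride for the residence/recrossing
#'   analysis.
#' @param seed Ensemble seed; defaults to the model seed.
#' @return An `lk_shoot`: per-shot data frame (`outcome`, endpoint states,
#'   `recrossings`, `residence_ps`, `v0`) and an aggregate list with the
#'   unweighted reactive fraction (exact binomial 95% CI) and the
#'   velocity-weighted reactive-flux transmission coefficient
#'   `kappa_flux` (bootstrap 95% CI), the quantity Grote-Hynes theory
#'   predicts for a parabolic barrier.
#' @export
shoot <- function(model, s_star, n_shots = 60L, t_max = 100, ts_window = 0.1,
                  configs = NULL, partition = NULL, path = NULL,
                  capture_distance = 1, sample_every = 5L, seed = NULL) {
  stopifnot(inherits(model, "lk_gle_model"))
  if (is.null(seed)) seed <- model$seed
  set.seed(derive_seed(seed, 101L))
  if (is.null(configs)) {
    configs <- ts_configurations(model, s_star, n_shots, ts_window)
  }
  if (length(configs) < n_shots) {
    stop("fewer configurations than shots", call. = FALSE)
  }
  bad <- vapply(configs, function(cf) abs(cf$s - s_star) > ts_window,
                logical(1))
  if (any(bad)) {
    stop(sum(bad), " configuration(s) outside the TS window |s - s*| <= ",
         ts_window, call. = FALSE)
  }
  kT <- thermal_energy(model$temperature)$amu
  ab <- .model_AB(model)
  n_steps <- ceiling(t_max / model$dt)
  dt_samp <- model$dt * sample_every

  classify_end <- function(s_end) {
    if (!is.null(partition) && !is.null(path)) {
      classify_state(path_point(path, s_end)[1, ], partition)
    } else {
      .classify_s(s_end, s_star, capture_distance)
    }
  }

  one_direction <- function(cf, v0, shot_seed) {
    raw <- .gle_integrate_cpp(model$grid, model$force_amu, model$mass, kT,
                              ab$A, ab$tau, model$gamma0,
                              model$dt, as.integer(n_steps),
                              as.integer(sample_every),
                              cf$s, v0, cf$z, 0, 0, FALSE, shot_seed)
    dev <- raw$s - s_star
    inside <- abs(dev) <= ts_window
    first_exit <- which(!inside)[1]
    rec <- 0L
    if (!is.na(first_exit) && first_exit < length(dev)) {
      sgn <- sign(dev[first_exit:length(dev)])
      sgn <- sgn[sgn != 0]
      rec <- sum(diff(sgn) != 0)
    }
    list(s_end = raw$s[length(raw$s)], residence = sum(inside) * dt_samp,
         recross = rec)
  }

  v_sd <- sqrt(kT / model$mass)
  rows <- vector("list", n_shots)
  for (i in seq_len(n_shots)) {
    set.seed(derive_seed(seed, 200L + i))
    v0 <- stats::rnorm(1, 0, v_sd)
    fw <- one_direction(configs[[i]], v0, derive_seed(seed, 500L + 2L * i))
    bw <- one_direction(configs[[i]], -v0,
                        derive_seed(seed, 501L + 2L * i))
    st_f <- classify_end(fw$s_end)
    st_b <- classify_end(bw$s_end)
    outcome <- if (st_f == "indeterminate" || st_b == "indeterminate") {
      "indeterminate"
    } else if (st_f != st_b) "reactive" else "nonreactive"
    rows[[i]] <- data.frame(shot = i, v0 = v0, fwd_state = st_f,
                            bwd_state = st_b, outcome = outcome,
                            recrossings = fw$recross + bw$recross,
                            residence_ps = fw$residence + bw$residence)
  }
  tab <- do.call(rbind, rows)
  n_ind <- sum(tab$outcome == "indeterminate")
  n_cls <- n_shots - n_ind
  n_re <- sum(tab$outcome == "reactive")
  if (n_ind > 0) {
    message(n_ind, " shot(s) with indeterminate endpoints excluded from ",
            "the reactive fraction")
  }
  ci <- if (n_cls > 0) {
    as.numeric(stats::binom.test(n_re, n_cls)$conf.int)
  } else {
    c(NA_real_, NA_real_)
  }
  # reactive-flux transmission coefficient: velocity-weighted count of
  # committed closed->open crossings, the estimator that Grote-Hynes
  # theory predicts for a parabolic barrier (the unweighted fraction is
  # the qualitative count)
  co <- as.numeric(tab$bwd_state == "closed" & tab$fwd_state == "open")
  oc <- as.numeric(tab$bwd_state == "open" & tab$fwd_state == "closed")
  wflux <- tab$v0 * (co - oc)
  kappa_flux <- mean(wflux) / mean(abs(tab$v0))
  boot <- vapply(seq_len(500), function(b) {
    idx <- sample.int(n_shots, replace = TRUE)
    mean(wflux[idx]) / mean(abs(tab$v0[idx]))
  }, numeric(1))
  structure(list(
    shots = tab,
    aggregate = list(n_shots = n_shots, n_classified = n_cls,
                     n_reactive = n_re, n_indeterminate = n_ind,
                     reactive_fraction = if (n_cls > 0) n_re / n_cls else
                       NA_real_,
                     ci95 = ci,
                     kappa_flux = kappa_flux,
                     kappa_flux_ci95 = as.numeric(
                       stats::quantile(boot, c(0.025, 0.975))),
                     mean_residence_ps = mean(tab$residence_ps))
  ), class = "lk_shoot")
}

#' @export
print.lk_shoot <- function(x, ...) {
  a <- x$aggregate
  cat("TS shooting: ", a$n_reactive, "/", a$n_classified,
      " reactive (fraction ", signif(a$reactive_fraction, 3),
      ", 95% CI [", signif(a$ci95[1], 3), ", ", signif(a$ci95[2], 3),
      "]) | kappa_flux ", signif(a$kappa_flux, 3),
      " | mean TS residence ", signif(a$mean_residence_ps, 3),
      " ps\n", sep = "")
  invisible(x)
}

#' Generate exact Brownian displacement paths
#'
#' Synthetic reference for the diffusive-displacement analysis: pure
#' Brownian motion with known diffusion coefficient.
#'
#' @param n_paths,n_steps Ensemble size and steps per path.
#' @param dt_ns Time step, ns.
#' @param D Diffusion coefficient, Angstrom^2/ns.
#' @param x0 Initial displacement.
#' @param seed RNG seed.
#' @return Matrix `n_paths x (n_steps + 1)` of positions (Angstrom).
#' @export
brownian_paths <- function(n_paths, n_steps, dt_ns, D, x0 = 0, seed = 1) {
  stopifnot(D > 0, dt_ns > 0)
  set.seed(as.integer(seed %% 2147483647))
  dx <- matrix(stats::rnorm(n_paths * n_steps, 0, sqrt(2 * D * dt_ns)),
               n_paths, n_steps)
  cbind(rep(x0, n_paths), x0 + t(apply(dx, 1, cumsum)))
}

#' Diffusion coefficient from the ensemble mean-squared displacement
#'
#' Fits `MSD(t) = 2 D t + b` over the requested range and derives the
#' time to complete a displacement of length `L` by pure diffusion,
#' `t = L^2 / (2 D)`, together with the corresponding rate `k_dis = 1/t`.
#'
#' @param paths Matrix of 1D distance trajectories, one row per path
#'   (>= 5 paths), or a list of equal-length numeric vectors.
#' @param dt_ns Sampling interval, ns.
#' @param fit_range Time range (ns) used in the linear fit; default the
#'   central 10-50% of the trajectory.
#' @param L Displacement to complete, Angstrom (default 4.4, a typical
#'   loop-anchor displacement between closed and open X-ray structures).
#' @return A `lk_diffusion`: `D` (A^2/ns), `slope`, `intercept`,
#'   `r_squared`, `completion_time_ns`, `k_dis` (1/s), `diffusive` flag.
#' @export
estimate_diffusion <- function(paths, dt_ns, fit_range = NULL, L = 4.4) {
  if (is.list(paths) && !is.matrix(paths)) paths <- do.call(rbind, paths)
  paths <- as.matrix(paths)
  if (nrow(paths) < 5) {
    stop("need at least 5 trajectories for the ensemble MSD",
         call. = FALSE)
  }
  nt <- ncol(paths)
  # time-origin-averaged ensemble MSD up to half the trajectory length
  lags <- seq_len(nt %/% 2)
  msd <- vapply(lags, function(L) {
    mean((paths[, (1 + L):nt, drop = FALSE] -
            paths[, 1:(nt - L), drop = FALSE])^2)
  }, numeric(1))
  msd <- c(0, msd)
  tt <- c(0, lags) * dt_ns
  # default fit window: low lags, where the origin-averaged MSD has the
  # smallest relative error (its variance grows with lag)
  if (is.null(fit_range)) fit_range <- c(0.01, 0.15) * max(tt)
  if (fit_range[2] > (nt - 1) * dt_ns) {
    stop("fit range extends beyond the trajectory length", call. = FALSE)
  }
  sel <- tt >= fit_range[1] & tt <= fit_range[2]
  fit <- stats::lm(msd[sel] ~ tt[sel])
  slope <- stats::coef(fit)[[2]]
  r2 <- summary(fit)$r.squared
  # scaling exponent MSD ~ t^alpha: 1 diffusive, 2 ballistic, <1 subdiffusive
  pos <- sel & msd > 0 & tt > 0
  alpha <- if (sum(pos) >= 3) {
    stats::coef(stats::lm(log(msd[pos]) ~ log(tt[pos])))[[2]]
  } else NA_real_
  diffusive <- is.finite(r2) && r2 >= 0.9 && slope > 0 &&
    is.finite(alpha) && abs(alpha - 1) <= 0.3
  if (!diffusive) {
    warning("non-diffusive displacement: MSD is not linear over the fit ",
            "range (R^2 = ", signif(r2, 3), ", scaling exponent ",
            signif(alpha, 3), ")")
  }
  D <- slope / 2
  ct <- if (D > 0) L^2 / (2 * D) else NA_real_
  structure(list(D = D, slope = slope,
                 intercept = stats::coef(fit)[[1]], r_squared = r2,
                 alpha = alpha,
                 completion_time_ns = ct,
                 k_dis = if (is.finite(ct)) 1 / (ct * 1e-9) else NA_real_,
                 L = L, fit_range = fit_range, diffusive = diffusive),
            class = "lk_diffusion")
}

#' @export
print.lk_diffusion <- function(x, ...) {
  cat("Diffusive displacement: D = ", signif(x$D, 4),
      " A^2/ns (R^2 = ", signif(x$r_squared, 3), ") | completion of ",
      x$L, " A in ", signif(x$completion_time_ns, 4), " ns\n", sep = "")
  invisible(x)
}

#' Diffusive completion time for a displacement
#'
#' @param D Diffusion coefficient, Angstrom^2/ns.
#' @param L Displacement, Angstrom.
#' @return List with `time_ns` (= L^2 / (2 D)) and `k_dis` (1/s).
#' @export
completion_time <- function(D, L) {
  stopifnot(D > 0, L > 0)
  t_ns <- L^2 / (2 * D)
  list(time_ns = t_ns, k_dis = 1 / (t_ns * 1e-9))
}
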