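#' Pipeline configuration
#'
#' Validated configuration for the end-to-end analysis
#' (screen -> string -> umbrella/WHAM -> rates -> friction -> Grote-Hynes
#' -> shooting -> report). Every stochastic stage derives its seed from the
#' single master seed; the config hash is embedded in every artifact.
#'
#' @param mu Reduced mass of the reaction coordinate (required).
#' @param temperature Temperature, K (required).
#' @param seed Master seed (required).
#' @param landscape Arguments for [landscape_spec()] (list), or an
#'   `lk_landscape`.
#' @param bath_preset Name of the [bath_preset()] friction environment.
#' @param cv_weight Metric weight of the two torsional CVs,
#'   amu^1/2 * Angstrom per degree. The default 0.0263 makes the 12
#'   kcal/mol default barrier about 409 1/cm wide at mu near 1.
#' @param dt Integration timestep, ps.
#' @param string List: `M` nodes, `tol`.
#' @param pmf_source "umbrella" (sample windows, reconstruct via WHAM) or
#'   "analytic" (evaluate the landscape along the path).
#' @param umbrella List: `n_windows`, `k_umb` (kcal/mol per s-unit^2),
#'   `n_steps`, `n_equil`, `sample_every`, `bin_width`.
#' @param friction List: `n_trajectories`, `n_steps`, `max_lag` (ps),
#'   `mode`.
#' @param shooting List: `n_shots`, `t_max` (ps), `ts_window`.
#' @param screening List: `n_samples` per state.
#' @param output_dir Optional artifact directory.
#' @return A validated `lk_config`.
#' @export
pipeline_config <- function(mu, temperature, seed,
                            landscape = list(),
                            bath_preset = "caging",
                            cv_weight = 0.0263,
                            dt = 0.001,
                            string = list(),
                            pmf_source = c("umbrella", "analytic"),
                            umbrella = list(),
                            friction = list(),
                            shooting = list(),
                            screening = list(),
                            output_dir = NULL) {
  for (field in c("mu", "temperature", "seed")) {
    if (eval(call("missing", as.name(field)))) {
      stop("config field `", field, "` is required", call. = FALSE)
    }
  }
  stopifnot(is.numeric(mu), mu > 0)
  check_temperature(temperature)
  pmf_source <- match.arg(pmf_source)
  defaults <- function(x, d) utils::modifyList(d, x)
  cfg <- list(
    mu = mu, temperature = temperature, seed = as.integer(seed),
    landscape = landscape, bath_preset = bath_preset,
    cv_weight = cv_weight, dt = dt,
    string = defaults(string, list(M = 48L, tol = 1e-4)),
    pmf_source = pmf_source,
    umbrella = defaults(umbrella, list(n_windows = 32L, k_umb = 60,
                                       n_steps = 40000L, n_equil = 4000L,
                                       sample_every = 5L,
                                       bin_width = 0.05)),
    friction = defaults(friction, list(n_trajectories = 60L,
                                       n_steps = 50000L, max_lag = 8,
                                       mode = "pure")),
    shooting = defaults(shooting, list(n_shots = 60L, t_max = 50,
                                       ts_window = 0.1)),
    screening = defaults(screening, list(n_samples = 1500L)),
    output_dir = output_dir
  )
  class(cfg) <- "lk_config"
  cfg
}

#' Deterministic hash of a pipeline configuration
#'
#' MD5 of the canonical (name-sorted) JSON serialization; embedded in every
#' artifact header so outputs are traceable to their configuration.
#'
#' @param config An `lk_config` (or any list).
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[!vapply(x, is.null, logical(1))]
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  cfg <- canon(unclass(config))
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

.stage_log <- function(stage, t0, ...) {
  message(sprintf("[loopkin] %-10s %6.2fs %s", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(..., collapse = " ")))
}

#' Run the full loop-kinetics pipeline
#'
#' Executes every analysis stage on the synthetic loop model described by
#' the configuration and assembles a kinetics report mirroring the
#' quantities tabulated for a loop transition: equilibrium constant, TST
#' and friction-corrected rate constants, activation free energies,
#' barrier and friction frequencies, transmission coefficients (GH and
#' Kramers), friction regime, and the shooting reactive fraction.
#' Deterministic for a fixed config. When `output_dir` is set, artifacts
#' (path, profile, kernel, spectrum, shooting table, report JSON) are
#' written there with the config hash in their headers, and the string and
#' profile stages are resumed from matching cached artifacts on reruns.
#'
#' @param config An [pipeline_config()].
#' @return A `lk_report` list; artifacts on disk when `output_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "lk_config"))
  t0 <- as.numeric(Sys.time())
  hash <- config_hash(config)
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  art <- function(name) if (is.null(outdir)) NULL else
    file.path(outdir, name)

  ## landscape + order-parameter screening
  landscape <- if (inherits(config$landscape, "lk_landscape")) {
    config$landscape
  } else {
    do.call(landscape_spec, config$landscape)
  }
  cvs <- list(
    collective_variable("psi", "dihedral", weight = config$cv_weight),
    collective_variable("phi", "dihedral", weight = config$cv_weight))
  if (landscape$n_distances > 0) {
    cvs <- c(cvs, lapply(seq_len(landscape$n_distances), function(j) {
      collective_variable(paste0("d", j), "distance")
    }))
  }
  ns <- config$screening$n_samples
  closed_samp <- sample_basin(landscape, "closed", ns,
                              config$temperature,
                              seed = derive_seed(config$seed, 1L))
  open_samp <- sample_basin(landscape, "open", ns, config$temperature,
                            seed = derive_seed(config$seed, 2L))
  screening <- screen_order_parameters(closed_samp, open_samp, cvs)
  .stage_log("screen", t0, sum(screening$separated), "of",
             nrow(screening), "CVs separated")

  ## string relaxation to the MFEP
  path_file <- art("path.tsv")
  path <- NULL
  if (!is.null(path_file) && file.exists(path_file)) {
    cached <- .read_tsv_with_header(path_file)
    if (identical(cached$header$config_hash, hash)) {
      path <- read_path_tsv(path_file)
      .stage_log("string", t0, "resumed from cache")
    }
  }
  if (is.null(path)) {
    ep <- rbind(c(landscape$basin_centers$closed,
                  rep(landscape$distance$center, landscape$n_distances)),
                c(landscape$basin_centers$open,
                  rep(landscape$distance$center, landscape$n_distances)))
    path <- relax_string(landscape, ep, cvs = cvs,
                         M = config$string$M, tol = config$string$tol)
    if (!is.null(path_file)) {
      write_path_tsv(path, path_file)
      .append_hash(path_file, hash)
    }
    .stage_log("string", t0, "s* =", signif(path$s_star, 4), "| length",
               signif(max(path$arc_length), 4))
  }

  ## free-energy profile along the path
  analytic_profile <- path_energy_profile(landscape, path)
  analytic_profile$temperature <- config$temperature
  model <- gle_model(function(s) {
    stats::approx(analytic_profile$grid, analytic_profile$G, xout = s,
                  rule = 2, ties = "ordered")$y
  }, baths = bath_preset(config$bath_preset), mass = config$mu,
  dt = config$dt, temperature = config$temperature, seed = config$seed,
  s_range = range(analytic_profile$grid))

  prof_file <- art("profile.tsv")
  profile <- NULL
  if (!is.null(prof_file) && file.exists(prof_file)) {
    cached <- .read_tsv_with_header(prof_file)
    if (identical(cached$header$config_hash, hash)) {
      profile <- read_profile_tsv(prof_file)
      .stage_log("pmf", t0, "resumed from cache")
    }
  }
  if (is.null(profile)) {
    if (config$pmf_source == "umbrella") {
      u <- config$umbrella
      centers <- seq(min(path$arc_length) + 0.05 * diff(range(path$arc_length)),
                     max(path$arc_length) - 0.05 * diff(range(path$arc_length)),
                     length.out = u$n_windows)
      windows <- lapply(seq_along(centers), function(i) {
        tr <- sample_biased_window(model, centers[i], u$k_umb,
                                   n_steps = u$n_steps,
                                   n_equil = u$n_equil,
                                   sample_every = u$sample_every,
                                   seed = derive_seed(config$seed,
                                                      1000L + i))
        as_biased_window(tr)
      })
      profile <- wham(windows, temperature = config$temperature,
                      bin_width = u$bin_width)
    } else {
      profile <- analytic_profile
    }
    if (!is.null(prof_file)) {
      write_profile_tsv(profile, prof_file)
      .append_hash(prof_file, hash)
    }
    .stage_log("pmf", t0, "barrier",
               signif(max(profile$G, na.rm = TRUE), 4), "kcal/mol")
  }
  # the TS on the measured profile (nearest the string s*)
  near <- abs(profile$grid - path$s_star) <=
    0.15 * diff(range(profile$grid))
  s_star <- profile$grid[near][which.max(profile$G[near])]

  ## friction at the TS and Grote-Hynes transmission
  fr <- config$friction
  ts_trajs <- sample_ts_constrained(model, s_star,
                                    n_trajectories = fr$n_trajectories,
                                    n_steps = fr$n_steps,
                                    seed = derive_seed(config$seed, 3L))
  kernel <- friction_kernel(ts_trajs, max_lag = fr$max_lag,
                            mode = fr$mode)
  spectrum <- power_spectrum(kernel)
  bf <- barrier_frequency(profile, s_star, config$mu)
  gh <- grote_hynes(kernel, bf$omega_eq, unit = "rad_ps")
  .stage_log("friction", t0, "kappa_GH =", signif(gh$kappa_GH, 3),
             "| regime", gh$regime)

  ## rates with the GH transmission coefficient
  rates <- loop_rates(profile, s_star, config$mu, config$temperature,
                      kappa = gh$kappa_GH)
  .stage_log("rates", t0, "k_opening =", signif(rates$k_opening, 3),
             "1/s")

  ## TS shooting
  sh <- config$shooting
  partition <- default_partition(landscape, s_star = s_star)
  shots <- shoot(model, s_star, n_shots = sh$n_shots, t_max = sh$t_max,
                 ts_window = sh$ts_window, partition = partition,
                 path = path, seed = derive_seed(config$seed, 4L))
  .stage_log("shoot", t0, "reactive fraction",
             signif(shots$aggregate$reactive_fraction, 3))

  report <- structure(list(
    K_eq = rates$K_eq,
    k_opening = rates$k_opening,
    k_closing = rates$k_closing,
    k_TST_opening = rates$k_TST_opening,
    k_TST_closing = rates$k_TST_closing,
    kappa_GH = gh$kappa_GH,
    kappa_Kramers = gh$kappa_Kramers,
    omega_eq = gh$omega_eq,
    omega_r = gh$omega_r,
    omega_eq_wavenumber = gh$omega_eq_wavenumber,
    xi0_wavenumber = kernel$xi0_wavenumber,
    dG_eq = rates$dG_eq,
    dG_act_opening = rates$dG_act_opening,
    dG_act_closing = rates$dG_act_closing,
    dG_kappa = rates$dG_kappa,
    regime = gh$regime,
    reactive_fraction = shots$aggregate$reactive_fraction,
    reactive_ci95 = shots$aggregate$ci95,
    mean_residence_ps = shots$aggregate$mean_residence_ps,
    s_star = s_star,
    screening = screening,
    provenance = list(config_hash = hash, seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("loopkin")))
  ), class = "lk_report")

  if (!is.null(outdir)) {
    write_report_json(report, file.path(outdir, "report.json"))
    .write_tsv_with_header(
      data.frame(t = kernel$t, xi_total = kernel$xi_total,
                 kernel$xi_by_component, check.names = FALSE),
      list(type = "loopkin_kernel", config_hash = hash),
      file.path(outdir, "kernel.tsv"))
    .write_tsv_with_header(spectrum,
                           list(type = "loopkin_spectrum",
                                config_hash = hash),
                           file.path(outdir, "spectrum.tsv"))
    .write_tsv_with_header(shots$shots,
                           list(type = "loopkin_shots",
                                config_hash = hash),
                           file.path(outdir, "shots.tsv"))
  }
  report
}

.append_hash <- function(file, hash) {
  lines <- readLines(file)
  writeLines(c(lines[1], paste0("# config_hash: ", hash),
               lines[-1]), file)
}

#' @export
print.lk_report <- function(x, ...) {
  cat("Loop kinetics report\n",
      "  K_eq              ", signif(x$K_eq, 4), "\n",
      "  k_opening (1/s)   ", signif(x$k_opening, 4), "\n",
      "  k_closing (1/s)   ", signif(x$k_closing, 4), "\n",
      "  kappa_GH / Kramers", signif(x$kappa_GH, 3), "/",
      signif(x$kappa_Kramers, 3), "\n",
      "  omega_eq (cm^-1)  ", signif(x$omega_eq_wavenumber, 4), "\n",
      "  sqrt(xi0) (cm^-1) ", signif(x$xi0_wavenumber, 4), "\n",
      "  regime            ", x$regime, "\n",
      "  reactive fraction ", signif(x$reactive_fraction, 3), "\n")
  invisible(x)
}
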