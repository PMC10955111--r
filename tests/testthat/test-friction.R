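test_that("zero forces give an identically zero kernel", {
  tr <- fake_ts_trajectory(data.frame(f_a = rep(0, 2000)))
  k <- friction_kernel(list(tr), max_lag = 1)
  expect_true(all(k$xi_total == 0))
  expect_equal(k$zeta, 0)
})

test_that("kernel estimator contracts: labels and lag range", {
  tr <- fake_ts_trajectory(data.frame(f_a = rnorm(1000)))
  expect_error(friction_kernel(list(tr), max_lag = 0.5,
                               components = "missing"),
               "missing labels")
  expect_error(friction_kernel(list(tr), max_lag = 1.5), "half")
})

test_that("decomposition modes: single component, additivity, anticorrelation", {
  set.seed(14)
  n <- 20000
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), n))
  y <- as.numeric(stats::arima.sim(list(ar = 0.7), n))
  # single component: both modes equal the total kernel
  tr1 <- fake_ts_trajectory(data.frame(f_a = x))
  kp <- friction_kernel(list(tr1), max_lag = 2, mode = "pure")
  kj <- friction_kernel(list(tr1), max_lag = 2, mode = "projected")
  expect_equal(kp$xi_by_component[, "a"], kp$xi_total, tolerance = 1e-12)
  expect_equal(kj$xi_by_component[, "a"], kj$xi_total, tolerance = 1e-12)

  # two independent components: projected mode is exactly additive
  tr2 <- fake_ts_trajectory(data.frame(f_a = x, f_b = y))
  k2 <- friction_kernel(list(tr2), max_lag = 2, mode = "projected")
  expect_lt(max(abs(rowSums(k2$xi_by_component) - k2$xi_total)),
            1e-10 * max(abs(k2$xi_total)))
  # pure mode differs from the total only by the cross term
  k2p <- friction_kernel(list(tr2), max_lag = 2, mode = "pure")
  expect_equal(rowSums(k2p$xi_by_component) + k2p$cross_term,
               k2p$xi_total, tolerance = 1e-10)

  # anti-correlated components: pure-mode sum exceeds the total at t = 0
  tr3 <- fake_ts_trajectory(data.frame(f_a = x,
                                       f_b = -0.8 * x + 0.3 * y))
  k3 <- friction_kernel(list(tr3), max_lag = 2, mode = "pure")
  expect_gt(sum(k3$xi_by_component[1, ]), k3$xi_total[1])
  expect_lt(k3$cross_term[1], 0)

  # relabeling permutes the component kernels
  k_ba <- friction_kernel(list(tr2), max_lag = 2, mode = "pure",
                          components = c("b", "a"))
  expect_identical(unname(k_ba$xi_by_component[, "a"]),
                   unname(k2p$xi_by_component[, "a"]))
})

test_that("power spectrum of an exponential kernel is Lorentzian", {
  for (tau in c(0.2, 1)) {
    A <- 5
    t <- seq(0, 25 * tau, by = tau / 200)
    kern <- structure(list(t = t, xi_total = A * exp(-t / tau),
                           xi_by_component = matrix(A * exp(-t / tau),
                                                    dimnames = list(NULL, "a")),
                           dt = t[2], mode = "pure"),
                      class = "lk_kernel")
    sp <- power_spectrum(kern, taper = "none",
                         wavenumber_max = omega_to_wavenumber(10 / tau),
                         n_freq = 200)
    ref <- A * tau / (1 + (sp$omega * tau)^2)
    expect_lt(max(abs(sp$density - ref) / ref), 0.03)
  }
})

test_that("Parseval identity holds for the tapered transform", {
  t <- seq(0, 30, by = 0.01)
  kern <- structure(list(t = t, xi_total = 4 * exp(-t / 1.5),
                         dt = 0.01, mode = "pure"), class = "lk_kernel")
  sp <- power_spectrum(kern, taper = "hann", wavenumber_max = 3000,
                       n_freq = 3000)
  integral <- pracma::trapz(sp$omega, sp$density)
  expect_equal(integral, pi * 4 / 2, tolerance = 0.05)
})

test_that("slow baths concentrate spectral power at low wavenumber", {
  mk <- function(tau) {
    t <- seq(0, 30 * tau, length.out = 6000)
    structure(list(t = t, xi_total = exp(-t / tau) / tau, dt = t[2],
                   mode = "pure"), class = "lk_kernel")
  }
  # fraction of the total spectral weight pi*xi(0)/2 below a wavenumber,
  # with a frequency grid fine enough to resolve each Lorentzian
  frac_below <- function(tau, nu) {
    sp <- power_spectrum(mk(tau), wavenumber_max = nu, n_freq = 4000,
                         taper = "none")
    pracma::trapz(sp$omega, sp$density) / (pi * (1 / tau) / 2)
  }
  expect_gt(frac_below(50, 50), 0.95)     # tau = 50 ps: all below 50/cm
  expect_lt(frac_below(0.05, 200), 0.8)   # tau = 50 fs: spreads past 200/cm
})

test_that("barrier frequency from the profile top", {
  # exact inverted parabola built to give 409 1/cm at mu = 1
  mu <- 1
  om <- wavenumber_to_omega(409)
  curv <- om^2 * mu / lk_constants()$kcal_to_amuA2ps2
  s <- seq(-1, 1, by = 0.005)
  prof <- fep_from_values(s, 10 - 0.5 * curv * s^2)
  bf <- barrier_frequency(prof, 0, mu, window = 0.3)
  expect_equal(bf$omega_eq_wavenumber, 409, tolerance = 1e-6)
  # window halving stability on the smooth top
  bf2 <- barrier_frequency(prof, 0, mu, window = 0.15)
  expect_equal(bf2$omega_eq, bf$omega_eq, tolerance = 0.1)
  # flat top errors
  flat <- fep_from_values(s, rep(1, length(s)))
  expect_error(barrier_frequency(flat, 0, mu), "curvature")
  # noisy profile: recovery within 5%
  set.seed(6)
  noisy <- fep_from_values(s, 10 - 0.5 * curv * s^2 +
                             rnorm(length(s), 0, 0.05))
  bf3 <- barrier_frequency(noisy, 0, mu, window = 0.3)
  expect_equal(bf3$omega_eq, om, tolerance = 0.05)
})

test_that("Grote-Hynes: frictionless, memoryless and caging limits", {
  # no friction: omega_r = omega_eq, kappa = 1
  gh0 <- grote_hynes(exp_kernel(numeric(0), numeric(0)), 409)
  expect_equal(gh0$kappa_GH, 1)
  # memoryless kernel with zeta = 1.5 omega_eq: kappa = 0.5 exactly
  om <- wavenumber_to_omega(409)
  gh1 <- grote_hynes(memoryless_kernel(1.5 * om), 409)
  expect_equal(gh1$kappa_GH, 0.5, tolerance = 1e-9)
  expect_equal(gh1$kappa_Kramers, 0.5, tolerance = 1e-12)
  # kernel amplitude at the printed caging ratio: sqrt(xi0)/omega_eq = 960/409
  xi0 <- wavenumber_to_omega(960)^2
  ghc <- grote_hynes(exp_kernel(xi0, 0.02), 409)
  expect_identical(ghc$regime, "polarization_caging")
})

test_that("Grote-Hynes root matches the closed-form cubic for exponential kernels", {
  om_eq <- wavenumber_to_omega(409)
  cases <- list(c(A = 4000, tau = 0.05), c(A = 30000, tau = 0.02),
                c(A = 500, tau = 2), c(A = 8000, tau = 0.3))
  for (cs in cases) {
    gh <- grote_hynes(exp_kernel(cs["A"], cs["tau"]), 409)
    roots <- polyroot(c(-om_eq^2 / cs["tau"], cs["A"] - om_eq^2,
                        1 / cs["tau"], 1))
    real_pos <- Re(roots[abs(Im(roots)) < 1e-6 * om_eq & Re(roots) > 0])
    expect_equal(gh$omega_r, min(real_pos), tolerance = 1e-8)
    expect_equal(gh$kappa_GH, gh$omega_r / om_eq, tolerance = 1e-12)
  }
})

test_that("GH never falls below Kramers and responds monotonically to friction", {
  set.seed(12)
  for (i in 1:30) {
    nb <- sample(1:3, 1)
    kern <- exp_kernel(runif(nb, 10, 4e4), 10^runif(nb, -1.6, 0.8))
    gh <- grote_hynes(kern, 409)
    expect_gte(gh$kappa_GH, gh$kappa_Kramers - 1e-9)
    expect_gt(gh$kappa_GH, 0)
    expect_lte(gh$kappa_GH, 1)
  }
  # global kernel scaling: kappa decreases monotonically
  kappas <- vapply(c(0.5, 1, 2, 4, 8), function(scale) {
    grote_hynes(exp_kernel(6000 * scale, 0.1), 409)$kappa_GH
  }, numeric(1))
  expect_true(all(diff(kappas) < 0))
})

test_that("GH reduces to Kramers in the fast-bath limit at fixed static friction", {
  zeta <- 600
  tau <- 1e-3
  gh <- grote_hynes(exp_kernel(zeta / tau, tau), 409)
  expect_equal(gh$kappa_GH, gh$kappa_Kramers, tolerance = 0.01)
})

test_that("tabulated-kernel GH agrees with the analytic route", {
  A <- 6000; tau <- 0.3
  t <- seq(0, 6, by = 0.001)
  kern <- structure(list(t = t, xi_total = A * exp(-t / tau), dt = 0.001,
                         mode = "pure"), class = "lk_kernel")
  gh_tab <- grote_hynes(kern, 409)
  gh_ana <- grote_hynes(exp_kernel(A, tau), 409)
  expect_equal(gh_tab$kappa_GH, gh_ana$kappa_GH, tolerance = 1e-3)
  # undecayed kernel is refused
  slow <- structure(list(t = t, xi_total = A * exp(-t / 40), dt = 0.001,
                         mode = "pure"), class = "lk_kernel")
  expect_error(grote_hynes(slow, 409), "decayed")
})

test_that("multi-bath kernel parameters are recovered component-wise", {
  m <- gle_model(harmonic_profile(2),
                 baths = list(bath_mode("fast", 30, 0.5),
                              bath_mode("slow", 6, 5)),
                 mass = 1, dt = 0.002, temperature = 300, seed = 91)
  ts <- sample_ts_constrained(m, 0, n_trajectories = 60, n_steps = 50000)
  kern <- friction_kernel(ts, max_lag = 20)
  f_fast <- fit_exp_kernel(kern, component = "fast")
  f_slow <- fit_exp_kernel(kern, component = "slow")
  expect_equal(f_fast$A, 30, tolerance = 0.15)
  expect_equal(f_fast$tau, 0.5, tolerance = 0.25)
  expect_equal(f_slow$A, 6, tolerance = 0.15)
  expect_equal(f_slow$tau, 5, tolerance = 0.25)
  # total amplitude within 15%
  expect_equal(kern$xi_total[1], 36, tolerance = 0.15)
})
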