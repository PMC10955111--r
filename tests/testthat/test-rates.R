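test_that("equilibrium constant: symmetry, width ratio, Boltzmann shift", {
  # mirror-symmetric double well
  s <- seq(-4, 4, by = 0.002)
  p <- double_well_1d(barrier_height = 6, s_closed = -1.5, s_open = 1.5,
                      k_closed = 2, open_width_scale = 1,
                      barrier_width = 0.5)
  prof <- fep_from_fun(p, s)
  expect_equal(equilibrium_constant(prof, 0), 1, tolerance = 1e-6)

  # equal-depth wells, sigma_open = 2 sigma_closed -> K = 2
  p2 <- double_well_1d(barrier_height = 8, s_closed = -2, s_open = 2,
                       k_closed = 4, open_width_scale = 2,
                       barrier_width = 0.4)
  s2 <- seq(-5, 6, by = 0.002)
  prof2 <- fep_from_fun(p2, s2)
  mid <- abs(s2) < 1
  sstar <- s2[mid][which.max(prof2$G[mid])]
  expect_equal(equilibrium_constant(prof2, sstar), 2, tolerance = 0.02)

  # deepening the open well by kBT ln 40 multiplies K_eq by 40
  kT <- thermal_energy(300)$kcal
  p3 <- double_well_1d(barrier_height = 8, s_closed = -2, s_open = 2,
                       k_closed = 4, open_width_scale = 2,
                       barrier_width = 0.4, open_offset = -kT * log(40))
  prof3 <- fep_from_fun(p3, s2)
  expect_equal(equilibrium_constant(prof3, sstar) /
                 equilibrium_constant(prof2, sstar), 40,
               tolerance = 0.01 * 40)
})

test_that("equilibrium constant contracts: divider and visited bins", {
  s <- seq(-2, 2, by = 0.01)
  prof <- fep_from_values(s, 0.5 * s^2)
  expect_error(equilibrium_constant(prof, 3), "inside the profile")
  prof$G[100:105] <- NA
  expect_error(equilibrium_constant(prof, 0), "unvisited")
})

test_that("Maxwell-Boltzmann mean speed and the TST prefactor", {
  # in reduced units sqrt(2 kBT / (pi mu)) with kBT = mu = 1 is 0.79788
  kT <- thermal_energy(300)$amu
  expect_equal(mean_abs_velocity(1, 300) / sqrt(kT), sqrt(2 / pi),
               tolerance = 1e-12)
  # PTP1B-like reduced mass: 0.5 * <|sdot|> / C_s = 6.58 1/ps
  expect_equal(0.5 * mean_abs_velocity(0.917, 300), 6.58,
               tolerance = 1e-3)
})

test_that("TST rate reaches the harmonic (omega0 / 2 pi) limit for deep wells", {
  kT <- thermal_energy(300)$kcal
  mu <- 1
  for (curv in c(3, 8)) {
    dG <- 8
    sstar <- sqrt(2 * dG / curv)
    s <- seq(-sstar - 4, sstar + 0.4, by = 0.001)
    G <- ifelse(s <= sstar, 0.5 * curv * s^2, dG - 5 * (s - sstar))
    prof <- fep_from_values(s, G)
    # the kink at the divider can trip the local-maximum advisory
    r <- suppressWarnings(tst_rate(prof, sstar, mu, 300, "opening"))
    omega0 <- sqrt(curv * lk_constants()$kcal_to_amuA2ps2 / mu)
    k_harm <- omega0 / (2 * pi) * exp(-dG / kT) * 1e12
    expect_equal(r$k_TST, k_harm, tolerance = 0.02)
  }
})

test_that("rate bookkeeping: detailed balance and barrier monotonicity", {
  set.seed(31)
  s <- seq(-4, 5, by = 0.002)
  p <- double_well_1d()
  prof <- fep_from_fun(p, s)
  sstar <- s[which.max(prof$G)]
  r <- loop_rates(prof, sstar, 0.917, 300, kappa = 0.2)
  expect_equal(r$k_opening / r$k_closing, r$K_eq, tolerance = 1e-10)
  expect_equal(r$dG_eq, -thermal_energy(300)$kcal * log(r$K_eq),
               tolerance = 1e-12)
  # raising G(s_star) by delta scales both rates by exp(-delta/kBT)
  delta <- 0.8
  kT <- thermal_energy(300)$kcal
  bumped <- prof
  bumped$G <- prof$G + delta * exp(-(s - sstar)^2 / (2 * 0.05^2))
  r2 <- suppressWarnings(loop_rates(bumped, sstar, 0.917, 300,
                                    kappa = 0.2))
  expect_equal(r2$k_opening / r$k_opening, exp(-delta / kT),
               tolerance = 0.01)
  expect_equal(r2$k_closing / r$k_closing, exp(-delta / kT),
               tolerance = 0.01)
})

test_that("free energies from constants reproduce printed worked examples", {
  expect_equal(free_energies(K_eq = 1, temperature = 300)$dG_eq, 0)
  # experimental open/closed equilibrium of 40 near physiological T
  expect_equal(free_energies(K_eq = 40, temperature = 310)$dG_eq, -2.27,
               tolerance = 0.005)
  # a 470 1/s rate corresponds to a 13.9 kcal/mol Eyring barrier at 300 K
  expect_equal(free_energies(k = 470, temperature = 300)$dG_act, 13.9,
               tolerance = 0.01)
  expect_equal(free_energies(kappa = 0.17,
                             temperature = 300)$dG_kappa,
               -thermal_energy(300)$kcal * log(0.17))
  expect_error(free_energies(kappa = 1.2), "unphysical")
  expect_error(free_energies(kappa = 0), "positive")
})

test_that("serial rate combination", {
  expect_equal(combine_serial_rates(100, 100), 50)
  expect_equal(combine_serial_rates(1e15, 470), 470, tolerance = 1e-9)
  # diffusion (~800 ns) vs conformational step: the activated step limits
  k <- combine_serial_rates(1.25e6, 470)
  expect_equal(k, 469.8, tolerance = 0.01)
  expect_lte(k, min(1.25e6, 470))
  expect_error(combine_serial_rates(-1, 10), "positive")
  expect_error(combine_serial_rates(10, 0), "positive")
})

test_that("TST warns when the divider is not the local profile maximum", {
  s <- seq(-3, 3, by = 0.01)
  p <- double_well_1d(barrier_height = 5, s_closed = -1.5, s_open = 1.5,
                      k_closed = 2, open_width_scale = 1,
                      barrier_width = 0.4)
  prof <- fep_from_fun(p, s)
  expect_warning(tst_rate(prof, 0.5, 1, 300, "opening"), "local maximum")
})
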