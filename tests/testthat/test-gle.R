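test_that("equipartition holds for an equilibrium ensemble in a harmonic well", {
  # zero-coupling bath: microcanonical dynamics; equipartition is tested
  # over an ensemble initialized from the Boltzmann distribution
  k <- 2
  m <- gle_model(harmonic_profile(k), baths = list(bath_mode("null", 0, 1)),
                 mass = 1, dt = 0.002, temperature = 300, seed = 1)
  kT <- thermal_energy(300)$amu
  sig_s <- sqrt(kT / (k * lk_constants()$kcal_to_amuA2ps2))
  n_traj <- 120
  per_traj <- numeric(n_traj)
  set.seed(99)
  for (i in seq_len(n_traj)) {
    init <- list(s = rnorm(1, 0, sig_s), v = rnorm(1, 0, sqrt(kT)), z = 0)
    tr <- simulate_gle(m, 2000, init = init, sample_every = 20, seed = i,
                       check_stability = FALSE)
    per_traj[i] <- mean(tr$columns$v^2)
  }
  se <- sd(per_traj) / sqrt(n_traj)
  expect_lt(abs(mean(per_traj) - kT), 3 * se)
})

test_that("memory-bath dynamics equilibrate to the correct marginals", {
  # fluctuation-dissipation: long-run velocity and position variance
  m <- gle_model(harmonic_profile(2), baths = list(bath_mode("b", 4, 10)),
                 mass = 1, dt = 0.002, temperature = 300, seed = 3)
  tr <- simulate_gle(m, 8e5, sample_every = 10)
  kT <- thermal_energy(300)$amu
  expect_equal(var(tr$columns$v), kT, tolerance = 0.1)
  expect_equal(var(tr$columns$s), kT / (2 * lk_constants()$kcal_to_amuA2ps2),
               tolerance = 0.12)
})

test_that("friction kernel of a single bath is recovered from TS forces", {
  m <- gle_model(harmonic_profile(2), baths = list(bath_mode("b", 4, 10)),
                 mass = 1, dt = 0.002, temperature = 300, seed = 11)
  ts <- sample_ts_constrained(m, 0, n_trajectories = 40, n_steps = 50000)
  k <- friction_kernel(ts, max_lag = 30)
  sel <- k$t <= 30
  rms <- sqrt(mean((k$xi_total[sel] - 4 * exp(-k$t[sel] / 10))^2))
  expect_lt(rms, 0.1 * 4)
})

test_that("unbiased sampling respects detailed balance on a double well", {
  p <- double_well_1d(barrier_height = 1.5, s_closed = -1, s_open = 1,
                      k_closed = 3, open_width_scale = 1, barrier_width = 0.4)
  m <- gle_model(p, baths = list(bath_mode("solvent", 2000, 0.02)),
                 mass = 1, dt = 0.001, temperature = 300, seed = 5)
  tr <- simulate_gle(m, 4e6, sample_every = 50)
  s <- tr$columns$s
  # symmetric wells: occupancy near 1/2 each
  expect_lt(abs(mean(s > 0) - 0.5), 0.1)
  # KL divergence of the sampled marginal from exp(-G/kBT)
  br <- seq(-2.2, 2.2, by = 0.1)
  hh <- hist(s[abs(s) < 2.2], breaks = br, plot = FALSE)$density
  kT <- thermal_energy(300)$kcal
  mid <- br[-length(br)] + 0.05
  pth <- exp(-profile_energy(p, mid) / kT)
  pth <- pth / sum(pth * 0.1)
  sel <- hh > 0
  kl <- sum(hh[sel] * log(hh[sel] / pth[sel])) * 0.1
  expect_lt(kl, 0.03)
})

test_that("trajectories are bit-identical under a fixed seed", {
  m <- gle_preset("moderate_friction", seed = 21)
  t1 <- simulate_gle(m, 5000, sample_every = 5)
  t2 <- simulate_gle(m, 5000, sample_every = 5)
  expect_identical(t1$columns, t2$columns)
  ts1 <- sample_ts_constrained(m, 0, n_trajectories = 2, n_steps = 1000)
  ts2 <- sample_ts_constrained(m, 0, n_trajectories = 2, n_steps = 1000)
  expect_identical(ts1[[1]]$columns, ts2[[1]]$columns)
})

test_that("recorded force components sum exactly to the total", {
  m <- gle_preset("caging", seed = 8)
  tr <- simulate_gle(m, 2000, sample_every = 2)
  cols <- tr$columns
  recon <- cols$f_landscape + cols$f_backbone_torsion +
    cols$f_sidechain_torsion + cols$f_solvent
  expect_lt(max(abs(recon - cols$f_total)), 1e-10 * max(abs(cols$f_total)))
  # angular-free check: s stays in the simulated range
  expect_true(all(cols$s >= m$s_range[1] & cols$s <= m$s_range[2]))
})

test_that("biased window sampling is Gaussian with variance kBT/k on a flat landscape", {
  flat <- harmonic_profile(1e-9, s_range = c(-30, 30))
  m <- gle_model(flat, baths = list(bath_mode("solvent", 1000, 0.02)),
                 mass = 1, dt = 0.001, temperature = 300, seed = 13)
  k_umb <- 20
  tr <- sample_biased_window(m, 0, k_umb, n_steps = 2e5, n_equil = 5000,
                             sample_every = 100)
  s <- tr$columns$s
  kT <- thermal_energy(300)$kcal
  expect_equal(var(s), kT / k_umb, tolerance = 0.1)
  expect_equal(mean(s), 0, tolerance = 3 * sd(s) / sqrt(length(s) / 5))
  # chi-square goodness of fit against the Gaussian reference
  q <- qnorm(seq(0.1, 0.9, by = 0.1), 0, sqrt(kT / k_umb))
  counts <- table(cut(s, c(-Inf, q, Inf)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("biased window guards: stiff bias warns, bad center errors", {
  m <- gle_model(harmonic_profile(2), baths = list(bath_mode("b", 100, 0.1)),
                 mass = 1, dt = 0.002, temperature = 300, seed = 2)
  expect_warning(sample_biased_window(m, 0, 500, n_steps = 500,
                                      n_equil = 100),
                 "stiff bias")
  expect_error(sample_biased_window(m, 99, 10, n_steps = 500), "range")
})

test_that("unstable timestep is caught by the energy-drift probe", {
  stiff <- harmonic_profile(5000, s_range = c(-1, 1))
  m <- gle_model(stiff, baths = list(), mass = 1, dt = 0.002,
                 temperature = 300, seed = 1)
  expect_error(simulate_gle(m, 1000, init = list(s = 0.3, v = 0,
                                                 z = numeric(0))),
               "unstable")
})

test_that("model validation rejects bad configurations", {
  expect_error(gle_model(harmonic_profile(2),
                         baths = list(bath_mode("a", 1, 0.01)),
                         dt = 0.002),
               "resolve")
  expect_error(gle_model(harmonic_profile(2),
                         baths = list(bath_mode("a", 1, 1),
                                      bath_mode("a", 2, 2))),
               "unique")
  expect_error(bath_mode("b", -1, 1))
  expect_error(bath_mode("b", 1, 0))
})

test_that("TS-constrained sampling: constraint exact, baths independent", {
  m <- gle_model(harmonic_profile(2),
                 baths = list(bath_mode("b1", 6, 0.5),
                              bath_mode("b2", 3, 5)),
                 mass = 1, dt = 0.002, temperature = 300, seed = 17)
  ts <- sample_ts_constrained(m, 0.25, n_trajectories = 6,
                              n_steps = 20000)
  for (tr in ts) expect_true(all(tr$columns$s == 0.25))
  # the two labeled bath forces are statistically independent
  cors <- vapply(ts, function(tr) {
    cor(tr$columns$f_b1, tr$columns$f_b2)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 / sqrt(6 * 20000 / 2500))
  # zero-coupling bath produces identically zero projected force
  m0 <- gle_model(harmonic_profile(2), baths = list(bath_mode("z", 0, 1)),
                  mass = 1, dt = 0.002, seed = 1)
  ts0 <- sample_ts_constrained(m0, 0, n_trajectories = 1, n_steps = 500)
  expect_true(all(ts0[[1]]$columns$f_z == 0))
})
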