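# loopkin

Activation and friction analysis of protein loop opening/closing
kinetics.

Enzyme active-site loops — the WPD loop of protein tyrosine phosphatases
(PTP1B, YopH), the M20 loop of *E. coli* dihydrofolate reductase —
interconvert between open and closed conformations on millisecond to
second timescales. `loopkin` implements the kinetic framework that
explains those rates as **activated barrier crossing along a path
collective variable** with strong, time-dependent internal friction:

* order-parameter screening (which torsions/distances separate the
  states),
* a simplified string method relaxing to the minimum free-energy path
  (MFEP) and the scalar path coordinate *s* (amu^1/2 Å),
* umbrella sampling + WHAM reconstruction of the potential of mean force
  G(s) with block-bootstrap uncertainties,
* equilibrium constants and transition-state-theory rates,

  k = κ·k^TST,  k^TST = ½⟨|ṡ|⟩ C_s⁻¹ exp(−ΔG‡_s/k_BT),
  K_eq = ∫_open C_s⁻¹ e^(−G/k_BT) ds / ∫_closed C_s⁻¹ e^(−G/k_BT) ds,

* time-dependent friction kernels from TS-constrained projected forces,
  ξ(t) = ⟨F_s(0)F_s(t)⟩‡/k_BT, their component decomposition and power
  spectra,
* the Grote–Hynes transmission coefficient (root of
  ω_r² − ω_eq² + ω_r·ξ̂(ω_r) = 0, κ = ω_r/ω_eq), the Kramers limit, and
  friction-regime classification (polarization caging when
  √ξ(0) > ω_eq),
* transition-state trajectory shooting (committor-style reactive
  fraction and the flux-weighted transmission estimator), TS residence
  times, and diffusive-displacement analysis (MSD → D → completion
  time).

Because the original all-atom trajectories cannot be regenerated at desk
scale, the package ships a synthetic generator: analytic model
free-energy landscapes for the torsional flip (two- or three-state,
periodic, with a sharp barrier and a wide open valley) and a generalized
Langevin simulator with exponential memory baths (exact
Ornstein–Uhlenbeck embedding, compiled with Rcpp) that produces every
input the analysis stages consume — unbiased runs, umbrella windows,
TS-constrained force series, and shooting ensembles. See the methods
vignette (`vignettes/loop-kinetics.Rmd`) for the model, its assumptions,
and all numerical choices.

## Worked example

The caging-regime preset: a 12 kcal/mol torsional barrier whose friction
amplitude (√ξ(0) ≈ 960 cm⁻¹) exceeds the barrier frequency
(ω_eq ≈ 400 cm⁻¹), so the environment dynamically traps the system at
the transition state.

```r
library(loopkin)
model <- gle_preset("caging", seed = 1)

# free-energy profile along the path coordinate
s <- seq(-5, 10, by = 0.002)
profile <- double_well_1d()
G <- profile_energy(profile, s)
fep <- structure(list(grid = s, G = G - min(G), stderr = rep(0, length(s)),
                      C_s = 1, temperature = 300, bin_width = 0.002,
                      visited = rep(TRUE, length(s))), class = "lk_fep")
s_star <- s[abs(s) < 1.5][which.max(fep$G[abs(s) < 1.5])]

# friction at the constrained TS and the Grote-Hynes transmission
ts <- sample_ts_constrained(model, s_star, n_trajectories = 60,
                            n_steps = 50000)
kernel <- friction_kernel(ts, max_lag = 8)
print(kernel)
#> Friction kernel (pure mode, 60 trajectories): xi(0) = 32840 ps^-2
#> (sqrt = 962.1 cm^-1) | zeta = 5235 1/ps
omega <- barrier_frequency(fep, s_star, mu = 0.917)
gh <- grote_hynes(kernel, omega$omega_eq, unit = "rad_ps")
print(gh)
#> Grote-Hynes solution: omega_eq = 402.2 cm^-1 | omega_r = 34.66 cm^-1 |
#> kappa_GH = 0.08616 | kappa_Kramers = 0.01447 | regime: polarization_caging

# rate constants with the GH transmission coefficient
rates <- loop_rates(fep, s_star, mu = 0.917, temperature = 300,
                    kappa = gh$kappa_GH)
print(rates)
#> Loop kinetics: K_eq = 2.365 | k_opening = 365.1 1/s |
#> k_closing = 154.4 1/s | kappa = 0.08616
```

Reading the output: the estimated kernel reproduces the bath
specification (√ξ(0) = 962 vs 960 cm⁻¹ by construction); because
√ξ(0) > ω_eq the regime is polarization caging; Grote–Hynes transmits
κ ≈ 0.086 where the memoryless Kramers estimate would give 0.014 — the
frequency dependence of the friction matters by a factor of six; and the
friction-corrected opening rate lands in the 10²–10³ s⁻¹ decade
characteristic of WPD-loop opening. `run_pipeline(pipeline_config(...))`
chains the same stages — including order-parameter screening, string
relaxation on the two-torsion landscape, and umbrella/WHAM profile
reconstruction — into a single seeded, cached, artifact-writing run.

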