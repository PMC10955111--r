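---
title: "Activated loop opening and closing: models and methods in loopkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activated loop opening and closing: models and methods in loopkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopkin)
```

## The problem

Active-site loops such as the WPD loop of protein tyrosine phosphatases or
the M20 loop of dihydrofolate reductase interconvert between open and
closed conformations on the millisecond-to-second timescale, far slower
than any diffusive loop displacement would suggest. The kinetic picture
this package implements treats the transition as **activated barrier
crossing along a path collective variable**: the rotation of a single
backbone peptide group (a concerted flip of one psi/phi pair) creates a
sharp torsional free-energy barrier, while the anchoring salt-bridge
distances only add a rugged but nearly flat background. The rate is then

$$k = \kappa \, k^{\mathrm{TST}}, \qquad
k^{\mathrm{TST}} = \tfrac{1}{2}\,\langle|\dot s|\rangle\,C_s^{-1}
\exp\!\left(-\Delta G^{\ddagger}_s / k_B T\right),$$

with the transmission coefficient $\kappa$ obtained from Grote-Hynes (GH)
theory: the reactive frequency $\omega_r$ solves

$$\omega_r^2 - \omega_{eq}^2 +
\omega_r \int_0^{\infty} \xi(t)\, e^{-\omega_r t}\, dt = 0,
\qquad \kappa = \omega_r / \omega_{eq},$$

where $\xi(t)$ is the time-dependent friction kernel, estimated from the
autocorrelation of the forces projected on the reaction coordinate with
the system constrained at the transition state (TS),
$\xi(t) = \langle F_s(0) F_s(t)\rangle_{\ddagger} / (k_B T)$ in
mass-weighted coordinates. When the initial friction amplitude
$\sqrt{\xi(0)}$ exceeds the barrier frequency $\omega_{eq}$, the
environment transiently traps the system at the TS — the *polarization
caging* regime — and the memoryless Kramers estimate badly overestimates
the effect of friction.

Because the all-atom trajectories behind such an analysis cannot be
regenerated at desk scale, the package pairs every analysis stage with a
**synthetic generator** whose statistical structure mimics the real data:
a model free-energy landscape with a sharp torsional barrier and a wide
open valley, and a generalized Langevin (GLE) simulator whose bath
components realize any exponential-mixture friction kernel exactly.

## The synthetic model and what it emulates

### Landscape

`landscape_spec()` builds an analytic, 360-degree-periodic surface over a
psi-like and a phi-like torsion: two periodic harmonic basins combined by
a soft-min (so energies and gradients are analytic everywhere), a
Gaussian-in-circular-distance barrier bump at the saddle, optional
torsion-torsion coupling, an optional high-energy intermediate (the
three-state variant seen for the DHFR M20 loop, where the relaxation of a
contiguous torsion produces a second barrier), and optional distance
coordinates with sinusoidal ruggedness of at most a couple of kcal/mol —
the "salt bridges break and re-form cheaply" regime. The bump height is
compensated for the well-arm energy at the saddle so the *realized*
barrier matches the requested height.

The one-dimensional profile used by the dynamics, `double_well_1d()`,
uses a raised-cosine barrier with compact support instead of a Gaussian:
outside the bump the basins are exactly harmonic, so the open/closed
width ratio (default 3, the entropic wide-open valley) and the barrier
top curvature can be controlled independently. Defaults: barrier 12
kcal/mol, well centers at $\mp 2.2$ amu$^{1/2}$ A, closed-well curvature
2.39 kcal/mol per unit$^2$, bump half-width 2.13 units — which makes
$\omega_{eq} \approx 409$ cm$^{-1}$ at reduced mass 0.917.

### Dynamics

`gle_model()` + `simulate_gle()` integrate 1D GLE dynamics of the path
coordinate. Memory friction is realized by a **Markovian embedding**: each
kernel component $\xi_i(t) = A_i e^{-t/\tau_i}$ becomes an auxiliary
Ornstein-Uhlenbeck (OU) acceleration variable with an exact OU substep,
inside a symmetric velocity-Verlet splitting; the fluctuation-dissipation
theorem fixes the noise amplitudes, and the long-run marginals reproduce
$e^{-G/k_BT}$ (tested). The default timestep is 2 fs; presets with a
20-fs bath use 1 fs, keeping `dt < 0.1 * min(tau)` (enforced). A
1000-step frictionless probe aborts on unstable timesteps.

A deliberate reduction: the multi-dimensional CV landscape enters the
dynamics only through its profile along the converged string path (a
"tube" approximation; orthogonal motion is not simulated). This is
exactly the 1D-GLE picture the rate theory assumes, it keeps every
operation testable against closed forms, and the multi-dimensional
landscape is still exercised analytically by the screening, string and
classification stages. What the generator therefore does **not** emulate:
multidimensional recrossing of a curved dividing surface, anharmonic
bath coupling, non-exponential kernels (any kernel in scope is a sum of
exponentials), and explicit solvent structure. Passing tests show the
analysis stages are correct on data with the right statistical structure;
they cannot certify force-field or sampling choices for real proteins.

### Friction presets

`bath_preset()` fixes the three study conditions:

* `caging` — caging regime: $\xi(0) = 32700$ ps$^{-2}$ so that
  $\sqrt{\xi(0)} = 960$ cm$^{-1}$, about 2.35 times the default barrier
  frequency (the printed caging ratio 960/409); dominated by a fast
  large-amplitude backbone-torsion component (A = 30200 ps$^{-2}$,
  tau = 20 fs) with a slow sidechain-torsion tail (2000, 2 ps) and a
  small solvent term (500, 0.1 ps). This yields kappa_GH near 0.09,
  kappa_Kramers near 0.015, and friction-corrected opening rates in the
  $10^2$–$10^3$ s$^{-1}$ decade on the default profile.
* `moderate_friction` — single fast bath (8000 ps$^{-2}$, 20 fs),
  kappa_GH near 0.6; the regime used for the shooting-vs-GH comparison.
* `low_friction` — (300 ps$^{-2}$, 20 fs), near-TST transmission.

The published work does not parameterize its kernel analytically; these
presets match only the two printed amplitudes (960 and 409 cm$^{-1}$)
and the qualitative decomposition (protein torsions dominate, solvent
minor), not the full kernel shape.

## Analysis stages and numerical choices

**Order-parameter screening** (`screen_order_parameters()`): overlap
coefficient = integral of the pointwise minimum of two histogram density
estimates (100 bins), periodic-aware — dihedral samples are recentred on
their pooled circular mean before binning so modes at the $\pm 180$ seam
are not split. Verdict "separated" below overlap 0.05 by default.

**String relaxation** (`relax_string()`): simplified string method on an
analytic (or pre-estimated) landscape — gradient descent on every
interior node followed by reparameterization to equal arc-length spacing,
until the per-iteration displacement falls below $10^{-4}$
amu$^{1/2}$ A (default M = 48 nodes). The on-the-fly sampling updates of
the adaptive string method are deliberately replaced by this analytic
relaxation. The descent step is scale-free (a fixed fraction of the node
spacing for the largest-gradient node). Reparameterization measures arc
length on the densified current polyline and assigns nodes equal
positions of that parameter, so total length is conserved exactly and
spacing is exactly uniform in the path parameter; chord lengths of a
curved path differ from it at second order in the node spacing.
Dihedral nodes are stored on a continuous unwrapped branch (each node in
the branch nearest its predecessor), so arc length never jumps by a
period.

**Projection** (`project_on_path()`): continuous piecewise-linear nearest
point in weighted CV space (not Voronoi cells) — simpler than the
reference path-CV construction and adequate for these analysis stages;
each segment sees the query point wrapped into its own branch; ties
between non-adjacent segments resolve to the smallest s (logged).

**Umbrella sampling + WHAM** (`sample_biased_window()`, `wham()`):
binned WHAM (default bin width 0.05 amu$^{1/2}$ A) iterated to
$10^{-8}$ kcal/mol on the window free energies, gauge fixed at min G = 0.
Windows are canonically sorted so the result is bit-identical under input
permutation; a disconnected window graph is an error naming the gap.
Unvisited bins are flagged, never interpolated; the "sampled range" for
error statements is defined by a minimum bin occupancy (100 samples in
the acceptance checks). Uncertainties come from a block bootstrap over
decorrelated segments (block length = integrated-autocorrelation
statistical inefficiency, capped at a tenth of the window), 95%
percentile CIs, flagged wide when any window has fewer than 10 blocks.

**Rates** (`equilibrium_constant()`, `tst_rate()`, `loop_rates()`):
trapezoidal Boltzmann integrals on the profile grid, split at $s^\ddagger$
(configurable bounds for narrower state definitions). The activation free
energy entering the TST rate is measured from the reactant-side ensemble,
$\Delta G^{\ddagger}_s = G(s^\ddagger) + k_BT\ln\!\big(C_s^{-1}\int_R
e^{-G/k_BT} ds\big)$ — the form consistent with the flux-over-population
definition. The reactant integral spans the full reactant side, as the
equilibrium-constant integral does. Opening and closing rates are built
from the same integrals, so $K_{eq} = k_{opening}/k_{closing}$ holds to
rounding and is revalidated at report serialization. The Eyring-form
bookkeeping $\Delta G^{\ddagger} = -k_BT\ln(kh/k_BT)$ is definitional and
uses a different prefactor than the flux expression; both are implemented
as printed. The $10^{12}$ ps-to-s factor is applied exactly once, at the
rate-assembly boundary. Default temperature for worked examples is 300 K
(the source never prints its simulation temperature; 298–310 K moves
$k_BT$ by under 3%).

**Friction kernels** (`friction_kernel()`): FFT-based, time-origin- and
ensemble-averaged autocorrelations divided by $k_BT$ (mass-weighted), from
the conventional 60 TS-constrained trajectories. Forces are demeaned with
the *ensemble* mean: per-trajectory demeaning of a slowly decorrelating
force biases the kernel tail downward (a 40% error on a 10-ps timescale
at 100-ps trajectories, versus a few percent with the ensemble mean).
Decomposition modes: `pure` (self-correlation of each labeled component;
the zeroed-force-field style; components need not sum to the total — the
cross term is reported) and `projected` (symmetrized component-total
cross-correlation; exactly additive). Power spectra are one-sided cosine
transforms with a Hann taper by default; the exact windowing behind the
published spectra is unstated, so the taper is configurable.

**Grote-Hynes** (`grote_hynes()`): the kernel Laplace transform is taken
over the full stored support; a tabulated kernel must have decayed below
1% of $\xi(0)$ (averaged over the last tenth of the lag range, so
pointwise estimator noise does not trip the guard) or the truncated
transform is refused. The root is bracketed on $(0, \omega_{eq}]$
(uniroot, relative tolerance $10^{-12}$); for exponential kernels it
matches the closed-form cubic root to $10^{-8}$, and a memoryless kernel
reproduces Kramers exactly,
$\kappa_{Kr} = \sqrt{1 + (\zeta/2\omega_{eq})^2} - \zeta/2\omega_{eq}$ —
the standard spatial-diffusion expression, chosen because the source
quotes its Kramers value without a formula. Regime taxonomy:
`polarization_caging` when $\sqrt{\xi(0)} > \omega_{eq}$ (the criterion
behind the 960-versus-409 comparison), `nonadiabatic` when friction
barely bites ($\kappa > 0.9$), `intermediate` otherwise.
$\sqrt{\xi(0)}$ is reported in cm$^{-1}$ so the comparison with
$\omega_{eq}$ is dimensionally coherent.

**Shooting** (`shoot()`): TS configurations (position within
$|s - s^\ddagger| \le 0.1$ amu$^{1/2}$ A, Boltzmann-weighted, plus the
bath state) receive one Maxwell-Boltzmann velocity each and are
propagated forward and, with reversed velocity and the same bath state,
backward. A trajectory is *reactive* when its two ends lie in different
basins (committor-style, stricter than forward-only; recrossers ending on
the same side count nonreactive); endpoints outside every basin are
"indeterminate" and excluded with a logged count. Two aggregates are
reported: the unweighted reactive fraction with its exact binomial CI
(the qualitative count used in the source methodology, e.g. 13 of 60),
and the velocity-weighted reactive-flux transmission coefficient
`kappa_flux` with a bootstrap CI. For stochastic GLE dynamics the
backward shot cannot be a deterministic time reversal (the OU innovations
are fresh noise), and the unweighted fraction does not converge to
$\kappa_{GH}$ in any friction regime; the flux-weighted estimator is the
quantity GH theory predicts for a parabolic barrier and agrees with it at
moderate friction (0.56 +/- 0.03 versus 0.59 at 200 shots). Basin
classification maps endpoint s values through the string path into the
rectangular psi/phi boxes of a `state_partition()` (closed boundaries;
periodic membership; default boxes $\pm 60$ degrees around the basin
centers); without a path, endpoints are classified on s directly with a
capture distance.

**Diffusive displacement** (`estimate_diffusion()`): time-origin-averaged
ensemble MSD, least-squares line over the low-lag window (1–15% of the
maximum lag by default, where the estimator variance is smallest),
D = slope/2, completion time $L^2/2D$. Non-diffusive inputs are flagged
both by fit quality ($R^2 < 0.9$) and by the MSD scaling exponent
($|\alpha - 1| > 0.3$ — straight-line/ballistic motion has $\alpha = 2$
yet can fit a line with high $R^2$). At the reference size (20 paths of
1000 points) the D estimate carries a sampling spread of roughly 8%.

## Pipeline and sizes

`run_pipeline()` chains screen, string, umbrella/WHAM (or analytic
profile), rates, TS friction, GH, and shooting on the 2D model
landscape, with a single master seed, per-stage derived seeds, a config
hash embedded in every artifact header, and cache-based resumption of the
string and profile stages. Artifacts are plain TSV with typed headers and
JSON reports, all round-tripping at full double precision. Default sizes
(32 windows of 40 ps, 60 TS trajectories of 50 ps, 60 shots of 50 ps at
1-fs steps) complete in well under a minute on one CPU; the test suite
uses smaller versions of the same conditions, and the acceptance checks
use the sizes stated with each criterion (60 x 100 ps kernels, 32 x 1e5
umbrella samples, 200 shots). At these sizes the remaining statistical
spread is visible and quantified above (kernel amplitude ~6–9%,
kappa_flux ~0.03, WHAM maximum error ~0.2–0.33 kcal/mol), comparable in
spirit to the ~1.1 kcal/mol uncertainty quoted for the original
activation free energies.

## Known limitations

* One-dimensional dynamics along the path: no orthogonal relaxation, so
  committor and recrossing statistics reflect the 1D GLE, not a
  multidimensional surface.
* Exponential-mixture kernels only; a genuinely algebraic kernel tail is
  outside the embedding's scope.
* The string stage needs an analytic or pre-estimated landscape gradient;
  sampling-based string updates are not implemented.
* K_eq from the pipeline inherits umbrella-sampling noise under the
  slow caging bath (about 0.5–1 kcal/mol on the well free-energy
  difference at default sizes); detailed-balance consistency of the
  reported rates is exact by construction regardless.
* The unweighted reactive fraction is a qualitative diagnostic; use
  `kappa_flux` for quantitative comparison with GH.
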