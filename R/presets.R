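#' Bath presets for the GLE loop models
#'
#' Three reference friction environments:
#' \describe{
#'   \item{caging}{Polarization-caging regime: total kernel amplitude
#'     `xi(0) = 32700 ps^-2` so that `sqrt(xi(0))` is 960 1/cm, about 2.35
#'     times the ~409 1/cm barrier frequency of the default 12 kcal/mol
#'     profile. Dominated by a fast, large-amplitude backbone-torsion
#'     component with a slow sidechain-torsion tail and a small solvent
#'     term.}
#'   \item{low_friction}{Weak fast friction; near-TST transmission.}
#'   \item{moderate_friction}{A single fast bath of intermediate
#'     amplitude, transmission coefficient around 0.6; the regime where
#'     the shooting reactive fraction tracks the Grote-Hynes estimate.}
#' }
#'
#' @param name Preset name.
#' @return List of [bath_mode()] objects.
#' @export
bath_preset <- function(name = c("caging", "low_friction",
                                 "moderate_friction")) {
  name <- match.arg(name)
  switch(name,
    caging = list(
      bath_mode("backbone_torsion", 30200, 0.02),
      bath_mode("sidechain_torsion", 2000, 2.0),
      bath_mode("solvent", 500, 0.1)
    ),
    low_friction = list(bath_mode("solvent", 300, 0.02)),
    moderate_friction = list(bath_mode("solvent", 8000, 0.02))
  )
}

#' Ready-made GLE loop models
#'
#' The default analytic double-well profile (12 kcal/mol torsional
#' barrier, open basin 3x wider than closed) combined with a
#' [bath_preset()]; reduced mass 0.917 as for a PTP1B-like weighted
#' reaction coordinate, integration step 1 fs to resolve the fastest bath.
#'
#' @param name Preset name (see [bath_preset()]).
#' @param seed Master seed.
#' @param temperature Temperature, K.
#' @param profile Optional profile override.
#' @return A [gle_model()].
#' @export
gle_preset <- function(name = c("caging", "low_friction",
                                "moderate_friction"),
                       seed = 1, temperature = 300, profile = NULL) {
  name <- match.arg(name)
  gle_model(profile %||% double_well_1d(),
            baths = bath_preset(name),
            mass = 0.917, dt = 0.001, temperature = temperature,
            seed = seed)
}

#' Metropolis sampling of one landscape basin
#'
#' Random-walk Metropolis Monte Carlo on the model landscape, started at a
#' basin center, used to generate the per-state CV samples consumed by the
#' order-parameter screening. With the default proposal the walker explores
#' its basin but does not cross the (many-kBT) torsional barrier on the
#' chain lengths used here.
#'
#' @param landscape An `lk_landscape`.
#' @param state "closed" or "open".
#' @param n Number of retained samples.
#' @param temperature Temperature, K.
#' @param step_deg Proposal standard deviation for angles, degrees.
#' @param step_dist Proposal SD for distance coordinates, Angstrom.
#' @param thin Keep every `thin`-th state.
#' @param seed RNG seed.
#' @return Data frame with columns `psi`, `phi` (and `d1`, ... when the
#'   landscape has distance coordinates).
#' @export
sample_basin <- function(landscape, state = c("closed", "open"), n = 2000,
                         temperature = 300, step_deg = 8, step_dist = 0.4,
                         thin = 5L, seed = 1) {
  state <- match.arg(state)
  set.seed(as.integer(seed %% 2147483647))
  kT <- thermal_energy(temperature)$kcal
  d <- .landscape_dim(landscape)
  x <- c(landscape$basin_centers[[state]],
         rep(landscape$distance$center, landscape$n_distances))
  e <- landscape_energy(landscape, x)
  sds <- c(rep(step_deg, 2), rep(step_dist, landscape$n_distances))
  out <- matrix(NA_real_, n, d)
  kept <- 0L
  while (kept < n) {
    for (j in seq_len(thin)) {
      prop <- x + stats::rnorm(d, 0, sds)
      prop[1:2] <- wrap_angle(prop[1:2])
      e_prop <- landscape_energy(landscape, prop)
      if (stats::runif(1) < exp(-(e_prop - e) / kT)) {
        x <- prop
        e <- e_prop
      }
    }
    kept <- kept + 1L
    out[kept, ] <- x
  }
  out <- as.data.frame(out)
  names(out) <- c("psi", "phi",
                  if (landscape$n_distances > 0)
                    paste0("d", seq_len(landscape$n_distances)))
  out
}
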