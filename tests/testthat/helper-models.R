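# Fixture builders shared across the suite. Everything is generated in
# code; sizes are kept small except where a check needs the statistics.

# simple analytic harmonic profile along s (kcal/mol per s-unit^2)
harmonic_profile <- function(k = 2, center = 0, s_range = c(-4, 4)) {
  structure(list(wells = list(list(center = center, k = k, offset = 0)),
                 bumps = list(), gamma = 0.5, s_range = s_range),
            class = "lk_profile_fun")
}

# tabulated lk_fep from an analytic profile (gauge min 0)
fep_from_fun <- function(p, s, temperature = 300) {
  G <- profile_energy(p, s)
  structure(list(grid = s, G = G - min(G), stderr = rep(0, length(s)),
                 C_s = 1, temperature = temperature,
                 bin_width = s[2] - s[1],
                 visited = rep(TRUE, length(s))),
            class = "lk_fep")
}

# tabulated lk_fep straight from values
fep_from_values <- function(s, G, temperature = 300) {
  structure(list(grid = s, G = G - min(G), stderr = rep(0, length(s)),
                 C_s = 1, temperature = temperature,
                 bin_width = s[2] - s[1],
                 visited = rep(TRUE, length(s))),
            class = "lk_fep")
}

# a hand-built TS-constrained trajectory carrying arbitrary force columns
fake_ts_trajectory <- function(fmat, dt = 0.002, temperature = 300,
                               mass = 1) {
  fmat <- as.data.frame(fmat)
  cols <- data.frame(s = rep(0, nrow(fmat)), v = 0,
                     f_landscape = 0)
  cols <- cbind(cols, fmat)
  cols$f_total <- rowSums(fmat) + cols$f_landscape
  structure(list(dt = dt, time = (seq_len(nrow(fmat)) - 1) * dt,
                 columns = cols, length = nrow(fmat),
                 metadata = list(temperature = temperature, mass = mass,
                                 seed = 0, dt_integration = dt,
                                 bias = list(type = "ts_constraint"),
                                 bath_labels = sub("^f_", "",
                                                   names(fmat)))),
            class = "lk_trajectory")
}

# dense steepest-descent MFEP oracle: follow -grad from just off the
# saddle in both directions with small Euler steps until the gradient
# norm drops below tol (a basin)
steepest_descent_path <- function(gradient, saddle, direction,
                                  h = 0.005, max_steps = 20000,
                                  gtol = 1e-4) {
  x <- saddle + direction * h
  out <- matrix(NA_real_, max_steps, length(saddle))
  for (i in seq_len(max_steps)) {
    g <- gradient(matrix(x, 1))
    out[i, ] <- x
    if (sqrt(sum(g^2)) < gtol) break
    x <- x - h * g / sqrt(sum(g^2))
  }
  out[seq_len(i), , drop = FALSE]
}

# distance from a point to a polyline
dist_to_polyline <- function(p, poly) {
  d2 <- rep(NA_real_, nrow(poly) - 1)
  for (k in seq_len(nrow(poly) - 1)) {
    a <- poly[k, ]
    b <- poly[k + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    d2[k] <- sum((p - a - t * ab)^2)
  }
  sqrt(min(d2))
}

# curved-valley 2D double well used by the string tests:
# U = (x^2 - 1)^2 + 2 (y - x^2 / 2)^2  (minima at (+/-1, 1/2), saddle (0,0))
curved_toy <- function() {
  list(
    energy = function(x) (x[, 1]^2 - 1)^2 + 2 * (x[, 2] - 0.5 * x[, 1]^2)^2,
    gradient = function(x) {
      cbind(4 * x[, 1] * (x[, 1]^2 - 1) -
              4 * (x[, 2] - 0.5 * x[, 1]^2) * x[, 1],
            4 * (x[, 2] - 0.5 * x[, 1]^2))
    }
  )
}

xy_cvs <- function() {
  list(collective_variable("x", "distance"),
       collective_variable("y", "distance"))
}
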