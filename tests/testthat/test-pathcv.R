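test_that("overlap coefficient: identical, separated-Gaussian, periodic cases", {
  cvs <- list(collective_variable("x", "distance"))
  set.seed(1)
  a <- data.frame(x = rnorm(1e5))
  # identical samples: overlap 1 within estimator tolerance
  r <- screen_order_parameters(a, a, cvs)
  expect_equal(r$overlap, 1, tolerance = 0.02)
  expect_false(r$separated)
  # unit-variance Gaussians 3 sigma apart: overlap -> 2*Phi(-1.5) = 0.1336
  b <- data.frame(x = rnorm(1e5, 3))
  r2 <- screen_order_parameters(a, b, cvs)
  expect_equal(r2$overlap, 2 * pnorm(-1.5), tolerance = 0.02)
  # circular data at -170 vs +170 degrees, sigma 5: only periodic wrapping
  # reveals the separation
  cvd <- list(collective_variable("psi", "dihedral"))
  ca <- data.frame(psi = wrap_angle(rnorm(2e4, -170, 5)))
  cb <- data.frame(psi = wrap_angle(rnorm(2e4, 170, 5)))
  r3 <- screen_order_parameters(ca, cb, cvd)
  expect_true(r3$separated)
  expect_lt(r3$overlap, 0.05)
})

test_that("screening input contracts", {
  cvs <- list(collective_variable("x", "distance"),
              collective_variable("y", "distance"))
  a <- data.frame(x = rnorm(10))
  expect_error(screen_order_parameters(a, a, cvs), "column for every CV")
  expect_error(screen_order_parameters(data.frame(x = numeric(0),
                                                  y = numeric(0)),
                                       data.frame(x = 1, y = 1), cvs),
               "nonempty")
})

test_that("string on an isotropic quadratic relaxes to the straight segment", {
  quad <- list(energy = function(x) 0.5 * rowSums(x^2),
               gradient = function(x) x)
  p <- relax_string(quad, rbind(c(-2, -1), c(2, 1)), cvs = xy_cvs(), M = 16)
  tt <- seq(0, 1, length.out = 16)
  straight <- outer(1 - tt, c(-2, -1)) + outer(tt, c(2, 1))
  expect_lt(max(abs(p$nodes - straight)), 1e-6)
  expect_true(p$converged)
})

test_that("string on a curved double well matches the steepest-descent oracle", {
  toy <- curved_toy()
  p <- relax_string(toy, rbind(c(-1, 0.5), c(1, 0.5)), cvs = xy_cvs(),
                    M = 32)
  expect_true(p$converged)
  # oracle: dense steepest-descent lines from the saddle (0, 0)
  left <- steepest_descent_path(toy$gradient, c(0, 0), c(-1, 0) * 1)
  right <- steepest_descent_path(toy$gradient, c(0, 0), c(1, 0) * 1)
  oracle <- rbind(left[rev(seq_len(nrow(left))), ], c(0, 0), right)
  dev <- vapply(seq_len(nrow(p$nodes)), function(i) {
    dist_to_polyline(p$nodes[i, ], oracle)
  }, numeric(1))
  expect_lt(max(dev), 0.02)  # within ~one oracle grid cell
  # TS sits at the saddle, mid-path by symmetry
  expect_equal(p$s_star, max(p$arc_length) / 2, tolerance = 0.05)
})

test_that("swapping endpoints reverses the path and maps the TS", {
  toy <- curved_toy()
  p1 <- relax_string(toy, rbind(c(-1, 0.5), c(1, 0.5)), cvs = xy_cvs(),
                     M = 24)
  p2 <- relax_string(toy, rbind(c(1, 0.5), c(-1, 0.5)), cvs = xy_cvs(),
                     M = 24)
  expect_equal(p2$nodes, p1$nodes[rev(seq_len(nrow(p1$nodes))), ],
               tolerance = 1e-6)
  expect_equal(p2$s_star, max(p1$arc_length) - p1$s_star, tolerance = 0.02)
})

test_that("reparameterization: equal spacing, conserved total length", {
  set.seed(3)
  nodes <- cbind(seq(0, 3, length.out = 20),
                 sin(seq(0, 3, length.out = 20)) + rnorm(20, 0, 0.05))
  p <- string_path(nodes, xy_cvs())
  total_before <- max(p$arc_length)
  pr <- reparameterize_path(p)
  expect_equal(max(pr$arc_length), total_before, tolerance = 1e-9)
  sp <- diff(pr$arc_length)
  expect_lt(diff(range(sp)) / mean(sp), 1e-6)
  expect_true(all(diff(pr$arc_length) > 0))
})

test_that("dihedral unwrapping keeps arc length continuous across the seam", {
  cvs <- list(collective_variable("psi", "dihedral", weight = 1),
              collective_variable("phi", "dihedral", weight = 1))
  nodes <- rbind(c(160, 0), c(175, 0), c(-170, 0), c(-155, 0))
  p <- string_path(nodes, cvs)
  # 15-degree steps throughout: no period jump in the arc length
  expect_equal(diff(p$arc_length), rep(15, 3), tolerance = 1e-9)
  # stored nodes continue past +180 on the unwrapped branch
  expect_equal(p$nodes[3, 1], 190)
})

test_that("projection returns exact node coordinates and orthogonal offsets", {
  toy <- curved_toy()
  p <- relax_string(toy, rbind(c(-1, 0.5), c(1, 0.5)), cvs = xy_cvs(),
                    M = 24)
  k <- 11
  pr <- project_on_path(p$nodes[k, ], p)
  expect_equal(pr$s, p$arc_length[k], tolerance = 1e-12)
  expect_equal(pr$z, 0, tolerance = 1e-12)
  # orthogonally displaced midpoint of a segment
  a <- p$nodes[5, ]; b <- p$nodes[6, ]
  tangent <- (b - a) / sqrt(sum((b - a)^2))
  normal <- c(-tangent[2], tangent[1])
  q <- (a + b) / 2 + 0.3 * normal
  pr2 <- project_on_path(q, p)
  expect_equal(pr2$s, (p$arc_length[5] + p$arc_length[6]) / 2,
               tolerance = 1e-9)
  expect_equal(pr2$z, 0.3, tolerance = 1e-9)
})

test_that("projection agrees with a brute-force densified search", {
  toy <- curved_toy()
  p <- relax_string(toy, rbind(c(-1, 0.5), c(1, 0.5)), cvs = xy_cvs(),
                    M = 24)
  dense_s <- seq(0, max(p$arc_length), length.out = 10000)
  dense_pts <- path_point(p, dense_s)
  set.seed(8)
  pts <- cbind(runif(25, -1.2, 1.2), runif(25, -0.3, 0.9))
  step <- dense_s[2] - dense_s[1]
  for (i in seq_len(nrow(pts))) {
    pr <- project_on_path(pts[i, ], p)
    d2 <- rowSums(sweep(dense_pts, 2, pts[i, ])^2)
    expect_lt(abs(pr$s - dense_s[which.min(d2)]), 1.5 * step + 1e-9)
  }
})

test_that("projection is stable under path refinement", {
  toy <- curved_toy()
  p1 <- relax_string(toy, rbind(c(-1, 0.5), c(1, 0.5)), cvs = xy_cvs(),
                     M = 16)
  p2 <- relax_string(toy, rbind(c(-1, 0.5), c(1, 0.5)), cvs = xy_cvs(),
                     M = 32)
  spacing <- max(p1$arc_length) / 15
  set.seed(4)
  pts <- cbind(runif(10, -1, 1), runif(10, 0, 0.6))
  for (i in seq_len(nrow(pts))) {
    s1 <- project_on_path(pts[i, ], p1)$s
    s2 <- project_on_path(pts[i, ], p2)$s
    expect_lt(abs(s1 - s2), spacing / 2)
  }
})

test_that("periodic-aware projection sees points across the seam", {
  cvs <- list(collective_variable("psi", "dihedral", weight = 1),
              collective_variable("phi", "dihedral", weight = 1))
  p <- string_path(rbind(c(150, 0), c(170, 0), c(190, 0), c(210, 0)), cvs)
  # -175 is 185 on the unwrapped branch: inside segment 2-3
  pr <- project_on_path(c(-175, 0.5), p)
  expect_equal(pr$s, 35, tolerance = 1e-9)
  expect_equal(pr$z, 0.5, tolerance = 1e-9)
})

test_that("state partition boxes must be disjoint and s_star embedded", {
  expect_error(state_partition(0, list(
    a = list(psi = c(-50, 50), phi = c(-50, 50)),
    b = list(psi = c(0, 100), phi = c(0, 100)))), "overlap")
  part <- state_partition(1.2, list(
    closed = list(psi = c(-100, 20), phi = c(-120, 0)),
    open = list(psi = c(70, 190), phi = c(50, 170))))
  expect_equal(part$s_star, 1.2)
})
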