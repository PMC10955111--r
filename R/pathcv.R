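#' Collective variable definition
#'
#' @param name CV name (e.g. "psi181", "d1").
#' @param kind "dihedral" (periodic, degrees) or "distance" (Angstrom).
#' @param weight Metric weight, amu^1/2 (dihedral weights also absorb the
#'   degree-to-length scaling), so that weighted CV space carries units of
#'   amu^1/2 * Angstrom and so does the path coordinate s. Default 1.
#' @return A `lk_cv` object with `period` 360 for dihedrals, NA otherwise.
#' @export
collective_variable <- function(name, kind = c("dihedral", "distance"),
                                weight = 1) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, weight > 0)
  structure(list(name = name, kind = kind,
                 period = if (kind == "dihedral") 360 else NA_real_,
                 weight = weight),
            class = "lk_cv")
}

.cv_periods <- function(cvs) vapply(cvs, function(cv) cv$period, numeric(1))
.cv_weights <- function(cvs) vapply(cvs, function(cv) cv$weight, numeric(1))
.cv_names <- function(cvs) vapply(cvs, function(cv) cv$name, character(1))

# wrap a displacement per-dimension: periodic dims into (-period/2, period/2]
.wrap_disp <- function(d, periods) {
  per <- which(is.finite(periods))
  for (j in per) {
    p <- periods[j]
    d[j] <- d[j] - p * floor((d[j] + p / 2) / p)
    if (d[j] == -p / 2) d[j] <- p / 2
  }
  d
}

#' Overlap-based screening of candidate order parameters
#'
#' For each collective variable, estimates the overlap coefficient between
#' its distributions in two states (the integral of the pointwise minimum of
#' the two histogram density estimates) and issues a separated/overlapping
#' verdict. Good order parameters separate the states (overlap near 0);
#' diffusive coordinates such as salt-bridge distances typically overlap.
#' Dihedral CVs are binned on the periodic domain so that samples split
#' across the +/-180 seam are handled correctly.
#'
#' @param state_A_samples,state_B_samples Data frames with one column per
#'   CV name; the two states being contrasted (e.g. closed and open).
#' @param cvs List of [collective_variable()] definitions for the columns.
#' @param threshold Overlap below which a CV is called separated
#'   (default 0.05).
#' @param n_bins Histogram bins (default 100).
#' @return Data frame with `cv`, `kind`, `overlap` in \[0, 1\] and
#'   `separated`.
#' @export
screen_order_parameters <- function(state_A_samples, state_B_samples, cvs,
                                    threshold = 0.05, n_bins = 100L) {
  nm <- .cv_names(cvs)
  if (!all(nm %in% names(state_A_samples)) ||
      !all(nm %in% names(state_B_samples))) {
    stop("sample sets must contain a column for every CV: ",
         paste(setdiff(nm, intersect(names(state_A_samples),
                                     names(state_B_samples))),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(state_A_samples) == 0 || nrow(state_B_samples) == 0) {
    stop("both sample sets must be nonempty", call. = FALSE)
  }
  res <- lapply(cvs, function(cv) {
    a <- state_A_samples[[cv$name]]
    b <- state_B_samples[[cv$name]]
    if (cv$kind == "dihedral") {
      a <- wrap_angle(a)
      b <- wrap_angle(b)
      # rotate the seam away from the data: center bins on the pooled
      # circular mean so a tight mode at +/-180 is not split
      mu <- atan2(mean(sin(c(a, b) * pi / 180)),
                  mean(cos(c(a, b) * pi / 180))) * 180 / pi
      a <- wrap_angle(a - mu)
      b <- wrap_angle(b - mu)
      breaks <- seq(-180, 180, length.out = n_bins + 1L)
    } else {
      rng <- range(c(a, b))
      pad <- diff(rng) * 0.05 + 1e-9
      breaks <- seq(rng[1] - pad, rng[2] + pad, length.out = n_bins + 1L)
    }
    ha <- graphics::hist(a, breaks = breaks, plot = FALSE)$density
    hb <- graphics::hist(b, breaks = breaks, plot = FALSE)$density
    sum(pmin(ha, hb)) * diff(breaks[1:2])
  })
  overlap <- unlist(res)
  data.frame(cv = nm,
             kind = vapply(cvs, function(cv) cv$kind, character(1)),
             overlap = overlap,
             separated = overlap < threshold)
}

#' Construct a string path through CV space
#'
#' Nodes are stored on a continuous (unwrapped) branch: each node's angular
#' coordinates are chosen in the branch nearest the previous node, so arc
#' length never jumps by a period.
#'
#' @param nodes Matrix, one node per row, columns in CV order.
#' @param cvs List of [collective_variable()]s matching the columns.
#' @param arc_length Optional arc-length parameter per node; default is the
#'   cumulative weighted chord length.
#' @param s_star Optional TS position along the path.
#' @return An `lk_path` object.
#' @export
string_path <- function(nodes, cvs, arc_length = NULL, s_star = NA_real_) {
  nodes <- as.matrix(nodes)
  stopifnot(nrow(nodes) >= 2, ncol(nodes) == length(cvs))
  periods <- .cv_periods(cvs)
  for (k in 2:nrow(nodes)) {
    d <- .wrap_disp(nodes[k, ] - nodes[k - 1, ], periods)
    nodes[k, ] <- nodes[k - 1, ] + d
  }
  w <- .cv_weights(cvs)
  if (is.null(arc_length)) {
    seg <- sqrt(rowSums((sweep(diff(nodes), 2, w, `*`))^2))
    arc_length <- c(0, cumsum(seg))
  }
  if (any(diff(arc_length) <= 0)) {
    stop("arc_length must be strictly increasing (degenerate nodes?)",
         call. = FALSE)
  }
  structure(list(nodes = nodes, cvs = cvs, weights = w, periods = periods,
                 arc_length = arc_length, s_star = s_star),
            class = "lk_path")
}

#' @export
print.lk_path <- function(x, ...) {
  cat("String path:", nrow(x$nodes), "nodes | length",
      signif(max(x$arc_length), 5), "amu^1/2*A | s* =",
      signif(x$s_star, 5), "\n")
  invisible(x)
}

#' Reparameterize a path to equal node spacing
#'
#' Nodes are redistributed at equal arc-length increments measured along a
#' densified version of the current polyline; the stored `arc_length`
#' parameter is the position on that source polyline, so total length is
#' conserved exactly and spacings are exactly equal in the path parameter.
#'
#' @param path An `lk_path`.
#' @param refine Densification factor used to measure the polyline.
#' @return A reparameterized `lk_path`.
#' @export
reparameterize_path <- function(path, refine = 8L) {
  M <- nrow(path$nodes)
  dense <- .interp_nodes(path, refine)
  seg <- sqrt(rowSums((sweep(diff(dense), 2, path$weights, `*`))^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  target <- seq(0, L, length.out = M)
  new_nodes <- matrix(NA_real_, M, ncol(path$nodes))
  for (j in seq_len(ncol(path$nodes))) {
    new_nodes[, j] <- stats::approx(cum, dense[, j], xout = target,
                                    ties = "ordered")$y
  }
  out <- string_path(new_nodes, path$cvs, arc_length = target,
                     s_star = path$s_star)
  out
}

.interp_nodes <- function(path, refine) {
  M <- nrow(path$nodes)
  tt <- seq(1, M, by = 1 / refine)
  lo <- pmin(floor(tt), M - 1)
  w <- tt - lo
  path$nodes[lo, , drop = FALSE] * (1 - w) +
    path$nodes[lo + 1, , drop = FALSE] * w
}

#' Relax a string to the minimum free-energy path
#'
#' Simplified string method on an analytic (or pre-estimated) landscape:
#' each iteration moves every interior node downhill along the landscape
#' gradient and then redistributes nodes to equal arc-length spacing, which
#' drives the string to the minimum free-energy path (MFEP) connecting the
#' two endpoint basins. Endpoints are held fixed. Convergence is declared
#' when the maximum node displacement per iteration (in weighted CV space)
#' falls below `tol`.
#'
#' @param landscape An `lk_landscape`, or a list with `energy(x)` and
#'   `gradient(x)` functions operating on row-matrices of CV points.
#' @param endpoints Two-row matrix (or list of two vectors): path ends, one
#'   in each basin.
#' @param cvs List of [collective_variable()]s; defaults to the two torsions
#'   of an `lk_landscape` (plus its distances).
#' @param M Number of string nodes (>= 10; default 48).
#' @param tol Convergence threshold on per-iteration node displacement,
#'   amu^1/2 * Angstrom (default 1e-4).
#' @param max_iter Iteration cap.
#' @param step_scale Descent step as a fraction of node spacing per unit
#'   normalized gradient (default 0.1).
#' @return A converged `lk_path` with `s_star` at the free-energy maximum
#'   along the path (located on a densified profile).
#' @export
relax_string <- function(landscape, endpoints, cvs = NULL, M = 48L,
                         tol = 1e-4, max_iter = 20000L, step_scale = 0.1) {
  if (M < 10) stop("need at least 10 string nodes", call. = FALSE)
  if (inherits(landscape, "lk_landscape")) {
    efun <- function(x) landscape_energy(landscape, x)
    gfun <- function(x) landscape_gradient(landscape, x)
    if (is.null(cvs)) {
      cvs <- c(list(collective_variable("psi", "dihedral"),
                    collective_variable("phi", "dihedral")),
               lapply(seq_len(landscape$n_distances), function(j) {
                 collective_variable(paste0("d", j), "distance")
               }))
    }
  } else {
    efun <- landscape$energy
    gfun <- landscape$gradient
    if (is.null(cvs)) stop("`cvs` must be given for a custom landscape",
                           call. = FALSE)
  }
  if (is.list(endpoints) && !is.matrix(endpoints)) {
    endpoints <- rbind(endpoints[[1]], endpoints[[2]])
  }
  stopifnot(nrow(endpoints) == 2, ncol(endpoints) == length(cvs))

  w <- .cv_weights(cvs)
  tt <- seq(0, 1, length.out = M)
  nodes <- outer(1 - tt, endpoints[1, ]) + outer(tt, endpoints[2, ])
  path <- string_path(nodes, cvs)
  path <- reparameterize_path(path)

  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nodes <- path$nodes
    g <- gfun(nodes)
    # scale-free step: a fixed fraction of the node spacing for the
    # largest-gradient node
    gw <- sqrt(rowSums(sweep(g, 2, w, `/`)^2))  # gradient norm in weighted space
    spacing <- max(path$arc_length) / (M - 1)
    eta <- step_scale * spacing / max(gw[2:(M - 1)], 1e-12)
    new_nodes <- nodes
    new_nodes[2:(M - 1), ] <- nodes[2:(M - 1), ] -
      eta * sweep(g[2:(M - 1), , drop = FALSE], 2, w^2, `/`)
    new_path <- reparameterize_path(string_path(new_nodes, cvs))
    disp <- sqrt(rowSums((sweep(new_path$nodes - path$nodes, 2, w,
                                `*`))^2))
    path <- new_path
    if (max(disp) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("string did not converge in ", max_iter,
            " iterations; residual displacement ", signif(max(disp), 3))
  }
  # locate the TS on a densified profile along the path
  dense <- .interp_nodes(path, 20L)
  seg <- sqrt(rowSums((sweep(diff(dense), 2, w, `*`))^2))
  cum <- c(0, cumsum(seg))
  e <- efun(dense)
  path$s_star <- cum[which.max(e)] / max(cum) * max(path$arc_length)
  path$converged <- converged
  path$iterations <- it
  path
}

#' Project a CV point onto a string path
#'
#' Finds the nearest point on the piecewise-linear path in weighted CV
#' space (periodic-aware for dihedral CVs: each segment sees the point in
#' its own branch) and returns the path coordinate s and the orthogonal
#' tube distance z. A projection equidistant to non-adjacent segments is
#' resolved to the smallest s with a message.
#'
#' @param point CV point (raw units: degrees / Angstrom).
#' @param path An `lk_path`.
#' @return List with `s` (amu^1/2 * Angstrom), `z` (orthogonal distance,
#'   same units) and `segment`.
#' @export
project_on_path <- function(point, path) {
  nodes <- path$nodes
  M <- nrow(nodes)
  w <- path$weights
  best <- NULL
  d2s <- numeric(M - 1)
  ts <- numeric(M - 1)
  for (k in seq_len(M - 1)) {
    a <- nodes[k, ]
    b <- nodes[k + 1, ]
    # represent the point in this segment's branch
    p <- a + .wrap_disp(point - a, path$periods)
    ab <- (b - a) * w
    ap <- (p - a) * w
    t <- sum(ap * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    dd <- ap - t * ab
    d2s[k] <- sum(dd * dd)
    ts[k] <- t
  }
  k_best <- which.min(d2s)
  near_tie <- which(d2s <= d2s[k_best] * (1 + 1e-12) + 1e-300)
  if (any(abs(near_tie - k_best) > 1)) {
    message("ambiguous projection: equidistant to non-adjacent segments; ",
            "taking the smallest s")
    k_best <- min(near_tie)
  }
  s <- path$arc_length[k_best] +
    ts[k_best] * diff(path$arc_length)[k_best]
  list(s = s, z = sqrt(d2s[k_best]), segment = k_best)
}

#' Interpolate the CV point at a given path coordinate
#'
#' @param path An `lk_path`.
#' @param s Path coordinate values (clamped to the path range).
#' @return Matrix of CV points (angular coordinates wrapped to
#'   (-180, 180]), one row per s value.
#' @export
path_point <- function(path, s) {
  s <- pmin(pmax(s, min(path$arc_length)), max(path$arc_length))
  out <- matrix(NA_real_, length(s), ncol(path$nodes))
  for (j in seq_len(ncol(path$nodes))) {
    out[, j] <- stats::approx(path$arc_length, path$nodes[, j], xout = s,
                              ties = "ordered")$y
  }
  per <- which(is.finite(path$periods))
  for (j in per) out[, j] <- wrap_angle(out[, j])
  colnames(out) <- .cv_names(path$cvs)
  out
}

#' Free-energy profile of a landscape along a path
#'
#' Evaluates the landscape on a dense set of points along the path and
#' returns an analytic-profile-like object usable by [gle_model()] (the
#' "tube" reduction: motion orthogonal to the path is ignored).
#'
#' @param landscape An `lk_landscape`.
#' @param path An `lk_path`.
#' @param n Number of evaluation points.
#' @return A function-backed profile: list with `grid`, `G` (kcal/mol,
#'   gauge min 0) of class `lk_fep`.
#' @export
path_energy_profile <- function(landscape, path, n = 1001L) {
  s <- seq(min(path$arc_length), max(path$arc_length), length.out = n)
  pts <- path_point(path, s)
  g <- landscape_energy(landscape, pts)
  g <- g - min(g)
  structure(list(grid = s, G = g, stderr = rep(0, n),
                 C_s = 1, temperature = NA_real_,
                 bin_width = s[2] - s[1], visited = rep(TRUE, n)),
            class = "lk_fep")
}

#' Two-state partition of CV space
#'
#' Rectangular basin boxes on the angular CVs plus a divider on the path
#' coordinate. Used to classify trajectory endpoints as closed / open.
#' Box boundaries are closed (a point on an edge is a member); boxes must
#' be disjoint.
#'
#' @param s_star Divider on s (interior to the path range when a path is
#'   attached).
#' @param boxes Named list of states; each a list with `psi = c(lo, hi)`,
#'   `phi = c(lo, hi)` in degrees (lo <= hi after unwrapping; boxes may
#'   straddle the seam by using e.g. c(150, 210)).
#' @return A `lk_partition`.
#' @export
state_partition <- function(s_star, boxes) {
  stopifnot(is.list(boxes), length(boxes) >= 2, !is.null(names(boxes)))
  # disjointness check on a wrapped sample grid
  grid <- as.matrix(expand.grid(psi = seq(-179, 180, by = 2),
                                phi = seq(-179, 180, by = 2)))
  member <- vapply(boxes, function(b) {
    .in_box(grid[, 1], b$psi) & .in_box(grid[, 2], b$phi)
  }, logical(nrow(grid)))
  if (any(rowSums(member) > 1)) {
    stop("basin boxes overlap", call. = FALSE)
  }
  structure(list(s_star = s_star, boxes = boxes), class = "lk_partition")
}

# periodic closed-interval membership for angles in degrees
.in_box <- function(x, lim) {
  lo <- lim[1]
  hi <- lim[2]
  d <- (wrap_angle(x) - lo) %% 360
  width <- (hi - lo) %% 360
  if (width == 0 && hi != lo) width <- 360
  d <= width + 1e-12
}

#' Default basin boxes around the landscape basin centers
#'
#' @param landscape An `lk_landscape`.
#' @param half_width Box half-width in degrees (default 60).
#' @param s_star TS position to embed in the partition.
#' @return A [state_partition()] with `closed` and `open` boxes.
#' @export
default_partition <- function(landscape, half_width = 60, s_star = NA_real_) {
  cc <- landscape$basin_centers$closed
  co <- landscape$basin_centers$open
  state_partition(s_star, list(
    closed = list(psi = cc[1] + c(-1, 1) * half_width,
                  phi = cc[2] + c(-1, 1) * half_width),
    open = list(psi = co[1] + c(-1, 1) * half_width,
                phi = co[2] + c(-1, 1) * half_width)
  ))
}
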