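#' Umbrella-sampling window container
#'
#' @param center Bias center on s.
#' @param k_umb Bias stiffness, kcal/mol per s-unit^2 (0 for an unbiased
#'   window).
#' @param samples Numeric s series recorded in the window.
#' @param correlation_block Decorrelation block length in samples; if NULL
#'   it is estimated from the integrated autocorrelation time when needed.
#' @param bias_offset Additive constant on the window bias energy,
#'   kcal/mol (physically irrelevant; retained to verify gauge invariance).
#' @return An `lk_window`.
#' @export
biased_window <- function(center, k_umb, samples, correlation_block = NULL,
                          bias_offset = 0) {
  stopifnot(is.numeric(center), length(center) == 1L,
            is.numeric(k_umb), k_umb >= 0, is.numeric(samples))
  if (length(samples) < 100) {
    stop("each window needs at least 100 samples (got ", length(samples),
         ")", call. = FALSE)
  }
  structure(list(center = center, k_umb = k_umb,
                 samples = as.numeric(samples),
                 correlation_block = correlation_block,
                 bias_offset = bias_offset),
            class = "lk_window")
}

#' Convert a biased trajectory into a WHAM window
#'
#' @param trajectory An `lk_trajectory` produced by
#'   [sample_biased_window()].
#' @return An `lk_window` holding the s series and bias parameters.
#' @export
as_biased_window <- function(trajectory) {
  stopifnot(inherits(trajectory, "lk_trajectory"))
  b <- trajectory$metadata$bias
  if (is.null(b) || b$type != "harmonic") {
    stop("trajectory does not carry a harmonic bias", call. = FALSE)
  }
  biased_window(b$center, b$k_umb, trajectory$columns$s)
}

#' Statistical inefficiency of a time series
#'
#' `g = 1 + 2 * sum(acf)` with the sum truncated at the first
#' non-positive autocorrelation, capped at length/10. The decorrelated
#' block length used by the block bootstrap.
#'
#' @param x Numeric series.
#' @return Statistical inefficiency in samples (>= 1).
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  a <- stats::acf(x, lag.max = min(n - 1, 2000), plot = FALSE,
                  demean = TRUE)$acf[-1]
  cut <- which(a <= 0)[1]
  if (!is.na(cut)) a <- a[seq_len(cut - 1)]
  g <- 1 + 2 * sum(a)
  min(max(g, 1), n / 10)
}

#' Weighted-histogram (WHAM) reconstruction of the free-energy profile
#'
#' Stitches overlapping harmonic umbrella windows into one potential of
#' mean force G(s) by iterating the self-consistent WHAM equations until
#' the window free energies change by less than `tol`. The gauge is fixed
#' at min G = 0. Bins never visited by any sample are flagged, not
#' interpolated. Windows are processed in a canonical order (sorted by
#' center) so the result is bit-identical under input permutation.
#'
#' @param windows List of [biased_window()]s (at least 2, unless a single
#'   unbiased window is given).
#' @param temperature Temperature, K.
#' @param bin_width Histogram bin width on s (default 0.05 amu^1/2 * A).
#' @param tol Convergence threshold on window free energies, kcal/mol
#'   (default 1e-8).
#' @param max_iter Iteration cap.
#' @return An `lk_fep`: `grid` (bin centers), `G` (kcal/mol, min 0),
#'   `stderr` (NA until [bootstrap_uncertainty()] fills it), `C_s` (1
#'   amu^1/2 * A), `visited` flags, per-bin sample `counts`, plus
#'   bookkeeping (`f_window`, iteration count).
#' @export
wham <- function(windows, temperature = 300, bin_width = 0.05, tol = 1e-8,
                 max_iter = 100000L) {
  if (inherits(windows, "lk_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1)
  if (length(windows) < 2 && windows[[1]]$k_umb > 0) {
    stop("need at least 2 overlapping windows (or one unbiased window)",
         call. = FALSE)
  }
  check_temperature(temperature)
  kT <- thermal_energy(temperature)$kcal

  ord <- order(vapply(windows, function(w) w$center, numeric(1)),
               vapply(windows, function(w) w$k_umb, numeric(1)))
  windows <- windows[ord]

  all_s <- unlist(lapply(windows, function(w) w$samples))
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  mids <- breaks[-length(breaks)] + bin_width / 2
  K <- length(mids)
  W <- length(windows)

  counts <- vapply(windows, function(w) {
    tabulate(findInterval(w$samples, breaks, rightmost.closed = TRUE),
             nbins = K)
  }, numeric(K))
  counts <- matrix(counts, nrow = K)
  n_tot <- rowSums(counts)
  visited <- n_tot > 0
  N <- colSums(counts)

  # connectivity of the window graph through shared visited bins
  if (W > 1) {
    vis_w <- counts > 0
    comp <- seq_len(W)
    repeat {
      changed <- FALSE
      for (k in which(visited)) {
        ws <- which(vis_w[k, ])
        if (length(ws) > 1) {
          m <- min(comp[ws])
          if (any(comp[ws] != m)) {
            comp[ws] <- m
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    if (length(unique(comp)) > 1) {
      centers <- vapply(windows, function(w) w$center, numeric(1))
      gap_at <- sort(centers)[which.max(diff(sort(centers)))]
      stop("umbrella windows are disconnected: no histogram overlap near ",
           "s = ", signif(gap_at, 4),
           "; add windows or lengthen sampling", call. = FALSE)
    }
  }

  # window bias energy per bin, kcal/mol
  u <- vapply(windows, function(w) {
    0.5 * w$k_umb * (mids - w$center)^2 + w$bias_offset
  }, numeric(K))
  u <- matrix(u, nrow = K)

  f <- numeric(W)
  lse <- function(m) {
    mx <- apply(m, 1, max)
    mx + log(rowSums(exp(m - mx)))
  }
  logN <- log(N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    log_denom <- lse(sweep(-u / kT, 2, logN + f / kT, `+`))
    logp <- ifelse(visited, log(pmax(n_tot, 1)) - log_denom, -Inf)
    f_new <- vapply(seq_len(W), function(i) {
      m <- logp[visited] - u[visited, i] / kT
      mx <- max(m)
      -kT * (mx + log(sum(exp(m - mx))))
    }, numeric(1))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || iter >= max_iter) break
  }
  if (iter >= max_iter && delta >= tol) {
    warning("WHAM did not reach tol = ", tol, " in ", max_iter,
            " iterations (residual ", signif(delta, 3), ")")
  }

  log_denom <- lse(sweep(-u / kT, 2, logN + f / kT, `+`))
  G <- rep(NA_real_, K)
  G[visited] <- -kT * (log(n_tot[visited]) - log_denom[visited])
  G <- G - min(G, na.rm = TRUE)

  structure(list(grid = mids, G = G, stderr = rep(NA_real_, K),
                 C_s = 1, temperature = temperature, bin_width = bin_width,
                 visited = visited, counts = n_tot, f_window = f,
                 iterations = iter, windows = windows),
            class = "lk_fep")
}

#' @export
print.lk_fep <- function(x, ...) {
  cat("Free-energy profile: ", sum(x$visited), "/", length(x$grid),
      " bins visited | range [", signif(min(x$grid), 4), ", ",
      signif(max(x$grid), 4), "] | max G = ",
      signif(max(x$G, na.rm = TRUE), 4), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Block-bootstrap uncertainty of a WHAM profile
#'
#' Resamples decorrelated blocks within every window, reruns WHAM, and
#' returns the 95 percent percentile confidence half-width per bin.
#'
#' @param windows List of [biased_window()]s.
#' @param n_boot Number of bootstrap replicates (> 0).
#' @param seed RNG seed (reproducible CIs).
#' @inheritParams wham
#' @return The [wham()] profile with `stderr` set to the 95% CI half-width,
#'   plus `ci_lower`, `ci_upper` and a `wide_ci` flag set when any window
#'   had fewer than 10 blocks.
#' @export
bootstrap_uncertainty <- function(windows, n_boot, seed = 1,
                                  temperature = 300, bin_width = 0.05,
                                  tol = 1e-8) {
  if (!is.numeric(n_boot) || n_boot < 1) {
    stop("n_boot must be a positive count", call. = FALSE)
  }
  base <- wham(windows, temperature = temperature, bin_width = bin_width,
               tol = tol)
  windows <- base$windows  # canonical order
  blocks <- lapply(windows, function(w) {
    g <- w$correlation_block %||% ceiling(statistical_inefficiency(w$samples))
    n_blk <- floor(length(w$samples) / g)
    list(g = g, n_blk = n_blk)
  })
  wide_ci <- any(vapply(blocks, function(b) b$n_blk < 10, logical(1)))
  if (wide_ci) {
    warning("fewer than 10 decorrelated blocks in at least one window; ",
            "confidence intervals are unreliable (flagged wide_ci)")
  }
  set.seed(as.integer(seed %% 2147483647))
  reps <- matrix(NA_real_, length(base$grid), n_boot)
  for (b in seq_len(n_boot)) {
    wb <- lapply(seq_along(windows), function(i) {
      w <- windows[[i]]
      g <- blocks[[i]]$g
      n_blk <- max(blocks[[i]]$n_blk, 1)
      starts <- sample.int(length(w$samples) - g + 1, n_blk, replace = TRUE)
      idx <- as.vector(outer(seq_len(g) - 1L, starts, `+`))
      biased_window(w$center, w$k_umb, w$samples[idx],
                    bias_offset = w$bias_offset)
    })
    p <- wham(wb, temperature = temperature, bin_width = bin_width,
              tol = tol)
    idx <- round((p$grid - base$grid[1]) / bin_width) + 1L
    ok <- idx >= 1L & idx <= length(base$grid)
    reps[idx[ok], b] <- p$G[ok]
  }
  qs <- apply(reps, 1, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  base$ci_lower <- qs[1, ]
  base$ci_upper <- qs[2, ]
  base$stderr <- (qs[2, ] - qs[1, ]) / 2
  base$wide_ci <- wide_ci
  base$n_boot <- n_boot
  base
}
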