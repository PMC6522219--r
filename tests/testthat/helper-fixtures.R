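# Shared fixtures and independent oracles for the test suite.

unit_square <- function() {
  polygon_region(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
}

big_square <- function(side = 10) {
  polygon_region(cbind(c(0, side, side, 0), c(0, 0, side, side)))
}

# Independent even-odd point-in-polygon oracle (pure R, crossing count;
# no shared code with the package's C++ implementation).
pip_oracle <- function(px, py, poly) {
  v <- unclass(poly)
  n <- nrow(v)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == 1L) n else i - 1L
      x1 <- v[j, 1L]; y1 <- v[j, 2L]; x2 <- v[i, 1L]; y2 <- v[i, 2L]
      # on-edge check
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-12 &&
          x >= min(x1, x2) - 1e-12 && x <= max(x1, x2) + 1e-12 &&
          y >= min(y1, y2) - 1e-12 && y <= max(y1, y2) + 1e-12)
        return(TRUE)
      if ((y1 > y) != (y2 > y)) {
        xi <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xi) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  }, logical(1))
}

# Numeric-integration oracle for the in-region arc fraction: sample the
# circle at fixed angular resolution and classify each sample point.
arc_fraction_oracle <- function(cx, cy, r, poly, step = 1e-4) {
  th <- seq(0, 2 * pi, by = step)
  mean(pip_oracle(cx + r * cos(th), cy + r * sin(th), poly))
}

# Brute-force edge-corrected N(r) with the numeric arc oracle.
ripley_nr_oracle <- function(pts, poly, radii, step = 1e-4) {
  n <- nrow(pts)
  vals <- numeric(length(radii))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    frac <- arc_fraction_oracle(pts[i, 1L], pts[i, 2L], d, poly, step)
    if (frac <= 0) next
    vals <- vals + ifelse(radii >= d, 1 / frac, 0)
  }
  vals / n
}

# Build a trajectories table from a list of (frame, x, y) matrices.
traj_fixture <- function(mats, cell_id = "c1") {
  df <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- mats[[i]]
    data.frame(traj_id = sprintf("t%02d", i), cell_id = cell_id,
               frame = m[, 1L], x = m[, 2L], y = m[, 3L])
  }))
  trajectories(df, max_gap = Inf)
}

# Monte-Carlo oracle for the absorbing-slab survival: sub-stepped
# random walk with Brownian-bridge barrier-crossing tests.
defocalization_mc <- function(D, dZ, t, n_walkers = 2e5, substeps = 60L,
                              seed = 1) {
  set.seed(seed)
  a <- dZ / 2
  dt <- t / substeps
  z <- runif(n_walkers, -a, a)
  alive <- rep(TRUE, n_walkers)
  for (s in seq_len(substeps)) {
    z1 <- z + rnorm(n_walkers, 0, sqrt(2 * D * dt))
    p_hi <- exp(-2 * pmax(a - z, 0) * pmax(a - z1, 0) / (2 * D * dt))
    p_lo <- exp(-2 * pmax(a + z, 0) * pmax(a + z1, 0) / (2 * D * dt))
    u1 <- runif(n_walkers); u2 <- runif(n_walkers)
    alive <- alive & abs(z1) < a & u1 >= p_hi & u2 >= p_lo
    z <- z1
  }
  mean(alive)
}

# Monte-Carlo sampler from the two-state jump-length mixture model.
two_state_mc_jumps <- function(params, n, n_jumps = 1e6, cap = 4L,
                               seed = 1) {
  set.seed(seed)
  t <- n * params$frame_interval
  zf <- mean(defocalization_fraction(params$D_free, params$dZ,
                                     (n + seq_len(cap) - 1) *
                                       params$frame_interval))
  wb <- params$F_bound
  wf <- (1 - params$F_bound) * zf
  is_bound <- runif(n_jumps) < wb / (wb + wf)
  D <- ifelse(is_bound, params$D_bound, params$D_free)
  scale <- 4 * (D * t + params$sigma_loc^2)
  sqrt(-scale * log(runif(n_jumps)))
}
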