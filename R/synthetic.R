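#' Configuration for the spaSPT trajectory simulator
#'
#' Defines a two-state (bound/free) Brownian simulation inside a
#' polygonal nucleus observed through an axial detection slab, emulating
#' stroboscopic photo-activatable single-particle tracking. Defaults are
#' the acquisition and model parameters of the assay this package
#' analyses: 7.447 ms between frames, 45 nm localization error, a
#' 0.7 µm detection slab, and a model protein with 50% bound fraction
#' and D_free = 3.5 µm²/s.
#'
#' @param n_trajectories number of molecules to emit.
#' @param F_bound probability a molecule is in the bound state.
#' @param D_free,D_bound diffusion coefficients (µm²/s); bound motion
#'   defaults to 0.005 µm²/s of residual chromatin-like mobility.
#' @param sigma_loc localization error SD per coordinate (µm).
#' @param frame_interval seconds between frames.
#' @param dZ axial detection slab depth (µm); molecules whose hidden z
#'   leaves `[-dZ/2, dZ/2]` are lost (defocalization).
#' @param nucleus [polygon_region()] bounding xy diffusion (reflecting).
#' @param compartments list of [polygon_region()]s (used to place traps
#'   and by downstream sorting; molecules diffuse through them freely).
#' @param n_frames observation window: maximum trajectory length in
#'   frames (12 supports all seven lags with the four-jump cap).
#' @param bleach_prob optional per-frame photobleaching probability
#'   (applies to both states; 0 disables).
#' @param traps optional list describing near-DNA binding traps:
#'   `density` (traps/µm², placed in the compartments, or the nucleus if
#'   none), `radius` (capture radius, µm; default 0.15),
#'   `escape_prob` (per-frame escape probability; default 0.3), and
#'   `mode`: `"confine"` (default; a trapped molecule keeps free-state
#'   mobility but is reflected inside the capture disc — transient
#'   confinement on clustered DNA) or `"freeze"` (bound-state mobility
#'   at the trap).
#' @param z_substeps sub-steps per frame for the hidden z walk; each
#'   sub-step applies a Brownian-bridge barrier-crossing test so the
#'   survival law matches the continuous absorbing-slab solution.
#' @param allow_switching if `TRUE`, molecules switch bound/free with
#'   the equilibrium-consistent per-frame rates implied by
#'   `switch_prob`; off by default to match the fitting model.
#' @param switch_prob per-frame probability that a free molecule binds
#'   when switching is enabled.
#' @param cell_id cell label stamped on the output.
#' @return object of class `spaspt_config`.
#' @export
spaspt_config <- function(n_trajectories = 5000L, F_bound = 0.5,
                          D_free = 3.5, D_bound = 0.005,
                          sigma_loc = 0.045, frame_interval = 0.007447,
                          dZ = 0.7,
                          nucleus = disc_region(0, 0, 5, 48L),
                          compartments = list(),
                          n_frames = 12L, bleach_prob = 0,
                          traps = NULL, z_substeps = 4L,
                          allow_switching = FALSE, switch_prob = 0.1,
                          cell_id = "sim") {
  stopifnot(F_bound >= 0, F_bound <= 1, frame_interval > 0,
            D_free > D_bound, D_bound >= 0, dZ > 0, sigma_loc >= 0,
            n_frames >= 2L)
  if (region_area(nucleus) <= 0) stop("nucleus has zero area")
  if (!is.null(traps)) {
    traps$radius <- traps$radius %||% 0.15
    traps$escape_prob <- traps$escape_prob %||% 0.3
    traps$mode <- match.arg(traps$mode %||% "confine",
                            c("confine", "freeze"))
    stopifnot(traps$density > 0, traps$radius > 0,
              traps$escape_prob > 0, traps$escape_prob <= 1)
  }
  structure(list(n_trajectories = as.integer(n_trajectories),
                 F_bound = F_bound, D_free = D_free, D_bound = D_bound,
                 sigma_loc = sigma_loc, frame_interval = frame_interval,
                 dZ = dZ, nucleus = nucleus, compartments = compartments,
                 n_frames = as.integer(n_frames),
                 bleach_prob = bleach_prob, traps = traps,
                 z_substeps = as.integer(z_substeps),
                 allow_switching = allow_switching,
                 switch_prob = switch_prob,
                 cell_id = cell_id),
            class = "spaspt_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closest point on the polygon boundary for each (x, y); returns matrix
closest_boundary_point <- function(x, y, region) {
  v <- unclass(region)
  n <- nrow(v)
  bestd <- rep(Inf, length(x))
  bx <- numeric(length(x)); by <- numeric(length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- v[i, 1L]; ay <- v[i, 2L]
    ex <- v[j, 1L] - ax; ey <- v[j, 2L] - ay
    l2 <- ex * ex + ey * ey
    t <- pmin(1, pmax(0, ((x - ax) * ex + (y - ay) * ey) / l2))
    px <- ax + t * ex; py <- ay + t * ey
    d <- (x - px)^2 + (y - py)^2
    upd <- d < bestd
    bestd[upd] <- d[upd]; bx[upd] <- px[upd]; by[upd] <- py[upd]
  }
  cbind(bx, by)
}

# Reflect points that left the region back inside: mirror through the
# closest boundary point; points still outside are clamped onto the
# boundary (inside by the on-edge tie-break).
reflect_into_region <- function(x, y, region) {
  out <- !in_region(x, y, region)
  if (any(out)) {
    cb <- closest_boundary_point(x[out], y[out], region)
    rx <- 2 * cb[, 1L] - x[out]
    ry <- 2 * cb[, 2L] - y[out]
    still <- !in_region(rx, ry, region)
    rx[still] <- cb[still, 1L]
    ry[still] <- cb[still, 2L]
    x[out] <- rx; y[out] <- ry
  }
  cbind(x, y)
}

# Survival of the hidden z walk over one frame, by sub-stepped Brownian
# bridge: returns list(z, alive).
z_step_survive <- function(z, alive, D, dt, dZ, substeps) {
  a <- dZ / 2
  sub <- dt / substeps
  D <- rep_len(D, length(z))
  sd_sub <- sqrt(2 * D * sub)
  for (s in seq_len(substeps)) {
    z1 <- z + stats::rnorm(length(z), 0, sd_sub)
    cross_hi <- cross_lo <- rep(FALSE, length(z))
    both_in <- abs(z1) < a & abs(z) < a
    if (any(both_in & sd_sub > 0)) {
      i <- which(both_in & sd_sub > 0)
      p_hi <- exp(-2 * (a - z[i]) * (a - z1[i]) / (2 * D[i] * sub))
      p_lo <- exp(-2 * (a + z[i]) * (a + z1[i]) / (2 * D[i] * sub))
      u <- stats::runif(length(i))
      u2 <- stats::runif(length(i))
      cross_hi[i] <- u < p_hi
      cross_lo[i] <- u2 < p_lo
    }
    alive <- alive & abs(z1) < a & !cross_hi & !cross_lo
    z <- z1
  }
  list(z = z, alive = alive)
}

#' Simulate spaSPT trajectories
#'
#' Two-state Brownian dynamics in a nucleus with axial defocalization.
#' Each molecule is assigned bound with probability `F_bound`; positions
#' evolve by isotropic Gaussian steps of per-axis variance `2*D*dt`;
#' trajectories are truncated when the hidden z coordinate leaves the
#' detection slab (Brownian-bridge exit test, so survival follows the
#' continuous absorbing-slab law used by the kinetic model); xy motion
#' reflects at the nucleus boundary; independent Gaussian localization
#' noise of SD `sigma_loc` is added to every observed coordinate.
#'
#' @param config a [spaspt_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `trajectories` (a [trajectories()] table),
#'   `truth` (data.frame: `traj_id`, `state`, `n_frames_observed`),
#'   `traps` (trap coordinates or `NULL`), and `config`.
#' @examples
#' sim <- simulate_spaspt(spaspt_config(n_trajectories = 100), seed = 1)
#' table(sim$truth$state)
#' @export
simulate_spaspt <- function(config, seed = NULL) {
  stopifnot(inherits(config, "spaspt_config"))
  with_seed(seed, {
    n <- config$n_trajectories
    dt <- config$frame_interval
    bound <- stats::runif(n) < config$F_bound
    D <- ifelse(bound, config$D_bound, config$D_free)
    xy <- runif_in_region(n, config$nucleus)
    x <- xy[, 1L]; y <- xy[, 2L]
    z <- stats::runif(n, -config$dZ / 2, config$dZ / 2)
    alive <- rep(TRUE, n)
    # photobleaching lifetime in frames (Inf when disabled)
    life <- if (config$bleach_prob > 0)
      stats::rgeom(n, config$bleach_prob) + 1L else rep(Inf, n)

    traps <- NULL
    trap_of <- rep(0L, n)      # 0 = untrapped; else trap row index
    if (!is.null(config$traps)) {
      regs <- if (length(config$compartments)) config$compartments
              else list(config$nucleus)
      traps <- do.call(rbind, lapply(regs, function(rg) {
        m <- stats::rpois(1L, config$traps$density * region_area(rg))
        if (m == 0L) return(NULL)
        runif_in_region(m, rg)
      }))
    }

    X <- matrix(NA_real_, n, config$n_frames)
    Y <- matrix(NA_real_, n, config$n_frames)
    X[, 1L] <- x; Y[, 1L] <- y
    state_now <- bound
    for (f in 2:config$n_frames) {
      alive <- alive & (f - 1L) < life
      if (!any(alive)) break
      idx <- which(alive)
      Dv <- ifelse(state_now[idx], config$D_bound, config$D_free)
      sd_xy <- sqrt(2 * Dv * dt)
      nx <- x[idx] + stats::rnorm(length(idx), 0, sd_xy)
      ny <- y[idx] + stats::rnorm(length(idx), 0, sd_xy)
      fixed <- reflect_into_region(nx, ny, config$nucleus)
      nx <- fixed[, 1L]; ny <- fixed[, 2L]

      if (!is.null(traps) && nrow(traps)) {
        tr <- config$traps
        # trapped molecules: escape or stay confined to the capture disc
        trapped <- which(trap_of[idx] > 0L)
        if (length(trapped)) {
          esc <- stats::runif(length(trapped)) < tr$escape_prob
          trap_of[idx[trapped[esc]]] <- 0L
          keep <- trapped[!esc]
          if (length(keep)) {
            ti <- trap_of[idx[keep]]
            if (tr$mode == "freeze") {
              sdb <- sqrt(2 * config$D_bound * dt)
              nx[keep] <- traps[ti, 1L] + stats::rnorm(length(keep), 0, sdb)
              ny[keep] <- traps[ti, 2L] + stats::rnorm(length(keep), 0, sdb)
            } else {
              # reflect radially into the capture disc
              dxk <- nx[keep] - traps[ti, 1L]
              dyk <- ny[keep] - traps[ti, 2L]
              r <- sqrt(dxk^2 + dyk^2)
              over <- r > tr$radius
              if (any(over)) {
                rr <- pmax(2 * tr$radius - r[over], 0)
                scl <- ifelse(r[over] > 0, rr / r[over], 0)
                nx[keep][over] <- traps[ti[over], 1L] + dxk[over] * scl
                ny[keep][over] <- traps[ti[over], 2L] + dyk[over] * scl
              }
            }
          }
        }
        # free-state molecules stepping within a capture radius bind
        free_now <- which(trap_of[idx] == 0L & !state_now[idx])
        if (length(free_now)) {
          d2 <- outer(nx[free_now], traps[, 1L], "-")^2 +
                outer(ny[free_now], traps[, 2L], "-")^2
          nearest <- max.col(-d2, ties.method = "first")
          hit <- d2[cbind(seq_along(free_now), nearest)] <= tr$radius^2
          trap_of[idx[free_now[hit]]] <- nearest[hit]
        }
      }

      if (config$allow_switching) {
        # equilibrium-consistent per-frame switching
        p_on <- config$switch_prob
        p_off <- if (config$F_bound > 0)
          p_on * (1 - config$F_bound) / config$F_bound else 1
        sw <- stats::runif(length(idx))
        was_bound <- state_now[idx]
        state_now[idx] <- ifelse(was_bound, sw >= pmin(p_off, 1),
                                 sw < p_on)
      }

      zs <- z_step_survive(z[idx], rep(TRUE, length(idx)),
                           D = ifelse(state_now[idx], config$D_bound,
                                      config$D_free),
                           dt = dt, dZ = config$dZ,
                           substeps = config$z_substeps)
      z[idx] <- zs$z
      alive[idx] <- zs$alive
      surv <- idx[zs$alive]
      x[surv] <- nx[zs$alive]; y[surv] <- ny[zs$alive]
      X[surv, f] <- x[surv]; Y[surv, f] <- y[surv]
    }

    if (config$sigma_loc > 0) {
      X <- X + stats::rnorm(length(X), 0, config$sigma_loc)
      Y <- Y + stats::rnorm(length(Y), 0, config$sigma_loc)
    }
    obs <- !is.na(X)
    len <- rowSums(obs)
    traj_id <- sprintf("t%06d", seq_len(n))
    df <- data.frame(
      traj_id = rep(traj_id, times = len),
      cell_id = config$cell_id,
      frame = unlist(lapply(len, function(l) seq_len(l) - 1L),
                     use.names = FALSE),
      x = as.vector(t(X))[as.vector(t(obs))],
      y = as.vector(t(Y))[as.vector(t(obs))])
    list(trajectories = trajectories(df, max_gap = 0L),
         truth = data.frame(traj_id = traj_id,
                            state = ifelse(bound, "bound", "free"),
                            n_frames_observed = len,
                            stringsAsFactors = FALSE),
         traps = traps,
         config = config)
  })
}

#' Simulate a multi-cell spaSPT data set
#'
#' Runs [simulate_spaspt()] once per cell with derived seeds, giving a
#' per-cell data set for resampling-based fitting.
#'
#' @param config a [spaspt_config()]; `cell_id` is overridden.
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @return list with pooled `trajectories` and `truth` (with `cell_id`).
#' @export
simulate_spaspt_cells <- function(config, n_cells, seed = NULL) {
  sims <- lapply(seq_len(n_cells), function(i) {
    cfg <- config
    cfg$cell_id <- sprintf("cell%03d", i)
    simulate_spaspt(cfg, seed = child_seed(seed %||% 0L,
                                           paste0("cell", i)))
  })
  trj <- do.call(rbind, lapply(sims, function(s)
    as.data.frame(s$trajectories)))
  tru <- do.call(rbind, lapply(seq_along(sims), function(i) {
    t <- sims[[i]]$truth
    t$cell_id <- sprintf("cell%03d", i)
    t
  }))
  list(trajectories = trajectories(trj, max_gap = 0L), truth = tru)
}

#' Simulate a 2-D point pattern in a region
#'
#' Complete spatial randomness (homogeneous Poisson) or a Thomas
#' cluster process (Poisson parents with Gaussian-displaced offspring;
#' offspring falling outside the region are discarded).
#'
#' @param region a [polygon_region()].
#' @param mode `"csr"` or `"thomas"`.
#' @param intensity CSR intensity (points/µm²).
#' @param parent_intensity Thomas parent intensity (parents/µm²).
#' @param mean_offspring mean offspring per parent (Poisson).
#' @param cluster_sd Gaussian displacement SD (µm).
#' @param n_points if given (CSR only), place exactly this many points
#'   instead of a Poisson-distributed count.
#' @param seed integer seed.
#' @return a [point_pattern()].
#' @export
simulate_point_pattern <- function(region, mode = c("csr", "thomas"),
                                   intensity = NULL,
                                   parent_intensity = NULL,
                                   mean_offspring = 50,
                                   cluster_sd = 0.05,
                                   n_points = NULL, seed = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    A <- region_area(region)
    if (mode == "csr") {
      n <- if (!is.null(n_points)) as.integer(n_points) else {
        if (is.null(intensity) || intensity <= 0)
          stop("CSR needs intensity > 0 (or n_points)", call. = FALSE)
        stats::rpois(1L, intensity * A)
      }
      pts <- runif_in_region(n, region)
    } else {
      if (is.null(parent_intensity) || parent_intensity <= 0)
        stop("thomas mode needs parent_intensity > 0", call. = FALSE)
      np <- stats::rpois(1L, parent_intensity * A)
      if (np == 0L) np <- 1L
      parents <- runif_in_region(np, region)
      kids <- lapply(seq_len(np), function(i) {
        m <- stats::rpois(1L, mean_offspring)
        if (m == 0L) return(NULL)
        cbind(parents[i, 1L] + stats::rnorm(m, 0, cluster_sd),
              parents[i, 2L] + stats::rnorm(m, 0, cluster_sd))
      })
      pts <- do.call(rbind, kids)
      if (is.null(pts)) pts <- matrix(numeric(0), ncol = 2L)
      keep <- in_region(pts[, 1L], pts[, 2L], region)
      pts <- pts[keep, , drop = FALSE]
    }
    point_pattern(pts, region)
  })
}

#' Simulate a FRAP or FLIP experiment
#'
#' Particle-based simulation: two-state molecules diffuse in a 2-D
#' nucleus; at bleach events every fluorescent molecule inside the
#' bleach circle is irreversibly darkened (once at the bleach frame for
#' FRAP; every frame for FLIP). The observed trace is the count of
#' fluorescent molecules in the measurement circle multiplied by a
#' global acquisition-photobleaching factor `exp(-bleach_rate * frame)`;
#' the whole-nucleus fluorescent count (with the same factor) is
#' returned as the reference channel.
#'
#' @param kind `"FRAP"` or `"FLIP"`.
#' @param n_molecules number of molecules.
#' @param F_bound immobile fraction.
#' @param D_free,D_bound diffusion coefficients (µm²/s).
#' @param nucleus a [polygon_region()].
#' @param bleach_center,bleach_radius bleach circle (µm); the default
#'   radius is the 0.956 µm-diameter spot.
#' @param measure_center,measure_radius measurement circle; defaults to
#'   the bleach circle (FRAP). Must intersect the nucleus.
#' @param n_frames total frames.
#' @param pre_frames pre-bleach frames (bleach applied between
#'   `pre_frames - 1` and `pre_frames`, 0-based).
#' @param frame_interval seconds per frame.
#' @param bleach_rate_per_frame global acquisition bleaching rate.
#' @param seed integer seed.
#' @return an [intensity_trace()].
#' @export
simulate_recovery <- function(kind = c("FRAP", "FLIP"),
                              n_molecules = 5000L, F_bound = 0.3,
                              D_free = 3.5, D_bound = 0,
                              nucleus = disc_region(0, 0, 5, 48L),
                              bleach_center = c(0, 0),
                              bleach_radius = 0.478,
                              measure_center = NULL,
                              measure_radius = NULL,
                              n_frames = 200L, pre_frames = 15L,
                              frame_interval = 0.25,
                              bleach_rate_per_frame = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (n_frames < pre_frames)
    stop("n_frames must cover the pre-bleach frames", call. = FALSE)
  measure_center <- measure_center %||% bleach_center
  measure_radius <- measure_radius %||% bleach_radius
  cb <- closest_boundary_point(measure_center[1L], measure_center[2L],
                               nucleus)
  inside <- in_region(measure_center[1L], measure_center[2L], nucleus)
  if (!inside && sqrt(sum((cb - measure_center)^2)) > measure_radius)
    stop("measurement circle lies outside the nucleus", call. = FALSE)
  with_seed(seed, {
    xy <- runif_in_region(n_molecules, nucleus)
    x <- xy[, 1L]; y <- xy[, 2L]
    bound <- stats::runif(n_molecules) < F_bound
    sd_xy <- sqrt(2 * ifelse(bound, D_bound, D_free) * frame_interval)
    lit <- rep(TRUE, n_molecules)
    spot <- ref <- numeric(n_frames)
    in_circle <- function(cx, cy, r) (x - cx)^2 + (y - cy)^2 <= r^2
    for (f in seq_len(n_frames) - 1L) {
      if (f >= pre_frames) {
        if ((kind == "FRAP" && f == pre_frames) || kind == "FLIP")
          lit <- lit & !in_circle(bleach_center[1L], bleach_center[2L],
                                  bleach_radius)
      }
      fade <- exp(-bleach_rate_per_frame * f)
      spot[f + 1L] <- sum(lit & in_circle(measure_center[1L],
                                          measure_center[2L],
                                          measure_radius)) * fade
      ref[f + 1L] <- sum(lit) * fade
      # propagate
      nx <- x + stats::rnorm(n_molecules, 0, sd_xy)
      ny <- y + stats::rnorm(n_molecules, 0, sd_xy)
      fixed <- reflect_into_region(nx, ny, nucleus)
      x <- fixed[, 1L]; y <- fixed[, 2L]
    }
    intensity_trace(spot, ref, bleach_frame = pre_frames,
                    frame_interval = frame_interval)
  })
}

#' Simulate FISH intensity measurements
#'
#' Per-compartment integrated intensities proportional to genome copy
#' number with lognormal measurement noise of the given coefficient of
#' variation. A PAA (replication-inhibited) condition with copy number
#' exactly 1 is always included, providing the single-genome intensity
#' calibration.
#'
#' @param copy_numbers named list: condition -> integer vector of
#'   per-compartment genome copy numbers (all >= 1).
#' @param intensity_per_copy mean intensity of a single genome (a.u.).
#' @param cv coefficient of variation of the lognormal noise (>= 0).
#' @param n_paa number of PAA calibration measurements to generate when
#'   the list has no "PAA" entry.
#' @param seed integer seed.
#' @return data.frame of class `fish_measurements` with `rc_id`,
#'   `condition`, `integrated_intensity`, `volume`.
#' @export
simulate_fish_intensities <- function(copy_numbers, intensity_per_copy = 1000,
                                      cv = 0.3, n_paa = 50L, seed = NULL) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!"PAA" %in% names(copy_numbers))
    copy_numbers <- c(list(PAA = rep(1L, n_paa)), copy_numbers)
  if (any(unlist(copy_numbers) < 1))
    stop("copy numbers must be >= 1", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(names(copy_numbers), function(cond) {
      cn <- copy_numbers[[cond]]
      noise <- if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        stats::rlnorm(length(cn), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, length(cn))
      data.frame(rc_id = paste0(cond, "_", seq_along(cn)),
                 condition = cond,
                 integrated_intensity = cn * intensity_per_copy * noise,
                 volume = 0.4 * cn^(2 / 3),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("fish_measurements", "data.frame")
    out
  })
}

#' Simulate a per-residue disorder profile
#'
#' Piecewise-constant segments plus Gaussian noise clipped to `[0, 1]`;
#' a fixture generator for the disorder-segmentation module.
#'
#' @param segments list of `c(length, mean_score)` pairs.
#' @param noise_sd Gaussian noise SD before clipping.
#' @param sequence_id identifier.
#' @param seed integer seed.
#' @return a [disorder_profile()].
#' @export
simulate_disorder_scores <- function(segments, noise_sd = 0,
                                     sequence_id = "synthetic",
                                     seed = NULL) {
  lens <- vapply(segments, function(s) s[1L], numeric(1))
  if (any(lens < 1)) stop("zero-length segment", call. = FALSE)
  with_seed(seed, {
    sc <- unlist(lapply(segments, function(s) rep(s[2L], s[1L])))
    if (noise_sd > 0)
      sc <- sc + stats::rnorm(length(sc), 0, noise_sd)
    disorder_profile(sequence_id, pmin(1, pmax(0, sc)))
  })
}
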