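#' Compile jump-length statistics
#'
#' Computes displacement lengths at lag times of 1..`n_lags` frames
#' from labelled trajectories, the input of the two-state kinetic fit.
#' A jump at lag `n` joins two localizations whose frame indices differ
#' by exactly `n`, so a detection gap is never spanned implicitly. At
#' most the first `cap` jumps of each trajectory are used at each lag
#' (the displacement statistics would otherwise be dominated by the
#' long-lived, mostly bound trajectories).
#'
#' @param trajs a [trajectories()] table, optionally with a `label`
#'   column from [assign_compartments()].
#' @param n_lags number of frame lags (default 7).
#' @param cap jumps kept per trajectory per lag (default 4).
#' @param frame_interval seconds per frame.
#' @return object of class `jump_length_data`: a list with one entry
#'   per label (or `"all"`), each holding `jumps` (list of numeric
#'   vectors, one per lag) and `counts`.
#' @export
compile_jump_statistics <- function(trajs, n_lags = 7L, cap = 4L,
                                    frame_interval = 0.007447) {
  df <- as.data.frame(trajs)
  if (!"label" %in% names(df)) df$label <- "all"
  out <- lapply(split(df, df$label), function(sub) {
    key <- paste(sub$cell_id, sub$traj_id)
    groups <- split(seq_len(nrow(sub)), key)
    acc <- lapply(seq_len(n_lags), function(n) vector("list", length(groups)))
    for (g in seq_along(groups)) {
      i <- groups[[g]]
      fr <- sub$frame[i]; px <- sub$x[i]; py <- sub$y[i]
      for (n in seq_len(n_lags)) {
        j <- match(fr + n, fr)
        ok <- which(!is.na(j))
        if (!length(ok)) next
        ok <- ok[seq_len(min(cap, length(ok)))]
        acc[[n]][[g]] <- sqrt((px[j[ok]] - px[ok])^2 +
                              (py[j[ok]] - py[ok])^2)
      }
    }
    jumps <- lapply(acc, function(a) unlist(a, use.names = FALSE))
    counts <- vapply(jumps, length, integer(1))
    for (n in seq_len(n_lags)) {
      if (counts[n] == 0L)
        warning("no jumps at lag ", n, "; lag omitted from fits",
                call. = FALSE)
    }
    list(jumps = jumps, counts = counts)
  })
  structure(list(by_label = out, n_lags = as.integer(n_lags),
                 cap = as.integer(cap),
                 n_trajectories = length(unique(paste(df$cell_id,
                                                      df$traj_id))),
                 frame_interval = frame_interval),
            class = "jump_length_data")
}

#' Axial defocalization survival fraction
#'
#' Probability that a molecule with axial diffusion coefficient `D`,
#' starting uniformly inside a detection slab of depth `dZ` with
#' absorbing boundaries, is still inside at time `t`. Computed with the
#' standard eigenfunction series for the 1-D absorbing slab,
#' `Z = sum_{k odd} (8 / (k pi)^2) exp(-(k pi)^2 D t / dZ^2)`,
#' truncated when terms fall below 1e-10.
#'
#' @param D axial diffusion coefficient (µm²/s).
#' @param dZ slab depth (µm).
#' @param t elapsed time (s); vectorized.
#' @return survival probabilities in (0, 1].
#' @export
defocalization_fraction <- function(D, dZ = 0.7, t) {
  stopifnot(D >= 0, dZ > 0, all(t > 0))
  if (D == 0) return(rep(1, length(t)))
  out <- numeric(length(t))
  tau <- pi^2 * D * t / dZ^2
  k <- 1
  repeat {
    term <- 8 / (k * pi)^2 * exp(-k^2 * tau)
    out <- out + term
    if (all(term < 1e-10)) break
    k <- k + 2
  }
  pmin(out, 1)
}

#' Two-state model parameters
#'
#' Parameter container for the bound/free jump-length mixture model,
#' with the fitting bounds used throughout: `D_free` in \[0.5, 25\]
#' µm²/s, `D_bound` in \[0.0001, 0.08\] µm²/s, `F_bound` in \[0, 1\];
#' the localization error is fixed at 45 nm and the slab depth at
#' 0.7 µm.
#'
#' @param F_bound bound (immobile) fraction.
#' @param D_free,D_bound diffusion coefficients (µm²/s).
#' @param sigma_loc localization error (µm).
#' @param dZ detection slab depth (µm).
#' @param frame_interval seconds per frame.
#' @return object of class `two_state_params`.
#' @export
two_state_params <- function(F_bound, D_free, D_bound,
                             sigma_loc = 0.045, dZ = 0.7,
                             frame_interval = 0.007447) {
  if (F_bound < 0 || F_bound > 1)
    stop("F_bound must lie in [0, 1]", call. = FALSE)
  if (D_free < 0.5 || D_free > 25)
    stop("D_free must lie in [0.5, 25] um^2/s", call. = FALSE)
  if (D_bound < 1e-4 || D_bound > 0.08)
    stop("D_bound must lie in [0.0001, 0.08] um^2/s", call. = FALSE)
  structure(list(F_bound = F_bound, D_free = D_free, D_bound = D_bound,
                 sigma_loc = sigma_loc, dZ = dZ,
                 frame_interval = frame_interval),
            class = "two_state_params")
}

# Defocalization weight of the free component at lag n. "cap" averages
# the absorbing-slab survival over the jumps actually compiled (the
# j-th retained lag-n jump requires surviving n+j frames); "single" is
# the plain survival at n*dt.
z_weight <- function(params, n, cap = 4L,
                     z_weighting = c("cap", "single")) {
  z_weighting <- match.arg(z_weighting)
  dt <- params$frame_interval
  if (z_weighting == "single")
    defocalization_fraction(params$D_free, params$dZ, n * dt)
  else
    mean(defocalization_fraction(params$D_free, params$dZ,
                                 (n + seq_len(cap) - 1) * dt))
}

#' Two-state jump-length model CDF
#'
#' Cumulative distribution of 2-D jump lengths at lag `n` frames under
#' the bound/free mixture with localization error and defocalization
#' correction. Component X contributes
#' `1 - exp(-r^2 / (4 (D_X t + sigma^2)))` with weight `F_bound` for
#' the bound state and `(1 - F_bound) * Z_n` for the free state, the
#' weights renormalized to 1; `Z_n` is the absorbing-slab survival
#' (see [defocalization_fraction()] and `z_weighting`).
#'
#' @param params a [two_state_params()].
#' @param n lag in frames.
#' @param r jump-length grid (µm, >= 0).
#' @param cap jumps-per-trajectory cap assumed for `z_weighting = "cap"`.
#' @param z_weighting `"cap"` (default; survival averaged over the
#'   retained jumps) or `"single"` (survival at `n * dt` only).
#' @return model CDF values on `r`.
#' @export
two_state_cdf <- function(params, n, r, cap = 4L,
                          z_weighting = c("cap", "single")) {
  stopifnot(inherits(params, "two_state_params"), all(r >= 0))
  t <- n * params$frame_interval
  s2 <- params$sigma_loc^2
  wb <- params$F_bound
  wf <- (1 - params$F_bound) * z_weight(params, n, cap, z_weighting)
  cb <- 1 - exp(-r^2 / (4 * (params$D_bound * t + s2)))
  cf <- 1 - exp(-r^2 / (4 * (params$D_free * t + s2)))
  (wb * cb + wf * cf) / (wb + wf)
}

#' Fit the two-state kinetic model
#'
#' Weighted least-squares fit of the two-state mixture CDF to the
#' empirical jump-length CDFs jointly over all lags, each lag weighted
#' by its jump count. Optimization is bounded (L-BFGS-B) within the
#' model's parameter ranges with stratified multi-start initialisation;
#' the best SSE solution is returned. The procedure is deterministic:
#' the restart grid is fixed.
#'
#' @param data a [compile_jump_statistics()] result.
#' @param label which label to fit (`"all"` when unlabelled).
#' @param sigma_loc,dZ fixed localization error and slab depth (µm).
#' @param grid_points maximum empirical-CDF support points per lag.
#' @param z_weighting see [two_state_cdf()].
#' @param min_trajectories refuse to fit below this many trajectories
#'   (warn below 1000, the minimum for a reliable two-state fit).
#' @return object of class `two_state_fit`: list with `params`
#'   (a [two_state_params()]), `sse`, `n_jumps`, `convergence`, and
#'   `restarts` (per-start results).
#' @export
fit_two_state <- function(data, label = NULL, sigma_loc = 0.045,
                          dZ = 0.7, grid_points = 500L,
                          z_weighting = c("cap", "single"),
                          min_trajectories = 100L) {
  stopifnot(inherits(data, "jump_length_data"))
  z_weighting <- match.arg(z_weighting)
  if (is.null(label)) label <- names(data$by_label)[1L]
  if (!label %in% names(data$by_label))
    stop("no such label: ", label, call. = FALSE)
  if (data$n_trajectories < min_trajectories)
    stop("refusing to fit ", data$n_trajectories,
         " trajectories (< ", min_trajectories, ")", call. = FALSE)
  if (data$n_trajectories < 1000L)
    warning("fewer than 1000 trajectories; two-state fits may be ",
            "unreliable", call. = FALSE)
  dt <- data$frame_interval
  jumps <- data$by_label[[label]]$jumps
  lags <- which(vapply(jumps, length, integer(1)) > 0L)
  # empirical CDF on (subsampled) pooled support per lag
  emp <- lapply(lags, function(n) {
    r <- sort(jumps[[n]])
    cdf <- seq_along(r) / length(r)
    if (length(r) > grid_points) {
      keep <- unique(round(seq(1L, length(r), length.out = grid_points)))
      r <- r[keep]; cdf <- cdf[keep]
    }
    list(r = r, cdf = cdf, w = length(jumps[[n]]))
  })
  wtot <- sum(vapply(emp, function(e) e$w, numeric(1)))
  objective <- function(p) {
    par <- structure(list(F_bound = p[1L], D_free = p[2L],
                          D_bound = p[3L], sigma_loc = sigma_loc,
                          dZ = dZ, frame_interval = dt),
                     class = "two_state_params")
    sse <- 0
    for (k in seq_along(lags)) {
      e <- emp[[k]]
      m <- two_state_cdf(par, lags[k], e$r, cap = data$cap,
                         z_weighting = z_weighting)
      sse <- sse + e$w / wtot * mean((m - e$cdf)^2)
    }
    sse
  }
  lower <- c(0, 0.5, 1e-4)
  upper <- c(1, 25, 0.08)
  starts <- expand.grid(F = c(0.25, 0.5, 0.75),
                        Df = c(1, 5, 15), Db = 0.005)
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    stats::optim(as.numeric(starts[i, ]), objective,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e3, maxit = 500L))
  })
  conv <- vapply(fits, function(f) f$convergence, numeric(1))
  if (all(conv != 0))
    stop("two-state fit failed to converge from any start",
         call. = FALSE)
  sses <- vapply(fits, function(f) f$value, numeric(1))
  sses[conv != 0] <- Inf
  best <- fits[[which.min(sses)]]
  structure(list(
    params = two_state_params(best$par[1L],
                              min(max(best$par[2L], 0.5), 25),
                              min(max(best$par[3L], 1e-4), 0.08),
                              sigma_loc = sigma_loc, dZ = dZ,
                              frame_interval = dt),
    sse = best$value,
    n_jumps = vapply(emp, function(e) e$w, numeric(1)),
    n_trajectories = data$n_trajectories,
    label = label, z_weighting = z_weighting,
    convergence = best$convergence,
    restarts = data.frame(F_bound = vapply(fits, function(f)
      f$par[1L], numeric(1)),
      D_free = vapply(fits, function(f) f$par[2L], numeric(1)),
      sse = vapply(fits, function(f) f$value, numeric(1)))),
    class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat("Two-state jump-length fit (", x$label, ")\n", sep = "")
  cat(sprintf("  F_bound = %.3f\n  D_free  = %.3f um^2/s\n",
              x$params$F_bound, x$params$D_free))
  cat(sprintf("  D_bound = %.4f um^2/s\n  SSE     = %.3g (%d traj)\n",
              x$params$D_bound, x$sse, x$n_trajectories))
  invisible(x)
}

#' Subsampled two-state fitting across cells
#'
#' Repeatedly samples `cells_per_resample` cells without replacement,
#' pools their trajectories (optionally restricted to one label), fits
#' the two-state model, and reports the median and standard deviation
#' of each parameter across resamples — the per-condition uncertainty
#' estimate used when single cells carry too few trajectories to fit
#' alone.
#'
#' @param trajs a [trajectories()] table covering many cells (with a
#'   `label` column if `label` is given).
#' @param label restrict to this compartment label (`NULL` = all).
#' @param cells_per_resample cells per draw (default 15).
#' @param n_resamples number of draws (default 100).
#' @param seed integer seed; draws are deterministic given the seed.
#' @param ... passed to [fit_two_state()].
#' @return object of class `subsample_fit`: list with `estimates`
#'   (data.frame: parameter, median, sd), `draws` (per-resample
#'   parameter table), and the settings.
#' @export
subsample_fit <- function(trajs, label = NULL, cells_per_resample = 15L,
                          n_resamples = 100L, seed = NULL, ...) {
  df <- as.data.frame(trajs)
  if (!is.null(label)) {
    if (!"label" %in% names(df))
      stop("trajectories carry no 'label' column", call. = FALSE)
    df <- df[df$label == label, , drop = FALSE]
  }
  cells <- unique(df$cell_id)
  if (length(cells) < cells_per_resample)
    stop("only ", length(cells), " cells available; lower ",
         "cells_per_resample", call. = FALSE)
  draws <- with_seed(seed, {
    lapply(seq_len(n_resamples), function(i) {
      pick <- sample(cells, cells_per_resample)
      sub <- df[df$cell_id %in% pick, , drop = FALSE]
      jl <- compile_jump_statistics(trajectories(sub[c("traj_id",
        "cell_id", "frame", "x", "y")], max_gap = Inf))
      fit <- suppressWarnings(fit_two_state(jl, ...))
      c(F_bound = fit$params$F_bound, D_free = fit$params$D_free,
        D_bound = fit$params$D_bound)
    })
  })
  dm <- do.call(rbind, draws)
  est <- data.frame(parameter = colnames(dm),
                    median = apply(dm, 2L, stats::median),
                    sd = apply(dm, 2L, stats::sd),
                    row.names = NULL)
  structure(list(estimates = est, draws = as.data.frame(dm),
                 cells_per_resample = cells_per_resample,
                 n_resamples = n_resamples, label = label),
            class = "subsample_fit")
}
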