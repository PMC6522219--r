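test_that("jump compilation honours the per-trajectory cap and lags", {
  # 8 gap-free points, cap 4: exactly 4 jumps at lag 1
  t8 <- traj_fixture(list(cbind(0:7, (0:7) * 0.1, rep(0, 8))))
  jl <- compile_jump_statistics(t8, n_lags = 7, cap = 4)
  counts <- jl$by_label$all$counts
  expect_equal(counts[1], 4)
  expect_equal(counts[7], 1)   # only one lag-7 pair exists
  # 3 points: 2 lag-1, 1 lag-2, none beyond
  t3 <- traj_fixture(list(cbind(0:2, c(0, 1, 3), rep(0, 3))))
  suppressWarnings(jl3 <- compile_jump_statistics(t3, n_lags = 3))
  expect_equal(jl3$by_label$all$counts, c(2L, 1L, 0L))
  expect_warning(compile_jump_statistics(t3, n_lags = 3), "lag 3")
})

test_that("jump lengths equal brute-force pairwise distances", {
  set.seed(21)
  mats <- lapply(1:5, function(i) {
    n <- sample(3:9, 1)
    cbind(seq_len(n) - 1, cumsum(rnorm(n, 0, 0.1)),
          cumsum(rnorm(n, 0, 0.1)))
  })
  trajs <- traj_fixture(mats)
  jl <- compile_jump_statistics(trajs, n_lags = 3, cap = 1000)
  for (lag in 1:3) {
    manual <- unlist(lapply(mats, function(m) {
      n <- nrow(m)
      if (n <= lag) return(numeric(0))
      i <- seq_len(n - lag)
      sqrt((m[i + lag, 2] - m[i, 2])^2 + (m[i + lag, 3] - m[i, 3])^2)
    }))
    expect_equal(sort(jl$by_label$all$jumps[[lag]]), sort(manual))
  }
})

test_that("gaps are never spanned implicitly", {
  tg <- traj_fixture(list(cbind(c(0, 2, 3), c(0, 1, 1.5), c(0, 0, 0))))
  jl <- suppressWarnings(compile_jump_statistics(tg, n_lags = 3))
  expect_equal(jl$by_label$all$counts[1], 1)  # only frames 2->3
  expect_equal(jl$by_label$all$counts[2], 1)  # frames 0->2
  expect_equal(jl$by_label$all$jumps[[3]], 1.5)  # frames 0->3
})

test_that("defocalization series has the right limits and monotonicity", {
  dt <- 0.007447
  expect_equal(defocalization_fraction(0, 0.7, dt), 1)
  expect_gte(defocalization_fraction(3.5, 50, dt), 0.99)
  z_t <- defocalization_fraction(3.5, 0.7, (1:7) * dt)
  expect_true(all(diff(z_t) < 0))
  z_D <- vapply(c(1, 3.5, 10), defocalization_fraction,
                numeric(1), dZ = 0.7, t = dt)
  expect_true(all(diff(z_D) < 0))
  z_dz <- vapply(c(0.5, 0.7, 1), function(dz)
    defocalization_fraction(3.5, dz, dt), numeric(1))
  expect_true(all(diff(z_dz) > 0))
})

test_that("defocalization series agrees with a Monte-Carlo oracle", {
  dt <- 0.007447
  for (k in c(1, 4, 7)) {
    mc <- defocalization_mc(3.5, 0.7, k * dt, n_walkers = 2e5,
                            seed = 100 + k)
    expect_lt(abs(defocalization_fraction(3.5, 0.7, k * dt) - mc),
              0.005)
  }
})

test_that("model CDF collapses correctly and has closed-form quantiles", {
  # F_bound = 1: single component with scale 4 (D_bound t + sigma^2)
  p <- two_state_params(1, 3.5, 0.01)
  r <- seq(0, 0.5, by = 0.01)
  t <- p$frame_interval
  expect_equal(two_state_cdf(p, 1, r),
               1 - exp(-r^2 / (4 * (0.01 * t + 0.045^2))))
  # immobile, sigma only: median jump = 2 sigma sqrt(ln 2) ~ 0.0749
  p0 <- two_state_params(1, 3.5, 1e-4, frame_interval = 1e-9)
  med <- stats::uniroot(function(r) two_state_cdf(p0, 1, r) - 0.5,
                        c(0.01, 0.3))$root
  expect_equal(med, 2 * 0.045 * sqrt(log(2)), tolerance = 1e-3)
})

test_that("model CDF is a proper, monotone distribution function", {
  for (p in list(two_state_params(0.3, 3.5, 0.005),
                 two_state_params(0.9, 1, 0.05),
                 two_state_params(0, 20, 0.01))) {
    for (n in c(1, 4, 7)) {
      r <- seq(0, 3, by = 0.01)
      v <- two_state_cdf(p, n, r)
      expect_true(all(diff(v) >= -1e-12))
      expect_equal(two_state_cdf(p, n, 1e3), 1, tolerance = 1e-10)
      expect_equal(v[1], 0)
    }
  }
})

test_that("model CDF matches Monte-Carlo mixture sampling", {
  p <- two_state_params(0.5, 3.5, 0.005)
  for (n in c(1, 4)) {
    jumps <- two_state_mc_jumps(p, n, n_jumps = 2e5, seed = n)
    grid <- seq(0, 2, by = 0.002)
    ks <- max(abs(two_state_cdf(p, n, grid) -
                    stats::ecdf(jumps)(grid)))
    expect_lt(ks, 0.01)
  }
})

test_that("the fit recovers an all-bound population at the boundary", {
  sim <- simulate_spaspt(spaspt_config(n_trajectories = 5000,
                                       F_bound = 1), seed = 31)
  jl <- compile_jump_statistics(sim$trajectories)
  fit <- fit_two_state(jl)
  expect_gte(fit$params$F_bound, 0.95)
})

test_that("optimised SSE is never worse than the truth parameters", {
  sim <- simulate_spaspt(spaspt_config(n_trajectories = 2000), seed = 32)
  jl <- compile_jump_statistics(sim$trajectories)
  fit <- fit_two_state(jl)
  # evaluate the fit objective at the generating parameters
  truth_sse <- local({
    emp <- jl$by_label$all
    lags <- seq_len(jl$n_lags)
    wtot <- sum(emp$counts)
    p <- two_state_params(0.5, 3.5, 0.005)
    sum(vapply(lags, function(n) {
      r <- sort(emp$jumps[[n]])
      cdf <- seq_along(r) / length(r)
      keep <- unique(round(seq(1, length(r), length.out = 500)))
      m <- two_state_cdf(p, n, r[keep])
      emp$counts[n] / wtot * mean((m - cdf[keep])^2)
    }, numeric(1)))
  })
  expect_lte(fit$sse, truth_sse + 1e-12)
})

test_that("fits refuse tiny data sets and warn on small ones", {
  sim <- simulate_spaspt(spaspt_config(n_trajectories = 50), seed = 33)
  jl <- compile_jump_statistics(sim$trajectories)
  expect_error(fit_two_state(jl), "refusing")
  sim2 <- simulate_spaspt(spaspt_config(n_trajectories = 300), seed = 34)
  jl2 <- compile_jump_statistics(sim2$trajectories)
  expect_warning(fit_two_state(jl2), "1000")
})

test_that("subsampled fits are tight and reproducible on homogeneous cells", {
  cells <- simulate_spaspt_cells(spaspt_config(n_trajectories = 400),
                                 n_cells = 8, seed = 35)
  sf <- subsample_fit(cells$trajectories, cells_per_resample = 4,
                      n_resamples = 6, seed = 11)
  est <- sf$estimates
  fb <- est[est$parameter == "F_bound", ]
  expect_lt(fb$sd, 0.05)
  expect_lt(abs(fb$median - 0.5), 0.05)
  sf2 <- subsample_fit(cells$trajectories, cells_per_resample = 4,
                       n_resamples = 6, seed = 11)
  expect_identical(sf$draws, sf2$draws)
  expect_error(subsample_fit(cells$trajectories,
                             cells_per_resample = 20, n_resamples = 2,
                             seed = 1), "lower")
})
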