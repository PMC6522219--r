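test_that("all-bound, noise-free simulation reproduces 4*D*dt MSD", {
  cfg <- spaspt_config(n_trajectories = 1500, F_bound = 1,
                       D_bound = 0.02, sigma_loc = 0, n_frames = 8)
  sim <- simulate_spaspt(cfg, seed = 1)
  jl <- compile_jump_statistics(sim$trajectories, n_lags = 1,
                                cap = 100)$by_label$all$jumps[[1]]
  msd <- mean(jl^2)
  expected <- 4 * cfg$D_bound * cfg$frame_interval
  se <- stats::sd(jl^2) / sqrt(length(jl))
  expect_lt(abs(msd - expected), 3 * se)
})

test_that("free-molecule MSD matches 4*D*dt without truncation", {
  # huge slab and nucleus: no defocalization, no boundary effects
  cfg <- spaspt_config(n_trajectories = 3000, F_bound = 0, D_free = 3.5,
                       sigma_loc = 0, dZ = 100,
                       nucleus = disc_region(0, 0, 200, 32),
                       n_frames = 6)
  sim <- simulate_spaspt(cfg, seed = 2)
  jl <- compile_jump_statistics(sim$trajectories, n_lags = 1,
                                cap = 100)$by_label$all$jumps[[1]]
  expect_gt(length(jl), 1e4)
  expected <- 4 * 3.5 * cfg$frame_interval
  se <- stats::sd(jl^2) / sqrt(length(jl))
  expect_lt(abs(mean(jl^2) - expected), 3 * se)
})

test_that("the bound-state assignment follows F_bound", {
  sim <- simulate_spaspt(spaspt_config(n_trajectories = 5000,
                                       F_bound = 0.5, D_free = 3.5),
                         seed = 3)
  p_hat <- mean(sim$truth$state == "bound")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("simulation is a pure function of (config, seed)", {
  cfg <- spaspt_config(n_trajectories = 200)
  a <- simulate_spaspt(cfg, seed = 7)
  b <- simulate_spaspt(cfg, seed = 7)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$truth, b$truth)
  c <- simulate_spaspt(cfg, seed = 8)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("defocalization loss grows with track length and mobility", {
  surv_by_len <- function(D) {
    sim <- simulate_spaspt(spaspt_config(n_trajectories = 3000,
                                         F_bound = 0, D_free = D,
                                         n_frames = 8), seed = 4)
    sapply(1:7, function(k) mean(sim$truth$n_frames_observed > k))
  }
  s35 <- surv_by_len(3.5)
  expect_true(all(diff(s35) < 0))
  s10 <- surv_by_len(10)
  expect_true(all(s10 <= s35))
  # and the survival matches the absorbing-slab series
  z <- defocalization_fraction(3.5, 0.7, (1:7) * 0.007447)
  expect_lt(max(abs(s35 - z)), 0.05)
})

test_that("CSR point counts follow the Poisson law", {
  sq <- unit_square()
  counts <- vapply(1:200, function(s)
    simulate_point_pattern(sq, "csr", intensity = 100, seed = s)$n,
    numeric(1))
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))
  p1 <- simulate_point_pattern(sq, "csr", intensity = 50, seed = 9)
  p2 <- simulate_point_pattern(sq, "csr", intensity = 50, seed = 9)
  expect_identical(p1$points, p2$points)
  expect_error(simulate_point_pattern(sq, "csr"), "intensity")
})

test_that("cluster-mode offspring stay near their parent", {
  sq <- big_square()
  # one parent on average; tiny spread
  p <- simulate_point_pattern(sq, "thomas", parent_intensity = 0.01,
                              mean_offspring = 50, cluster_sd = 0.02,
                              seed = 11)
  ctr <- colMeans(p$points)
  d <- sqrt((p$points[, 1] - ctr[1])^2 + (p$points[, 2] - ctr[2])^2)
  expect_true(all(d < 5 * 0.02 * sqrt(2)))
})

test_that("FRAP simulation limits: instant recovery and frozen pools", {
  fast <- simulate_recovery("FRAP", n_molecules = 8000, F_bound = 0,
                            D_free = 500, n_frames = 40, seed = 1)
  nf <- normalize_frap(fast)
  expect_gt(mean(nf$normalized[17:40]), 0.95)
  frozen <- simulate_recovery("FRAP", n_molecules = 8000, F_bound = 1,
                              D_bound = 0, n_frames = 40, seed = 1)
  nz <- normalize_frap(frozen)
  post <- nz$normalized[16:40]
  expect_lt(max(post) - min(post), 0.05)
})

test_that("FLIP with a decoupled spot decays at the global bleach rate", {
  # immobile molecules, measurement spot far from the bleach circle:
  # the observed decay is exactly the acquisition photobleaching
  tr <- simulate_recovery("FLIP", n_molecules = 4000, F_bound = 1,
                          D_bound = 0, bleach_center = c(20, 0),
                          measure_center = c(0, 0),
                          n_frames = 60, bleach_rate_per_frame = 0.09,
                          seed = 2)
  expected <- tr$spot_raw[1] * exp(-0.09 * tr$frame)
  expect_equal(tr$spot_raw, expected, tolerance = 1e-8)
  expect_error(simulate_recovery("FRAP", measure_center = c(50, 0),
                                 seed = 1), "outside the nucleus")
})

test_that("FISH intensities scale exactly with copy number when CV = 0", {
  fm <- simulate_fish_intensities(list(`6hpi` = c(1L, 47L)),
                                  intensity_per_copy = 500, cv = 0,
                                  seed = 1)
  paa <- fm$integrated_intensity[fm$condition == "PAA"]
  expect_true(all(paa == 500))
  hpi6 <- fm$integrated_intensity[fm$condition == "6hpi"]
  expect_equal(hpi6[2] / hpi6[1], 47)
  expect_identical(fm, simulate_fish_intensities(
    list(`6hpi` = c(1L, 47L)), intensity_per_copy = 500, cv = 0,
    seed = 1))
  expect_error(simulate_fish_intensities(list(a = 1), cv = -1), "cv")
  expect_error(simulate_fish_intensities(list(a = 0L)), ">= 1")
})

test_that("disorder profile generator builds exact step profiles", {
  p <- simulate_disorder_scores(list(c(100, 0.9)), noise_sd = 0)
  expect_equal(p$scores, rep(0.9, 100))
  p2 <- simulate_disorder_scores(list(c(50, 0.2), c(50, 0.9)),
                                 noise_sd = 0)
  expect_equal(p2$scores[50:51], c(0.2, 0.9))
  expect_identical(simulate_disorder_scores(list(c(30, 0.5)),
                                            noise_sd = 0.1, seed = 5),
                   simulate_disorder_scores(list(c(30, 0.5)),
                                            noise_sd = 0.1, seed = 5))
  expect_error(simulate_disorder_scores(list(c(0, 0.5))), "zero-length")
})
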