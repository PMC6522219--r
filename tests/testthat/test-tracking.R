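make_locs <- function(frame, x, y, cell = "c1") {
  localizations(x, y, frame, rep(cell, length(x)))
}

test_that("nearby consecutive detections link into one trajectory", {
  locs <- make_locs(c(0, 1), c(0, 0.1), c(0, 0))
  tr <- link_localizations(locs, linking_config())
  expect_equal(length(unique(tr$traj_id)), 1)
  expect_equal(nrow(tr), 2)
})

test_that("a one-frame detection gap is bridged when allowed", {
  locs <- make_locs(c(0, 2), c(0, 0.2), c(0, 0))
  tr1 <- link_localizations(locs, linking_config(gap_frames = 1))
  expect_equal(length(unique(tr1$traj_id)), 1)
  tr0 <- link_localizations(locs, linking_config(gap_frames = 0))
  expect_equal(length(unique(tr0$traj_id)), 2)
})

test_that("greedy assignment matches exhaustive matching on a 2x2 case", {
  # two ends at frame 0, two candidates at frame 1; the shortest-first
  # greedy choice coincides with the minimal-total-distance assignment
  locs <- make_locs(c(0, 0, 1, 1), c(0, 1, 0.05, 0.80),
                    c(0, 0, 0, 0))
  tr <- link_localizations(locs, linking_config())
  # brute-force: evaluate both possible pairings
  d <- function(i, j) abs(c(0, 1)[i] - c(0.05, 0.80)[j])
  tot_a <- d(1, 1) + d(2, 2)  # 0.05 + 0.20
  tot_b <- d(1, 2) + d(2, 1)  # 0.80 + 0.95
  expect_lt(tot_a, tot_b)
  ids <- split(tr$x, tr$traj_id)
  pairs <- Filter(function(v) length(v) == 2, ids)
  expect_equal(length(pairs), 2)
  sorted <- lapply(pairs, sort)
  expect_true(any(vapply(sorted, identical, logical(1), c(0, 0.05))))
  expect_true(any(vapply(sorted, identical, logical(1), c(0.80, 1))))
})

test_that("linking never creates a jump longer than its search radius", {
  cfg <- linking_config()
  set.seed(99)
  for (rep in 1:5) {
    n <- 120
    locs <- make_locs(sample(0:10, n, replace = TRUE),
                      runif(n, 0, 3), runif(n, 0, 3))
    locs <- locs[!duplicated(locs[c("frame", "x", "y")]), ]
    class(locs) <- c("localizations", "data.frame")
    tr <- suppressWarnings(link_localizations(locs, cfg))
    df <- as.data.frame(tr)
    key <- paste(df$cell_id, df$traj_id)
    a <- seq_len(nrow(df) - 1); b <- a + 1
    same <- key[a] == key[b]
    if (!any(same)) next
    k <- df$frame[b][same] - df$frame[a][same]
    jump <- sqrt((df$x[b] - df$x[a])^2 + (df$y[b] - df$y[a])^2)[same]
    expect_true(all(jump <= sqrt(4 * cfg$d_max * k *
                                   cfg$frame_interval) + 1e-12))
  }
})

test_that("annotation interpolation is exact at endpoints and linear", {
  nuc <- disc_region(5, 5, 4, 16)
  comp <- unit_square()
  ann <- cell_annotation("c1", nuc,
                         nucleus_after = translate_region(nuc, 1, 0),
                         compartments_before = list(comp),
                         compartments_after =
                           list(translate_region(comp, 1, 0)),
                         n_frames = 101)
  expect_equal(unclass(interpolate_annotation(ann, 0)$compartments[[1]]),
               unclass(comp), ignore_attr = TRUE)
  expect_equal(unclass(interpolate_annotation(ann, 100)$compartments[[1]]),
               unclass(translate_region(comp, 1, 0)), ignore_attr = TRUE)
  mid <- interpolate_annotation(ann, 50)$compartments[[1]]
  expect_equal(unclass(mid), unclass(translate_region(comp, 0.5, 0)),
               ignore_attr = TRUE)
  expect_error(interpolate_annotation(ann, 101), "out of range")
})

test_that("one inside localization labels the whole trajectory inside", {
  nuc <- big_square()
  comp <- polygon_region(cbind(c(4, 6, 6, 4), c(4, 4, 6, 6)))
  ann <- cell_annotation("c1", nuc, compartments_before = list(comp))
  trajs <- traj_fixture(list(
    cbind(0:4, c(1, 2, 5, 2, 1), rep(5, 5)),   # one point inside
    cbind(0:2, c(1, 1.2, 1.4), rep(1, 3))))    # fully outside
  lab <- assign_compartments(trajs, ann)
  lab_by <- tapply(lab$label, lab$traj_id, unique)
  expect_equal(lab_by[["t01"]], "inside")
  expect_equal(lab_by[["t02"]], "outside")
})

test_that("static-annotation labels match brute-force containment", {
  nuc <- big_square()
  comp <- disc_region(5, 5, 1.5, 20)
  ann <- cell_annotation("c1", nuc, compartments_before = list(comp))
  sim <- simulate_spaspt(spaspt_config(
    n_trajectories = 150,
    nucleus = polygon_region(cbind(c(1, 9, 9, 1), c(1, 1, 9, 9)))),
    seed = 5)
  lab <- assign_compartments(sim$trajectories, ann)
  manual <- pip_oracle(lab$x, lab$y, comp)
  expect_equal(lab$in_compartment, manual)
  expected <- tapply(manual, lab$traj_id, any)
  got <- tapply(lab$label == "inside", lab$traj_id, unique)
  expect_equal(as.logical(got[names(expected)]),
               as.logical(expected))
})

test_that("nuclear masking discards detections outside the nucleus", {
  nuc <- unit_square()
  ann <- cell_annotation("c1", nuc)
  trajs <- traj_fixture(list(cbind(0:2, c(0.5, 1.5, 0.6), rep(0.5, 3))))
  lab <- assign_compartments(trajs, ann)
  expect_equal(nrow(lab), 2)
  expect_true(all(lab$x <= 1))
})

test_that("mock compartments are placed inside and avoid nucleoli", {
  nuc <- disc_region(0, 0, 5, 32)
  lib <- list(disc_region(0, 0, 1, 16))
  tgt <- cell_annotation("c1", nuc,
                         nucleoli = list(disc_region(2, 2, 0.8, 16)))
  mock <- place_mock_compartments(lib, 2L, tgt, seed = 1)
  expect_length(mock$compartments_before, 2)
  for (cp in mock$compartments_before) {
    expect_true(all(in_region(cp[, 1], cp[, 2], nuc)))
    expect_false(regions_overlap(cp, tgt$nucleoli[[1]]))
  }
  expect_false(regions_overlap(mock$compartments_before[[1]],
                               mock$compartments_before[[2]]))
  # deterministic given seed
  mock2 <- place_mock_compartments(lib, 2L, tgt, seed = 1)
  expect_identical(lapply(mock$compartments_before, unclass),
                   lapply(mock2$compartments_before, unclass))
})

test_that("impossible mock placement raises a placement error", {
  nuc <- disc_region(0, 0, 2, 32)
  tgt <- cell_annotation("cX", nuc,
                         nucleoli = list(disc_region(0, 0, 1.9, 32)))
  expect_error(place_mock_compartments(list(disc_region(0, 0, 1, 16)),
                                       1L, tgt, seed = 1,
                                       max_attempts = 50),
               "cX")
})

test_that("mock labelling fraction tracks the mock area fraction", {
  nuc <- disc_region(0, 0, 5, 32)
  tgt <- cell_annotation("sim", nuc)
  mock <- place_mock_compartments(list(disc_region(0, 0, 1.2, 24)),
                                  3L, tgt, seed = 3)
  afrac <- sum(vapply(mock$compartments_before, region_area,
                      numeric(1))) / region_area(nuc)
  # single-localization trajectories make the trajectory-level label
  # equivalent to point containment, for which the area fraction is
  # the exact expectation
  sim <- simulate_spaspt(spaspt_config(n_trajectories = 4000,
                                       nucleus = nuc, sigma_loc = 0),
                         seed = 6)
  first <- as.data.frame(sim$trajectories)
  first <- first[first$frame == 0, ]
  singles <- trajectories(first, max_gap = Inf)
  lab <- assign_compartments(singles, mock)
  p_hat <- mean(lab$label == "inside")
  expect_lt(abs(p_hat - afrac), 3 * sqrt(afrac * (1 - afrac) / 4000))
})

test_that("boundary-crossing events are counted and symmetric for free diffusion", {
  # alternating in/out trajectory: n jumps split between entering/exiting
  nuc <- big_square()
  comp <- polygon_region(cbind(c(0, 5, 5, 0), c(0, 0, 10, 10)))
  ann <- cell_annotation("c1", nuc, compartments_before = list(comp))
  xs <- rep(c(4.5, 5.5), 4)  # in, out, in, out ...
  trajs <- traj_fixture(list(cbind(0:7, xs, rep(5, 8))))
  lab <- assign_compartments(trajs, ann)
  bc <- boundary_crossing_jumps(lab)
  expect_equal(length(bc$entering) + length(bc$exiting), 7)
  expect_equal(abs(length(bc$entering) - length(bc$exiting)), 1)
  # all-inside trajectories give empty CDFs with a warning
  inside_only <- traj_fixture(list(cbind(0:3, rep(2, 4), rep(5, 4))))
  lab2 <- assign_compartments(inside_only, ann)
  expect_warning(bc2 <- boundary_crossing_jumps(lab2), "no boundary")
  expect_length(bc2$entering, 0)
  # free diffusion across a straight boundary: entering and exiting
  # jump CDFs are statistically indistinguishable
  # no axial loss, long tracks: plenty of crossings of the straight
  # compartment boundary at x = 5
  sim <- simulate_spaspt(spaspt_config(
    n_trajectories = 1500, F_bound = 0, D_free = 2, dZ = 100,
    n_frames = 20,
    nucleus = polygon_region(cbind(c(0.5, 9.5, 9.5, 0.5),
                                   c(0.5, 0.5, 9.5, 9.5)))), seed = 8)
  lab3 <- assign_compartments(sim$trajectories, ann)
  bc3 <- boundary_crossing_jumps(lab3)
  expect_gt(length(bc3$entering), 100)
  ks <- suppressWarnings(stats::ks.test(bc3$entering, bc3$exiting))
  expect_gt(ks$p.value, 0.01)
})
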