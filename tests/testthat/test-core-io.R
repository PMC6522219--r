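test_that("localization reading converts pixels to micrometres linearly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,frame,cell_id", "10,20,0,c1", "11,21,1,c1",
               "12,22,2,c2"), f)
  locs <- read_localizations(f, pixel_size = 0.160)
  expect_s3_class(locs, "localizations")
  expect_equal(nrow(locs), 3)
  expect_equal(locs$x, c(10, 11, 12) * 0.160)
  # doubling the pixel size doubles all coordinates
  locs2 <- read_localizations(f, pixel_size = 0.320)
  expect_equal(locs2$x, 2 * locs$x)
  expect_equal(locs2$y, 2 * locs$y)
})

test_that("localization reading flags bad rows and missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,frame,cell_id", "1,2,-1,c1"), f)
  expect_error(read_localizations(f, pixel_size = 0.1), "row 1")
  writeLines(c("x,y,cell_id", "1,2,c1"), f)
  expect_error(read_localizations(f, pixel_size = 0.1), "frame")
  writeLines("x,y,frame,cell_id", f)
  expect_equal(nrow(read_localizations(f, pixel_size = 0.1)), 0)
  writeLines(c("x,y,frame,cell_id", "1,oops,0,c1"), f)
  expect_error(read_localizations(f, pixel_size = 0.1), "non-numeric")
  expect_error(read_localizations(f), "pixel_size")
})

test_that("trajectory write/read round-trips, including gaps", {
  sim <- simulate_spaspt(spaspt_config(n_trajectories = 10), seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(sim$trajectories, f)
  back <- read_trajectories(f, max_gap = 0)
  expect_equal(back$frame, sim$trajectories$frame)
  expect_equal(back$traj_id, sim$trajectories$traj_id)
  expect_lt(max(abs(back$x - sim$trajectories$x)), 1e-9)
  expect_lt(max(abs(back$y - sim$trajectories$y)), 1e-9)
  # a trajectory with a one-frame gap survives the round trip
  gappy <- trajectories(data.frame(traj_id = "g", cell_id = "c",
                                   frame = c(0, 2, 3),
                                   x = c(0, 0.1, 0.2), y = c(0, 0, 0)),
                        max_gap = 1)
  write_trajectories(gappy, f)
  expect_equal(read_trajectories(f)$frame, c(0L, 2L, 3L))
  # empty collection -> header-only file, read back empty
  write_trajectories(gappy[0, ], f)
  expect_equal(nrow(read_trajectories(f)), 0)
})

test_that("trajectory validation enforces frame ordering and gaps", {
  expect_error(trajectories(data.frame(traj_id = "a", cell_id = "c",
                                       frame = c(0, 0), x = 1:2, y = 1:2)),
               "strictly increase")
  expect_error(trajectories(data.frame(traj_id = "a", cell_id = "c",
                                       frame = c(0, 3), x = 1:2, y = 1:2),
                            max_gap = 1), "gap")
  expect_silent(trajectories(data.frame(traj_id = "a", cell_id = "c",
                                        frame = c(0, 3), x = 1:2, y = 1:2),
                             max_gap = Inf))
})

test_that("annotation JSON round-trips and validates vertex pairing", {
  nuc <- disc_region(5, 5, 4, 16)
  comp <- disc_region(6, 5, 1, 12)
  anns <- list(cell_annotation("c1", nuc,
                               nucleus_after = translate_region(nuc, 1, 0),
                               compartments_before = list(comp),
                               compartments_after =
                                 list(translate_region(comp, 1, 0)),
                               n_frames = 100),
               cell_annotation("c2", nuc, nucleoli = list(comp)))
  f <- withr::local_tempfile(fileext = ".json")
  write_annotations(anns, f)
  back <- read_annotations(f)
  expect_length(back, 2)
  expect_equal(names(back), c("c1", "c2"))
  expect_equal(unclass(back$c1$nucleus_before), unclass(nuc),
               ignore_attr = TRUE)
  expect_length(back$c1$compartments_before, 1)
  expect_equal(back$c1$n_frames, 100L)
  expect_length(back$c2$nucleoli, 1)
  # before/after vertex-count mismatch is a validation error
  sq4 <- unit_square()
  sq5 <- polygon_region(cbind(c(0, 0.5, 1, 1, 0), c(0, 0, 0, 1, 1)))
  expect_error(cell_annotation("bad", nuc,
                               compartments_before = list(sq4),
                               compartments_after = list(sq5)),
               "vertex counts differ")
})

test_that("labelled mask TIFFs are traced into polygons", {
  skip_if_not_installed("tiff")
  img <- matrix(0L, 40, 40)
  img[5:35, 5:35] <- 1L   # nucleus block
  img[10:20, 12:22] <- 2L # one compartment
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(img / 65535, f, bits.per.sample = 16)
  px <- 0.1
  masks <- read_mask_tiff(f, pixel_size = px)
  expect_s3_class(masks$nucleus, "polygon_region")
  expect_length(masks$compartments, 1)
  # the compartment polygon must contain its own pixel centres and
  # exclude far-away ones (x = col, y = row, 0-based centres)
  expect_true(in_region(16 * px, 14 * px, masks$compartments[[1]]))
  expect_false(in_region(30 * px, 30 * px, masks$compartments[[1]]))
  expect_true(in_region(30 * px, 30 * px, masks$nucleus))
  # areas close to the pixel counts
  expect_equal(region_area(masks$compartments[[1]]),
               11 * 11 * px^2, tolerance = 0.15)
})

test_that("disorder score files read into validated profiles", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# IUPred-style output", paste(1:5, c(0.1, 0.9, 0.8, 0.2, 0.55),
                                              sep = "\t")), f)
  prof <- read_disorder_scores(f, "ICP4")
  expect_equal(prof$length, 5)
  expect_equal(prof$scores[2], 0.9)
  expect_error(disorder_profile("x", c(0.5, 1.2)), "\\[0, 1\\]")
})
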