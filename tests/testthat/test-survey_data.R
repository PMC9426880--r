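test_that("observation CSV round-trips through the canonical dialect", {
  obs <- make_obs(distances = c(10, 200, 414))
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(obs, path)
  back <- read_observations(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$perp_distance, c(10, 200, 414))
  expect_s3_class(back$canopy, "factor")
  expect_equal(levels(back$canopy), c("hardwood", "mixed", "open"))
  # full round trip: identical numeric content
  expect_equal(back$group_size, obs$group_size)
  expect_equal(back$along_track, obs$along_track)
})

test_that("schema mapping reads foreign dialects and errors name columns", {
  obs <- make_obs()
  names(obs)[names(obs) == "perp_distance"] <- "distance"
  names(obs)[names(obs) == "group_size"] <- "size"
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(obs, path)
  back <- read_observations(path, obs_schema(perp_distance = "distance",
                                             group_size = "size"))
  expect_equal(back$perp_distance, c(10, 200, 414))
  # file lacking a distance column under the default schema
  expect_error(read_observations(path), "perp_distance")
  # non-numeric distance reports the row index
  obs2 <- make_obs()
  obs2$perp_distance <- c("10", "oops", "414")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_table(obs2, path2)
  expect_error(read_observations(path2), "row")
  # unknown canopy level
  obs3 <- make_obs(canopy = c("hardwood", "pine", "open"))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_table(obs3, path3)
  expect_error(read_observations(path3), "pine")
})

test_that("synthetic survey tables survive a write/read round trip", {
  sim <- simulate_survey_data(small_scenario(), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(sim$survey$obs, path)
  back <- read_observations(path)
  expect_equal(nrow(back), nrow(sim$survey$obs))
  expect_equal(back$perp_distance, sim$survey$obs$perp_distance)
  expect_equal(as.character(back$canopy), sim$survey$obs$canopy)
  expect_equal(back$segment_id, sim$survey$obs$segment_id)
})

test_that("truncation keeps x <= w inclusively, preserves order, reports counts", {
  obs <- make_obs(distances = c(100, 350, 351))
  out <- truncate_observations(obs, 350)
  expect_equal(nrow(out), 2L)
  expect_equal(out$perp_distance, c(100, 350))
  expect_equal(attr(out, "n_in"), 3L)
  expect_equal(attr(out, "n_kept"), 2L)
  # w = Inf leaves input unchanged
  expect_equal(truncate_observations(obs, Inf)$perp_distance,
               obs$perp_distance)
  expect_error(truncate_observations(obs, 0), "> 0")
  expect_error(truncate_observations(obs, -5), "> 0")
})

test_that("truncation is idempotent: w then w' >= w equals single truncation at w", {
  set.seed(11)
  for (rep in 1:10) {
    obs <- make_obs(distances = runif(40, 0, 600),
                    along = runif(40, 0, 10000))
    w <- runif(1, 100, 400)
    w2 <- w + runif(1, 0, 300)
    once <- truncate_observations(obs, w)
    twice <- truncate_observations(truncate_observations(obs, w2), w)
    expect_equal(once$perp_distance, twice$perp_distance)
  }
})

test_that("segmentize cuts 10-km transects into four 2.5-km segments", {
  segs <- segmentize(make_transects(1), survey_design())
  expect_equal(nrow(segs), 4L)
  expect_equal(segs$length, rep(2500, 4))
  expect_equal(sum(segs$length), 10000)
  expect_equal(segs$x, c(1.25, 3.75, 6.25, 8.75))
  expect_equal(segs$y, rep(0.5, 4))
  expect_error(segmentize(data.frame(transect_id = "t", unit_id = "u",
                                     length = 0, x0 = 0, y0 = 0,
                                     x1 = 0, y1 = 0)),
               "length")
})

test_that("80 units x 3 transects x 4 segments gives 960 segments with exact effort", {
  tr <- do.call(rbind, lapply(1:80, function(u) {
    t <- make_transects(3, unit = paste0("u", u))
    t$transect_id <- paste0("u", u, "-", t$transect_id)
    t
  }))
  segs <- segmentize(tr, survey_design())
  expect_equal(nrow(segs), 960L)
  # effort conserved per transect and overall
  per_tr <- tapply(segs$length, segs$transect_id, sum)
  expect_true(all(per_tr == 10000))
  expect_equal(sum(segs$length), sum(tr$length))
})

test_that("segment assignment uses left-closed right-open bins, last closed", {
  segs <- segmentize(make_transects(1), survey_design())
  obs <- make_obs(distances = c(10, 10, 10, 10),
                  along = c(2499, 2500, 10000, 0))
  out <- assign_to_segments(obs, segs)
  expect_equal(out$segment_id, c("t1-1", "t1-2", "t1-4", "t1-1"))
  # empty observation set passes through
  empty <- assign_to_segments(make_obs()[0, ], segs)
  expect_equal(nrow(empty), 0L)
  # outside the transect extent errors with the ids
  bad <- make_obs(distances = 10, along = 10001)
  expect_error(assign_to_segments(bad, segs), "outside")
})

test_that("assignment partitions simulated detections across segments", {
  sim <- simulate_survey_data(small_scenario(), seed = 3)
  obs <- sim$survey$obs
  segs <- sim$survey$segments
  counts <- table(factor(obs$segment_id, levels = segs$segment_id))
  expect_equal(sum(counts), nrow(obs))
  expect_true(all(obs$segment_id %in% segs$segment_id))
})

test_that("effort area is 2wL in km^2", {
  segs <- segmentize(make_transects(1), survey_design())
  expect_equal(segment_effort_area(segs, 350), rep(2 * 0.35 * 2.5, 4))
  expect_error(segment_effort_area(segs, 0), "> 0")
})
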