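test_that("identical seeds give identical tables; different seeds differ", {
  sc <- small_scenario()
  a <- simulate_survey_data(sc, seed = 10)
  b <- simulate_survey_data(sc, seed = 10)
  expect_identical(a$grid, b$grid)
  expect_identical(a$groups, b$groups)
  expect_identical(a$survey$obs, b$survey$obs)
  expect_identical(a$survey$segments, b$survey$segments)
  c <- simulate_survey_data(sc, seed = 11)
  expect_false(identical(a$survey$obs, c$survey$obs))
})

test_that("zero field variance gives a constant covariate", {
  sc <- small_scenario(elevation_sd = 0)
  g <- simulate_landscape(sc, seed = 2)
  expect_equal(diff(range(g$elevation)), 0)
})

test_that("distance fields vanish at feature cells and are true distances", {
  sc <- small_scenario()
  g <- simulate_landscape(sc, seed = 4)
  feats <- attr(g, "features")
  expect_true(length(feats) >= 7)
  for (feat in names(feats)) {
    col <- g[[paste0("dist_", feat)]]
    expect_true(all(col >= 0))
    # the cell containing each (snapped) feature point has distance 0
    for (k in seq_len(nrow(feats[[feat]]))) {
      i <- which(g$x == feats[[feat]]$x[k] & g$y == feats[[feat]]$y[k])
      expect_equal(col[i], 0)
    }
    # brute-force oracle on a few random cells
    idx <- sample(nrow(g), 5)
    for (i in idx) {
      oracle <- 1000 * sqrt(min((g$x[i] - feats[[feat]]$x)^2 +
                                  (g$y[i] - feats[[feat]]$y)^2))
      expect_equal(col[i], oracle, tolerance = 1e-9)
    }
  }
})

test_that("smooth fields have the configured correlation length", {
  sc <- survey_scenario(n_units_x = 12, n_units_y = 12, n_surveyed = 10,
                        cor_length_km = 12, elevation_sd = 300)
  est <- vapply(1:10, function(s) {
    g <- simulate_landscape(sc, seed = s)
    nx <- sc$Lx / sc$res_km
    f <- matrix(g$elevation, nrow = nx)
    # binned correlation along x; first crossing of 1/e
    r <- vapply(1:25, function(d) {
      cor(as.vector(f[1:(nx - d), ]), as.vector(f[(1 + d):nx, ]))
    }, numeric(1))
    which(r < exp(-1))[1]
  }, numeric(1))
  expect_equal(mean(est), sc$cor_length_km, tolerance = 0.25)
})

test_that("population process has the configured mean structure", {
  sc <- small_scenario()
  g <- simulate_landscape(sc, seed = 3)
  pop <- simulate_population(sc, g, seed = 5)
  truth <- attr(pop, "truth")
  # intensity integral equals the configured expectation exactly
  expect_equal(sum(truth$lambda_groups) * sc$group_size_mean,
               sc$expected_N, tolerance = 1e-9)
  expect_equal(sum(truth$density * g$area), sc$expected_N,
               tolerance = 1e-9)
  expect_true(all(pop$size >= 1))
  # zero intensity gives zero groups
  sc0 <- sc; sc0$expected_N <- 0
  pop0 <- simulate_population(sc0, g, seed = 5)
  expect_equal(nrow(pop0), 0L)
})

test_that("group counts are Poisson with the configured mean", {
  sc <- small_scenario(expected_N = 320)  # 100 expected groups
  g <- simulate_landscape(sc, seed = 6)
  counts <- vapply(1:400, function(s)
    nrow(simulate_population(sc, g, seed = s)), numeric(1))
  m <- sc$expected_N / sc$group_size_mean
  # z-test on the mean of 400 Poisson(100) draws
  z <- (mean(counts) - m) / sqrt(m / length(counts))
  expect_lt(abs(z), 2.6)
  # Poisson dispersion: var/mean near 1
  expect_gt(var(counts) / mean(counts), 0.75)
  expect_lt(var(counts) / mean(counts), 1.3)
})

test_that("group sizes follow the shifted NB law with mean 3.2", {
  sc <- small_scenario(expected_N = 32000)  # ~1e4 groups
  g <- simulate_landscape(sc, seed = 7)
  pop <- simulate_population(sc, g, seed = 8)
  expect_gt(nrow(pop), 8000)
  expect_equal(mean(pop$size), 3.2, tolerance = 0.1)   # within 10% spec
  expect_equal(sd(pop$size), 2.89, tolerance = 0.15)
  expect_true(all(pop$size >= 1))
})

test_that("census detection records every in-strip group within w", {
  sc <- small_scenario()
  sc$detection$sigma[] <- 1e9   # g ~ 1 everywhere
  sim <- simulate_survey_data(sc, seed = 9)
  obs <- sim$survey$obs
  w_km <- sc$design$truncation / 1000
  expect_true(all(obs$perp_distance <= sc$design$truncation))
  # count groups inside surveyed strips directly
  tr <- sim$survey$transects
  n_in <- 0
  for (t in seq_len(nrow(tr))) {
    n_in <- n_in + sum(sim$groups$x >= tr$x0[t] & sim$groups$x <= tr$x1[t] &
                         abs(sim$groups$y - tr$y0[t]) <= w_km)
  }
  expect_equal(nrow(obs), n_in)
})

test_that("observed detection frequency tracks the detection function", {
  sc <- survey_scenario(n_units_x = 10, n_units_y = 10, n_surveyed = 60,
                        expected_N = 30000)  # dense: many strip groups
  sim <- simulate_survey_data(sc, seed = 13)
  obs <- sim$survey$obs
  tr <- sim$survey$transects
  w_km <- sc$design$truncation / 1000
  # all in-strip groups with their true distances and canopy
  strip <- do.call(rbind, lapply(seq_len(nrow(tr)), function(t) {
    inx <- sim$groups$x >= tr$x0[t] & sim$groups$x <= tr$x1[t] &
      abs(sim$groups$y - tr$y0[t]) <= w_km
    data.frame(d = abs(sim$groups$y[inx] - tr$y0[t]) * 1000,
               canopy = sim$groups$canopy[inx])
  }))
  breaks <- seq(0, 350, by = 50)
  det_n <- table(cut(obs$perp_distance, breaks))
  all_n <- table(cut(strip$d, breaks))
  phat <- as.numeric(det_n) / as.numeric(all_n)
  # binomial check against the canopy-averaged detection curve
  mids <- breaks[-1] - 25
  for (k in seq_along(mids)) {
    p_true <- mean(key_g(mids[k] + numeric(nrow(strip)),
                         sc$detection$sigma[strip$canopy],
                         sc$detection$key, sc$detection$shape))
    se <- sqrt(p_true * (1 - p_true) / as.numeric(all_n)[k])
    expect_lt(abs(phat[k] - p_true), 4 * se + 0.06)
  }
})

test_that("doubling the intensity doubles mean detections", {
  sc1 <- small_scenario(expected_N = 400)
  sc2 <- small_scenario(expected_N = 800)
  n1 <- vapply(1:25, function(s)
    nrow(simulate_survey_data(sc1, seed = s)$survey$obs), numeric(1))
  n2 <- vapply(1:25, function(s)
    nrow(simulate_survey_data(sc2, seed = s)$survey$obs), numeric(1))
  expect_equal(mean(n2) / mean(n1), 2, tolerance = 0.25)
})

test_that("scenario round-trips through its JSON config", {
  skip_if_not_installed("jsonlite")
  sc <- small_scenario(expected_N = 555)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back[order(names(back))], sc[order(names(sc))],
               tolerance = 1e-12)
  # identical downstream behaviour
  expect_identical(simulate_landscape(sc, 3), simulate_landscape(back, 3))
})

test_that("the registered default scenario matches the survey's scale", {
  sc <- paper_like_scenario()
  expect_equal(sc$n_units, 784)
  expect_equal(sc$n_surveyed, 80)
  expect_equal(sc$design$truncation, 350)
  expect_equal(sc$area_km2, 23520)
  # expected N near 16,000 (integral check is exact by construction)
  expect_equal(sc$expected_N, 0.68 * 23520, tolerance = 1e-12)
  expect_lt(abs(sc$expected_N - 16000) / 16000, 0.05)
  expect_equal(sc$group_size_mean, 3.2)
})
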