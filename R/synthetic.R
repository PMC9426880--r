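## Synthetic aerial surveys with known truth. The generator emulates the
## statistical structure of a winter helicopter survey of deer groups:
## spatially autocorrelated landscape covariates, an inhomogeneous Poisson
## group process with log-linear intensity, shifted negative-binomial group
## sizes, strip transects in rectangular survey units, and
## distance-dependent detection with canopy-class scale effects.

#' Define a simulation scenario
#'
#' Defaults describe the full "paper-like" world (see
#' [paper_like_scenario()]); pass smaller unit grids for desk-scale runs.
#' Expected abundance defaults to `target_density` times the landscape
#' area, keeping density comparable across scales.
#'
#' @param n_units_x,n_units_y survey-unit grid dimensions (units are
#'   `unit_length_km` x `unit_width_km`, long axis along x).
#' @param n_surveyed units actually flown (simple random sample).
#' @param design a [survey_design()].
#' @param res_km landscape grid resolution.
#' @param cor_length_km correlation length (1/e distance) of the smooth
#'   random fields.
#' @param target_density expected individuals per km^2 over the landscape.
#' @param expected_N expected total abundance; overrides `target_density`.
#' @param group_size_mu,group_size_k shifted negative-binomial group-size
#'   law `size = 1 + NB(mu, k)`: mean `1 + mu` (default 3.2), and with
#'   `k = 0.787` an SD near 2.9.
#' @param density_beta named log-linear coefficients on *standardized*
#'   landscape covariates driving group intensity.
#' @param detection list: `key`, `shape`, named `sigma` per canopy class
#'   (m). Defaults give survey-wide average detection probability near
#'   0.6 at w = 350 m.
#' @param canopy_probs cover-class areal fractions (hardwood, mixed,
#'   open).
#' @param feature_rate feature points per 1000 km^2 for each
#'   distance-to-cover covariate.
#' @return object of class `dsurf_scenario`.
#' @export
survey_scenario <- function(n_units_x = 28, n_units_y = 28,
                            n_surveyed = 80,
                            design = survey_design(),
                            res_km = 1, cor_length_km = 12,
                            elevation_sd = 300, snow_sd = 25,
                            target_density = 0.68, expected_N = NULL,
                            group_size_mu = 2.2, group_size_k = 0.787,
                            density_beta = c(elevation = -0.6,
                                             snow_days = -0.5,
                                             dist_agriculture = -0.3,
                                             dist_developed = -0.4,
                                             dist_timber = -0.4),
                            detection = list(key = "hazard_rate",
                                             shape = 2.5,
                                             sigma = c(hardwood = 140,
                                                       mixed = 160,
                                                       open = 200)),
                            canopy_probs = c(hardwood = 0.45, mixed = 0.35,
                                             open = 0.20),
                            feature_rate = c(agriculture = 1.1,
                                             developed = 1.3,
                                             forest = 2.5, shrub = 1.7,
                                             timber = 2.1, wetland = 1.7,
                                             water = 1.5)) {
  n_units <- n_units_x * n_units_y
  if (n_surveyed > n_units) stop("cannot survey more units than exist",
                                 call. = FALSE)
  Lx <- n_units_x * design$unit_length_km
  Ly <- n_units_y * design$unit_width_km
  area <- Lx * Ly
  if (is.null(expected_N)) expected_N <- target_density * area
  if (expected_N <= 0) stop("expected abundance must be > 0", call. = FALSE)
  structure(list(
    n_units_x = n_units_x, n_units_y = n_units_y, n_units = n_units,
    n_surveyed = n_surveyed, design = design,
    res_km = res_km, cor_length_km = cor_length_km,
    elevation_sd = elevation_sd, snow_sd = snow_sd,
    Lx = Lx, Ly = Ly, area_km2 = area,
    expected_N = expected_N,
    group_size_mu = group_size_mu, group_size_k = group_size_k,
    group_size_mean = 1 + group_size_mu,
    density_beta = density_beta, detection = detection,
    canopy_probs = canopy_probs, feature_rate = feature_rate
  ), class = "dsurf_scenario")
}

#' The registered full-scale default scenario
#'
#' 784 candidate 10 x 3 km units (28 x 28), 80 surveyed, truncation
#' 350 m, group-size mean 3.2, average detection probability near 0.6,
#' expected abundance near 16,000 over roughly 24,000 km^2.
#'
#' @param ... overrides forwarded to [survey_scenario()].
#' @export
paper_like_scenario <- function(...) survey_scenario(...)

#' @export
print.dsurf_scenario <- function(x, ...) {
  cat(sprintf(
    "Simulation scenario: %d x %d units (%d surveyed of %d), %g x %g km landscape\n",
    x$n_units_x, x$n_units_y, x$n_surveyed, x$n_units, x$Lx, x$Ly))
  cat(sprintf("  expected N = %.0f individuals (%.2f /km^2), group-size mean %.2f\n",
              x$expected_N, x$expected_N / x$area_km2, x$group_size_mean))
  cat(sprintf("  detection: %s key, b = %g, sigma = (%s) m, w = %g m\n",
              x$detection$key, x$detection$shape,
              paste(x$detection$sigma, collapse = ", "),
              x$design$truncation))
  invisible(x)
}

# Gaussian-kernel row smoother; row-normalized so the marginal variance is
# one everywhere and correlation ~ exp(-d^2 / (4 h^2)) along an axis, i.e.
# 1/e correlation length 2h.
.smoother_matrix <- function(n, h) {
  if (h <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  W <- exp(-d^2 / (2 * h^2))
  W[d > 4 * h] <- 0
  W / sqrt(rowSums(W^2))
}

.smooth_field <- function(nx, ny, h_cells) {
  M <- matrix(rnorm(nx * ny), nx, ny)
  if (h_cells <= 0) return(M)
  Wx <- .smoother_matrix(nx, h_cells)
  Wy <- .smoother_matrix(ny, h_cells)
  Wx %*% M %*% t(Wy)
}

#' Simulate the landscape covariate grid
#'
#' Smooth random fields (elevation, snow days, plus the cover field that
#' classifies canopy) with configured correlation length, and
#' distance-to-feature covariates as exact planar distances to seeded
#' feature points snapped to cell centres. Deterministic per seed.
#'
#' @param scenario a `dsurf_scenario`.
#' @param seed integer seed.
#' @return grid data.frame: `cell_id`, `x`, `y` (km, cell centres),
#'   `area`, landscape covariates, `canopy`.
#' @export
simulate_landscape <- function(scenario, seed = 1) {
  res <- scenario$res_km
  nx <- round(scenario$Lx / res)
  ny <- round(scenario$Ly / res)
  if (nx <= 0 || ny <= 0) stop("non-positive grid dimensions",
                               call. = FALSE)
  set.seed(seed)
  h <- scenario$cor_length_km / (2 * res)
  f_elev <- .smooth_field(nx, ny, h)
  f_ind <- .smooth_field(nx, ny, h)
  f_cover <- .smooth_field(nx, ny, h)
  xs <- (seq_len(nx) - 0.5) * res
  ys <- (seq_len(ny) - 0.5) * res
  cx <- rep(xs, times = ny)
  cy <- rep(ys, each = nx)
  elev_f <- as.vector(f_elev)
  # snow days track elevation (corr 0.6) with independent local weather
  snow_f <- 0.6 * elev_f + 0.8 * as.vector(f_ind)
  grid <- data.frame(
    cell_id = seq_len(nx * ny), x = cx, y = cy, area = res^2,
    elevation = pmax(500 + scenario$elevation_sd * elev_f, 30),
    snow_days = pmin(pmax(60 + scenario$snow_sd * snow_f, 0), 150)
  )
  # distance-to-cover fields from seeded feature points (snapped to cells)
  features <- list()
  for (feat in names(scenario$feature_rate)) {
    n_pts <- max(3L, round(scenario$feature_rate[[feat]] *
                             scenario$area_km2 / 1000))
    px <- xs[sample.int(nx, n_pts, replace = TRUE)]
    py <- ys[sample.int(ny, n_pts, replace = TRUE)]
    features[[feat]] <- data.frame(x = px, y = py)
    d2 <- outer(cx, px, `-`)^2 + outer(cy, py, `-`)^2
    grid[[paste0("dist_", feat)]] <- 1000 * sqrt(apply(d2, 1, min))
  }
  cv <- as.vector(f_cover)
  q <- quantile(cv, cumsum(scenario$canopy_probs))
  grid$canopy <- ifelse(cv <= q[1], "hardwood",
                        ifelse(cv <= q[2], "mixed", "open"))
  attr(grid, "features") <- features
  grid
}

#' Serialize / restore a scenario as a plain-text JSON config
#'
#' @param scenario a `dsurf_scenario`.
#' @param path file path for the JSON config.
#' @return `read_scenario` returns the reconstructed `dsurf_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("scenario serialization requires the jsonlite package",
         call. = FALSE)
  }
  cfg <- list(
    n_units_x = scenario$n_units_x, n_units_y = scenario$n_units_y,
    n_surveyed = scenario$n_surveyed,
    truncation = scenario$design$truncation,
    res_km = scenario$res_km, cor_length_km = scenario$cor_length_km,
    elevation_sd = scenario$elevation_sd, snow_sd = scenario$snow_sd,
    expected_N = scenario$expected_N,
    group_size_mu = scenario$group_size_mu,
    group_size_k = scenario$group_size_k,
    density_beta = as.list(scenario$density_beta),
    detection = list(key = scenario$detection$key,
                     shape = scenario$detection$shape,
                     sigma = as.list(scenario$detection$sigma)),
    canopy_probs = as.list(scenario$canopy_probs),
    feature_rate = as.list(scenario$feature_rate)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("scenario serialization requires the jsonlite package",
         call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  survey_scenario(
    n_units_x = cfg$n_units_x, n_units_y = cfg$n_units_y,
    n_surveyed = cfg$n_surveyed,
    design = survey_design(truncation = cfg$truncation),
    res_km = cfg$res_km, cor_length_km = cfg$cor_length_km,
    elevation_sd = cfg$elevation_sd, snow_sd = cfg$snow_sd,
    expected_N = cfg$expected_N,
    group_size_mu = cfg$group_size_mu, group_size_k = cfg$group_size_k,
    density_beta = unlist(cfg$density_beta),
    detection = list(key = cfg$detection$key, shape = cfg$detection$shape,
                     sigma = unlist(cfg$detection$sigma)),
    canopy_probs = unlist(cfg$canopy_probs),
    feature_rate = unlist(cfg$feature_rate)
  )
}

#' Simulate the group point process
#'
#' Group intensity is log-linear in the standardized landscape covariates
#' (`density_beta`), normalized so its integral equals the expected group
#' count `expected_N / group_size_mean`. The realized count is Poisson;
#' locations are drawn cell-proportional to intensity, uniform within a
#' cell; sizes are `1 + NB(mu, k)`.
#'
#' @param scenario a `dsurf_scenario`.
#' @param grid output of [simulate_landscape()].
#' @param seed integer seed.
#' @return data.frame of groups (`group_id`, `x`, `y`, `size`,
#'   `cell_id`, `canopy`) with attribute `truth`: per-cell expected group
#'   intensity and individual density, expected and realized totals.
#' @export
simulate_population <- function(scenario, grid, seed = 1) {
  set.seed(seed)
  beta <- scenario$density_beta
  eta <- rep(0, nrow(grid))
  for (v in names(beta)) {
    z <- grid[[v]]
    if (is.null(z)) stop("density_beta names a missing covariate: ", v,
                         call. = FALSE)
    eta <- eta + beta[[v]] * as.vector(scale(z))
  }
  rel <- exp(eta)
  if (any(!is.finite(rel)) || any(rel < 0)) {
    stop("non-finite or negative intensity", call. = FALSE)
  }
  E_groups <- scenario$expected_N / scenario$group_size_mean
  lambda <- rel / sum(rel) * E_groups        # expected groups per cell
  n_groups <- rpois(1, E_groups)
  out <- if (n_groups > 0) {
    cell <- sample.int(nrow(grid), n_groups, replace = TRUE,
                       prob = lambda)
    res <- scenario$res_km
    data.frame(
      group_id = seq_len(n_groups),
      x = grid$x[cell] + runif(n_groups, -res / 2, res / 2),
      y = grid$y[cell] + runif(n_groups, -res / 2, res / 2),
      size = 1L + rnbinom(n_groups, size = scenario$group_size_k,
                          mu = scenario$group_size_mu),
      cell_id = grid$cell_id[cell],
      canopy = grid$canopy[cell],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(group_id = integer(0), x = numeric(0), y = numeric(0),
               size = integer(0), cell_id = integer(0),
               canopy = character(0))
  }
  attr(out, "truth") <- list(
    lambda_groups = lambda,
    density = lambda * scenario$group_size_mean / grid$area,
    expected_N = scenario$expected_N,
    N_true = sum(out$size)
  )
  out
}

# transect layout for a set of surveyed units
.build_transects <- function(scenario, surveyed_units) {
  des <- scenario$design
  ij <- arrayInd(surveyed_units, c(scenario$n_units_x, scenario$n_units_y))
  n_t <- des$n_transects
  rows <- lapply(seq_along(surveyed_units), function(k) {
    i <- ij[k, 1]; j <- ij[k, 2]
    uid <- sprintf("u%04d", surveyed_units[k])
    x0 <- (i - 1) * des$unit_length_km
    y0 <- (j - 1) * des$unit_width_km
    ty <- y0 + (seq_len(n_t) - 0.5) * des$transect_spacing_km
    data.frame(
      transect_id = paste0(uid, "-t", seq_len(n_t)), unit_id = uid,
      length = des$unit_length_km * 1000,
      x0 = x0, y0 = ty, x1 = x0 + des$unit_length_km, y1 = ty,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate the aerial survey of a realized population
#'
#' Samples `n_surveyed` units at random, flies the design's parallel
#' transects, and for every group inside a strip of half-width `w` of a
#' transect records a detection with probability
#' `g(perp distance; sigma(canopy), b)`. Observation and segment tables
#' conform to the canonical dialect; segments carry landscape covariates
#' looked up at their midpoints.
#'
#' @param scenario a `dsurf_scenario`.
#' @param groups output of [simulate_population()].
#' @param grid output of [simulate_landscape()].
#' @param seed integer seed.
#' @return list: `obs` (segment-assigned observation table), `segments`,
#'   `transects`, `surveyed_units`, `effort_km`, `unit_effort_km`.
#' @export
simulate_survey <- function(scenario, groups, grid, seed = 1) {
  set.seed(seed)
  des <- scenario$design
  w_km <- des$truncation / 1000
  surveyed <- sort(sample.int(scenario$n_units, scenario$n_surveyed))
  tr <- .build_transects(scenario, surveyed)

  # per-unit flight conditions (shared by a unit's transects)
  units <- unique(tr$unit_id)
  cond <- data.frame(
    unit_id = units,
    cloud_cover = round(runif(length(units), 0, 100)),
    temperature = round(runif(length(units), -15, 0), 1),
    fatigue_hours = round(runif(length(units), 0, 6), 2)
  )

  obs_list <- list()
  det <- scenario$detection
  for (t in seq_len(nrow(tr))) {
    in_strip <- which(groups$x >= tr$x0[t] & groups$x <= tr$x1[t] &
                        abs(groups$y - tr$y0[t]) <= w_km)
    if (!length(in_strip)) next
    d <- abs(groups$y[in_strip] - tr$y0[t]) * 1000
    sigma <- det$sigma[groups$canopy[in_strip]]
    p <- key_g(d, sigma, det$key, det$shape)
    hit <- runif(length(in_strip)) < p
    if (!any(hit)) next
    g <- groups[in_strip[hit], , drop = FALSE]
    obs_list[[t]] <- data.frame(
      obs_id = g$group_id, unit_id = tr$unit_id[t],
      transect_id = tr$transect_id[t],
      perp_distance = d[hit],
      group_size = g$size, canopy = g$canopy,
      along_track = (g$x - tr$x0[t]) * 1000,
      stringsAsFactors = FALSE
    )
  }
  obs <- if (length(obs_list)) do.call(rbind, obs_list) else
    data.frame(obs_id = integer(0), unit_id = character(0),
               transect_id = character(0), perp_distance = numeric(0),
               group_size = integer(0), canopy = character(0),
               along_track = numeric(0))
  obs <- merge(obs, cond, by = "unit_id", sort = FALSE)
  if (nrow(obs)) {
    obs <- obs[order(obs$transect_id, obs$along_track), , drop = FALSE]
    obs$obs_id <- seq_len(nrow(obs))
    rownames(obs) <- NULL
  }

  segments <- segmentize(tr, des)
  # covariates at segment midpoints: containing-cell lookup
  res <- scenario$res_km
  nx <- round(scenario$Lx / res)
  ci <- pmin(pmax(ceiling(segments$x / res), 1), nx)
  cj <- pmin(pmax(ceiling(segments$y / res),
                  1), round(scenario$Ly / res))
  cell <- (cj - 1) * nx + ci
  for (v in intersect(landscape_covariates(), names(grid))) {
    segments[[v]] <- grid[[v]][cell]
  }
  if (nrow(obs)) obs <- assign_to_segments(obs, segments)
  else obs$segment_id <- character(0)

  list(obs = obs, segments = segments, transects = tr,
       surveyed_units = surveyed,
       effort_km = sum(tr$length) / 1000,
       unit_effort_km = tapply(tr$length / 1000, tr$unit_id, sum))
}

#' Generate a complete synthetic survey with known truth
#'
#' Runs landscape, population and survey generation with named sub-seeds
#' spawned from one master seed, so stages can be re-run independently
#' and identical seeds give identical tables.
#'
#' @param scenario a `dsurf_scenario`.
#' @param seed master integer seed.
#' @return list: `grid`, `groups`, `survey` (obs/segments/...), `truth`
#'   (true N, per-cell density, detection parameters), `scenario`,
#'   `seeds`.
#' @export
simulate_survey_data <- function(scenario, seed = 1) {
  set.seed(seed)
  seeds <- sample.int(2147483646L, 3)
  grid <- simulate_landscape(scenario, seed = seeds[1])
  groups <- simulate_population(scenario, grid, seed = seeds[2])
  survey <- simulate_survey(scenario, groups, grid, seed = seeds[3])
  truth <- attr(groups, "truth")
  truth$detection <- scenario$detection
  truth$truncation <- scenario$design$truncation
  list(grid = grid, groups = groups, survey = survey, truth = truth,
       scenario = scenario,
       seeds = setNames(seeds, c("landscape", "population", "survey")))
}
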