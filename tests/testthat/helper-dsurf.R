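# Shared fixtures, all built in code.

# tiny canonical observation table
make_obs <- function(distances = c(10, 200, 414),
                     sizes = rep(2L, length(distances)),
                     canopy = rep("hardwood", length(distances)),
                     transect = "t1", unit = "u1",
                     along = seq(100, by = 400,
                                 length.out = length(distances))) {
  data.frame(
    obs_id = seq_along(distances), unit_id = unit, transect_id = transect,
    perp_distance = distances, group_size = sizes, canopy = canopy,
    cloud_cover = 50, temperature = -5, fatigue_hours = 1,
    along_track = along, stringsAsFactors = FALSE
  )
}

# one straight transect table in km coordinates
make_transects <- function(n = 1, length_km = 10, unit = "u1") {
  data.frame(
    transect_id = paste0("t", seq_len(n)), unit_id = unit,
    length = length_km * 1000,
    x0 = 0, y0 = seq_len(n) - 0.5, x1 = length_km, y1 = seq_len(n) - 0.5,
    stringsAsFactors = FALSE
  )
}

# small reduced-scale scenario for fast end-to-end runs
small_scenario <- function(n_surveyed = 14, ...) {
  survey_scenario(n_units_x = 6, n_units_y = 6, n_surveyed = n_surveyed,
                  ...)
}

# sample distances from a detection function by rejection (independent of
# the package's likelihood machinery)
sample_distances <- function(n, w, key, sigma, shape = NULL) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, 0, w)
    keep <- runif(2 * n) < key_g(x, sigma, key, shape)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

# an artificial perfect-detection fit (p = 1 everywhere)
perfect_detfit <- function(w = 350) {
  structure(list(
    key = "half_normal", formula = ~1, w = w,
    beta = c(`(Intercept)` = log(1e9)), shape = NULL,
    theta = log(1e9), vcov = NULL, singular_info = TRUE,
    xlevels = NULL
  ), class = "dsurf_detfit")
}
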