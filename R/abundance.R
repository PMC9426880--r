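## Horvitz-Thompson corrected abundance from stage-1 detection fits.
## N_hat over a set of detections = sum(s_i / p_i): each group's size
## weighted by the inverse of its estimated detection probability.

#' Horvitz-Thompson abundance for one observation set
#'
#' @param size group sizes (>= 1).
#' @param p per-observation average detection probabilities in (0, 1\].
#' @return `sum(size / p)`; 0 for an empty set.
#' @export
ht_abundance <- function(size, p) {
  if (length(size) == 0L) return(0)
  if (any(p <= 0) || any(p > 1)) {
    stop("detection probabilities must lie in (0, 1]", call. = FALSE)
  }
  sum(size / p)
}

#' Per-segment Horvitz-Thompson abundance
#'
#' Builds the stage-2 response: for every segment, the HT-corrected number
#' of individuals from its detections, together with effort area
#' `2 w L` (km^2). Segments with no detections get `n_hat = 0`.
#'
#' @param obs truncated observation table with `segment_id` assigned.
#' @param segments segment table.
#' @param fit a `dsurf_detfit` (used via [predict.dsurf_detfit()]); or
#'   pass `p` directly.
#' @param p optional per-observation detection probabilities overriding
#'   `fit`.
#' @param w truncation distance (m); defaults to `fit$w`.
#' @return `segments` with columns `n_hat`, `raw_groups`,
#'   `raw_individuals`, `effort_area` (km^2) appended.
#' @export
ht_segments <- function(obs, segments, fit = NULL, p = NULL, w = NULL) {
  if (is.null(p)) {
    if (is.null(fit)) stop("supply a detection fit or p", call. = FALSE)
    p <- predict(fit, obs)
  }
  if (is.null(w)) {
    if (is.null(fit)) stop("supply w or a fit carrying it", call. = FALSE)
    w <- fit$w
  }
  if (nrow(obs) && (any(p <= 0) || any(p > 1))) {
    stop("detection probabilities must lie in (0, 1]", call. = FALSE)
  }
  sid <- factor(as.character(obs$segment_id),
                levels = as.character(segments$segment_id))
  if (nrow(obs) && anyNA(sid)) {
    stop("observation(s) reference unknown segment ids", call. = FALSE)
  }
  hw <- obs$group_size / p
  out <- segments
  out$n_hat <- as.numeric(tapply(hw, sid, sum, default = 0))
  out$raw_groups <- as.integer(tapply(rep(1L, nrow(obs)), sid, sum,
                                      default = 0L))
  out$raw_individuals <- as.integer(tapply(obs$group_size, sid, sum,
                                           default = 0L))
  out$effort_area <- segment_effort_area(segments, w)
  out
}

#' Conventional distance sampling total abundance
#'
#' Scales the Horvitz-Thompson total over the covered strips to the whole
#' region: `N_hat = A / (2 w L) * sum(s_i / p_i)`. The CV combines the
#' design-based encounter-rate component (survey *unit* as the sampling
#' unit, since transects within a unit are not independent) with the
#' detection-parameter component (delta method through the HT sum), as
#' `CV^2 = CV_er^2 + CV_det^2`.
#'
#' @param obs truncated observation table (needs `unit_id`, `group_size`).
#' @param fit a `dsurf_detfit`.
#' @param effort_km total transect length surveyed (km).
#' @param area_km2 region area A (km^2).
#' @param unit_effort_km named vector of per-unit effort (km); defaults to
#'   equal effort across the units present in `obs` -- supply it when
#'   surveyed units saw zero groups, as those must enter the variance.
#' @return list with `N_hat`, `cv`, `cv_er`, `cv_det`, `ci` (95%
#'   log-normal), `covered_area_km2`, `encounter_rate`.
#' @export
cds_total <- function(obs, fit, effort_km, area_km2,
                      unit_effort_km = NULL) {
  w_km <- fit$w / 1000
  if (effort_km <= 0) stop("effort must be > 0", call. = FALSE)
  covered <- 2 * w_km * effort_km
  if (area_km2 < covered) stop("region area smaller than covered area",
                               call. = FALSE)
  p <- predict(fit, obs)
  ht <- ht_abundance(obs$group_size, p)
  N_hat <- area_km2 / covered * ht

  # encounter-rate variance: ratio estimator over survey units
  if (is.null(unit_effort_km)) {
    units <- unique(as.character(obs$unit_id))
    unit_effort_km <- setNames(rep(effort_km / length(units), length(units)),
                               units)
  }
  nk <- tapply(rep(1L, nrow(obs)), factor(as.character(obs$unit_id),
                                          levels = names(unit_effort_km)),
               sum, default = 0L)
  lk <- unit_effort_km
  Kn <- length(lk)
  er <- nrow(obs) / effort_km
  cv_er <- 0
  if (Kn > 1L && nrow(obs) > 0L) {
    var_er <- Kn / (effort_km^2 * (Kn - 1)) *
      sum(lk^2 * (nk / lk - er)^2)
    cv_er <- sqrt(var_er) / er
  }

  # detection component: delta method on log HT sum through theta
  cv_det <- 0
  if (!fit$singular_info && nrow(obs) > 0L) {
    nb <- length(fit$beta)
    gr <- .num_grad(function(th) {
      b <- th[seq_len(nb)]
      sh <- if (fit$key == "hazard_rate") 1 + exp(th[nb + 1L]) else NULL
      sigma <- detection_scale(b, obs, fit$formula, fit$xlevels)
      # names of beta may not match; build sigma directly
      sum(obs$group_size / average_p(sigma, fit$w, fit$key, sh))
    }, fit$theta)
    v <- drop(t(gr) %*% fit$vcov %*% gr)
    cv_det <- sqrt(max(v, 0)) / ht
  }

  cv <- sqrt(cv_er^2 + cv_det^2)
  list(N_hat = N_hat, cv = cv, cv_er = cv_er, cv_det = cv_det,
       ci = lognormal_ci(N_hat, cv),
       covered_area_km2 = covered, encounter_rate = er)
}

#' Log-normal confidence interval for an abundance estimate
#'
#' `C = exp(z * sqrt(log(1 + CV^2)))`; interval `(N/C, N*C)`. The standard
#' asymmetric interval for strictly positive abundance estimates.
#'
#' @param N_hat point estimate (> 0).
#' @param cv coefficient of variation (>= 0).
#' @param level confidence level.
#' @return named vector `c(lo =, hi =)`.
#' @export
lognormal_ci <- function(N_hat, cv, level = 0.95) {
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (N_hat <= 0) stop("N_hat must be > 0", call. = FALSE)
  if (cv == 0) return(c(lo = N_hat, hi = N_hat))
  z <- qnorm(1 - (1 - level) / 2)
  C <- exp(z * sqrt(log(1 + cv^2)))
  c(lo = N_hat / C, hi = N_hat * C)
}

#' Encounter rate (groups per km of effort)
#'
#' @param n_groups number of detected groups.
#' @param effort_km total transect length (km).
#' @return groups/km.
#' @export
encounter_rate <- function(n_groups, effort_km) {
  if (effort_km <= 0) stop("effort must be > 0", call. = FALSE)
  n_groups / effort_km
}
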