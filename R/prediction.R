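## Apply a fitted DSM to a covariate grid: per-cell density, SE and CV
## maps, regional totals with log-normal intervals, threshold-area
## bookkeeping, and rank correlation between two density surfaces.

#' Predict a density surface over a grid
#'
#' Evaluates the fitted model's linear predictor at every grid cell:
#' `density = exp(eta)` (individuals/km^2), `abundance = density * area`.
#' Standard errors come from the coefficient covariance (the propagated
#' covariance when [dsm_varprop()] has been run) pushed through the log
#' link by the delta method; per-cell `cv = se / density` equals the SE of
#' the linear predictor. Cells with missing coordinates or covariates are
#' excluded and counted.
#'
#' @param fit a `dsurf_dsm`.
#' @param grid prediction-grid table: `cell_id`, `x`, `y` (km), `area`
#'   (km^2) and either PC-score columns for the fitted terms or, when
#'   `pca` is supplied, the raw training covariates.
#' @param pca optional `dsurf_pca`; when given, grid rows are scored with
#'   the training standardization constants.
#' @return data.frame of class `dsurf_cells`: `cell_id`, `x`, `y`,
#'   `area`, `density`, `abundance`, `se`, `cv`; attributes `lp` (the
#'   linear-predictor matrix), `V` (coefficient covariance), `n_excluded`,
#'   `cv_p_extra` (delta-fallback detection CV, 0 otherwise).
#' @export
predict_grid <- function(fit, grid, pca = NULL) {
  need_pc <- setdiff(fit$terms, "xy")
  if (!is.null(pca)) {
    S <- pca_scores(pca, grid,
                    n_components = max(pca$n_retained,
                                       length(need_pc)))
    for (cn in colnames(S)) grid[[cn]] <- S[, cn]
  }
  miss_col <- setdiff(need_pc, names(grid))
  if (length(miss_col)) {
    stop("grid lacks model term column(s): ",
         paste(miss_col, collapse = ", "),
         "; supply a PCA model or score the grid first", call. = FALSE)
  }
  use_cols <- c("x", "y", "area", need_pc)
  ok <- rowSums(is.na(grid[, use_cols, drop = FALSE])) == 0
  n_excluded <- sum(!ok)
  g <- grid[ok, , drop = FALSE]
  nd <- g
  nd$effort_area <- 1  # offset placeholder; lpmatrix excludes the offset

  use_prop <- !is.null(fit$varprop) && identical(fit$varprop$method, "refit")
  gobj <- if (use_prop) fit$varprop$gam else fit$gam
  if (use_prop) {
    nd$.dflp <- matrix(rep(fit$varprop$d_bar, each = nrow(nd)),
                       nrow = nrow(nd))
  }
  Xp <- predict(gobj, newdata = nd, type = "lpmatrix")
  beta <- coef(gobj)
  eta <- drop(Xp %*% beta)
  V <- fit$V
  se_eta <- sqrt(pmax(rowSums((Xp %*% V) * Xp), 0))

  cv_extra <- 0
  if (!is.null(fit$varprop) && identical(fit$varprop$method, "delta")) {
    cv_extra <- fit$varprop$cv_p
  }
  cv <- sqrt(se_eta^2 + cv_extra^2)

  density <- exp(eta)
  out <- data.frame(
    cell_id = g$cell_id, x = g$x, y = g$y, area = g$area,
    density = density, abundance = density * g$area,
    se = density * cv, cv = cv,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dsurf_cells", "data.frame")
  attr(out, "lp") <- Xp
  attr(out, "V") <- V
  attr(out, "cv_p_extra") <- cv_extra
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Total abundance and summary of a predicted surface
#'
#' `N_hat = sum(density * area)`. The CV propagates the coefficient
#' covariance through the summed response-scale prediction
#' (`var = u' V u` with `u = X' w`, `w = area * exp(eta)`), adds the
#' delta-fallback detection CV when present, and the CI uses the
#' log-normal form.
#'
#' @param cells output of [predict_grid()].
#' @param threshold density threshold (individuals/km^2) for the
#'   area-fraction summary (inclusive `<=`).
#' @param level confidence level.
#' @return list: `N_hat`, `ci_lo`, `ci_hi`, `cv`, `area_total`,
#'   `n_cells`, `n_excluded`, `pct_area_below_threshold`, `threshold`,
#'   `density_range`, `mean_density`.
#' @export
total_abundance <- function(cells, threshold = 2, level = 0.95) {
  if (nrow(cells) < 1L) stop("no cells", call. = FALSE)
  N_hat <- sum(cells$abundance)
  Xp <- attr(cells, "lp")
  V <- attr(cells, "V")
  cv <- NA_real_
  if (!is.null(Xp) && !is.null(V)) {
    w <- cells$abundance
    u <- drop(crossprod(Xp, w))
    var_tot <- drop(t(u) %*% V %*% u)
    cv <- sqrt(max(var_tot, 0)) / N_hat
    extra <- attr(cells, "cv_p_extra")
    if (!is.null(extra) && extra > 0) cv <- sqrt(cv^2 + extra^2)
  }
  ci <- if (is.finite(cv)) lognormal_ci(N_hat, cv, level)
        else c(lo = NA_real_, hi = NA_real_)
  list(
    N_hat = N_hat, ci_lo = unname(ci["lo"]), ci_hi = unname(ci["hi"]),
    cv = cv, area_total = sum(cells$area), n_cells = nrow(cells),
    n_excluded = attr(cells, "n_excluded") %||% 0L,
    pct_area_below_threshold = area_fraction_below(cells, threshold),
    threshold = threshold,
    density_range = range(cells$density),
    mean_density = N_hat / sum(cells$area)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent of area at or below a density threshold
#'
#' @param cells table with `density` and `area` columns.
#' @param threshold density threshold (inclusive `<=`).
#' @return percent in \[0, 100\].
#' @export
area_fraction_below <- function(cells, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  100 * sum(cells$area[cells$density <= threshold]) / sum(cells$area)
}

#' Spearman rank correlation between two density surfaces
#'
#' Pairs the surfaces on shared `cell_id`s and computes Spearman's rho
#' with midrank ties.
#'
#' @param surface_a,surface_b tables with `cell_id` and `density`.
#' @return rho in \[-1, 1\].
#' @export
spearman_surfaces <- function(surface_a, surface_b) {
  shared <- intersect(surface_a$cell_id, surface_b$cell_id)
  if (length(shared) < 3L) stop("need at least 3 shared cells",
                                call. = FALSE)
  a <- surface_a$density[match(shared, surface_a$cell_id)]
  b <- surface_b$density[match(shared, surface_b$cell_id)]
  cor(a, b, method = "spearman")
}

#' Back-calculate pre-season abundance from a harvest total
#'
#' A winter (post-season) abundance estimate plus the reported harvest
#' gives a simple pre-season reconstruction:
#' `preseason = winter + harvest`, density `preseason / area`, and the
#' fraction of the pre-season population removed by harvest.
#'
#' @param winter_N post-season abundance estimate.
#' @param harvest_N animals harvested.
#' @param area_km2 region area.
#' @return list: `preseason_N`, `preseason_density`, `harvest_fraction`.
#' @export
preseason_backcalc <- function(winter_N, harvest_N, area_km2) {
  if (area_km2 <= 0) stop("area must be > 0", call. = FALSE)
  if (winter_N < 0 || harvest_N < 0) stop("inputs must be >= 0",
                                          call. = FALSE)
  pre <- winter_N + harvest_N
  list(preseason_N = pre,
       preseason_density = pre / area_km2,
       harvest_fraction = if (pre > 0) harvest_N / pre else 0)
}
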