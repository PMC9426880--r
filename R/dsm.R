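## Stage 2: density surface model. A Tweedie GAM of Horvitz-Thompson
## corrected segment abundance on a bivariate thin-plate smooth of planar
## coordinates and univariate smooths of PC scores, with log effort-area
## offset. Smoothing parameters by REML; shrinkage ("ts") bases penalize
## the null space so uninformative terms can shrink out. Backed by mgcv.

.dsm_formula <- function(terms, k_xy, k_pc) {
  rhs <- character(0)
  if ("xy" %in% terms) {
    rhs <- c(rhs, sprintf("s(x, y, bs = 'ts', k = %d)", k_xy))
  }
  for (t in setdiff(terms, "xy")) {
    rhs <- c(rhs, sprintf("s(%s, bs = 'ts', k = %d)", t, k_pc))
  }
  rhs <- c(rhs, "offset(log(effort_area))")
  as.formula(paste("n_hat ~", paste(rhs, collapse = " + ")))
}

#' Fit a Tweedie density surface GAM
#'
#' Response: HT-corrected individuals per segment (`n_hat` from
#' [ht_segments()]); offset `log(effort_area)` so the linear predictor is
#' log density (individuals/km^2). Family `mgcv::tw()` with the Tweedie
#' power estimated alongside the smoothing parameters by REML, restricted
#' to (1, 2). Thin-plate shrinkage bases throughout.
#'
#' @param segments segment table carrying `n_hat`, `effort_area`, `x`,
#'   `y` (km) and any PC-score columns named in `terms`.
#' @param terms model terms: `"xy"` for the bivariate coordinate smooth
#'   and/or PC score column names (e.g. `"PC1"`). Empty = null
#'   (intercept-only) model.
#' @param k_xy,k_pc basis dimensions (defaults 25 / 10; fitted effective
#'   degrees of freedom sit well below these caps in practice).
#' @param min_segments guard on sample size.
#' @return object of class `dsurf_dsm`: `gam` (the mgcv fit), `terms`,
#'   `AIC`, `edf`, `V` (Bayesian coefficient covariance; replaced by the
#'   propagated covariance after [dsm_varprop()]), `varprop` (NULL until
#'   propagation).
#' @export
fit_dsm <- function(segments, terms = c("xy", "PC1"), k_xy = 25, k_pc = 10,
                    min_segments = 30L) {
  if (nrow(segments) < min_segments) {
    stop(sprintf("need at least %d segments", min_segments), call. = FALSE)
  }
  if (any(segments$effort_area <= 0)) {
    stop("offsets (effort_area) must be > 0", call. = FALSE)
  }
  if (all(segments$n_hat == 0)) {
    stop("all-zero response: degenerate fit", call. = FALSE)
  }
  miss <- setdiff(setdiff(terms, "xy"), names(segments))
  if (length(miss)) {
    stop("segment table lacks term column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fml <- .dsm_formula(terms, k_xy, k_pc)
  g <- mgcv::gam(fml, data = segments, family = mgcv::tw(),
                 method = "REML")
  structure(list(
    gam = g, terms = terms, k_xy = k_xy, k_pc = k_pc,
    AIC = AIC(g), edf = .dsm_edf(g),
    tweedie_power = .tw_power(g),
    V = .gam_vcov(g),
    data = segments,
    varprop = NULL
  ), class = "dsurf_dsm")
}

# Bayesian coefficient covariance, corrected for smoothing-parameter
# uncertainty when mgcv can provide it
.gam_vcov <- function(g) {
  V <- tryCatch(vcov(g, unconditional = TRUE), error = function(e) NULL)
  if (is.null(V) || anyNA(V)) V <- vcov(g, unconditional = FALSE)
  V
}

.tw_power <- function(g) {
  fam <- g$family$family
  p <- suppressWarnings(as.numeric(sub(".*p=([0-9.]+).*", "\\1", fam)))
  if (is.na(p)) NA_real_ else p
}

.dsm_edf <- function(g) {
  st <- summary(g)$s.table
  if (is.null(st)) return(numeric(0))
  setNames(st[, "edf"], rownames(st))
}

#' @export
print.dsurf_dsm <- function(x, ...) {
  cat("Tweedie density surface model: n_hat ~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1",
      "+ offset(log(effort_area))\n")
  cat(sprintf("  Tweedie power p = %.3f, AIC = %.3f%s\n", x$tweedie_power,
              x$AIC,
              if (!is.null(x$varprop)) ", detection variance propagated"
              else ""))
  if (length(x$edf)) {
    cat("  edf:", paste(sprintf("%s %.3f", names(x$edf), x$edf),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' All-subsets DSM model selection
#'
#' Fits every subset of the term pool (2^p models including the null),
#' ranks by AIC, and applies the parsimony rule: among models within
#' `delta` AIC of the best, select the one with the fewest terms (ties by
#' lower AIC, then lexicographic model label).
#'
#' @param segments segment table (see [fit_dsm()]).
#' @param pool candidate terms, e.g. `c("xy", "PC1", "PC2", "PC3")`.
#' @param delta AIC window (default 2).
#' @param grid optional prediction grid (with PC scores); when supplied,
#'   per-model predicted totals, CIs and CVs are added to the table.
#' @param ... passed to [fit_dsm()].
#' @return list: `table` (ranked data.frame), `fits` (named list),
#'   `selected` (a `dsurf_dsm`).
#' @export
all_subsets_dsm <- function(segments, pool = c("xy", "PC1", "PC2", "PC3"),
                            delta = 2, grid = NULL, ...) {
  if (!length(pool)) stop("term pool must be non-empty", call. = FALSE)
  subsets <- list(character(0))
  for (k in seq_along(pool)) {
    subsets <- c(subsets, combn(pool, k, simplify = FALSE))
  }
  labels <- vapply(subsets, function(s)
    if (length(s)) paste(s, collapse = " + ") else "null", character(1))
  fits <- list()
  errs <- character(0)
  for (i in seq_along(subsets)) {
    f <- tryCatch(fit_dsm(segments, terms = subsets[[i]], ...),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) errs <- c(errs, paste0(labels[i], ": ", f))
    else fits[[labels[i]]] <- f
  }
  if (!length(fits)) {
    stop("all DSM fits failed:\n", paste(errs, collapse = "\n"),
         call. = FALSE)
  }
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  nterms <- vapply(fits, function(f) length(f$terms), integer(1))
  tab <- data.frame(model = names(fits), n_terms = nterms, AIC = aic,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(grid)) {
    tot <- lapply(fits, function(f) {
      s <- total_abundance(predict_grid(f, grid = grid))
      c(s$N_hat, s$ci_lo, s$ci_hi, s$cv)
    })
    m <- do.call(rbind, tot)
    tab$N_hat <- m[, 1]; tab$ci_lo <- m[, 2]; tab$ci_hi <- m[, 3]
    tab$cv <- m[, 4]
  }
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  sel <- parsimony_select(aic, nterms, names(fits), delta)
  list(table = tab, fits = fits, selected = fits[[sel]])
}

## ---- variance propagation -------------------------------------------------

# Per-segment derivative of the log HT-weighted mean detection probability
# with respect to the packed detection parameters. For segments with
# detections, the HT-weighted average of d log p_i / d theta over the
# segment's observations; for empty segments, the survey-wide HT-weighted
# average (the population-level detection sensitivity).
.seg_dlogp <- function(obs, segments, detfit, eps = 1e-5) {
  th <- detfit$theta
  nb <- length(detfit$beta)
  p_of <- function(th) {
    b <- th[seq_len(nb)]
    sh <- if (detfit$key == "hazard_rate") 1 + exp(th[nb + 1L]) else NULL
    sigma <- detection_scale(b, obs, detfit$formula, detfit$xlevels)
    average_p(sigma, detfit$w, detfit$key, sh)
  }
  p0 <- p_of(th)
  D_obs <- matrix(0, nrow(obs), length(th))
  for (j in seq_along(th)) {
    h <- eps * max(1, abs(th[j]))
    tp <- th; tp[j] <- th[j] + h
    tm <- th; tm[j] <- th[j] - h
    D_obs[, j] <- (log(p_of(tp)) - log(p_of(tm))) / (2 * h)
  }
  wgt <- obs$group_size / p0
  sid <- factor(as.character(obs$segment_id),
                levels = as.character(segments$segment_id))
  D_seg <- matrix(0, nrow(segments), length(th))
  for (j in seq_len(length(th))) {
    num <- tapply(wgt * D_obs[, j], sid, sum, default = 0)
    den <- tapply(wgt, sid, sum, default = 0)
    col <- as.numeric(num) / ifelse(as.numeric(den) > 0, as.numeric(den), 1)
    col[as.numeric(den) == 0] <- sum(wgt * D_obs[, j]) / sum(wgt)
    D_seg[, j] <- col
  }
  list(D_seg = D_seg, d_bar = colSums(wgt * D_obs) / sum(wgt))
}

#' Propagate detection-function uncertainty into the DSM
#'
#' Refits the GAM with extra parametric columns holding the per-segment
#' derivative of the log average detection probability with respect to the
#' detection parameters, penalized as a random effect whose prior
#' covariance is the detection fit's parameter covariance (smoothing
#' parameter fixed at 1 so the penalty *is* the prior precision). The
#' refit's coefficient covariance replaces the base covariance for all
#' downstream prediction uncertainty; predicted-abundance CV can only
#' grow. If the detection covariance is singular the method falls back to
#' a delta-method combination `CV^2 = CV_gam^2 + CV_p^2` applied at
#' summary time, with a warning.
#'
#' @param fit a `dsurf_dsm`.
#' @param detfit the selected `dsurf_detfit`.
#' @param obs the truncated, segment-assigned observation table used for
#'   [ht_segments()].
#' @return `fit` with `varprop` filled: `gam` (augmented fit), `d_bar`
#'   (survey-average derivative row used at prediction), `V_det`,
#'   `method` (`"refit"` or `"delta"`), `cv_p` (detection CV of the HT
#'   total, for the delta fallback/cross-check).
#' @export
dsm_varprop <- function(fit, detfit, obs) {
  p0 <- predict(detfit, obs)
  ht <- sum(obs$group_size / p0)
  cv_p <- 0
  if (!detfit$singular_info) {
    nb <- length(detfit$beta)
    gr <- .num_grad(function(th) {
      b <- th[seq_len(nb)]
      sh <- if (detfit$key == "hazard_rate") 1 + exp(th[nb + 1L]) else NULL
      sigma <- detection_scale(b, obs, detfit$formula, detfit$xlevels)
      sum(obs$group_size / average_p(sigma, detfit$w, detfit$key, sh))
    }, detfit$theta)
    cv_p <- sqrt(max(drop(t(gr) %*% detfit$vcov %*% gr), 0)) / ht
  }

  if (detfit$singular_info) {
    warning("singular detection covariance: falling back to delta-method CV combination",
            call. = FALSE)
    fit$varprop <- list(method = "delta", cv_p = cv_p, V_det = NULL,
                        gam = NULL, d_bar = NULL)
    return(fit)
  }

  V_det <- detfit$vcov
  S_det <- tryCatch(solve(V_det), error = function(e) NULL)
  if (!is.null(S_det)) S_det <- (S_det + t(S_det)) / 2  # exact symmetry
  if (is.null(S_det)) {
    warning("detection covariance not invertible: delta-method fallback",
            call. = FALSE)
    fit$varprop <- list(method = "delta", cv_p = cv_p, V_det = V_det,
                        gam = NULL, d_bar = NULL)
    return(fit)
  }

  der <- .seg_dlogp(obs, fit$data, detfit)
  dat <- fit$data
  dat$.dflp <- der$D_seg
  fml <- .dsm_formula(fit$terms, fit$k_xy, fit$k_pc)
  fml <- update(fml, . ~ . + .dflp)
  # the refit estimates only the new random-effect coefficients: Tweedie
  # power and the original smoothing parameters stay at their fitted
  # values, so added detection uncertainty cannot be re-absorbed
  fam <- if (is.finite(fit$tweedie_power)) {
    mgcv::Tweedie(p = fit$tweedie_power, link = "log")
  } else mgcv::tw()
  # sp vector: paraPen penalties come first, then the smooths in order;
  # the random-effect penalty is fixed at 1 so it IS the prior precision
  sp_fix <- c(1, if (length(fit$gam$sp)) unname(fit$gam$sp))
  g2 <- tryCatch(
    mgcv::gam(fml, data = dat, family = fam, method = "REML",
              paraPen = list(.dflp = list(S_det)), sp = sp_fix),
    error = function(e) NULL)
  if (is.null(g2)) {
    warning("variance-propagation refit failed: delta-method fallback",
            call. = FALSE)
    fit$varprop <- list(method = "delta", cv_p = cv_p, V_det = V_det,
                        gam = NULL, d_bar = NULL)
    return(fit)
  }
  fit$varprop <- list(method = "refit", gam = g2, d_bar = der$d_bar,
                      V_det = V_det, cv_p = cv_p)
  fit$V <- .gam_vcov(g2)
  fit$edf <- .dsm_edf(g2)
  fit
}

#' Per-term significance of the DSM smooths
#'
#' Wald-type smooth-term tests (edf, reference df, F, p-value) from the
#' propagated fit when available, otherwise the base fit.
#'
#' @param fit a `dsurf_dsm`.
#' @return data.frame with columns `term`, `edf`, `Ref.df`, `F`,
#'   `p_value`.
#' @export
dsm_term_significance <- function(fit) {
  g <- if (!is.null(fit$varprop) && identical(fit$varprop$method, "refit"))
    fit$varprop$gam else fit$gam
  st <- summary(g)$s.table
  if (is.null(st)) {
    return(data.frame(term = character(0), edf = numeric(0),
                      Ref.df = numeric(0), F = numeric(0),
                      p_value = numeric(0)))
  }
  data.frame(term = rownames(st), edf = st[, "edf"],
             Ref.df = st[, "Ref.df"], F = st[, "F"],
             p_value = st[, "p-value"], row.names = NULL,
             stringsAsFactors = FALSE)
}
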