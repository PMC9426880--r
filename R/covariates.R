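## Correlation-matrix PCA of landscape covariates with the retention and
## interpretation rules used for density-surface covariate compression:
## latent-root retention (eigenvalue >= 1), correlation-scaled loadings
## (eigenvector * sqrt(eigenvalue)), contribution = 100 * loading^2 /
## eigenvalue, and 0.40 / 0.60 loading thresholds for interpretation.

#' Default landscape covariate names
#' @export
landscape_covariates <- function() {
  c("elevation", "snow_days", "dist_agriculture", "dist_developed",
    "dist_forest", "dist_shrub", "dist_timber", "dist_wetland",
    "dist_water")
}

#' Principal components analysis of segment covariates
#'
#' Standardizes each covariate (correlation-matrix PCA: the eigenvalues
#' then sum to the number of covariates) and eigendecomposes. Components
#' are ordered by decreasing eigenvalue and sign-canonicalized so the
#' covariate with the largest absolute loading on each component loads
#' positively.
#'
#' @param x data.frame or matrix of covariate columns (rows = segments).
#' @param covariates columns to use; default all numeric columns of `x`
#'   intersected with [landscape_covariates()] when present, otherwise all
#'   numeric columns.
#' @return object of class `dsurf_pca`: `means`, `sds`, `rotation`
#'   (unit eigenvectors), `loadings` (correlation-scaled), `eigenvalues`,
#'   `pct_variance`, `contributions`, `n_retained`.
#' @export
fit_pca <- function(x, covariates = NULL) {
  if (is.null(covariates)) {
    num <- names(x)[vapply(x, is.numeric, logical(1))]
    covariates <- intersect(landscape_covariates(), num)
    if (!length(covariates)) covariates <- num
  }
  X <- as.matrix(as.data.frame(x)[, covariates, drop = FALSE])
  if (ncol(X) < 2L) stop("need at least 2 covariates", call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (anyNA(X)) stop("missing values in covariates", call. = FALSE)
  means <- colMeans(X)
  sds <- apply(X, 2, sd)
  zero <- which(sds == 0)
  if (length(zero)) {
    stop("zero-variance covariate(s): ",
         paste(covariates[zero], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X, center = means, scale = sds)
  e <- eigen(cor(X), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors
  # deterministic sign: largest-|loading| covariate positive per component
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- covariates
  colnames(V) <- paste0("PC", seq_len(ncol(V)))
  loadings <- sweep(V, 2, sqrt(ev), `*`)
  contributions <- sweep(loadings^2, 2, ev, `/`) * 100
  contributions[, ev == 0] <- NA_real_
  structure(list(
    covariates = covariates, means = means, sds = sds,
    rotation = V, loadings = loadings, eigenvalues = ev,
    pct_variance = 100 * ev / sum(ev),
    contributions = contributions,
    n_retained = retain_components(ev)
  ), class = "dsurf_pca")
}

#' Latent-root retention rule
#'
#' Number of components with eigenvalue >= 1 (correlation-matrix PCA).
#'
#' @param x a `dsurf_pca` or a numeric eigenvalue vector.
#' @return integer count.
#' @export
retain_components <- function(x) {
  ev <- if (inherits(x, "dsurf_pca")) x$eigenvalues else x
  sum(ev >= 1)
}

#' Percent contribution of covariates to components
#'
#' `100 * loading^2 / eigenvalue` with correlation-scaled loadings, so
#' each component's column sums to 100.
#'
#' @param model a `dsurf_pca`.
#' @param n_components columns to return (default retained components).
#' @return matrix of percents (covariate x component).
#' @export
pca_contributions <- function(model, n_components = model$n_retained) {
  model$contributions[, seq_len(n_components), drop = FALSE]
}

#' Project rows onto retained components
#'
#' Standardizes `newdata` with the *training* means/sds and projects onto
#' the unit eigenvectors, so training-set scores have mean 0 and variance
#' equal to the eigenvalue per component. Grid rows are scored with the
#' same constants as segments, keeping scores commensurable.
#'
#' @param model a `dsurf_pca`.
#' @param newdata rows carrying all training covariates.
#' @param n_components how many score columns (default retained).
#' @return matrix of scores, columns `PC1..PCk`.
#' @export
pca_scores <- function(model, newdata, n_components = model$n_retained) {
  miss <- setdiff(model$covariates, names(as.data.frame(newdata)))
  if (length(miss)) {
    stop("missing covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(newdata)[, model$covariates, drop = FALSE])
  Z <- scale(X, center = model$means, scale = model$sds)
  S <- Z %*% model$rotation[, seq_len(n_components), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(n_components))
  S
}

#' Classify loadings by interpretation thresholds
#'
#' Flags each covariate on each component as `strong` (|loading| >= 0.60),
#' `moderate` (>= 0.40), or `none`.
#'
#' @param model a `dsurf_pca`.
#' @param moderate,strong absolute-loading thresholds.
#' @param n_components components to report.
#' @return character matrix (covariate x component).
#' @export
interpret_loadings <- function(model, moderate = 0.40, strong = 0.60,
                               n_components = model$n_retained) {
  L <- abs(model$loadings[, seq_len(n_components), drop = FALSE])
  out <- matrix("none", nrow(L), ncol(L), dimnames = dimnames(L))
  out[L >= moderate] <- "moderate"
  out[L >= strong] <- "strong"
  out
}

#' @export
print.dsurf_pca <- function(x, ...) {
  k <- x$n_retained
  cat(sprintf("Correlation-matrix PCA of %d covariates; %d component(s) retained (eigenvalue >= 1)\n",
              length(x$covariates), k))
  tab <- rbind(eigenvalue = x$eigenvalues[seq_len(k)],
               pct_variance = x$pct_variance[seq_len(k)])
  colnames(tab) <- paste0("PC", seq_len(k))
  print(round(tab, 3))
  cat("Loadings (correlation-scaled):\n")
  print(round(x$loadings[, seq_len(k), drop = FALSE], 2))
  invisible(x)
}
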