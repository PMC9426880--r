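## End-to-end orchestration in survey order: truncate -> fit/select
## detection -> HT segment abundances -> PCA -> all-subsets DSM ->
## variance propagation -> grid prediction -> summaries. Deterministic
## given data and configuration.

#' Run the full two-stage density surface pipeline
#'
#' @param obs raw observation table (canonical columns; `segment_id` may
#'   be empty if `along_track` is present so assignment can run).
#' @param segments segment table (km coordinates, landscape covariates).
#' @param grid prediction-grid table (or `NULL` to stop after stage 1).
#' @param truncation truncation distance w (m).
#' @param det_covariates candidate detection covariates; `NULL` fits the
#'   intercept-only scale model per key.
#' @param det_keys key functions to consider.
#' @param dsm_pool DSM term pool; empty vector = stage-1 (CDS) only.
#' @param delta_aic AIC window of the parsimony rule for both stages.
#' @param threshold density threshold for the area summary.
#' @param area_km2 region area for the stage-1 CDS total; defaults to the
#'   grid's total area, else the covered area.
#' @param moose optional comparison surface (`cell_id`, `density`) for
#'   rank correlation.
#' @param out_dir optional directory; when given, intermediate tables are
#'   written as CSV and the report as JSON (if jsonlite is installed).
#' @return a run report (list): per-stage tables mirroring the ranked
#'   detection table, PCA summary, ranked DSM table, term significance,
#'   and the surface summary.
#' @export
run_pipeline <- function(obs, segments, grid = NULL, truncation = 350,
                         det_covariates = c("canopy", "cloud_cover"),
                         det_keys = c("hazard_rate", "half_normal"),
                         dsm_pool = c("xy", "PC1", "PC2", "PC3"),
                         delta_aic = 2, threshold = 2, area_km2 = NULL,
                         moose = NULL, out_dir = NULL) {
  report <- list(config = list(
    truncation = truncation, det_covariates = det_covariates,
    det_keys = det_keys, dsm_pool = dsm_pool, delta_aic = delta_aic,
    threshold = threshold
  ))
  stage <- "truncation"
  out <- tryCatch({
    obs_t <- truncate_observations(obs, truncation)
    report$truncation <- list(n_in = attr(obs_t, "n_in"),
                              n_kept = attr(obs_t, "n_kept"))
    if (!"segment_id" %in% names(obs_t) || anyNA(obs_t$segment_id) ||
        !all(nzchar(as.character(obs_t$segment_id)))) {
      obs_t <- assign_to_segments(obs_t, segments)
    }

    stage <- "detection"
    det_fits <- if (is.null(det_covariates)) {
      fits <- lapply(det_keys, function(k)
        fit_detection(obs_t, truncation, key = k, formula = ~1))
      names(fits) <- det_keys
      for (k in det_keys) fits[[k]]$label <- paste0(k, ": 1")
      attr(fits, "ranking") <- rank_detections(fits)
      fits
    } else {
      all_subsets_detection(obs_t, truncation,
                            covariates = det_covariates, keys = det_keys)
    }
    detfit <- select_detection(det_fits, delta = delta_aic)
    report$detection <- list(ranking = attr(det_fits, "ranking"),
                             selected = detfit$label,
                             p_bar = detfit$p_bar,
                             p_bar_se = detfit$p_bar_se,
                             cvm = detfit$cvm)

    stage <- "abundance"
    seg_ab <- ht_segments(obs_t, segments, fit = detfit)
    effort_km <- sum(segments$length) / 1000
    A <- area_km2 %||% if (!is.null(grid)) sum(grid$area) else
      2 * truncation / 1000 * effort_km
    cds <- cds_total(obs_t, detfit, effort_km, A)
    report$cds <- cds
    report$encounter_rate <- encounter_rate(nrow(obs_t), effort_km)

    dsm_sel <- NULL
    cells <- NULL
    if (length(dsm_pool)) {
      stage <- "pca"
      pca <- NULL
      pc_terms <- grep("^PC", dsm_pool, value = TRUE)
      if (length(pc_terms)) {
        pca <- fit_pca(segments)
        S <- pca_scores(pca, segments,
                        n_components = max(pca$n_retained,
                                           length(pc_terms)))
        for (cn in colnames(S)) seg_ab[[cn]] <- S[, cn]
        report$pca <- list(eigenvalues = pca$eigenvalues,
                           pct_variance = pca$pct_variance,
                           n_retained = pca$n_retained,
                           loadings = pca$loadings)
      }

      stage <- "dsm"
      grid_scored <- NULL
      if (!is.null(grid)) {
        grid_scored <- grid
        if (!is.null(pca)) {
          Sg <- pca_scores(pca, grid,
                           n_components = max(pca$n_retained,
                                              length(pc_terms)))
          for (cn in colnames(Sg)) grid_scored[[cn]] <- Sg[, cn]
        }
      }
      sel <- all_subsets_dsm(seg_ab, pool = dsm_pool, delta = delta_aic,
                             grid = grid_scored)
      dsm_sel <- sel$selected
      report$dsm <- list(table = sel$table,
                         selected = paste(dsm_sel$terms, collapse = " + "),
                         tweedie_power = dsm_sel$tweedie_power)

      stage <- "varprop"
      dsm_sel <- dsm_varprop(dsm_sel, detfit, obs_t)
      report$dsm$terms <- dsm_term_significance(dsm_sel)
      report$dsm$varprop_method <- dsm_sel$varprop$method
      report$dsm$cv_p <- dsm_sel$varprop$cv_p

      if (!is.null(grid_scored)) {
        stage <- "prediction"
        cells <- predict_grid(dsm_sel, grid_scored)
        summ <- total_abundance(cells, threshold = threshold)
        report$surface <- summ
        if (!is.null(moose)) {
          report$spearman_vs_moose <- spearman_surfaces(cells, moose)
        }
      }
    }
    list(report = report, detfit = detfit, segments = seg_ab,
         dsm = dsm_sel, cells = cells)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  if (!is.null(out_dir)) .write_run(out, out_dir)
  out
}

.write_run <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(out$segments, file.path(out_dir, "segments.csv"))
  if (!is.null(out$cells)) {
    write_table(as.data.frame(out$cells), file.path(out_dir, "cells.csv"))
  }
  rk <- out$report$detection$ranking
  if (!is.null(rk)) write_table(rk, file.path(out_dir, "detection_models.csv"))
  if (!is.null(out$report$dsm$table)) {
    write_table(out$report$dsm$table, file.path(out_dir, "dsm_models.csv"))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(.jsonable(out$report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

# strip non-serializable pieces for the JSON report
.jsonable <- function(x) {
  if (is.list(x)) {
    lapply(x, .jsonable)
  } else if (is.matrix(x)) {
    as.data.frame(x)
  } else x
}
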