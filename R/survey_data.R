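#' Canonical column names for survey flat files
#'
#' `dsurf` reads and writes plain CSV tables. Internally every table uses a
#' fixed set of canonical column names; a *schema* maps canonical names to
#' the column names actually present in a file, so files written in other
#' dialects (e.g. `Distance`-style `Sample.Label`/`Effort`/`distance`/`size`)
#' can be ingested without editing them.
#'
#' Canonical observation columns: `obs_id`, `unit_id`, `transect_id`,
#' `segment_id` (optional), `perp_distance` (m), `group_size`, `canopy`
#' (one of `hardwood`, `mixed`, `open`), `cloud_cover` (percent),
#' `temperature` (deg C), `fatigue_hours`, `along_track` (m, optional).
#'
#' Canonical segment columns: `segment_id`, `transect_id`, `unit_id`,
#' `length` (m), `x`, `y` (planar coordinates; converted to km on read),
#' plus any number of landscape covariates.
#'
#' Canonical grid columns: `cell_id`, `x`, `y`, `area` (km^2), plus
#' landscape covariates.
#'
#' @param ... named overrides, canonical = file column name, e.g.
#'   `obs_schema(perp_distance = "distance", group_size = "size")`.
#' @return a named character vector mapping canonical to file columns.
#' @export
obs_schema <- function(...) {
  schema <- c(
    obs_id = "obs_id", unit_id = "unit_id", transect_id = "transect_id",
    segment_id = "segment_id", perp_distance = "perp_distance",
    group_size = "group_size", canopy = "canopy",
    cloud_cover = "cloud_cover", temperature = "temperature",
    fatigue_hours = "fatigue_hours", along_track = "along_track"
  )
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(schema))
    if (length(bad)) stop("unknown canonical column(s): ",
                          paste(bad, collapse = ", "))
    schema[names(override)] <- override
  }
  schema
}

#' @rdname obs_schema
#' @export
segment_schema <- function(...) {
  schema <- c(
    segment_id = "segment_id", transect_id = "transect_id",
    unit_id = "unit_id", length = "length", x = "x", y = "y"
  )
  override <- c(...)
  if (length(override)) schema[names(override)] <- override
  schema
}

.canopy_levels <- c("hardwood", "mixed", "open")

# columns that must be present (segment_id/along_track may be absent on read)
.obs_required <- c("obs_id", "unit_id", "transect_id", "perp_distance",
                   "group_size", "canopy")
.obs_optional <- c("segment_id", "along_track", "cloud_cover",
                   "temperature", "fatigue_hours")

.rename_by_schema <- function(df, schema, required, what) {
  present <- schema[schema %in% names(df)]
  missing <- setdiff(required, names(present))
  if (length(missing)) {
    stop(sprintf("%s file is missing required column(s): %s", what,
                 paste(schema[missing], collapse = ", ")), call. = FALSE)
  }
  out <- df
  idx <- match(present, names(df))
  names(out)[idx] <- names(present)
  out
}

#' Read an observation table
#'
#' Reads a CSV of detected groups, renames columns to the canonical
#' dialect via `schema`, and validates types and categorical levels.
#'
#' @param path path to a CSV file with a header row.
#' @param schema column map from [obs_schema()].
#' @return a `data.frame` of observations in canonical columns, one row per
#'   detected group, row count equal to the file's.
#' @export
read_observations <- function(path, schema = obs_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .rename_by_schema(df, schema, .obs_required, "observation")
  validate_observations(df)
}

#' Validate an observation table in canonical columns
#'
#' @param df a data.frame carrying at least the required canonical columns.
#' @return `df`, with `canopy` as a factor on the closed 3-level set.
#' @export
validate_observations <- function(df) {
  for (col in .obs_required) {
    if (!col %in% names(df)) {
      stop("observation table is missing required column: ", col,
           call. = FALSE)
    }
  }
  d <- suppressWarnings(as.numeric(df$perp_distance))
  bad <- which(is.na(d) & !is.na(df$perp_distance) | is.na(df$perp_distance))
  if (length(bad)) {
    stop("non-numeric or missing perp_distance at row(s): ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (any(d < 0)) stop("perp_distance must be >= 0", call. = FALSE)
  df$perp_distance <- d
  s <- suppressWarnings(as.integer(df$group_size))
  if (any(is.na(s)) || any(s < 1L)) {
    stop("group_size must be integer >= 1", call. = FALSE)
  }
  df$group_size <- s
  lev <- unique(as.character(df$canopy))
  unknown <- setdiff(lev, .canopy_levels)
  if (length(unknown)) {
    stop("unknown canopy level(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df$canopy <- factor(as.character(df$canopy), levels = .canopy_levels)
  df
}

#' Read a segment table
#'
#' Coordinates are converted to kilometres internally (spline numerics are
#' better behaved in km than in metres); segment `length` stays in metres.
#'
#' @param path CSV path.
#' @param schema column map from [segment_schema()].
#' @param coord_units units of the `x`,`y` columns in the file.
#' @return data.frame of segments; extra columns are kept as covariates.
#' @export
read_segments <- function(path, schema = segment_schema(),
                          coord_units = c("m", "km")) {
  coord_units <- match.arg(coord_units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .rename_by_schema(df, schema,
                          c("segment_id", "transect_id", "length", "x", "y"),
                          "segment")
  if (any(!is.finite(df$length)) || any(df$length <= 0)) {
    stop("segment length must be finite and > 0", call. = FALSE)
  }
  if (coord_units == "m") {
    df$x <- df$x / 1000
    df$y <- df$y / 1000
  }
  df
}

#' Read a prediction-grid table
#'
#' @inheritParams read_segments
#' @export
read_grid <- function(path, coord_units = c("m", "km")) {
  coord_units <- match.arg(coord_units)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cell_id", "x", "y", "area")) {
    if (!col %in% names(df)) {
      stop("grid file is missing required column: ", col, call. = FALSE)
    }
  }
  if (coord_units == "m") {
    df$x <- df$x / 1000
    df$y <- df$y / 1000
  }
  df
}

#' Write a table as RFC-4180 CSV with a header row
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Survey design geometry
#'
#' Describes the nominal aerial design: rectangular survey units holding
#' parallel transects flown along the unit's long axis, each transect cut
#' into equal-length segments for the spatial model, and a perpendicular
#' truncation distance bounding the searched strip.
#'
#' @param truncation truncation distance w in metres.
#' @param unit_length_km,unit_width_km unit dimensions (default 10 x 3 km).
#' @param n_transects transects per unit.
#' @param transect_spacing_km spacing between parallel transects.
#' @param segments_per_transect segments each transect is divided into.
#' @return an object of class `dsurf_design`.
#' @export
survey_design <- function(truncation = 350, unit_length_km = 10,
                          unit_width_km = 3, n_transects = 3,
                          transect_spacing_km = 1,
                          segments_per_transect = 4) {
  if (truncation <= 0) stop("truncation must be > 0", call. = FALSE)
  if (unit_length_km <= 0 || unit_width_km <= 0) {
    stop("unit dimensions must be > 0", call. = FALSE)
  }
  structure(list(
    truncation = truncation, unit_length_km = unit_length_km,
    unit_width_km = unit_width_km, n_transects = n_transects,
    transect_spacing_km = transect_spacing_km,
    segments_per_transect = segments_per_transect,
    segment_length_m = unit_length_km * 1000 / segments_per_transect
  ), class = "dsurf_design")
}

#' @export
print.dsurf_design <- function(x, ...) {
  cat(sprintf(
    "Survey design: %g x %g km units, %d transects at %g km spacing,\n  %d segments/transect (%g m each), truncation %g m\n",
    x$unit_length_km, x$unit_width_km, x$n_transects,
    x$transect_spacing_km, x$segments_per_transect, x$segment_length_m,
    x$truncation))
  invisible(x)
}

#' Truncate observations at a perpendicular distance
#'
#' Retains exactly the records with `perp_distance <= w` (inclusive
#' boundary), preserving input order.
#'
#' @param obs observation table.
#' @param w truncation distance (m), must be > 0 (may be `Inf`).
#' @return the truncated table, with attributes `n_in`, `n_kept`.
#' @export
truncate_observations <- function(obs, w) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w <= 0) {
    stop("truncation distance w must be a single value > 0", call. = FALSE)
  }
  keep <- obs$perp_distance <= w
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_in") <- nrow(obs)
  attr(out, "n_kept") <- nrow(out)
  attr(out, "truncation") <- w
  out
}

#' Cut transects into equal segments
#'
#' Divides each transect into `design$segments_per_transect` contiguous,
#' non-overlapping segments whose lengths sum exactly to the transect
#' length; segment midpoints are placed on the transect line.
#'
#' @param transects data.frame with columns `transect_id`, `unit_id`,
#'   `length` (m) and line geometry `x0`, `y0`, `x1`, `y1` (km). Extra
#'   columns are carried through to every segment of the transect.
#' @param design a [survey_design()].
#' @return segment table: `segment_id`, `transect_id`, `unit_id`, `length`
#'   (m), `x`, `y` (km, midpoint), `seg_index`, `start_m`, `end_m`
#'   (along-track extent in metres).
#' @export
segmentize <- function(transects, design = survey_design()) {
  if (any(transects$length <= 0)) {
    stop("zero or negative transect length", call. = FALSE)
  }
  k <- design$segments_per_transect
  n <- nrow(transects)
  idx <- rep(seq_len(n), each = k)
  seg_i <- rep(seq_len(k), times = n)
  len <- transects$length[idx] / k
  # fractional positions of segment midpoints and boundaries along the line
  fr_mid <- (seg_i - 0.5) / k
  out <- data.frame(
    segment_id = paste0(transects$transect_id[idx], "-", seg_i),
    transect_id = transects$transect_id[idx],
    unit_id = transects$unit_id[idx],
    seg_index = seg_i,
    length = len,
    start_m = (seg_i - 1) / k * transects$length[idx],
    end_m = seg_i / k * transects$length[idx],
    x = transects$x0[idx] + fr_mid * (transects$x1[idx] - transects$x0[idx]),
    y = transects$y0[idx] + fr_mid * (transects$y1[idx] - transects$y0[idx]),
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(transects),
                   c("transect_id", "unit_id", "length",
                     "x0", "y0", "x1", "y1"))
  for (col in extra) out[[col]] <- transects[[col]][idx]
  out
}

#' Assign observations to transect segments
#'
#' Bins each observation's along-track position into the segments of its
#' transect. Bins are left-closed right-open with the final segment closed
#' on the right, so a tie at an interior boundary goes to the downstream
#' segment.
#'
#' @param obs observation table with `transect_id` and `along_track` (m).
#' @param segments segment table from [segmentize()].
#' @return `obs` with `segment_id` filled.
#' @export
assign_to_segments <- function(obs, segments) {
  if (nrow(obs) == 0L) {
    obs$segment_id <- character(0)
    return(obs)
  }
  if (!"along_track" %in% names(obs) || any(is.na(obs$along_track))) {
    stop("assign_to_segments requires an along_track position per observation",
         call. = FALSE)
  }
  seg_id <- character(nrow(obs))
  unassigned <- character(0)
  split_seg <- split(seq_len(nrow(segments)), segments$transect_id)
  for (i in seq_len(nrow(obs))) {
    rows <- split_seg[[as.character(obs$transect_id[i])]]
    if (is.null(rows)) {
      unassigned <- c(unassigned, as.character(obs$obs_id[i]))
      next
    }
    s <- segments[rows, , drop = FALSE]
    s <- s[order(s$start_m), , drop = FALSE]
    at <- obs$along_track[i]
    if (at < min(s$start_m) || at > max(s$end_m)) {
      unassigned <- c(unassigned, as.character(obs$obs_id[i]))
      next
    }
    j <- findInterval(at, s$start_m)      # left-closed right-open
    j <- min(j, nrow(s))                  # last bin right-closed
    seg_id[i] <- s$segment_id[j]
  }
  if (length(unassigned)) {
    stop("observation(s) outside all transect extents: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  obs$segment_id <- seg_id
  obs
}

#' Effort area of segments
#'
#' Area searched per segment: both sides of the line out to the truncation
#' distance, `2 w L`, reported in km^2.
#'
#' @param segments segment table with `length` in m.
#' @param w truncation distance in m.
#' @return numeric vector of km^2 areas.
#' @export
segment_effort_area <- function(segments, w) {
  if (w <= 0) stop("truncation must be > 0", call. = FALSE)
  2 * (w / 1000) * (segments$length / 1000)
}
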