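SUIT_CLASSES <- c("unsuitable", "low", "medium", "high")

# report-layer rounding: half away from zero, 2 decimals
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Classify a suitability map into four classes
#'
#' IPCC-style probability bins on the logistic output: unsuitable
#' `p < 0.05`, low `0.05 <= p < 0.33`, medium `0.33 <= p < 0.66`, high
#' `p >= 0.66` (upper boundaries inclusive on the high side of each
#' cut). Nodata is preserved.
#'
#' @param map a logistic-transform `suitability_map`.
#' @param thresholds strictly increasing cut points (default
#'   `c(0.05, 0.33, 0.66)`).
#' @return object of class `classified_map`: `grid` (integer codes
#'   0 = unsuitable ... 3 = high), `thresholds`, `scenario`.
#' @export
classify_suitability <- function(map, thresholds = c(0.05, 0.33, 0.66)) {
  stopifnot(inherits(map, "suitability_map"))
  if (!identical(map$transform, "logistic"))
    stop("classification requires a logistic-transform map (got \"",
         map$transform, "\")")
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("thresholds must be three strictly increasing values")
  p <- map$grid$values
  codes <- (p >= thresholds[1]) + (p >= thresholds[2]) + (p >= thresholds[3])
  codes[is.na(p)] <- NA_real_
  structure(list(grid = grid_like(map$grid, codes),
                 thresholds = thresholds, scenario = map$scenario),
            class = "classified_map")
}

#' @export
print.classified_map <- function(x, ...) {
  tb <- table(factor(x$grid$values, levels = 0:3, labels = SUIT_CLASSES))
  cat(sprintf("classified_map%s: %s\n",
              if (is.null(x$scenario)) "" else paste0(" (", x$scenario, ")"),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Per-class area breakdown
#'
#' Construct directly from areas (Table-2 style input) or compute from a
#' classified map via [class_areas()]. Areas are in units of 10^4 km^2;
#' `total_suitable = low + medium + high`.
#'
#' @param low,medium,high,unsuitable class areas in 10^4 km^2.
#' @param scenario,decade optional labels.
#' @return object of class `class_breakdown`.
#' @export
class_breakdown <- function(low, medium, high, unsuitable = NA_real_,
                            scenario = NA_character_, decade = NA_character_) {
  structure(list(areas = c(unsuitable = unsuitable, low = low,
                           medium = medium, high = high),
                 total_suitable = low + medium + high,
                 units = "1e4_km2", scenario = scenario, decade = decade),
            class = "class_breakdown")
}

#' @export
print.class_breakdown <- function(x, ...) {
  cat(sprintf("class_breakdown [10^4 km^2]%s: low %.2f, medium %.2f, high %.2f, total suitable %.2f\n",
              if (is.na(x$scenario)) "" else paste0(" (", x$scenario, ")"),
              x$areas["low"], x$areas["medium"], x$areas["high"],
              x$total_suitable))
  invisible(x)
}

#' Areas of each suitability class
#'
#' Geographic mode: each cell covers
#' `(cellsize * 111.32 km)^2 * cos(latitude of cell centre)`; planar
#' mode: `cellsize^2` (cellsize in km). Reported in 10^4 km^2.
#'
#' @param cmap a `classified_map`.
#' @param crs_mode `"geographic"` (default) or `"planar"`.
#' @return a [class_breakdown()].
#' @export
class_areas <- function(cmap, crs_mode = c("geographic", "planar")) {
  crs_mode <- match.arg(crs_mode)
  stopifnot(inherits(cmap, "classified_map"))
  g <- cmap$grid
  if (crs_mode == "geographic") {
    cc <- cell_center_coords(g)
    cell_km2 <- (g$cellsize * KM_PER_DEG)^2 * cos(cc$y * pi / 180)
  } else {
    cell_km2 <- matrix(g$cellsize^2, g$nrows, g$ncols)
  }
  a <- vapply(0:3, function(k)
    sum(cell_km2[!is.na(g$values) & g$values == k]) / 1e4, numeric(1))
  class_breakdown(low = a[2], medium = a[3], high = a[4], unsuitable = a[1],
                  scenario = if (is.null(cmap$scenario)) NA_character_
                             else cmap$scenario)
}

#' Class-area change between two breakdowns
#'
#' `100 * (future - current) / current` per suitability class and for
#' the total suitable area. Unrounded values are returned alongside a
#' reporting column rounded half-up to two decimals; a class with zero
#' current area is flagged undefined (`NA`).
#'
#' @param current,future [class_breakdown()] objects.
#' @return data.frame with `class`, `current`, `future`, `change_pct`
#'   (unrounded) and `change_pct_2dp`.
#' @export
area_change <- function(current, future) {
  stopifnot(inherits(current, "class_breakdown"),
            inherits(future, "class_breakdown"))
  cls <- c("low", "medium", "high", "total_suitable")
  cur <- c(current$areas[c("low", "medium", "high")], current$total_suitable)
  fut <- c(future$areas[c("low", "medium", "high")], future$total_suitable)
  pct <- ifelse(cur == 0, NA_real_, 100 * (fut - cur) / cur)
  data.frame(class = cls, current = unname(cur), future = unname(fut),
             change_pct = unname(pct),
             change_pct_2dp = unname(round_half_up(pct, 2)),
             undefined = cur == 0)
}

#' Great-circle distance in km
#'
#' Haversine formula on a sphere with 111.32 km per degree
#' (radius 6378.137 km), the same scale used for cell areas and
#' thinning.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  R <- KM_PER_DEG * 180 / pi
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# initial great-circle bearing, degrees clockwise from north
bearing_deg <- function(lon1, lat1, lon2, lat2, planar = FALSE) {
  if (planar) {
    b <- atan2(lon2 - lon1, lat2 - lat1) * 180 / pi
  } else {
    to_rad <- pi / 180
    dlon <- (lon2 - lon1) * to_rad
    y <- sin(dlon) * cos(lat2 * to_rad)
    x <- cos(lat1 * to_rad) * sin(lat2 * to_rad) -
      sin(lat1 * to_rad) * cos(lat2 * to_rad) * cos(dlon)
    b <- atan2(y, x) * 180 / pi
  }
  (b + 360) %% 360
}

#' Centroid of the highly suitable class
#'
#' Weighted mean of the cell-centre coordinates over cells classified
#' high; weights are the logistic suitability (or 1 when
#' `weighted = FALSE`).
#'
#' @param cmap a `classified_map`.
#' @param map the matching logistic `suitability_map` (weights source).
#' @param weighted use suitability weights (default) or plain means.
#' @return list with `lon`, `lat`, `n_cells`, `empty` flag.
#' @export
suitability_centroid <- function(cmap, map = NULL, weighted = TRUE) {
  stopifnot(inherits(cmap, "classified_map"))
  g <- cmap$grid
  idx <- which(!is.na(g$values) & g$values == 3)
  if (!length(idx))
    return(list(lon = NA_real_, lat = NA_real_, n_cells = 0L, empty = TRUE))
  cc <- cell_center_coords(g)
  w <- if (weighted && !is.null(map)) map$grid$values[idx] else rep(1, length(idx))
  list(lon = sum(cc$x[idx] * w) / sum(w),
       lat = sum(cc$y[idx] * w) / sum(w),
       n_cells = length(idx), empty = FALSE)
}

#' Centroid shift between baseline and scenario
#'
#' Computes the high-class suitability-weighted centroid of both maps,
#' the displacement distance (haversine in geographic mode, Euclidean
#' in planar mode) and the bearing from baseline to scenario centroid
#' in degrees clockwise from north.
#'
#' @param baseline_cmap,baseline_map classified + suitability map of the
#'   baseline.
#' @param scenario_cmap,scenario_map same for the scenario.
#' @param crs_mode `"geographic"` or `"planar"`.
#' @param weighted suitability-weighted centroid (default) or binary.
#' @return one-row data.frame (`centroid_record`): scenario label,
#'   baseline and scenario centroids, `distance_km`, `bearing_deg`,
#'   `empty` flag (TRUE when either high class is empty).
#' @export
centroid_shift <- function(baseline_cmap, baseline_map,
                           scenario_cmap, scenario_map,
                           crs_mode = c("geographic", "planar"),
                           weighted = TRUE) {
  crs_mode <- match.arg(crs_mode)
  f <- geom_fields_equal(baseline_cmap$grid, scenario_cmap$grid)
  if (!is.null(f)) stop(sprintf("map geometry mismatch: field %s", f))
  c0 <- suitability_centroid(baseline_cmap, baseline_map, weighted)
  c1 <- suitability_centroid(scenario_cmap, scenario_map, weighted)
  empty <- c0$empty || c1$empty
  if (empty) {
    dist <- NA_real_; brg <- NA_real_
  } else if (crs_mode == "planar") {
    dist <- sqrt((c1$lon - c0$lon)^2 + (c1$lat - c0$lat)^2)
    brg <- bearing_deg(c0$lon, c0$lat, c1$lon, c1$lat, planar = TRUE)
  } else {
    dist <- haversine_km(c0$lon, c0$lat, c1$lon, c1$lat)
    brg <- bearing_deg(c0$lon, c0$lat, c1$lon, c1$lat)
  }
  out <- data.frame(
    scenario = if (is.null(scenario_cmap$scenario)) NA_character_
               else scenario_cmap$scenario,
    baseline_lon = c0$lon, baseline_lat = c0$lat,
    lon = c1$lon, lat = c1$lat,
    distance_km = dist, bearing_deg = brg,
    weighted = weighted, empty = empty)
  class(out) <- c("centroid_record", "data.frame")
  out
}
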