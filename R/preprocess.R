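KM_PER_DEG <- 111.32  # km per degree of latitude; longitude scaled by cos(lat)

#' Species occurrence records
#'
#' @param lon,lat coordinate vectors (degrees in geographic mode, map
#'   units in planar mode). Input order is preserved; thinning relies
#'   on it.
#' @param species species label.
#' @param crs_mode `"geographic"` or `"planar"`.
#' @return object of class `occurrence_set`.
#' @export
occurrence_set <- function(lon, lat, species = "species",
                           crs_mode = c("geographic", "planar")) {
  crs_mode <- match.arg(crs_mode)
  if (length(lon) != length(lat)) stop("lon and lat lengths differ")
  if (crs_mode == "geographic" && length(lon) &&
      (any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)))
    stop("geographic coordinates outside [-180,180] x [-90,90]")
  structure(list(species = species,
                 lon = as.numeric(lon), lat = as.numeric(lat),
                 crs_mode = crs_mode),
            class = "occurrence_set")
}

#' @export
length.occurrence_set <- function(x) length(x$lon)

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d records of \"%s\" (%s)\n",
              length(x$lon), x$species, x$crs_mode))
  invisible(x)
}

#' Read occurrences from CSV (header: species,longitude,latitude)
#' @param path CSV file path.
#' @param crs_mode coordinate interpretation.
#' @return an [occurrence_set()].
#' @export
read_occurrences <- function(path, crs_mode = c("geographic", "planar")) {
  crs_mode <- match.arg(crs_mode)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(d)))
    stop(sprintf("occurrence CSV %s must have header columns %s",
                 path, paste(need, collapse = ",")))
  occurrence_set(d$longitude, d$latitude,
                 species = if (nrow(d)) d$species[1] else "species",
                 crs_mode = crs_mode)
}

#' Write occurrences as CSV (species,longitude,latitude)
#' @param occ an [occurrence_set()].
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  d <- data.frame(species = rep(occ$species, length(occ$lon)),
                  longitude = occ$lon, latitude = occ$lat)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Spatially thin occurrence records
#'
#' Keeps at most one record per `cell_km` x `cell_km` thinning cell,
#' retaining the first record (input order) in each cell; the output
#' preserves input order. In geographic mode coordinates are converted
#' to km with an equirectangular projection at the dataset's mean
#' latitude (1 degree latitude = 111.32 km, 1 degree longitude =
#' 111.32 * cos(mean lat) km); the thinning grid is anchored at
#' `anchor` (typically the raster's lower-left corner).
#'
#' @param occ an [occurrence_set()].
#' @param cell_km thinning cell edge, km (default 4.5).
#' @param anchor `c(lon, lat)` grid anchor; default `c(-180, -90)`
#'   (planar: `c(0, 0)`).
#' @param mean_lat reference latitude for the longitude scale; default
#'   the mean latitude of `occ`.
#' @return thinned [occurrence_set()].
#' @export
thin_occurrences <- function(occ, cell_km = 4.5, anchor = NULL,
                             mean_lat = NULL) {
  stopifnot(inherits(occ, "occurrence_set"), cell_km > 0)
  n <- length(occ$lon)
  if (n == 0) return(occ)
  planar <- occ$crs_mode == "planar"
  if (is.null(anchor)) anchor <- if (planar) c(0, 0) else c(-180, -90)
  if (planar) {
    xk <- occ$lon - anchor[1]
    yk <- occ$lat - anchor[2]
  } else {
    if (is.null(mean_lat)) mean_lat <- mean(occ$lat)
    sx <- KM_PER_DEG * cos(mean_lat * pi / 180)
    xk <- (occ$lon - anchor[1]) * sx
    yk <- (occ$lat - anchor[2]) * KM_PER_DEG
  }
  key <- paste(floor(xk / cell_km), floor(yk / cell_km))
  keep <- !duplicated(key)
  occurrence_set(occ$lon[keep], occ$lat[keep], occ$species, occ$crs_mode)
}

#' Extract presence and background samples from a stack
#'
#' Presence rows are the layer values at each occurrence's cell; points
#' falling outside the grid or on nodata cells are dropped (their count
#' is reported in the `n_dropped` field and a message). Background rows
#' are drawn uniformly without replacement from the valid cells.
#'
#' @param stack an `env_stack`.
#' @param occ an [occurrence_set()].
#' @param n_background number of background cells; `NULL` (default) uses
#'   `min(10000, number of valid cells)`. An explicit value larger than
#'   the number of valid cells is an error.
#' @param seed integer seed for the background draw.
#' @return object of class `sample_matrix`: `variable_names`, numeric
#'   matrix `x` (one row per sample), logical `is_presence`, `coords`
#'   (per-row lon/lat; cell centres for background rows), `n_dropped`.
#' @export
extract_samples <- function(stack, occ, n_background = NULL, seed = 1L) {
  stopifnot(inherits(stack, "env_stack"), inherits(occ, "occurrence_set"))
  tab <- stack_cell_table(stack)
  n_valid <- nrow(tab$X)
  if (is.null(n_background)) {
    n_background <- min(10000L, n_valid)
  } else if (n_background > n_valid) {
    stop(sprintf("n_background (%d) exceeds the %d valid cells",
                 n_background, n_valid))
  }
  g <- tab$geom
  rc <- locate_cells(g, occ$lon, occ$lat)
  lin <- ifelse(is.na(rc[, 1]), NA_integer_,
                (rc[, 2] - 1L) * g$nrows + rc[, 1])  # column-major index
  pres_vals <- matrix(NA_real_, length(occ$lon), length(stack$layers))
  inb <- !is.na(lin)
  for (j in seq_along(stack$layers))
    pres_vals[inb, j] <- stack$layers[[j]]$values[lin[inb]]
  ok <- inb & !apply(pres_vals, 1, anyNA)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("extract_samples: dropped %d occurrence(s) outside the grid or on nodata cells",
                    n_dropped))
  set.seed(seed)
  bg <- sample(n_valid, n_background, replace = FALSE)
  X <- rbind(pres_vals[ok, , drop = FALSE], tab$X[bg, , drop = FALSE])
  colnames(X) <- names(stack$layers)
  coords <- rbind(cbind(lon = occ$lon[ok], lat = occ$lat[ok]),
                  cbind(lon = tab$x[bg], lat = tab$y[bg]))
  structure(list(variable_names = names(stack$layers),
                 x = X,
                 is_presence = rep(c(TRUE, FALSE), c(sum(ok), n_background)),
                 coords = coords,
                 n_dropped = n_dropped,
                 crs_mode = stack$crs_mode),
            class = "sample_matrix")
}

#' @export
print.sample_matrix <- function(x, ...) {
  cat(sprintf("sample_matrix: %d presence + %d background rows, %d variables (%s)\n",
              sum(x$is_presence), sum(!x$is_presence),
              length(x$variable_names), paste(x$variable_names, collapse = ", ")))
  invisible(x)
}

#' Restrict a sample matrix to named variables
#'
#' Typically used to keep the collinearity-pruned variable set from
#' [correlation_filter()] before feature building.
#'
#' @param samples a `sample_matrix`.
#' @param vars variable names to keep (order defines column order).
#' @return the restricted `sample_matrix`.
#' @export
subset_samples <- function(samples, vars) {
  keep <- match(vars, samples$variable_names)
  if (anyNA(keep)) stop("unknown variable in subset_samples")
  samples$variable_names <- vars
  samples$x <- samples$x[, keep, drop = FALSE]
  samples
}

#' Prune collinear layers by pairwise Pearson correlation
#'
#' Pearson correlations are computed over all valid raster cells. Pairs
#' with `|r|` above the threshold are visited in decreasing `|r|`; when
#' both members are still retained, the lower-priority member is dropped.
#' After one pass no over-threshold pair remains among the retained set.
#'
#' Priority: larger value = kept. When `priority` is `NULL` and
#' `samples` is supplied, priority is the univariate maximum-entropy
#' training gain of each candidate (linear + quadratic features, ties
#' broken alphabetically); with neither, alphabetical order (earlier
#' names win).
#'
#' Constant (zero-variance) layers have undefined correlations and are
#' dropped up-front with a warning entry (`kept = NA`).
#'
#' @param stack an `env_stack`.
#' @param candidates candidate layer names (default all layers).
#' @param threshold absolute-correlation threshold (default 0.8).
#' @param priority optional named numeric priority vector.
#' @param samples optional [extract_samples()] result for gain-based
#'   priority.
#' @param rm regularization multiplier used for the univariate gain fits.
#' @return object of class `correlation_report`: `matrix`, `dropped`
#'   (data.frame dropped/kept/r), `retained`, `priority`.
#' @export
correlation_filter <- function(stack, candidates = names(stack$layers),
                               threshold = 0.8, priority = NULL,
                               samples = NULL, rm = 1) {
  stopifnot(inherits(stack, "env_stack"))
  if (length(candidates) < 2) stop("need at least two candidate layers")
  miss <- setdiff(candidates, names(stack$layers))
  if (length(miss)) stop(sprintf("unknown candidate layer(s): %s",
                                 paste(miss, collapse = ", ")))
  tab <- stack_cell_table(stack)
  X <- tab$X[, candidates, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  dropped <- data.frame(dropped = character(), kept = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  constant <- candidates[sds == 0 | !is.finite(sds)]
  if (length(constant)) {
    warning(sprintf("constant layer(s) dropped (correlation undefined): %s",
                    paste(constant, collapse = ", ")))
    dropped <- rbind(dropped, data.frame(dropped = constant, kept = NA_character_,
                                         r = NA_real_))
  }
  cand <- setdiff(candidates, constant)
  M <- stats::cor(X[, cand, drop = FALSE])

  if (is.null(priority)) {
    if (!is.null(samples)) {
      pri <- vapply(cand, function(v) {
        s1 <- subset_samples(samples, v)
        fs <- build_features(s1, classes = c("L", "Q"))
        fit_maxent(s1, fs, rm = rm, max_iterations = 200)$training_gain
      }, numeric(1))
    } else {
      pri <- -rank(cand)  # alphabetical: earlier name wins
      names(pri) <- cand
    }
  } else {
    if (!all(cand %in% names(priority)))
      stop("priority must name every candidate")
    pri <- priority[cand]
  }

  retained <- cand
  if (length(cand) >= 2) {
    pairs <- which(upper.tri(M) & abs(M) > threshold, arr.ind = TRUE)
    if (nrow(pairs)) {
      r <- M[pairs]
      o <- order(-abs(r))
      pairs <- pairs[o, , drop = FALSE]; r <- r[o]
      for (i in seq_len(nrow(pairs))) {
        a <- cand[pairs[i, 1]]; b <- cand[pairs[i, 2]]
        if (!(a %in% retained) || !(b %in% retained)) next
        # drop the lower-priority member; ties broken alphabetically
        # (the later name is dropped)
        drop <- if (pri[a] < pri[b] || (pri[a] == pri[b] && a > b)) a else b
        keep <- if (drop == a) b else a
        retained <- setdiff(retained, drop)
        dropped <- rbind(dropped, data.frame(dropped = drop, kept = keep,
                                             r = M[pairs[i, 1], pairs[i, 2]]))
      }
    }
  }
  if (length(retained) >= 2) {
    sub <- abs(M[retained, retained])
    stopifnot(max(sub[upper.tri(sub)]) <= threshold)
  }
  structure(list(matrix = M, dropped = dropped,
                 retained = retained, threshold = threshold,
                 priority = pri),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: %d retained (%s), %d dropped, threshold %g\n",
              length(x$retained), paste(x$retained, collapse = ", "),
              nrow(x$dropped), x$threshold))
  invisible(x)
}
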