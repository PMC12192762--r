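#' Default cross-correlation target for synthetic landscapes
#'
#' Modest background correlation (0.2) between all layers, plus two
#' engineered blocks that emulate real bioclim structure: annual
#' precipitation vs precipitation of the wettest month
#' (`bio12`~`bio13` = 0.9, deliberately above the 0.8 pruning threshold)
#' and annual mean temperature vs coldest-month minimum
#' (`bio1`~`bio6` = 0.7).
#'
#' @param layer_names layer names the matrix should cover.
#' @return symmetric positive-semidefinite correlation matrix.
#' @export
default_cross_correlation <- function(layer_names) {
  k <- length(layer_names)
  C <- matrix(0.2, k, k, dimnames = list(layer_names, layer_names))
  diag(C) <- 1
  set_pair <- function(C, a, b, r) {
    if (all(c(a, b) %in% layer_names)) { C[a, b] <- r; C[b, a] <- r }
    C
  }
  C <- set_pair(C, "bio12", "bio13", 0.9)
  C <- set_pair(C, "bio1", "bio6", 0.7)
  C
}

#' Default true niche coefficients
#'
#' The stated synthetic world: a unimodal (quadratic) niche driven by
#' annual precipitation (`bio12`) and coldest-month minimum temperature
#' (`bio6`) only, mirroring the dominance of those two variables in the
#' study system; every other layer is a non-informative correlate.
#' Coefficients apply to standardized (mean 0, sd 1) layer values.
#'
#' @param layer_names layer names.
#' @return named list of `c(linear, quadratic)` pairs.
#' @export
default_truth_coefficients <- function(layer_names) {
  co <- lapply(layer_names, function(n) c(linear = 0, quadratic = 0))
  names(co) <- layer_names
  if ("bio12" %in% layer_names) co[["bio12"]] <- c(linear = 0.9, quadratic = -1.4)
  if ("bio6" %in% layer_names) co[["bio6"]] <- c(linear = 1.3, quadratic = -1.0)
  co
}

#' Specification of a synthetic landscape
#'
#' Bundles everything [simulate_landscape()] needs: grid shape and
#' geometry, layer names, spatial smoothness (moving-average correlation
#' length, in cells), the target cross-correlation matrix between layers,
#' the true Gibbs log-density coefficients, the masked (nodata) fraction
#' and the seed.
#'
#' @param nrows,ncols grid shape (each must be >= 20).
#' @param xllcorner,yllcorner,cellsize grid geometry (degrees by default).
#' @param crs_mode `"geographic"` or `"planar"`.
#' @param layer_names layer names; default the eight retained bioclim
#'   variables (`alt`, `bio1`, `bio3`, `bio6`, `bio8`, `bio12`, `bio13`,
#'   `bio15`).
#' @param smoothness moving-average kernel width in cells (default 7).
#' @param cross_correlation target correlation matrix; must be symmetric,
#'   unit-diagonal and positive semidefinite.
#' @param truth_coefficients named list of `c(linear, quadratic)` per
#'   layer, on standardized layer values.
#' @param intercept intercept of the true log-density.
#' @param nodata_fraction fraction of cells masked out (default 0.05).
#' @param seed integer seed.
#' @return object of class `landscape_spec`.
#' @export
landscape_spec <- function(nrows = 50, ncols = 60,
                           xllcorner = 100, yllcorner = 25, cellsize = 0.05,
                           crs_mode = c("geographic", "planar"),
                           layer_names = c("alt", "bio1", "bio3", "bio6",
                                           "bio8", "bio12", "bio13", "bio15"),
                           smoothness = 7,
                           cross_correlation = default_cross_correlation(layer_names),
                           truth_coefficients = default_truth_coefficients(layer_names),
                           intercept = 0,
                           nodata_fraction = 0.05,
                           seed = 1L) {
  crs_mode <- match.arg(crs_mode)
  if (nrows < 20 || ncols < 20) stop("landscape shape must be at least 20 x 20")
  k <- length(layer_names)
  C <- cross_correlation
  if (!is.matrix(C) || nrow(C) != k || ncol(C) != k)
    stop("cross_correlation must be a k x k matrix")
  if (max(abs(C - t(C))) > 1e-12) stop("cross_correlation must be symmetric")
  if (max(abs(diag(C) - 1)) > 1e-12) stop("cross_correlation must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("cross_correlation target is not positive semidefinite")
  if (!all(names(truth_coefficients) %in% layer_names))
    stop("truth_coefficients name unknown layers")
  structure(list(nrows = nrows, ncols = ncols, xllcorner = xllcorner,
                 yllcorner = yllcorner, cellsize = cellsize,
                 crs_mode = crs_mode, layer_names = layer_names,
                 smoothness = as.integer(smoothness),
                 cross_correlation = C,
                 truth_coefficients = truth_coefficients,
                 intercept = intercept,
                 nodata_fraction = nodata_fraction,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# Square moving-average smoothing of a matrix, width w, edge-padded with
# extra noise so the crop has no edge artefacts.
smooth_field <- function(m, w) {
  if (w <= 1) return(m)
  k <- rep(1 / w, w)
  f <- stats::filter(m, k, sides = 2)              # smooth columns
  f <- t(stats::filter(t(f), k, sides = 2))        # smooth rows
  matrix(as.numeric(f), nrow(m), ncol(m))
}

#' Simulate a synthetic landscape with known truth
#'
#' Generates independent Gaussian noise fields, smooths each with a
#' square moving-average kernel (width = `smoothness` cells), mixes them
#' with the Cholesky factor of the target correlation matrix, and
#' standardizes each layer over the valid cells. The true (unnormalized)
#' log suitability is `intercept + sum_v a_v x_v + b_v x_v^2` on the
#' standardized layers; the normalized density is its softmax over valid
#' cells. A smooth auxiliary field masks the lowest `nodata_fraction`
#' of cells, emulating, e.g., water bodies.
#'
#' @param spec a [landscape_spec()].
#' @return list with `stack` (an `env_stack`) and `truth` (class
#'   `truth_surface`: grids `log_density` and `normalized_density`, plus
#'   the generating [landscape_spec()]).
#' @export
simulate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  nr <- spec$nrows; nc <- spec$ncols
  w <- spec$smoothness
  pad <- w + 1
  k <- length(spec$layer_names)
  # smoothed, standardized independent fields (generated on a padded
  # canvas, cropped to avoid moving-average edge effects)
  gen <- function() {
    m <- smooth_field(matrix(stats::rnorm((nr + 2 * pad) * (nc + 2 * pad)),
                             nr + 2 * pad, nc + 2 * pad), w)
    m <- m[pad + seq_len(nr), pad + seq_len(nc)]
    (m - mean(m)) / stats::sd(m)
  }
  Z <- vapply(seq_len(k), function(i) as.numeric(gen()), numeric(nr * nc))
  R <- chol(spec$cross_correlation + diag(1e-10, k))
  X <- Z %*% R
  mask_field <- gen()
  mask <- matrix(TRUE, nr, nc)
  if (spec$nodata_fraction > 0) {
    cut <- stats::quantile(mask_field, spec$nodata_fraction)
    mask <- matrix(as.numeric(mask_field) > cut, nr, nc)
  }
  grids <- list()
  for (i in seq_len(k)) {
    v <- X[, i]
    v <- (v - mean(v[mask])) / stats::sd(v[mask])
    m <- matrix(v, nr, nc)
    m[!mask] <- NA_real_
    grids[[spec$layer_names[i]]] <- env_grid(m, spec$xllcorner, spec$yllcorner,
                                             spec$cellsize)
  }
  stack <- stack_layers(grids, spec$crs_mode)

  logd <- matrix(spec$intercept, nr, nc)
  for (nm in names(spec$truth_coefficients)) {
    co <- spec$truth_coefficients[[nm]]
    x <- stack$layers[[nm]]$values
    x0 <- ifelse(is.na(x), 0, x)
    logd <- logd + co[1] * x0 + co[2] * x0^2
  }
  logd[!mask] <- NA_real_
  val <- logd[mask]
  dens <- exp(val - max(val))
  dens <- dens / sum(dens)
  nd <- matrix(NA_real_, nr, nc)
  nd[mask] <- dens
  truth <- structure(list(
    log_density = grid_like(stack$layers[[1]], logd),
    normalized_density = grid_like(stack$layers[[1]], nd),
    spec = spec), class = "truth_surface")
  list(stack = stack, truth = truth)
}

#' Sample presence points from a truth surface
#'
#' Cells are drawn (with replacement) with probability proportional to
#' the normalized true density; each draw is jittered uniformly within
#' its cell (half-width 0.5 cell), so coordinates are cell centre +
#' jitter and duplicates rarely coincide.
#'
#' @param truth a `truth_surface`.
#' @param stack the matching `env_stack` (geometry source).
#' @param n number of presence points.
#' @param seed integer seed.
#' @param species species label for the output.
#' @return an [occurrence_set()].
#' @export
sample_presences <- function(truth, stack, n, seed = 1L, species = "synthetic") {
  stopifnot(inherits(truth, "truth_surface"), n >= 1)
  g <- truth$normalized_density
  idx <- which(!is.na(g$values))
  if (length(idx) == 0) stop("truth surface is entirely masked")
  p <- g$values[idx]
  set.seed(seed)
  draw <- sample(length(idx), n, replace = TRUE, prob = p)
  cells <- idx[draw]
  cc <- cell_center_coords(g)
  jx <- stats::runif(n, -0.5, 0.5) * g$cellsize
  jy <- stats::runif(n, -0.5, 0.5) * g$cellsize
  occurrence_set(lon = cc$x[cells] + jx, lat = cc$y[cells] + jy,
                 species = species)
}

#' Build a future-scenario stack by shifting layers
#'
#' @param stack baseline `env_stack`.
#' @param deltas named list mapping layer names to an additive shift:
#'   either a scalar or a full matrix of the grid shape.
#' @param label scenario label stored on the result (e.g. "SSP5-8.5 2050s").
#' @return an `env_stack` with identical geometry and mask; layers not
#'   named in `deltas` are bit-identical to the input.
#' @export
make_future_scenario <- function(stack, deltas, label = "future") {
  stopifnot(inherits(stack, "env_stack"))
  unknown <- setdiff(names(deltas), names(stack$layers))
  if (length(unknown))
    stop(sprintf("unknown layer(s) in deltas: %s", paste(unknown, collapse = ", ")))
  out <- stack
  for (nm in names(deltas)) {
    d <- deltas[[nm]]
    g <- out$layers[[nm]]
    if (is.matrix(d)) {
      if (!all(dim(d) == dim(g$values))) stop("delta matrix shape mismatch")
      g$values <- g$values + d
    } else {
      g$values <- g$values + as.numeric(d)
    }
    out$layers[[nm]] <- g
  }
  attr(out, "scenario") <- label
  out
}

#' Write a simulated landscape to disk
#'
#' One `.asc` per layer plus a JSON manifest recording layer names, the
#' truth coefficients, intercept and seed, and a presence CSV if given.
#'
#' @param sim result of [simulate_landscape()].
#' @param dir output directory.
#' @param occurrences optional [occurrence_set()] to write alongside.
#' @return invisibly, the manifest path.
#' @export
write_landscape <- function(sim, dir, occurrences = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack_asc(sim$stack, dir)
  spec <- sim$truth$spec
  manifest <- list(layer_names = spec$layer_names,
                   truth_coefficients = spec$truth_coefficients,
                   intercept = spec$intercept,
                   seed = spec$seed,
                   crs_mode = spec$crs_mode)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(occurrences))
    write_occurrences(occurrences, file.path(dir, "occurrences.csv"))
  invisible(mpath)
}
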