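#' @useDynLib entsdm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Per-class default regularization tables (piecewise-linear in the
# number of presences), following the published MaxEnt defaults:
#   linear/quadratic/product: beta 1.0 below 10 presences, 0.2 at 30,
#     0.05 at 100+; hinge: constant 0.5; threshold: 2.0 down to 1.0 at
#     100+ presences. Values beyond the last knot are clamped.
BETA_TABLES <- list(
  lqp = list(m = c(0, 10, 30, 100), beta = c(1, 1, 0.2, 0.05)),
  hinge = list(m = c(0, 15), beta = c(0.5, 0.5)),
  threshold = list(m = c(0, 100), beta = c(2, 1))
)

beta_table_for <- function(feature_class) {
  switch(feature_class,
         L = , Q = , P = , linear = , quadratic = , product = "lqp",
         H = , hinge_fwd = , hinge_rev = "hinge",
         T = , threshold = "threshold",
         stop(sprintf("unknown feature class \"%s\"", feature_class)))
}

#' Default per-class regularization weight
#'
#' Piecewise-linear interpolation in the number of presence records over
#' the built-in per-class table (see `BETA_TABLES` in the source);
#' clamped at the table ends. The per-feature penalty used in
#' [fit_maxent()] is `rm * default_beta(class, m) * sd_j / sqrt(m)`,
#' with `sd_j` the feature's standard deviation over presence rows.
#'
#' @param feature_class one of `"L"`, `"Q"`, `"P"`, `"H"`, `"T"` (or the
#'   long feature-class names).
#' @param n_presence number of presence records (>= 1).
#' @return scalar weight.
#' @export
default_beta <- function(feature_class, n_presence) {
  stopifnot(n_presence >= 1)
  tb <- BETA_TABLES[[beta_table_for(feature_class)]]
  stats::approx(tb$m, tb$beta, xout = n_presence, rule = 2)$y
}

FEATURE_CLASS_LETTERS <- c("L", "Q", "H", "P", "T")

#' Build a maximum-entropy feature set
#'
#' Expands the sample variables into model features: `L` one linear
#' feature per variable, `Q` squares, `P` all unordered variable pairs,
#' `H` forward and reverse hinges at knots placed at equally spaced
#' background quantiles, `T` step (threshold) features at the same
#' knots. Every feature is min-max normalized to `[0, 1]` over the
#' training rows; features constant on the training data are dropped.
#'
#' @param samples a `sample_matrix` from [extract_samples()].
#' @param classes nonempty subset of `c("L","Q","P","H","T")`.
#' @param knots_per_variable hinge/threshold knots per variable
#'   (default 30).
#' @return object of class `feature_set`.
#' @export
build_features <- function(samples, classes = c("L", "Q"),
                           knots_per_variable = 30) {
  stopifnot(inherits(samples, "sample_matrix"))
  classes <- unique(match.arg(classes, FEATURE_CLASS_LETTERS, several.ok = TRUE))
  X <- samples$x
  vars <- samples$variable_names
  nv <- length(vars)
  vmin <- apply(X, 2, min); vmax <- apply(X, 2, max)
  bg <- X[!samples$is_presence, , drop = FALSE]

  defs <- list()
  add <- function(name, class, var1, var2 = NA_integer_, knot = NA_real_) {
    defs[[length(defs) + 1]] <<- data.frame(
      name = name, class = class, var1 = var1, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  }
  if ("L" %in% classes)
    for (v in seq_len(nv)) add(sprintf("L(%s)", vars[v]), "linear", v)
  if ("Q" %in% classes)
    for (v in seq_len(nv)) add(sprintf("Q(%s)", vars[v]), "quadratic", v)
  if ("P" %in% classes) {
    if (nv < 2) {
      warning("product features requested with a single variable; ignored")
    } else {
      for (v in seq_len(nv - 1)) for (u in (v + 1):nv)
        add(sprintf("P(%s*%s)", vars[v], vars[u]), "product", v, u)
    }
  }
  if (any(c("H", "T") %in% classes)) {
    kq <- (seq_len(knots_per_variable)) / (knots_per_variable + 1)
    for (v in seq_len(nv)) {
      ks <- unique(as.numeric(stats::quantile(bg[, v], kq, names = FALSE)))
      ks <- ks[ks > vmin[v] & ks < vmax[v]]
      for (k in ks) {
        if ("H" %in% classes) {
          add(sprintf("H(%s>%.6g)", vars[v], k), "hinge_fwd", v, knot = k)
          add(sprintf("H(%s<%.6g)", vars[v], k), "hinge_rev", v, knot = k)
        }
        if ("T" %in% classes)
          add(sprintf("T(%s>%.6g)", vars[v], k), "threshold", v, knot = k)
      }
    }
  }
  if (!length(defs)) stop("no features produced")
  defs <- do.call(rbind, defs)

  fs <- structure(list(definitions = defs, variable_names = vars,
                       var_min = vmin, var_max = vmax,
                       classes = classes,
                       knots_per_variable = knots_per_variable),
                  class = "feature_set")
  raw <- raw_feature_matrix(fs, X)
  fmin <- apply(raw, 2, min); fmax <- apply(raw, 2, max)
  keep <- (fmax - fmin) > 0
  fs$definitions <- defs[keep, , drop = FALSE]
  fs$fmin <- fmin[keep]; fs$fmax <- fmax[keep]
  rownames(fs$definitions) <- NULL
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d features (%s) over %d variables\n",
              nrow(x$definitions), paste(x$classes, collapse = ""),
              length(x$variable_names)))
  invisible(x)
}

# Unnormalized feature values for a variable matrix X (columns in
# fs$variable_names order).
raw_feature_matrix <- function(fs, X) {
  d <- fs$definitions
  out <- matrix(0, nrow(X), nrow(d))
  colnames(out) <- d$name
  for (j in seq_len(nrow(d))) {
    v <- X[, d$var1[j]]
    out[, j] <- switch(d$class[j],
      linear = v,
      quadratic = v^2,
      product = v * X[, d$var2[j]],
      hinge_fwd = pmax(0, v - d$knot[j]),
      hinge_rev = pmax(0, d$knot[j] - v),
      threshold = as.numeric(v > d$knot[j]),
      stop("unknown feature class"))
  }
  out
}

#' Evaluate normalized features on a variable matrix
#'
#' @param fs a `feature_set`.
#' @param X numeric matrix with columns in `fs$variable_names` order.
#' @param clamp clip variable values to the training range (and the
#'   normalized features to `[0, 1]`) before evaluation.
#' @return matrix of features in `[0, 1]` on training-range inputs.
#' @export
feature_matrix <- function(fs, X, clamp = FALSE) {
  stopifnot(inherits(fs, "feature_set"))
  if (clamp)
    for (v in seq_along(fs$variable_names))
      X[, v] <- pmin(pmax(X[, v], fs$var_min[v]), fs$var_max[v])
  raw <- raw_feature_matrix(fs, X)
  F <- sweep(sweep(raw, 2, fs$fmin, "-"), 2, fs$fmax - fs$fmin, "/")
  if (clamp) F <- pmin(pmax(F, 0), 1)
  F
}

# parent variable index/indices of each feature (list)
feature_parents <- function(fs) {
  d <- fs$definitions
  lapply(seq_len(nrow(d)), function(j)
    if (is.na(d$var2[j])) d$var1[j] else c(d$var1[j], d$var2[j]))
}

#' Fit an L1-regularized maximum-entropy model
#'
#' Minimizes the convex presence-background objective
#' `-mean_presence(lambda . f) + log sum_background exp(lambda . f) +
#' sum_j beta_j |lambda_j|` by cyclic coordinate descent (compiled;
#' monotone by construction). The per-feature penalty is
#' `beta_j = rm * default_beta(class_j, m) * sd_j / sqrt(m)` unless
#' `beta` is supplied explicitly.
#'
#' @param samples a `sample_matrix` (>= 1 presence and >= 2 background
#'   rows).
#' @param features a [build_features()] result.
#' @param rm regularization multiplier (the study tunes 0.1-4).
#' @param max_iterations maximum optimizer sweeps (default 5000).
#' @param tolerance convergence tolerance on the objective decrease per
#'   sweep (default 1e-5).
#' @param beta optional explicit per-feature penalty (scalar or vector),
#'   overriding the default schedule.
#' @param track_contributions record per-feature gain credits for
#'   [percent_contribution()].
#' @return object of class `maxent_model`: `features`, `lambda`, `rm`,
#'   `beta`, `log_Z`, `Z`, `entropy_H`, `training_gain` (regularized
#'   gain over uniform), `gain_unpenalized`, `objective`, `trace`,
#'   `iterations_run`, `converged`, `contributions`.
#' @export
fit_maxent <- function(samples, features, rm = 1, max_iterations = 5000,
                       tolerance = 1e-5, beta = NULL,
                       track_contributions = FALSE) {
  stopifnot(inherits(samples, "sample_matrix"), inherits(features, "feature_set"))
  m <- sum(samples$is_presence)
  nb <- sum(!samples$is_presence)
  if (m < 1) stop("no presence rows: cannot fit")
  if (nb < 2) stop("need at least 2 background rows")
  F <- feature_matrix(features, samples$x, clamp = FALSE)
  if (any(!is.finite(F))) stop("non-finite feature values")
  Fp <- F[samples$is_presence, , drop = FALSE]
  Fb <- F[!samples$is_presence, , drop = FALSE]
  pbar <- colMeans(Fp)
  p <- ncol(F)
  if (is.null(beta)) {
    sdp <- pmax(apply(Fp, 2, stats::sd), 1e-3)
    if (m == 1) sdp <- rep(1e-3, p)
    cls <- features$definitions$class
    tab <- vapply(cls, default_beta, numeric(1), n_presence = m)
    beta <- rm * tab * sdp / sqrt(m)
  } else {
    beta <- rep_len(beta, p)
  }
  fit <- maxent_cd_cpp(Fb, pbar, beta, numeric(p),
                       as.integer(max_iterations), tolerance,
                       isTRUE(track_contributions))
  lambda <- as.numeric(fit$lambda)
  names(lambda) <- features$definitions$name
  eta_b <- as.numeric(Fb %*% lambda)
  mx <- max(eta_b)
  log_Z <- mx + log(sum(exp(eta_b - mx)))
  q <- exp(eta_b - log_Z)
  H <- -sum(q * log(pmax(q, 1e-300)))
  gain_unpen <- log(nb) + sum(lambda * pbar) - log_Z
  contrib <- NULL
  if (isTRUE(track_contributions)) {
    contrib <- as.numeric(fit$credits)
    names(contrib) <- features$definitions$name
  }
  structure(list(features = features, lambda = lambda, rm = rm, beta = beta,
                 log_Z = log_Z, Z = exp(log_Z), entropy_H = H,
                 training_gain = log(nb) - fit$objective,
                 gain_unpenalized = gain_unpen,
                 objective = fit$objective,
                 trace = as.numeric(fit$trace),
                 iterations_run = fit$iterations,
                 converged = fit$converged,
                 contributions = contrib,
                 n_presence = m, n_background = nb),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(paste0("maxent_model: %d features (%d nonzero), rm = %g, ",
                     "gain = %.4f, H = %.4f, %d sweeps (%s)\n"),
              length(x$lambda), sum(x$lambda != 0), x$rm, x$training_gain,
              x$entropy_H, x$iterations_run,
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

# Scores for a plain variable matrix (columns in model variable order).
predict_samples <- function(model, X, clamp = TRUE) {
  F <- feature_matrix(model$features, X, clamp = clamp)
  eta <- as.numeric(F %*% model$lambda)
  lraw <- eta - model$log_Z
  list(eta = eta, raw = exp(lraw),
       logistic = stats::plogis(lraw + model$entropy_H))
}

#' Predict habitat suitability over a raster stack
#'
#' Features are evaluated with the training normalizers; with
#' `clamp = TRUE` (the default) variable values outside the training
#' range are clipped first. `raw(x) = exp(lambda . f(x)) / Z` sums to 1
#' over the training background; the logistic output is
#' `raw * e^H / (1 + raw * e^H)`, the usual [0, 1] suitability scale.
#'
#' @param object a `maxent_model`.
#' @param stack an `env_stack` supplying every model variable.
#' @param clamp clip projection values to the training range.
#' @param transform `"logistic"` (default) or `"raw"`.
#' @param ... unused.
#' @return object of class `suitability_map`: `grid` (an [env_grid()] of
#'   suitability), `transform`, `scenario` (taken from the stack's
#'   scenario attribute, if any).
#' @export
predict.maxent_model <- function(object, stack, clamp = TRUE,
                                 transform = c("logistic", "raw"), ...) {
  transform <- match.arg(transform)
  stopifnot(inherits(stack, "env_stack"))
  vars <- object$features$variable_names
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop(sprintf("stack is missing model layer(s): %s",
                 paste(miss, collapse = ", ")))
  tab <- stack_cell_table(stack)
  X <- tab$X[, vars, drop = FALSE]
  sc <- predict_samples(object, X, clamp = clamp)
  vals <- matrix(NA_real_, tab$geom$nrows, tab$geom$ncols)
  vals[tab$idx] <- if (transform == "logistic") sc$logistic else sc$raw
  structure(list(grid = grid_like(tab$geom, vals),
                 transform = transform,
                 scenario = attr(stack, "scenario", exact = TRUE)),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  r <- range(x$grid$values, na.rm = TRUE)
  cat(sprintf("suitability_map (%s%s): %d x %d, range [%.4f, %.4f]\n",
              x$transform,
              if (is.null(x$scenario)) "" else paste0(", ", x$scenario),
              x$grid$nrows, x$grid$ncols, r[1], r[2]))
  invisible(x)
}

#' Serialize a fitted model to a structured text (JSON) file
#'
#' Stores feature definitions, normalizers, coefficients, `log_Z`,
#' entropy and the regularization settings with full numeric precision,
#' sufficient to reload and predict identically (to double-precision
#' round-trip).
#'
#' @param model a `maxent_model`.
#' @param path output file.
#' @export
write_maxent_model <- function(model, path) {
  fs <- model$features
  payload <- list(
    package = "entsdm", format = "maxent_model", version = 1L,
    variable_names = fs$variable_names,
    var_min = fs$var_min, var_max = fs$var_max,
    classes = fs$classes, knots_per_variable = fs$knots_per_variable,
    definitions = fs$definitions, fmin = fs$fmin, fmax = fs$fmax,
    lambda = unname(model$lambda), beta = model$beta, rm = model$rm,
    log_Z = model$log_Z, entropy_H = model$entropy_H,
    training_gain = model$training_gain,
    gain_unpenalized = model$gain_unpenalized,
    objective = model$objective,
    iterations_run = model$iterations_run, converged = model$converged,
    n_presence = model$n_presence, n_background = model$n_background)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Reload a serialized model
#' @param path file written by [write_maxent_model()].
#' @return a `maxent_model` (without optimizer trace or contributions).
#' @export
read_maxent_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "maxent_model"))
    stop(sprintf("%s is not an entsdm model file", path))
  defs <- as.data.frame(p$definitions, stringsAsFactors = FALSE)
  defs$var2 <- as.integer(defs$var2)
  fs <- structure(list(definitions = defs,
                       variable_names = p$variable_names,
                       var_min = stats::setNames(p$var_min, p$variable_names),
                       var_max = stats::setNames(p$var_max, p$variable_names),
                       classes = p$classes,
                       knots_per_variable = p$knots_per_variable,
                       fmin = p$fmin, fmax = p$fmax),
                  class = "feature_set")
  lambda <- stats::setNames(p$lambda, defs$name)
  structure(list(features = fs, lambda = lambda, rm = p$rm, beta = p$beta,
                 log_Z = p$log_Z, Z = exp(p$log_Z), entropy_H = p$entropy_H,
                 training_gain = p$training_gain,
                 gain_unpenalized = p$gain_unpenalized,
                 objective = p$objective,
                 trace = NULL, iterations_run = p$iterations_run,
                 converged = p$converged, contributions = NULL,
                 n_presence = p$n_presence, n_background = p$n_background),
            class = "maxent_model")
}
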