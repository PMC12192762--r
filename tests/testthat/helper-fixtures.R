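# Shared fixtures and independent oracles. Everything is generated in
# code; no binary files.

# small planar stack of smooth, deterministic layers
tiny_stack <- function(nr = 6, nc = 5, layers = c("a", "b"),
                       crs_mode = "geographic", mask = NULL) {
  grids <- list()
  for (i in seq_along(layers)) {
    v <- outer(seq_len(nr), seq_len(nc), function(r, c) r * i + c / i)
    if (!is.null(mask)) v[mask] <- NA_real_
    grids[[layers[i]]] <- env_grid(v, xllcorner = 100, yllcorner = 30,
                                   cellsize = 0.1)
  }
  stack_layers(grids, crs_mode)
}

# sample_matrix built directly from matrices (bypasses rasters)
manual_samples <- function(xp, xb, vars = colnames(xp)) {
  if (is.null(vars)) vars <- paste0("v", seq_len(ncol(xp)))
  X <- rbind(xp, xb)
  colnames(X) <- vars
  structure(list(variable_names = vars, x = X,
                 is_presence = rep(c(TRUE, FALSE), c(nrow(xp), nrow(xb))),
                 coords = cbind(lon = numeric(nrow(X)), lat = numeric(nrow(X))),
                 n_dropped = 0L, crs_mode = "planar"),
            class = "sample_matrix")
}

# default synthetic world at test scale; seeds vary by test
default_sim <- function(seed = 1, nrows = 50, ncols = 60, n_presences = 250) {
  spec <- landscape_spec(nrows = nrows, ncols = ncols, seed = seed)
  sim <- simulate_landscape(spec)
  occ <- sample_presences(sim$truth, sim$stack, n = n_presences,
                          seed = seed + 1)
  samples <- extract_samples(sim$stack, occ, seed = seed + 2)
  list(sim = sim, occ = occ, samples = samples, spec = spec)
}

# ---- independent oracles ------------------------------------------------

# the penalized maximum-entropy objective, written independently of the
# package's optimizer (plain R, no shared code path)
oracle_objective <- function(lambda, pbar, Fbg, beta) {
  eta <- as.numeric(Fbg %*% lambda)
  m <- max(eta)
  -sum(lambda * pbar) + m + log(sum(exp(eta - m))) + sum(beta * abs(lambda))
}

# refined 2-D grid search minimizer of the same objective: a dense grid
# over [lo, hi]^2, iteratively zoomed; resolution well below 1e-4 after
# the stated refinements
oracle_grid_search <- function(pbar, Fbg, beta, lo = -5, hi = 5,
                               n_grid = 41, refinements = 8) {
  lo1 <- lo2 <- lo; hi1 <- hi2 <- hi
  best <- c(0, 0)
  for (it in seq_len(refinements)) {
    g1 <- seq(lo1, hi1, length.out = n_grid)
    g2 <- seq(lo2, hi2, length.out = n_grid)
    vals <- outer(g1, g2, Vectorize(function(a, b)
      oracle_objective(c(a, b), pbar, Fbg, beta)))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(g1[ij[1]], g2[ij[2]])
    s1 <- (hi1 - lo1) / (n_grid - 1); s2 <- (hi2 - lo2) / (n_grid - 1)
    lo1 <- best[1] - 2 * s1; hi1 <- best[1] + 2 * s1
    lo2 <- best[2] - 2 * s2; hi2 <- best[2] + 2 * s2
  }
  best
}

# random tiny fitting instance (<= 30 background cells, 2 features);
# presence means are a Gibbs reweighting of the background features, so
# the optimum is interior to the [-5, 5]^2 oracle box
tiny_instance <- function(seed) {
  set.seed(seed)
  n_bg <- sample(10:30, 1)
  Fbg <- matrix(runif(n_bg * 2), n_bg, 2)
  gamma <- runif(2, -2, 2)
  w <- exp(Fbg %*% gamma); w <- w / sum(w)
  pbar <- as.numeric(t(Fbg) %*% w)
  beta <- runif(2, 0.01, 0.1)
  list(Fbg = Fbg, pbar = pbar, beta = beta, gamma = gamma)
}

# fit the package model on a tiny instance by wrapping the instance in a
# sample_matrix/feature_set whose features are exactly the two columns
fit_tiny_instance <- function(inst, tolerance = 1e-12) {
  # presences: single pseudo presence row whose feature values equal pbar
  # (the objective depends on presences only through the feature means)
  xp <- matrix(inst$pbar, 1, 2)
  samples <- manual_samples(xp, inst$Fbg, vars = c("v1", "v2"))
  fs <- build_features(samples, classes = "L")
  # undo min-max normalization so model features equal the raw columns
  fs$fmin <- c(0, 0); fs$fmax <- c(1, 1)
  fit_maxent(samples, fs, beta = inst$beta, tolerance = tolerance,
             max_iterations = 5000)
}
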