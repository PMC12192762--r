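#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve for presence vs background scores, computed
#' from ranks with ties counted 0.5. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param presence_scores,background_scores nonempty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np < 1 || nb < 1) stop("both score vectors must be nonempty")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximum TSS and omission rate
#'
#' TSS(t) = sensitivity(t) + specificity(t) - 1, maximized over all
#' distinct observed scores as candidate thresholds (a cell counts as
#' predicted-presence when its score >= t). The omission rate is the
#' fraction of test presences scoring strictly below the omission
#' threshold, which defaults to the 10th percentile of the training
#' presence scores (OR10).
#'
#' @param presence_scores_test test presence scores.
#' @param background_scores background scores.
#' @param threshold explicit omission threshold; overrides
#'   `train_presence_scores`.
#' @param train_presence_scores training presence scores used for the
#'   default OR10 threshold.
#' @return list with `max_tss`, `tss_threshold`, `omission_rate`,
#'   `omission_threshold`.
#' @export
tss_and_omission <- function(presence_scores_test, background_scores,
                             threshold = NULL,
                             train_presence_scores = NULL) {
  stopifnot(length(presence_scores_test) >= 1, length(background_scores) >= 1)
  cand <- sort(unique(c(presence_scores_test, background_scores)))
  np <- length(presence_scores_test); nb <- length(background_scores)
  sp <- sort(presence_scores_test); sb <- sort(background_scores)
  # sens(t) = P(pres >= t), spec(t) = P(bg < t), via binary search counts
  sens <- 1 - (findInterval(cand, sp, left.open = TRUE) / np)
  spec <- findInterval(cand, sb, left.open = TRUE) / nb
  tss <- sens + spec - 1
  i <- which.max(tss)
  om_thr <- if (!is.null(threshold)) threshold
            else if (!is.null(train_presence_scores))
              as.numeric(stats::quantile(train_presence_scores, 0.10))
            else NA_real_
  om <- if (is.na(om_thr)) NA_real_ else mean(presence_scores_test < om_thr)
  list(max_tss = tss[i], tss_threshold = cand[i],
       omission_rate = om, omission_threshold = om_thr)
}

# sample_matrix restricted to given row indices
subset_rows <- function(samples, rows) {
  samples$x <- samples$x[rows, , drop = FALSE]
  samples$is_presence <- samples$is_presence[rows]
  samples$coords <- samples$coords[rows, , drop = FALSE]
  samples
}

#' Replicate-based model evaluation
#'
#' Repeats a random presence split (default 75/25, background shared
#' across replicates), fits a model per replicate, and scores it:
#' training and test AUC, test omission at the OR10 threshold, and the
#' maximum TSS over thresholds. When a stack is supplied the replicate
#' logistic maps are averaged cellwise into `averaged_map`.
#'
#' @param samples a `sample_matrix`.
#' @param features a `feature_set` built on the full samples.
#' @param rm regularization multiplier.
#' @param n_replicates number of random splits (default 10).
#' @param test_fraction presence fraction held out per replicate
#'   (default 0.25; 0 disables test metrics).
#' @param seed integer; replicate r uses seed `seed + r`.
#' @param stack optional `env_stack` for map averaging.
#' @param keep_models keep the per-replicate models (needed to project
#'   averaged maps onto other scenarios).
#' @param max_iterations,tolerance passed to [fit_maxent()].
#' @return object of class `eval_report`: `replicates` (per-replicate
#'   data.frame), `summary` (mean/sd), `averaged_map`, `models`,
#'   `n_replicates`, `test_fraction`.
#' @export
evaluate_replicates <- function(samples, features, rm = 1, n_replicates = 10,
                                test_fraction = 0.25, seed = 1L,
                                stack = NULL, keep_models = FALSE,
                                max_iterations = 5000, tolerance = 1e-5) {
  stopifnot(inherits(samples, "sample_matrix"))
  pres <- which(samples$is_presence)
  bg <- which(!samples$is_presence)
  m <- length(pres)
  n_test <- floor(m * test_fraction)
  if (test_fraction > 0 && (n_test < 1 || m - n_test < 1))
    stop(sprintf("too few presences (%d) for a %.0f%% test split",
                 m, 100 * test_fraction))
  rows <- vector("list", n_replicates)
  maps <- NULL
  models <- if (keep_models) vector("list", n_replicates) else NULL
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    test_idx <- if (n_test > 0) sample(pres, n_test) else integer()
    train_idx <- setdiff(pres, test_idx)
    fit <- fit_maxent(subset_rows(samples, c(train_idx, bg)), features,
                      rm = rm, max_iterations = max_iterations,
                      tolerance = tolerance)
    sc <- predict_samples(fit, samples$x)$logistic
    train_auc <- auc(sc[train_idx], sc[bg])
    if (n_test > 0) {
      test_auc <- auc(sc[test_idx], sc[bg])
      to <- tss_and_omission(sc[test_idx], sc[bg],
                             train_presence_scores = sc[train_idx])
      test_omission <- to$omission_rate
      max_tss <- to$max_tss; tss_thr <- to$tss_threshold
    } else {
      test_auc <- NA_real_; test_omission <- NA_real_
      max_tss <- NA_real_; tss_thr <- NA_real_
    }
    rows[[r]] <- data.frame(replicate = r, train_auc = train_auc,
                            test_auc = test_auc,
                            test_omission = test_omission,
                            max_tss = max_tss, tss_threshold = tss_thr,
                            gain = fit$training_gain,
                            n_nonzero = sum(fit$lambda != 0))
    if (!is.null(stack)) {
      mp <- predict(fit, stack, transform = "logistic")
      maps <- if (is.null(maps)) mp$grid$values / n_replicates
              else maps + mp$grid$values / n_replicates
    }
    if (keep_models) models[[r]] <- fit
  }
  reps <- do.call(rbind, rows)
  num <- c("train_auc", "test_auc", "test_omission", "max_tss", "gain")
  summ <- data.frame(metric = num,
                     mean = vapply(num, function(k) mean(reps[[k]]), 0),
                     sd = vapply(num, function(k) stats::sd(reps[[k]]), 0))
  avg <- NULL
  if (!is.null(stack)) {
    g <- stack$layers[[1]]
    avg <- structure(list(grid = grid_like(g, maps), transform = "logistic",
                          scenario = attr(stack, "scenario", exact = TRUE)),
                     class = "suitability_map")
  }
  structure(list(replicates = reps, summary = summ, averaged_map = avg,
                 models = models, n_replicates = n_replicates,
                 test_fraction = test_fraction, rm = rm, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d replicates, test fraction %.2f\n",
              x$n_replicates, x$test_fraction))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Project replicate models onto a (scenario) stack and average
#'
#' Cellwise mean of the replicate logistic maps, the projection analogue
#' of `averaged_map` from [evaluate_replicates()] (fit with
#' `keep_models = TRUE`).
#'
#' @param models list of `maxent_model` replicates.
#' @param stack the `env_stack` to project onto.
#' @return a logistic `suitability_map`.
#' @export
average_projection <- function(models, stack) {
  acc <- NULL
  for (fit in models) {
    mp <- predict(fit, stack, transform = "logistic")
    acc <- if (is.null(acc)) mp$grid$values / length(models)
           else acc + mp$grid$values / length(models)
  }
  structure(list(grid = grid_like(stack$layers[[1]], acc),
                 transform = "logistic",
                 scenario = attr(stack, "scenario", exact = TRUE)),
            class = "suitability_map")
}

#' Percent contribution of each variable
#'
#' During coordinate descent every accepted update's gain increase is
#' credited to the updated feature; credits roll up to the feature's
#' parent variable (product features split equally between their two
#' parents) and are rescaled to sum to 100.
#'
#' @param model a `maxent_model` fitted with `track_contributions = TRUE`.
#' @return named numeric vector (percent per variable, sums to 100).
#' @export
percent_contribution <- function(model) {
  stopifnot(inherits(model, "maxent_model"))
  if (is.null(model$contributions))
    stop("model was fitted without contribution tracking; refit with track_contributions = TRUE")
  fs <- model$features
  parents <- feature_parents(fs)
  out <- stats::setNames(numeric(length(fs$variable_names)), fs$variable_names)
  cr <- model$contributions
  for (j in seq_along(cr)) {
    pv <- parents[[j]]
    out[pv] <- out[pv] + cr[j] / length(pv)
  }
  tot <- sum(out)
  if (tot <= 0) return(out * 0)
  100 * out / tot
}

#' Permutation importance of each variable
#'
#' Each variable's column is shuffled across all presence + background
#' rows, the training AUC is recomputed, and the importance is the AUC
#' drop (floored at 0), normalized to sum to 100. The drop is averaged
#' over `n_shuffles` independent shuffles to stabilize the estimate.
#'
#' @param model a `maxent_model`.
#' @param samples the `sample_matrix` the model was fitted on.
#' @param seed integer seed for the shuffles.
#' @param n_shuffles shuffles averaged per variable (default 5).
#' @return named numeric vector (percent per variable).
#' @export
permutation_importance <- function(model, samples, seed = 1L,
                                   n_shuffles = 5L) {
  stopifnot(inherits(model, "maxent_model"), inherits(samples, "sample_matrix"))
  pres <- samples$is_presence
  sc0 <- predict_samples(model, samples$x)$logistic
  auc0 <- auc(sc0[pres], sc0[!pres])
  vars <- model$features$variable_names
  set.seed(seed)
  drops <- vapply(seq_along(vars), function(v) {
    d <- vapply(seq_len(n_shuffles), function(i) {
      X <- samples$x
      X[, v] <- X[sample(nrow(X)), v]
      sc <- predict_samples(model, X)$logistic
      auc0 - auc(sc[pres], sc[!pres])
    }, numeric(1))
    max(0, mean(d))
  }, numeric(1))
  names(drops) <- vars
  tot <- sum(drops)
  if (tot <= 0) return(drops * 0)
  100 * drops / tot
}

# feature_set restricted to a subset of feature rows
subset_features <- function(fs, keep) {
  fs$definitions <- fs$definitions[keep, , drop = FALSE]
  rownames(fs$definitions) <- NULL
  fs$fmin <- fs$fmin[keep]; fs$fmax <- fs$fmax[keep]
  fs
}

#' Jackknife variable-importance gains
#'
#' For each variable: the training gain of a model fit with only that
#' variable's features, the gain without any of its features, and the
#' full-model gain (regularized gain over uniform in all three).
#' Product features belong to both parents: they are included in
#' neither "only" model and excluded from both parents' "without"
#' models.
#'
#' @param samples a `sample_matrix`.
#' @param features full `feature_set`.
#' @param rm regularization multiplier shared by all fits.
#' @param variables variables to jackknife (default all, >= 2 required).
#' @param max_iterations,tolerance passed to [fit_maxent()].
#' @return data.frame with `variable`, `gain_with_only`, `gain_without`,
#'   `gain_full`.
#' @export
jackknife_gains <- function(samples, features, rm = 1, variables = NULL,
                            max_iterations = 5000, tolerance = 1e-5) {
  vars <- features$variable_names
  if (is.null(variables)) variables <- vars
  if (length(variables) < 2) stop("jackknife needs at least two variables")
  parents <- feature_parents(features)
  full <- fit_maxent(samples, features, rm = rm,
                     max_iterations = max_iterations, tolerance = tolerance)
  res <- lapply(variables, function(vn) {
    v <- match(vn, vars)
    only_idx <- vapply(parents, function(p) identical(p, v), logical(1))
    without_idx <- vapply(parents, function(p) !(v %in% p), logical(1))
    g_only <- if (any(only_idx))
      fit_maxent(samples, subset_features(features, only_idx), rm = rm,
                 max_iterations = max_iterations,
                 tolerance = tolerance)$training_gain else 0
    g_without <- if (any(without_idx))
      fit_maxent(samples, subset_features(features, without_idx), rm = rm,
                 max_iterations = max_iterations,
                 tolerance = tolerance)$training_gain else 0
    data.frame(variable = vn, gain_with_only = g_only,
               gain_without = g_without, gain_full = full$training_gain)
  })
  do.call(rbind, res)
}

#' Marginal response curve of a variable
#'
#' Sweeps the target variable over `n_points` equally spaced values of
#' its training range while every other variable is held at its
#' presence-sample mean, and evaluates the model's logistic output.
#'
#' @param model a `maxent_model`.
#' @param samples the fitting `sample_matrix` (source of presence means).
#' @param variable variable name.
#' @param n_points number of sweep points (default 101).
#' @return data.frame with `value` and `suitability` (logistic, in
#'   `[0, 1]`).
#' @export
response_curve <- function(model, samples, variable, n_points = 101) {
  fs <- model$features
  v <- match(variable, fs$variable_names)
  if (is.na(v)) stop(sprintf("variable \"%s\" is not in the model", variable))
  mu <- colMeans(samples$x[samples$is_presence, , drop = FALSE])
  sweep_vals <- seq(fs$var_min[v], fs$var_max[v], length.out = n_points)
  X <- matrix(mu, n_points, length(mu), byrow = TRUE)
  colnames(X) <- fs$variable_names
  X[, v] <- sweep_vals
  data.frame(value = sweep_vals,
             suitability = predict_samples(model, X)$logistic)
}
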