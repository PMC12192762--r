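#' Build the tuning candidate grid
#'
#' Regularization multipliers run from `rm_min` to `rm_max` in steps of
#' `rm_step` (inclusive, decimal-exact), crossed with every nonempty
#' subset of the feature classes (canonical class order L, Q, H, P, T;
#' subsets enumerated in binary order). With the defaults this yields
#' 40 x 31 = 1240 candidates.
#'
#' @param rm_min,rm_max,rm_step regularization-multiplier grid
#'   (defaults 0.1, 4.0, 0.1).
#' @param classes feature classes (default all five).
#' @return data.frame with `feature_classes` (subset label, e.g. "LQH")
#'   and `rm`.
#' @export
candidate_grid <- function(rm_min = 0.1, rm_max = 4.0, rm_step = 0.1,
                           classes = c("L", "Q", "H", "P", "T")) {
  if (rm_step <= 0) stop("rm_step must be > 0")
  if (length(classes) < 1) stop("empty feature-class set")
  classes <- FEATURE_CLASS_LETTERS[FEATURE_CLASS_LETTERS %in% classes]
  if (length(classes) < 1) stop("no valid feature classes")
  n <- round((rm_max - rm_min) / rm_step)
  rms <- round(rm_min + (0:n) * rm_step, 10)
  rms <- rms[rms <= rm_max + 1e-12]
  k <- length(classes)
  labels <- vapply(seq_len(2^k - 1), function(bits)
    paste(classes[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0], collapse = ""),
    character(1))
  out <- expand.grid(rm = rms, feature_classes = labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("feature_classes", "rm")]
  rownames(out) <- NULL
  out
}

#' Sample-size-corrected AIC of a fitted model
#'
#' The log-likelihood is computed from the raw output renormalized over
#' all valid landscape cells: `ln L = sum over presences of
#' ln(exp(eta_x) / sum_cells exp(eta))`. `k` is the number of nonzero
#' coefficients; `AICc = 2k - 2 ln L + 2k(k+1)/(n-k-1)`, and `+Inf`
#' when `n - k - 1 <= 0` or a presence has zero raw score.
#'
#' @param model a `maxent_model`.
#' @param presence_rows numeric matrix of presence environment values
#'   (columns in model variable order), or a `sample_matrix` whose
#'   presence rows are used.
#' @param landscape_stack `env_stack` defining the normalization domain.
#' @return AICc value.
#' @export
aicc <- function(model, presence_rows, landscape_stack) {
  stopifnot(inherits(model, "maxent_model"))
  if (inherits(presence_rows, "sample_matrix"))
    presence_rows <- presence_rows$x[presence_rows$is_presence, , drop = FALSE]
  n <- nrow(presence_rows)
  if (n < 1) stop("no presence rows")
  k <- sum(model$lambda != 0)
  if (n - k - 1 <= 0) return(Inf)
  vars <- model$features$variable_names
  tab <- stack_cell_table(landscape_stack)
  eta_land <- predict_samples(model, tab$X[, vars, drop = FALSE])$eta
  mx <- max(eta_land)
  lse_land <- mx + log(sum(exp(eta_land - mx)))
  eta_pres <- predict_samples(model, presence_rows[, vars, drop = FALSE])$eta
  lnL <- sum(eta_pres - lse_land)
  if (!is.finite(lnL)) return(Inf)
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

#' Score every candidate of a tuning grid
#'
#' For each (feature classes, rm) candidate: a reduced number of
#' replicate splits (default 3, shared across candidates) provides the
#' mean test omission, mean test AUC and the significance flag (mean
#' test AUC above 0.5 by at least two standard errors); a full-data fit
#' provides AICc over the landscape and the nonzero-coefficient count.
#' `delta_aicc` is computed after all candidates are scored.
#'
#' @param samples a `sample_matrix` (already collinearity-pruned).
#' @param grid a [candidate_grid()] data.frame.
#' @param landscape_stack `env_stack` for the AICc normalization.
#' @param knots_per_variable hinge/threshold knots (default 30).
#' @param n_replicates replicate splits per candidate (default 3).
#' @param test_fraction held-out presence fraction (default 0.25).
#' @param seed integer seed (splits are identical across candidates).
#' @param max_iterations,tolerance passed to [fit_maxent()].
#' @return data.frame of candidate records, class `candidate_table`.
#' @export
evaluate_candidates <- function(samples, grid, landscape_stack,
                                knots_per_variable = 30, n_replicates = 3,
                                test_fraction = 0.25, seed = 1L,
                                max_iterations = 500, tolerance = 1e-4) {
  stopifnot(inherits(samples, "sample_matrix"), nrow(grid) >= 1)
  rows <- vector("list", nrow(grid))
  feats_cache <- list()
  for (i in seq_len(nrow(grid))) {
    label <- grid$feature_classes[i]; rm <- grid$rm[i]
    if (is.null(feats_cache[[label]]))
      feats_cache[[label]] <- build_features(
        samples, classes = strsplit(label, "")[[1]],
        knots_per_variable = knots_per_variable)
    features <- feats_cache[[label]]
    ev <- evaluate_replicates(samples, features, rm = rm,
                              n_replicates = n_replicates,
                              test_fraction = test_fraction, seed = seed,
                              max_iterations = max_iterations,
                              tolerance = tolerance)
    full <- fit_maxent(samples, features, rm = rm,
                       max_iterations = max_iterations, tolerance = tolerance)
    a <- aicc(full, samples, landscape_stack)
    mean_auc <- mean(ev$replicates$test_auc)
    se_auc <- stats::sd(ev$replicates$test_auc) / sqrt(n_replicates)
    signif_flag <- if (!is.finite(se_auc) || se_auc == 0) mean_auc > 0.5
                   else (mean_auc - 0.5) > 2 * se_auc
    rows[[i]] <- data.frame(
      feature_classes = label, rm = rm, aicc = a,
      mean_test_omission = mean(ev$replicates$test_omission),
      mean_test_auc = mean_auc, se_test_auc = se_auc,
      significant = signif_flag,
      n_nonzero = sum(full$lambda != 0),
      training_gain = full$training_gain)
  }
  out <- do.call(rbind, rows)
  fin <- is.finite(out$aicc)
  out$delta_aicc <- if (any(fin)) out$aicc - min(out$aicc[fin]) else NA_real_
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Select the optimal candidate
#'
#' Eligible candidates have mean test omission below 5% and
#' `delta_aicc <= 2`; the winner is the eligible candidate with the
#' smallest AICc (ties: smaller omission, then fewer nonzero
#' coefficients, then lexicographic feature classes, then smaller rm).
#' If nothing is eligible the omission condition is relaxed
#' (`delta_aicc <= 2` only) and the returned record carries
#' `relaxed = TRUE`.
#'
#' @param candidates a `candidate_table` (or compatible data.frame).
#' @return the winning one-row data.frame with an added `relaxed` flag.
#' @export
select_model <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  if (!any(is.finite(candidates$aicc)))
    stop("all candidates have infinite AICc")
  elig <- which(candidates$mean_test_omission < 0.05 &
                candidates$delta_aicc <= 2)
  relaxed <- FALSE
  if (!length(elig)) {
    relaxed <- TRUE
    elig <- which(candidates$delta_aicc <= 2)
  }
  sub <- candidates[elig, , drop = FALSE]
  o <- order(sub$aicc, sub$mean_test_omission, sub$n_nonzero,
             sub$feature_classes, sub$rm)
  winner <- sub[o[1], , drop = FALSE]
  winner$relaxed <- relaxed
  rownames(winner) <- NULL
  winner
}
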