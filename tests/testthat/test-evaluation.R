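test_that("auc matches hand-enumerated cases and monotone invariance", {
  expect_equal(auc(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_equal(auc(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  # enumerate the 4 pairs: 0.9>0.5, 0.9>0.1, 0.4<0.5, 0.4>0.1 -> 3/4
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(auc(numeric(), 1), "nonempty")

  # invariance under strictly monotone transforms (property)
  set.seed(71)
  for (i in 1:5) {
    p <- rnorm(40, 1); b <- rnorm(60)
    a0 <- auc(p, b)
    expect_equal(auc(exp(p), exp(b)), a0)
    expect_equal(auc(stats::plogis(3 * p - 1), stats::plogis(3 * b - 1)), a0)
  }
})

test_that("tss_and_omission maximizes TSS and counts omissions", {
  # perfect separation
  r <- tss_and_omission(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(r$max_tss, 1.0)
  # hand-counted omission at a given threshold
  r2 <- tss_and_omission(c(0.1, 0.6, 0.7), c(0.5, 0.4), threshold = 0.5)
  expect_equal(r2$omission_rate, 1 / 3)
  # class-independent scores -> max TSS near 0
  set.seed(73)
  r3 <- tss_and_omission(runif(1000), runif(1000))
  expect_lte(r3$max_tss, 0.1)
  # OR10 default threshold comes from training presences
  r4 <- tss_and_omission(c(0.05, 0.5, 0.9), c(0.2, 0.3),
                         train_presence_scores = seq(0.1, 1, by = 0.1))
  expect_equal(r4$omission_threshold,
               as.numeric(stats::quantile(seq(0.1, 1, by = 0.1), 0.1)))
  expect_equal(r4$omission_rate, 1 / 3)
})

test_that("evaluate_replicates: determinism, averaging, degenerate split", {
  d <- default_sim(seed = 79, nrows = 25, ncols = 25, n_presences = 60)
  fs <- build_features(d$samples, c("L", "Q"))

  ev1 <- evaluate_replicates(d$samples, fs, rm = 1, n_replicates = 2,
                             seed = 5, stack = d$sim$stack, keep_models = TRUE)
  ev2 <- evaluate_replicates(d$samples, fs, rm = 1, n_replicates = 2,
                             seed = 5, stack = d$sim$stack)
  expect_identical(ev1$replicates, ev2$replicates)
  expect_equal(ev1$averaged_map$grid$values, ev2$averaged_map$grid$values)

  # averaged map is the cellwise mean of the replicate maps
  m1 <- predict(ev1$models[[1]], d$sim$stack)$grid$values
  m2 <- predict(ev1$models[[2]], d$sim$stack)$grid$values
  expect_equal(ev1$averaged_map$grid$values, (m1 + m2) / 2, tolerance = 1e-12)
  expect_true(all(ev1$averaged_map$grid$values >= 0 &
                  ev1$averaged_map$grid$values <= 1, na.rm = TRUE))

  # train-only evaluation flags test metrics absent
  ev0 <- evaluate_replicates(d$samples, fs, rm = 1, n_replicates = 1,
                             test_fraction = 0)
  expect_false(is.na(ev0$replicates$train_auc))
  expect_true(is.na(ev0$replicates$test_auc))
  expect_true(is.na(ev0$replicates$test_omission))

  # too few presences for a 25% split
  few <- subset_rows(d$samples, c(which(d$samples$is_presence)[1:3],
                                  which(!d$samples$is_presence)))
  expect_error(evaluate_replicates(few, fs, n_replicates = 1), "too few")
})

test_that("percent_contribution sums to 100 and isolates drivers", {
  d <- default_sim(seed = 83, nrows = 25, ncols = 25, n_presences = 100)
  fs <- build_features(d$samples, c("L", "Q"))
  m <- fit_maxent(d$samples, fs, rm = 1, track_contributions = TRUE)
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 0.1)
  expect_true(all(names(pc) == d$samples$variable_names))

  # tracking disabled -> error
  m0 <- fit_maxent(d$samples, fs, rm = 1)
  expect_error(percent_contribution(m0), "tracking")

  # single-variable model -> 100%
  s1 <- entsdm:::subset_samples(d$samples, "bio12")
  m1 <- fit_maxent(s1, build_features(s1, c("L", "Q")), rm = 1,
                   track_contributions = TRUE)
  expect_equal(unname(percent_contribution(m1)), 100, tolerance = 1e-9)

  # a variable never updated (zero lambda throughout) contributes 0%:
  # with presences == background every coordinate stays at zero
  set.seed(7)
  xb <- matrix(runif(60), 30, 2)
  sbal <- manual_samples(xb, xb)
  mbal <- fit_maxent(sbal, build_features(sbal, c("L", "Q")), rm = 1,
                     track_contributions = TRUE)
  expect_true(all(percent_contribution(mbal) == 0))
})

test_that("permutation_importance: zeros, single-variable, stability", {
  # ~5000 rows: 2150 presences + all ~2850 valid cells of the default grid
  d <- default_sim(seed = 89, n_presences = 2150)
  fs <- build_features(d$samples, c("L", "Q"))
  m <- fit_maxent(d$samples, fs, rm = 1)
  pi1 <- permutation_importance(m, d$samples, seed = 1)
  expect_equal(sum(pi1), 100, tolerance = 0.1)

  # variable with all-zero coefficients has zero importance
  zl <- tapply(m$lambda == 0, fs$definitions$var1, all)
  for (v in names(which(zl)))
    expect_equal(unname(pi1[as.integer(v)]), 0)

  # single-variable model scores 100
  s1 <- entsdm:::subset_samples(d$samples, "bio6")
  m1 <- fit_maxent(s1, build_features(s1, c("L", "Q")), rm = 1)
  expect_equal(unname(permutation_importance(m1, s1)), 100)

  # two different shuffle seeds agree within 2 percentage points
  pi2 <- permutation_importance(m, d$samples, seed = 2)
  expect_lt(max(abs(pi1 - pi2)), 2)
})

test_that("jackknife gains satisfy the nesting property", {
  d <- default_sim(seed = 97, nrows = 25, ncols = 25, n_presences = 100)
  fs <- build_features(d$samples, c("L", "Q"))
  jk <- jackknife_gains(d$samples, fs, rm = 1)
  expect_true(all(jk$gain_without <= jk$gain_full + 1e-6))
  expect_true(all(jk$gain_with_only >= -1e-12))
  # the truth drivers carry most solo gain
  expect_gt(jk$gain_with_only[jk$variable == "bio12"],
            jk$gain_with_only[jk$variable == "bio3"])
})

test_that("jackknife: uninformative alone ~ 0; duplicated layer barely matters", {
  # null landscape: truth uniform, so no variable should carry gain
  spec0 <- landscape_spec(nrows = 25, ncols = 25, truth_coefficients = list(),
                          seed = 7)
  sim0 <- simulate_landscape(spec0)
  occ0 <- sample_presences(sim0$truth, sim0$stack, 150, seed = 8)
  s0 <- extract_samples(sim0$stack, occ0, seed = 9)
  fs0 <- build_features(s0, c("L", "Q"))
  jk0 <- jackknife_gains(s0, fs0, rm = 1)
  expect_true(all(jk0$gain_with_only <= 0.05))

  # duplicate of an informative variable: dropping one copy loses < 5% gain
  d <- default_sim(seed = 101, nrows = 25, ncols = 25, n_presences = 150)
  s <- entsdm:::subset_samples(d$samples, c("bio12", "bio6"))
  s$variable_names <- c(s$variable_names, "bio12_copy")
  s$x <- cbind(s$x, bio12_copy = s$x[, "bio12"])
  fs <- build_features(s, c("L", "Q"))
  jk <- jackknife_gains(s, fs, rm = 1)
  full <- jk$gain_full[1]
  wo <- jk$gain_without[jk$variable == "bio12_copy"]
  expect_gt(wo, 0.95 * full)
})

test_that("response curves sweep the training range at presence means", {
  d <- default_sim(seed = 103, nrows = 25, ncols = 25, n_presences = 150)
  fs <- build_features(d$samples, c("L", "Q"))
  m <- fit_maxent(d$samples, fs, rm = 1)
  rc <- response_curve(m, d$samples, "bio12", n_points = 11)
  expect_equal(nrow(rc), 11L)
  expect_equal(rc$value[1], m$features$var_min[["bio12"]])
  expect_equal(rc$value[11], m$features$var_max[["bio12"]])
  expect_true(all(rc$suitability >= 0 & rc$suitability <= 1))
  expect_error(response_curve(m, d$samples, "nope"), "not in the model")

  # positive linear-only model on one variable -> monotone curve
  s1 <- entsdm:::subset_samples(d$samples, "bio6")
  m1 <- fit_maxent(s1, build_features(s1, "L"), rm = 0.5)
  rc1 <- response_curve(m1, s1, "bio6", n_points = 21)
  expect_true(all(diff(rc1$suitability) >= 0) ||
              all(diff(rc1$suitability) <= 0))

  # quadratic truth: fitted argmax close to the true optimum of bio12
  # true log-density 0.9 x - 1.4 x^2 peaks at x* = 0.9 / 2.8
  rc2 <- response_curve(m, d$samples, "bio12", n_points = 101)
  xstar_true <- 0.9 / (2 * 1.4)
  xstar_fit <- rc2$value[which.max(rc2$suitability)]
  rng <- diff(range(rc2$value))
  expect_lt(abs(xstar_fit - xstar_true), 0.15 * rng)
})
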