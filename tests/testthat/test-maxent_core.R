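test_that("build_features produces the contracted feature counts", {
  set.seed(1)
  s <- manual_samples(matrix(runif(30), 10, 3), matrix(runif(150), 50, 3),
                      vars = c("x", "y", "z"))
  expect_equal(nrow(build_features(s, "L")$definitions), 3L)
  expect_equal(nrow(build_features(s, c("L", "Q", "P"))$definitions), 9L)
  fs_h <- build_features(manual_samples(matrix(runif(20), 10, 2),
                                        matrix(runif(100), 50, 2)),
                         "H", knots_per_variable = 10)
  expect_equal(nrow(fs_h$definitions), 40L)  # 2 dirs x 2 vars x 10 knots
  expect_true(all(fs_h$definitions$knot > 0 & fs_h$definitions$knot < 1))
  expect_warning(build_features(manual_samples(matrix(runif(5), 5, 1),
                                               matrix(runif(20), 20, 1)),
                                c("L", "P")),
                 "single variable")
})

test_that("features are min-max normalized to [0,1] on training data", {
  set.seed(2)
  s <- manual_samples(matrix(rnorm(40, 5, 2), 20, 2),
                      matrix(rnorm(200, 5, 2), 100, 2))
  fs <- build_features(s, c("L", "Q", "P", "H", "T"), knots_per_variable = 7)
  F <- feature_matrix(fs, s$x)
  expect_gte(min(F), 0)
  expect_lte(max(F), 1)
  expect_true(all(apply(F, 2, max) == 1))
  expect_true(all(apply(F, 2, min) == 0))
})

test_that("default_beta interpolates, clamps and is non-increasing", {
  # table knots are returned exactly
  expect_equal(default_beta("L", 10), 1)
  expect_equal(default_beta("Q", 30), 0.2)
  expect_equal(default_beta("P", 100), 0.05)
  expect_equal(default_beta("T", 100), 1)
  expect_equal(default_beta("H", 8), 0.5)
  # clamped above the largest knot
  expect_equal(default_beta("L", 10000), 0.05)
  expect_equal(default_beta("T", 10000), 1)
  # monotone non-increasing scan over each class table
  for (cl in c("L", "H", "T")) {
    v <- vapply(1:120, function(m) default_beta(cl, m), numeric(1))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("penalized optimum is zero when presence means equal background means", {
  set.seed(3)
  xb <- matrix(runif(60), 30, 2)
  s <- manual_samples(xb, xb)  # presences ARE the background cells
  fs <- build_features(s, c("L", "Q"))
  m <- fit_maxent(s, fs, rm = 1)
  expect_true(all(m$lambda == 0))
  expect_equal(m$training_gain, 0, tolerance = 1e-12)
  expect_equal(m$gain_unpenalized, 0, tolerance = 1e-12)
})

test_that("two-cell universe matches the closed-form optimum", {
  # f(A)=1, f(B)=0, all presences at A, beta = 0.1:
  # stationarity mean_pres f - beta = E_q f  ->  q(A) = 0.9, lambda = ln 9
  s <- manual_samples(matrix(1, 5, 1), matrix(c(1, 0), 2, 1), vars = "f")
  fs <- build_features(s, "L")
  fs$fmin <- 0; fs$fmax <- 1
  m <- fit_maxent(s, fs, beta = 0.1, tolerance = 1e-14)
  expect_equal(unname(m$lambda), log(9), tolerance = 1e-6)
  q <- exp(1 * m$lambda - m$log_Z)
  expect_equal(unname(q), 0.9, tolerance = 1e-6)
})

test_that("fitted coefficients match the grid-search oracle", {
  inst <- tiny_instance(101)
  fit <- fit_tiny_instance(inst)
  orc <- oracle_grid_search(inst$pbar, inst$Fbg, inst$beta)
  expect_lt(max(abs(unname(fit$lambda) - orc)), 1e-3)
  expect_equal(fit$objective,
               oracle_objective(unname(fit$lambda), inst$pbar, inst$Fbg,
                                inst$beta),
               tolerance = 1e-10)
})

test_that("model invariants: raw sums to 1, entropy and gains non-negative", {
  d <- default_sim(seed = 41, nrows = 25, ncols = 25, n_presences = 80)
  fs <- build_features(d$samples, c("L", "Q", "H"), knots_per_variable = 5)
  m <- fit_maxent(d$samples, fs, rm = 1)
  bg <- d$samples$x[!d$samples$is_presence, ]
  raw <- predict_samples(m, bg)$raw
  expect_equal(sum(raw), 1, tolerance = 1e-8)
  expect_gte(m$entropy_H, 0)
  expect_gte(m$training_gain, 0)
  expect_gte(m$gain_unpenalized, m$training_gain - 1e-12)
})

test_that("objective trace is monotone non-increasing", {
  d <- default_sim(seed = 43, nrows = 25, ncols = 25, n_presences = 60)
  fs <- build_features(d$samples, c("L", "Q", "H", "T"), knots_per_variable = 5)
  m <- fit_maxent(d$samples, fs, rm = 0.5)
  expect_true(all(diff(m$trace) <= 1e-12))
  expect_true(m$converged)
})

test_that("training gain is non-increasing in the regularization multiplier", {
  d <- default_sim(seed = 47, nrows = 25, ncols = 25, n_presences = 100)
  fs <- build_features(d$samples, c("L", "Q"))
  gains <- vapply(c(0.1, 1, 4), function(rm)
    fit_maxent(d$samples, fs, rm = rm)$training_gain, numeric(1))
  expect_true(all(diff(gains) <= 1e-9))
})

test_that("huge regularization collapses to the uniform model", {
  d <- default_sim(seed = 53, nrows = 25, ncols = 25, n_presences = 100)
  fs <- build_features(d$samples, c("L", "Q"))
  m <- fit_maxent(d$samples, fs, rm = 1e6)
  expect_true(all(m$lambda == 0))
  sc <- predict_samples(m, d$samples$x)$logistic
  a <- auc(sc[d$samples$is_presence], sc[!d$samples$is_presence])
  expect_equal(a, 0.5, tolerance = 0.02)
})

test_that("uniform model prediction has the closed form", {
  st <- tiny_stack(6, 5, c("a", "b"))
  occ <- occurrence_set(st$layers$a$xllcorner + 0.15,
                        st$layers$a$yllcorner + 0.15)
  s <- extract_samples(st, occ, n_background = 20, seed = 1)
  fs <- build_features(s, "L")
  m <- fit_maxent(s, fs, rm = 1e9)  # forces lambda = 0
  expect_equal(m$entropy_H, log(20))
  pr <- predict(m, st, transform = "raw")
  expect_equal(unique(as.numeric(pr$grid$values)), 1 / 20)
  pl <- predict(m, st, transform = "logistic")
  expect_equal(unique(as.numeric(pl$grid$values)), 0.5)
})

test_that("clamping clips projection values to the training range", {
  d <- default_sim(seed = 59, nrows = 25, ncols = 25, n_presences = 100)
  fs <- build_features(d$samples, c("L", "Q", "H"), knots_per_variable = 5)
  m <- fit_maxent(d$samples, fs, rm = 1)
  X <- d$samples$x[1:5, , drop = FALSE]
  X[, "bio12"] <- m$features$var_min["bio12"] - 10  # far below training min
  Xmin <- X; Xmin[, "bio12"] <- m$features$var_min["bio12"]
  expect_equal(predict_samples(m, X)$logistic,
               predict_samples(m, Xmin)$logistic)
  # logistic is strictly increasing in raw
  sc <- predict_samples(m, d$samples$x)
  o <- order(sc$raw)
  expect_true(all(diff(sc$logistic[o]) >= 0))
})

test_that("prediction demands every model layer", {
  st <- tiny_stack(6, 5, c("a", "b"))
  occ <- occurrence_set(st$layers$a$xllcorner + 0.15,
                        st$layers$a$yllcorner + 0.15)
  s <- extract_samples(st, occ, n_background = 20, seed = 1)
  m <- fit_maxent(s, build_features(s, "L"), rm = 1)
  st_a <- stack_layers(list(a = st$layers$a))
  expect_error(predict(m, st_a), "missing model layer.*b")
})

test_that("model serialization round-trips predictions", {
  d <- default_sim(seed = 61, nrows = 25, ncols = 25, n_presences = 80)
  fs <- build_features(d$samples, c("L", "Q", "H"), knots_per_variable = 6)
  m <- fit_maxent(d$samples, fs, rm = 0.7)
  p <- file.path(tempdir(), "model.json")
  write_maxent_model(m, p)
  m2 <- read_maxent_model(p)
  expect_equal(unname(m2$lambda), unname(m$lambda))
  s1 <- predict_samples(m, d$samples$x)$logistic
  s2 <- predict_samples(m2, d$samples$x)$logistic
  expect_equal(s1, s2, tolerance = 1e-12)
  unlink(p)
})
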