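test_that("thin_occurrences keeps the first point per cell", {
  # hand-built case: two points ~1.1 km apart inside one 4.5 km cell,
  # using the package's stated equirectangular conversion at mean lat 30
  anchor <- c(100, 30)
  sx <- 111.32 * cos(30 * pi / 180)
  # both points inside thinning cell [0, 4.5) km from the anchor
  lon <- anchor[1] + c(1.0, 2.1) / sx
  lat <- anchor[2] + c(1.0, 1.5) / 111.32
  occ <- occurrence_set(lon, lat)
  th <- thin_occurrences(occ, cell_km = 4.5, anchor = anchor, mean_lat = 30)
  expect_equal(length(th), 1L)
  expect_equal(th$lon, lon[1])  # the FIRST point wins

  # opposite corners of a large extent -> both kept
  occ2 <- occurrence_set(c(100, 110), c(25, 35))
  expect_equal(length(thin_occurrences(occ2, 4.5)), 2L)

  # empty input is not an error
  occ0 <- occurrence_set(numeric(), numeric())
  expect_equal(length(thin_occurrences(occ0, 4.5)), 0L)
})

test_that("thinning is idempotent and order-preserving", {
  set.seed(31)
  occ <- occurrence_set(100 + runif(200, 0, 0.5), 30 + runif(200, 0, 0.5))
  t1 <- thin_occurrences(occ, 4.5, anchor = c(100, 30))
  t2 <- thin_occurrences(t1, 4.5, anchor = c(100, 30))
  expect_identical(t1$lon, t2$lon)
  expect_identical(t1$lat, t2$lat)
  expect_lte(length(t1), length(occ))
  expect_gte(length(t1), 1L)
  # output preserves input order
  expect_identical(t1$lon, occ$lon[occ$lon %in% t1$lon])
})

test_that("extract_samples maps points to cells and draws background", {
  st <- tiny_stack(6, 5, c("a", "b"))
  g <- st$layers$a
  # point at the exact centre of cell (r = 2, c = 3)
  lon <- g$xllcorner + 2.5 * g$cellsize
  lat <- g$yllcorner + (6 - 2 + 0.5) * g$cellsize
  occ <- occurrence_set(lon, lat)
  s <- extract_samples(st, occ, n_background = 10, seed = 1)
  expect_equal(unname(s$x[1, "a"]), g$values[2, 3])
  expect_equal(unname(s$x[1, "b"]), st$layers$b$values[2, 3])
  expect_equal(sum(s$is_presence), 1L)

  s2 <- extract_samples(st, occ, n_background = 10, seed = 1)
  expect_identical(s$x, s2$x)

  expect_error(extract_samples(st, occ, n_background = 1000),
               "exceeds the 30 valid cells")
})

test_that("points outside the grid or on nodata cells are dropped", {
  st <- tiny_stack(6, 5, c("a", "b"), mask = cbind(1, 1))
  g <- st$layers$a
  # one point on the masked cell (1,1), one far outside
  lon <- c(g$xllcorner + 0.5 * g$cellsize, 0)
  lat <- c(g$yllcorner + 5.5 * g$cellsize, 0)
  occ <- occurrence_set(lon, lat)
  expect_message(s <- extract_samples(st, occ, n_background = 5, seed = 1),
                 "dropped 2")
  expect_equal(sum(s$is_presence), 0L)
  expect_equal(s$n_dropped, 2L)
  fs <- build_features(s, "L")
  expect_error(fit_maxent(s, fs), "no presence rows")
})

test_that("background rows have no nodata and no duplicates", {
  sim <- simulate_landscape(landscape_spec(nrows = 25, ncols = 25, seed = 17))
  occ <- sample_presences(sim$truth, sim$stack, 30, seed = 18)
  s <- extract_samples(sim$stack, occ, n_background = 400, seed = 19)
  bg <- s$x[!s$is_presence, ]
  expect_false(anyNA(bg))
  expect_equal(anyDuplicated(s$coords[!s$is_presence, ]), 0L)
})

test_that("correlation_filter matches the hand Pearson computation", {
  # 1x3 layers x = (1,2,3), y = (1,2,4): r = 3 / sqrt(2 * 14/3) = 0.98198
  gx <- env_grid(matrix(c(1, 2, 3), 1, 3), 0, 0, 1)
  gy <- env_grid(matrix(c(1, 2, 4), 1, 3), 0, 0, 1)
  st <- stack_layers(list(x = gx, y = gy))
  rep <- correlation_filter(st, threshold = 0.8)
  expect_equal(rep$matrix["x", "y"], 0.9819805, tolerance = 1e-6)
  expect_equal(length(rep$retained), 1L)
  expect_equal(nrow(rep$dropped), 1L)
  # alphabetical default priority keeps "x"
  expect_identical(rep$retained, "x")
})

test_that("duplicated layer: exactly one of the pair is retained", {
  g <- env_grid(matrix(rnorm(100, 10, 3), 10, 10), 0, 0, 1)
  st <- stack_layers(list(p = g, q = g))
  rep <- correlation_filter(st)
  expect_equal(length(rep$retained), 1L)
  expect_equal(abs(rep$dropped$r[1]), 1)
})

test_that("uncorrelated layers are all retained; constants are warned out", {
  set.seed(23)
  grids <- list(u = env_grid(matrix(rnorm(400), 20, 20), 0, 0, 1),
                v = env_grid(matrix(rnorm(400), 20, 20), 0, 0, 1),
                w = env_grid(matrix(rnorm(400), 20, 20), 0, 0, 1))
  st <- stack_layers(grids)
  rep <- correlation_filter(st)
  expect_setequal(rep$retained, c("u", "v", "w"))
  expect_equal(nrow(rep$dropped), 0L)

  grids$k <- env_grid(matrix(5, 20, 20), 0, 0, 1)
  st2 <- stack_layers(grids)
  expect_warning(rep2 <- correlation_filter(st2), "constant")
  expect_false("k" %in% rep2$retained)
  expect_true(is.na(rep2$dropped$kept[rep2$dropped$dropped == "k"]))
})

test_that("retained set never contains an over-threshold pair (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(rnorm(400), 20, 20)
    grids <- list()
    for (i in 1:6) {
      mix <- runif(1)
      grids[[paste0("l", i)]] <-
        env_grid(mix * base + (1 - mix) * matrix(rnorm(400), 20, 20), 0, 0, 1)
    }
    st <- stack_layers(grids)
    rep <- correlation_filter(st, threshold = 0.8)
    if (length(rep$retained) >= 2) {
      sub <- abs(rep$matrix[rep$retained, rep$retained])
      expect_lte(max(sub[upper.tri(sub)]), 0.8)
    }
    expect_setequal(c(rep$retained, rep$dropped$dropped), names(grids))
  }
})

test_that("gain-based priority keeps the informative member of a pair", {
  d <- default_sim(seed = 29, nrows = 30, ncols = 30, n_presences = 150)
  rep <- correlation_filter(d$sim$stack, samples = d$samples)
  expect_true("bio12" %in% rep$retained)
  expect_true("bio13" %in% rep$dropped$dropped)
})

test_that("occurrence CSV round-trip and validation", {
  occ <- occurrence_set(c(100.5, 101), c(30, 31), species = "P. aubei")
  p <- file.path(tempdir(), "occ.csv")
  write_occurrences(occ, p)
  occ2 <- read_occurrences(p)
  expect_equal(occ2$lon, occ$lon)
  expect_equal(occ2$species, "P. aubei")
  writeLines("a,b\n1,2", p)
  expect_error(read_occurrences(p), "species,longitude,latitude")
  unlink(p)
  expect_error(occurrence_set(200, 30), "outside")
})
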