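# SDM support: grids, sampling, tuning enumeration, collinearity,
# backward selection.

test_that("ASCII grid round-trips through the plain-text format", {
  g <- simulateLandscape(7, 5, seed = 3)$environment
  v <- gridValues(g)
  v[2, 3] <- NA
  g2 <- methods::new("RasterGrid", values = v, xll = 10, yll = -5,
                     cellsize = 0.5)
  p <- tempfile(fileext = ".asc")
  writeAsciiGrid(g2, p)
  back <- readAsciiGrid(p)
  expect_equal(gridValues(back), unname(gridValues(g2)), tolerance = 1e-6)
  expect_equal(back@cellsize, 0.5)
  expect_equal(back@xll, 10)
})

test_that("bias sampling respects weights and the seed", {
  one <- methods::new("RasterGrid",
                      values = matrix(c(0, 0, 1, 0), 2, 2),
                      xll = 0, yll = 0, cellsize = 1)
  pts <- biasSample(one, 200, seed = 1)
  expect_true(all(pts$row == 1 & pts$col == 2))

  two <- methods::new("RasterGrid", values = matrix(c(0.25, 0.75), 1, 2),
                      xll = 0, yll = 0, cellsize = 1)
  n <- 30000
  pts <- biasSample(two, n, seed = 2)
  frac <- mean(pts$col == 2)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(frac - 0.75), 3 * se)

  unif <- methods::new("RasterGrid", values = matrix(1, 5, 8),
                       xll = 0, yll = 0, cellsize = 1)
  pts <- biasSample(unif, 1e5, seed = 3)
  counts <- table(factor(paste(pts$row, pts$col),
                         levels = paste(rep(1:5, 8), rep(1:8, each = 5))))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)

  expect_identical(biasSample(two, 50, seed = 9),
                   biasSample(two, 50, seed = 9))
  zero <- methods::new("RasterGrid", values = matrix(0, 2, 2),
                       xll = 0, yll = 0, cellsize = 1)
  expect_error(biasSample(zero, 10, seed = 1), "zero")
})

test_that("tuning grid enumerates subset x smoothing cells", {
  expect_equal(nrow(tuningGrid("linear", 1)), 1)
  expect_equal(nrow(tuningGrid(c("linear", "quadratic"), c(1, 2))), 6)
  expect_equal(nrow(tuningGrid()), 161)
  for (u in 1:3) for (s in c(1, 4, 9)) {
    tg <- tuningGrid(letters[seq_len(u)], seq_len(s))
    expect_equal(nrow(tg), (2^u - 1) * s)
    expect_equal(nrow(unique(tg)), nrow(tg))
  }
  expect_error(tuningGrid(character(0)), "empty")
})

test_that("collinearity filter drops the higher-VIF member of close pairs", {
  set.seed(31)
  n <- 200
  a <- rnorm(n)
  b <- a + rnorm(n, 0, 0.1)          # near-copy of a
  c_ <- 0.7 * b + rnorm(n, 0, 0.7)   # leans on b -> VIF(b) > VIF(a)
  d <- rnorm(n)
  X <- data.frame(a = a, b = b, c = c_, d = d)
  kept <- collinearityFilter(X, r_threshold = 0.8)
  expect_false("b" %in% kept)
  expect_true(all(c("a", "d") %in% kept))

  ident <- data.frame(p = a, q = a)
  expect_length(suppressWarnings(collinearityFilter(ident, 0.8)), 1)

  indep <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  expect_setequal(collinearityFilter(indep, 0.8), c("x", "y", "z"))

  cst <- data.frame(x = rnorm(n), k = rep(1, n), y = rnorm(n))
  expect_warning(kc <- collinearityFilter(cst, 0.8), "constant")
  expect_false("k" %in% kc)
})

test_that("backward selection drops pure noise before signal", {
  small_grid <- tuningGrid(c("linear", "quadratic"), c(1, 2))
  hits <- vapply(1:30, function(s) {
    set.seed(700 + s)
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    p <- plogis(2 * x1)
    d <- data.frame(presence = rbinom(n, 1, p), x1 = x1, x2 = x2)
    bs <- backwardSelect(d, tuning = small_grid, seed = s)
    drops <- vapply(bs$trace, function(tr) tr$dropped, "")
    identical(drops[!is.na(drops)], "x2") ||
      all(is.na(drops))                       # or nothing dropped at all
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("backward-selection traces shrink by one and importances sum", {
  set.seed(55)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  p <- plogis(1.5 * x1 - 1.2 * x2 + x3)
  d <- data.frame(presence = rbinom(n, 1, p), x1 = x1, x2 = x2, x3 = x3)
  bs <- backwardSelect(d, tuning = tuningGrid("linear", 1), seed = 2)
  sizes <- vapply(bs$trace, function(tr) length(tr$predictors), 0L)
  expect_true(all(diff(sizes) == -1L) || length(sizes) == 1)
  for (tr in bs$trace) {
    expect_true(all(tr$importance >= 0))
    expect_equal(sum(tr$importance), 100, tolerance = 1e-6)
  }
  # all informative predictors retained in a single iteration
  if (length(bs$trace) == 1)
    expect_true(is.na(bs$trace[[1]]$dropped))
})

test_that("occurrence thinning enforces separation, preferring specimens", {
  set.seed(77)
  occ <- data.frame(lon = c(-115, -115.001, -114.5, -114.0),
                    lat = c(44, 44.001, 44, 44),
                    source = c("observation", "specimen", "observation",
                               "observation"))
  th <- thinOccurrences(occ, min_km = 10, seed = 1)
  # the two ~0.1 km neighbours collapse to the specimen record
  expect_true(any(th$source == "specimen"))
  expect_false(any(th$lon == -115 & th$source == "observation"))
  d <- as.matrix(dist(cbind(th$lon * 85, th$lat * 111)))  # rough km
  expect_true(all(d[upper.tri(d)] > 9))
})
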