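test_that("the centered 11-year moving average has the documented span", {
  s <- movingAverage(rep(50, 140), startYear = 1961)
  expect_equal(range(s$years), c(1966, 2095))
  expect_equal(length(s$values), 130)
  expect_equal(s$values, rep(50, 130))

  # linear series: centered mean equals the centre value exactly
  lin <- movingAverage(seq_len(21), startYear = 1961)
  expect_equal(lin$values, 6:16)

  # smoothed values stay within their window's range
  set.seed(3)
  x <- rnorm(40)
  sm <- movingAverage(x, startYear = 2000)
  for (k in seq_along(sm$values)) {
    w <- x[k:(k + 10)]
    expect_gte(sm$values[k], min(w)); expect_lte(sm$values[k], max(w))
  }

  expect_error(movingAverage(1:5), "shorter")
  expect_error(movingAverage(1:20, window = 10), "odd")
})

test_that("ensemble percentiles match a sort-based oracle with type-7 interpolation", {
  # degenerate: identical members
  m <- matrix(7, 3, 5)
  env <- ensemblePercentiles(m)
  expect_true(all(env$p10 == 7 & env$p50 == 7 & env$p90 == 7))

  # two members 0 and 10: median 5
  env2 <- ensemblePercentiles(matrix(c(0, 10), 2, 4, byrow = FALSE))
  expect_true(all(env2$p50 == 5))

  # six distinct members vs an explicit order-statistic interpolation
  set.seed(13)
  vals <- matrix(sample(1:100, 6), 6, 1)
  env6 <- ensemblePercentiles(vals, probs = c(0.1, 0.5, 0.9))
  s <- sort(vals[, 1])
  oracle <- function(p) {
    h <- (6 - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, 6)] - s[lo])
  }
  expect_equal(env6$p10, oracle(0.1))
  expect_equal(env6$p50, oracle(0.5))
  expect_equal(env6$p50, mean(s[3:4]))   # median of six = mean of 3rd and 4th
  expect_equal(env6$p90, oracle(0.9))

  # envelope ordering holds on random ensembles
  r <- matrix(rnorm(6 * 20), 6, 20)
  envr <- ensemblePercentiles(r)
  expect_true(all(envr$p10 <= envr$p50 & envr$p50 <= envr$p90))

  expect_error(ensemblePercentiles(list(1:3, 1:4)), "lengths")
  expect_error(ensemblePercentiles(matrix(1, 1, 5)), "2 members")
})

test_that("average rate honours both denominator conventions", {
  s <- movingAverage(rep(42, 140), startYear = 1961)
  expect_equal(averageRate(s), 0)

  # linear input with slope b: difference convention recovers b exactly,
  # the inclusive convention scales it by span/(span + 1)
  b <- 0.73
  lin <- movingAverage(b * (0:139), startYear = 1961)
  expect_equal(averageRate(lin, "difference"), b)
  expect_equal(averageRate(lin, "inclusive"), b * 129 / 130)

  expect_error(averageRate(list(years = 2000, values = 1)), "at least 2")
})

test_that("the Monte Carlo trend test is seeded, one-sided and rank-based", {
  inc <- monteCarloTrendTest(as.numeric(1:131), nIter = 200, seed = 5)
  expect_true(all(inc@significant))
  expect_equal(inc@exceedFraction, 1)

  const <- monteCarloTrendTest(rep(4, 131), nIter = 200, seed = 5)
  expect_equal(const@slope, 0)
  expect_false(any(const@significant))

  a <- monteCarloTrendTest(rnorm(50), nIter = 200, seed = 9)
  b <- monteCarloTrendTest(rnorm(50), nIter = 200, seed = 9)
  # seeding makes the null ranking reproducible for the same input
  set.seed(1); x <- rnorm(50)
  expect_identical(monteCarloTrendTest(x, nIter = 200, seed = 9)@exceedFraction,
                   monteCarloTrendTest(x, nIter = 200, seed = 9)@exceedFraction)

  expect_error(monteCarloTrendTest(1:5), "too short")
  expect_error(monteCarloTrendTest(1:50, nIter = 50), "nIter")
})

test_that("test power grows with the injected trend", {
  set.seed(77)
  nRep <- 40
  rejections <- vapply(c(0, 0.05, 0.15), function(slope) {
    hits <- 0L
    for (r in seq_len(nRep)) {
      y <- slope * (1:60) + rnorm(60)
      tt <- monteCarloTrendTest(y, nIter = 200, seed = 1000 + r)
      hits <- hits + tt@significant[["p95"]]
    }
    hits / nRep
  }, numeric(1))
  expect_true(all(diff(rejections) >= 0))
  expect_lt(rejections[1], 0.3)
  expect_gt(rejections[3], 0.7)
})

test_that("trend maps flag structurally saturated cells and reduce to the scalar test", {
  # every cell saturated at 365 days/year: no trend is possible
  sat <- new("AnnualCountGrid", counts = array(365, c(40, 2, 2)),
             category = "Hda2", years = c(1961L, 2000L),
             lat = c(-30, -28), lon = c(18, 20))
  tg <- trendMap(sat, nIter = 200, seed = 2)
  expect_true(all(tg@flag == -1L))
  expect_true(all(tg@rate == 0))

  # a single-cell grid reproduces the scalar pipeline exactly
  set.seed(19)
  series <- pmin(pmax(round(100 + 1.2 * (0:39) + rnorm(40, 0, 5)), 0), 365)
  one <- new("AnnualCountGrid", counts = array(series, c(40, 1, 1)),
             category = "Hda2", years = c(1961L, 2000L), lat = 0, lon = 0)
  tg1 <- trendMap(one, nIter = 200, seed = 7)
  sm <- movingAverage(series, years = 1961:2000)
  expect_equal(tg1@rate[1, 1], averageRate(sm, "inclusive"))
  tt <- monteCarloTrendTest(sm$values, nIter = 200, seed = 7, years = sm$years)
  expectedFlag <- if (any(tt@significant)) max(tt@levels[tt@significant]) else 0L
  expect_equal(as.integer(tg1@flag[1, 1]), as.integer(expectedFlag))
})

test_that("trended cells are detected and untrended cells stay near the nominal rate", {
  set.seed(101)
  nYear <- 60L
  counts <- array(NA_real_, c(nYear, 2, 2))
  trended <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  for (j in 1:2) for (i in 1:2) {
    slope <- if (trended[j, i]) 2 else 0
    counts[, j, i] <- pmin(pmax(round(120 + slope * (1:nYear) +
                                        rnorm(nYear, 0, 6)), 0), 365)
  }
  grid <- new("AnnualCountGrid", counts = counts, category = "Hda2",
              years = c(1961L, 1960L + nYear),
              lat = c(-30, -28), lon = c(18, 20))
  tg <- trendMap(grid, nIter = 500, seed = 3)
  expect_true(all(tg@flag[trended] == 99L))
  expect_true(all(tg@rate[trended] > 1))
})

test_that("the ensemble median of six members averages the middle order statistics", {
  grids <- lapply(1:6, function(k)
    new("AnnualCountGrid", counts = array(k * 10, c(5, 1, 1)),
        category = "Hda2", years = c(1961L, 1965L), lat = 0, lon = 0))
  med <- ensembleMedianCounts(grids)
  expect_equal(as.vector(fieldValues(med)), rep(35, 5))  # mean of 30 and 40
})
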