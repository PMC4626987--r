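test_that("generation is reproducible given the seed and differs across seeds", {
  cfg1 <- synthConfig(nMembers = 2, years = c(1961, 1963), nLat = 2, nLon = 2,
                      seed = 11)
  e1 <- generateEnsemble(cfg1)
  e2 <- generateEnsemble(cfg1)
  expect_identical(fieldValues(getMember(e1, 1)$tmax),
                   fieldValues(getMember(e2, 1)$tmax))
  expect_identical(fieldValues(getMember(e1, 2)$rh),
                   fieldValues(getMember(e2, 2)$rh))
  cfg2 <- synthConfig(nMembers = 2, years = c(1961, 1963), nLat = 2, nLon = 2,
                      seed = 12)
  e3 <- generateEnsemble(cfg2)
  expect_false(identical(fieldValues(getMember(e1, 1)$tmax),
                         fieldValues(getMember(e3, 1)$tmax)))
})

test_that("without trend, bias and noise, every year repeats the same cycle", {
  cfg <- cleanConfig(years = c(1961, 1965))
  tmax <- fieldValues(getMember(generateEnsemble(cfg), 1)$tmax)
  dim(tmax) <- c(365, 5, 4)  # [doy, year, cell]
  for (y in 2:5)
    expect_equal(tmax[, y, ], tmax[, 1, ])
})

test_that("a 3 degC/century trend separates the same calendar day by 3 degC over 100 years", {
  cfg <- cleanConfig(years = c(1961, 2061), nLat = 1, nLon = 1, trend = 3)
  tmax <- fieldValues(getMember(generateEnsemble(cfg), 1)$tmax)
  d1 <- tmax[1:365, 1, 1]
  d101 <- tmax[100 * 365 + 1:365, 1, 1]
  expect_equal(d101 - d1, rep(3, 365))
})

test_that("generated RH stays in [0, 100] and wind is non-negative", {
  cfg <- synthConfig(nMembers = 1, years = c(1961, 1970), nLat = 2, nLon = 2,
                     rhBase = 95, noiseSdRh = 20, biasRh = 1.2,
                     windMean = 0.5, windSd = 2, seed = 4)
  m <- getMember(generateEnsemble(cfg), 1)
  expect_true(all(fieldValues(m$rh) >= 0 & fieldValues(m$rh) <= 100))
  expect_true(all(fieldValues(m$wind) >= 0))
  expect_gt(max(fieldValues(m$rh)), 99)  # clipping actually exercised
})

test_that("reference climatology is the ensemble climatology with biases removed", {
  # additive: constant +2 degC model bias, no noise/trend
  cfg <- synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 2, nLon = 2,
                     trendDegCPerCentury = 0, biasT = 2, biasRh = 1,
                     noiseSdT = 0, noiseSdRh = 0, windSd = 0)
  ref <- generateReferenceClimatology(cfg)
  m <- getMember(generateEnsemble(cfg), 1)
  modelClim <- monthlyClimatology(m$tmax, c(1961, 1990))
  expect_equal(fieldValues(ref$tmax), fieldValues(modelClim) - 2)

  # multiplicative: factor 1.25, unclipped humidity
  cfg2 <- synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 2, nLon = 2,
                      rhBase = 60, biasT = 0, biasRh = 1.25,
                      noiseSdT = 0, noiseSdRh = 0, windSd = 0,
                      trendDegCPerCentury = 0)
  ref2 <- generateReferenceClimatology(cfg2)
  m2 <- getMember(generateEnsemble(cfg2), 1)
  rhClim <- monthlyClimatology(m2$rh, c(1961, 1990))
  expect_equal(fieldValues(ref2$rh), fieldValues(rhClim) / 1.25)
})

test_that("with noise, model-minus-reference January mean approximates the injected bias", {
  biasT <- 1.5 * cospi(2 * (0:11) / 12)
  cfg <- synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 2, nLon = 2,
                     trendDegCPerCentury = 0, biasT = biasT, biasRh = 1,
                     noiseSdT = 1, noiseSdRh = 0, windSd = 0, seed = 21)
  ref <- generateReferenceClimatology(cfg)
  m <- getMember(generateEnsemble(cfg), 1)
  modelClim <- monthlyClimatology(m$tmax, c(1961, 1990))
  diffJan <- fieldValues(modelClim)[1, , ] - fieldValues(ref$tmax)[1, , ]
  se <- 1 / sqrt(31 * 30)  # January days over 30 baseline years
  expect_true(all(abs(diffJan - biasT[1]) < 3 * se + 1e-12))
})

test_that("monthly climatologies match the closed form up to sampling noise", {
  cfg <- synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 3, nLon = 2,
                     trendDegCPerCentury = 0, noiseSdT = 0.8, noiseSdRh = 0,
                     windSd = 0, biasRh = 1, seed = 31)
  m <- getMember(generateEnsemble(cfg), 1)
  clim <- monthlyClimatology(m$tmax, c(1961, 1990))
  lat <- gridLat(m$tmax)
  peak <- ifelse(lat < 0, 15, 196)
  # closed-form expectation: tBase + monthly mean seasonal cycle + monthly bias
  expected <- array(NA_real_, c(12, 3, 2))
  for (j in seq_along(lat)) {
    seasMonth <- tapply(6 * cos(2 * pi * ((1:365) - peak[j]) / 365),
                        monthOfDay(1:365), mean)
    expected[, j, ] <- (32 - 0.22 * abs(lat[j])) + seasMonth + cfg@biasT
  }
  se <- 0.8 / sqrt(daysInMonth(1:12) * 30)
  z <- (fieldValues(clim) - expected) / se
  # 72 independent standardized errors: centred, unit scale, no outliers
  expect_lt(abs(mean(z)), 3 / sqrt(72))
  expect_lt(max(abs(z)), 4.5)
  expect_gt(sd(z), 0.6); expect_lt(sd(z), 1.5)
})

test_that("the warming-trend field is recovered by regressing annual means on year", {
  trend <- matrix(seq(0.5, 4, length.out = 6), 2, 3)
  cfg <- synthConfig(nMembers = 1, years = c(1961, 2100), nLat = 2, nLon = 3,
                     trendDegCPerCentury = trend, noiseSdT = 1,
                     noiseSdRh = 0, windSd = 0, biasT = 0, biasRh = 1,
                     seed = 41)
  tmax <- fieldValues(getMember(generateEnsemble(cfg), 1)$tmax)
  dim(tmax) <- c(365, 140, 6)
  annual <- apply(tmax, c(2, 3), mean)
  yrs <- 1961:2100
  # analytic slope s.e.: daily noise sd 1 -> annual-mean sd 1/sqrt(365)
  seSlope <- (1 / sqrt(365)) / sqrt(sum((yrs - mean(yrs))^2)) * 100
  for (c in 1:6) {
    slope <- coef(lm(annual[, c] ~ yrs))[2] * 100
    expect_lt(abs(slope - trend[c]), max(0.05 * trend[c], 3 * seSlope))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(nMembers = 0), "nMembers")
  expect_error(synthConfig(years = c(1990, 1961)), "inclusive")
  expect_error(synthConfig(biasRh = -1), "> 0")
  expect_error(synthConfig(ar1 = 1), "ar1")
})
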