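test_that("monthly climatology reduces means correctly", {
  # constant field
  f <- makeField(20, years = c(1961, 1962))
  clim <- monthlyClimatology(f, c(1961, 1962))
  expect_equal(fieldValues(clim), array(20, c(12, 2, 2)))

  # 2-year baseline, January 10 in year 1 and 12 in year 2 -> mean 11
  v <- array(20, c(730, 2, 2))
  v[1:31, , ] <- 10
  v[366:396, , ] <- 12
  clim2 <- monthlyClimatology(makeField(v, years = c(1961, 1962)),
                              c(1961, 1962))
  expect_equal(fieldValues(clim2)[1, , ], matrix(11, 2, 2))
  expect_equal(fieldValues(clim2)[2, , ], matrix(20, 2, 2))
})

test_that("baseline years missing from the field are reported by name", {
  f <- makeField(20, years = c(1961, 1962))
  expect_error(monthlyClimatology(f, c(1961, 1964)), "1963")
  expect_error(monthlyClimatology(f, c(1961, 1964)), "1964")
})

test_that("deriving corrections is subtraction / division with identity at zero bias", {
  model <- makeClim(25)
  ref <- makeClim(23)
  corr <- deriveCorrection(model, ref, "additive")
  expect_equal(fieldValues(corr), array(-2, c(12, 2, 2)))

  modelRh <- makeClim(80, variable = "rh")
  refRh <- makeClim(60, variable = "rh")
  corrRh <- deriveCorrection(modelRh, refRh, "multiplicative")
  expect_equal(fieldValues(corrRh), array(0.75, c(12, 2, 2)))

  expect_equal(fieldValues(deriveCorrection(model, model, "additive")),
               array(0, c(12, 2, 2)))
  expect_equal(fieldValues(deriveCorrection(modelRh, modelRh, "multiplicative")),
               array(1, c(12, 2, 2)))
})

test_that("zero model climatology yields a missing multiplicative factor", {
  model <- makeClim(0, variable = "rh")
  ref <- makeClim(50, variable = "rh")
  corr <- deriveCorrection(model, ref, "multiplicative")
  expect_true(all(is.na(fieldValues(corr))))
})

test_that("corrections apply per calendar month and RH clips at 100", {
  f <- makeField(30)
  corrVals <- array(0, c(12, 2, 2)); corrVals[2, , ] <- -2  # February only
  corr <- new("CorrectionField", values = corrVals, variable = "tmax",
              mode = "additive", lat = gridLat(f), lon = gridLon(f))
  out <- applyCorrection(f, corr)
  expect_equal(fieldValues(out)[32:59, , ], array(28, c(28, 2, 2)))
  expect_equal(fieldValues(out)[1:31, , ], array(30, c(31, 2, 2)))

  rh <- makeField(90, variable = "rh", units = "percent")
  corrRh <- new("CorrectionField", values = array(1.2, c(12, 2, 2)),
                variable = "rh", mode = "multiplicative",
                lat = gridLat(rh), lon = gridLon(rh))
  outRh <- applyCorrection(rh, corrRh)
  expect_equal(fieldValues(outRh), array(100, c(365, 2, 2)))
  expect_equal(attr(outRh, "clippedFraction"), 1)
})

test_that("additive correction restores the reference climatology exactly", {
  cfg <- synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 3, nLon = 3,
                     biasT = 3 * cospi(2 * (0:11) / 12), noiseSdT = 1,
                     seed = 7)
  ref <- generateReferenceClimatology(cfg)
  m <- getMember(generateEnsemble(cfg), 1)
  corr <- deriveCorrection(monthlyClimatology(m$tmax, c(1961, 1990)),
                           ref$tmax, "additive")
  corrected <- applyCorrection(m$tmax, corr)
  roundTrip <- monthlyClimatology(corrected, c(1961, 1990))
  expect_lt(max(abs(fieldValues(roundTrip) - fieldValues(ref$tmax))), 1e-9)
})

test_that("multiplicative correction restores the RH reference where unclipped", {
  cfg <- synthConfig(nMembers = 1, years = c(1961, 1990), nLat = 3, nLon = 3,
                     rhBase = 55, biasRh = 1 + 0.2 * sinpi(2 * (0:11) / 12),
                     noiseSdRh = 4, seed = 8)
  ref <- generateReferenceClimatology(cfg)
  m <- getMember(generateEnsemble(cfg), 1)
  corr <- deriveCorrection(monthlyClimatology(m$rh, c(1961, 1990)),
                           ref$rh, "multiplicative")
  corrected <- applyCorrection(m$rh, corr)
  expect_equal(attr(corrected, "clippedFraction"), 0)
  roundTrip <- monthlyClimatology(corrected, c(1961, 1990))
  expect_lt(max(abs(fieldValues(roundTrip) - fieldValues(ref$rh))), 1e-9)
})

test_that("correction preserves within-month ordering and year-to-year trend differences", {
  set.seed(5)
  v <- array(rnorm(2 * 365 * 4, 25, 5), c(730, 2, 2))
  f <- makeField(v, years = c(1961, 1962))
  corr <- new("CorrectionField",
              values = array(rnorm(12, 0, 2), c(12, 2, 2)),
              variable = "tmax", mode = "additive",
              lat = gridLat(f), lon = gridLon(f))
  out <- applyCorrection(f, corr)
  # ordering within January, and Jan mean differences between years, unchanged
  expect_equal(order(fieldValues(out)[1:31, 1, 1]), order(v[1:31, 1, 1]))
  d0 <- mean(v[366:396, 1, 1]) - mean(v[1:31, 1, 1])
  d1 <- mean(fieldValues(out)[366:396, 1, 1]) - mean(fieldValues(out)[1:31, 1, 1])
  expect_equal(d1, d0)
})

test_that("bilinear regridding is exact on identity, constants and affine fields", {
  f <- makeField(17, nLat = 3, nLon = 3, lat = c(-30, -28, -26),
                 lon = c(18, 20, 22))
  # identity
  expect_identical(regridToReference(f, c(-30, -28, -26), c(18, 20, 22)), f)
  # constant field onto an interior grid
  out <- regridToReference(f, c(-29, -27), c(19, 21))
  expect_equal(fieldValues(out), array(17, c(365, 2, 2)))
  # a plane linear in longitude is reproduced exactly at interior points
  v <- array(0, c(365, 3, 3))
  for (i in 1:3) v[, , i] <- 10 + 2.5 * c(18, 20, 22)[i]
  fp <- makeField(v, nLat = 3, nLon = 3, lat = c(-30, -28, -26),
                  lon = c(18, 20, 22))
  outp <- regridToReference(fp, c(-29, -27), c(18.5, 21.5))
  expect_equal(fieldValues(outp)[, 1, ],
               matrix(10 + 2.5 * c(18.5, 21.5), 365, 2, byrow = TRUE))
  # disjoint grids are refused
  expect_error(regridToReference(f, c(50, 52), c(120, 122)), "overlap")
})

test_that("cells outside the source hull come back missing", {
  f <- makeField(5, nLat = 2, nLon = 2, lat = c(-30, -28), lon = c(18, 20))
  out <- regridToReference(f, c(-31, -29), c(18, 19))
  expect_true(all(is.na(fieldValues(out)[, 1, ])))   # -31 south of the grid
  expect_true(all(!is.na(fieldValues(out)[, 2, ])))
})

test_that("grid and variable mismatches are refused", {
  model <- makeClim(25)
  refOther <- makeClim(23, lat = c(0, 2))
  expect_error(deriveCorrection(model, refOther, "additive"), "grid")
  refVar <- makeClim(23, variable = "rh")
  expect_error(deriveCorrection(model, refVar, "additive"), "variable")
})
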