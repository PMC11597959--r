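noiselessData <- function(n = 50, a = 0.5, b = 10, species = "pansy") {
  d <- seq(20, 60, length.out = n)
  data.frame(species = species, d_mm = d, h_mm = a * d + b)
}

test_that("noiseless data is fitted exactly", {
  m <- fitSpeciesModel(noiselessData(), "pansy", trainFrac = 0.8, seed = 4)
  expect_equal(m@slope, 0.5, tolerance = 1e-9)
  expect_equal(m@intercept, 10, tolerance = 1e-9)
  expect_identical(m@nTrain, 40L)
  expect_identical(m@nTest, 10L)
  expect_equal(mean(m@residuals), 0, tolerance = 1e-12)
})

test_that("the fit matches a closed-form normal-equations oracle on the same split", {
  params <- defaultSpeciesParams()
  meas <- makeMeasurements(params[params$species == "marigold", ],
                           nPerSpecies = 240L, seed = 77)
  m <- fitSpeciesModel(meas, "marigold", trainFrac = 0.8, seed = 9)
  train <- meas[m@trainIdx, ]
  oracle <- olsOracle(train$d_mm, train$h_mm)
  expect_equal(m@slope, unname(oracle["a"]), tolerance = 1e-12)
  expect_equal(m@intercept, unname(oracle["b"]), tolerance = 1e-12)
  ## generator truth (0.66, 7.10) recovered to sampling precision
  expect_lt(abs(m@slope - 0.66), 0.1)
  expect_lt(abs(m@intercept - 7.10), 4)
})

test_that("too few measurements are an insufficient-data error", {
  few <- noiselessData(n = 4)
  expect_error(fitSpeciesModel(few, "pansy", trainFrac = 0.8, seed = 1),
               class = "pluckvision_insufficient_data")
  expect_error(fitSpeciesModel(noiselessData(), "rose", seed = 1),
               class = "pluckvision_insufficient_data")
})

test_that("upper boundary translates by the empirical residual quantile", {
  m <- fitSpeciesModel(noiselessData(), "pansy", seed = 2)
  ## all residuals zero -> boundary == regression for any coverage
  for (cov in c(0.5, 0.85, 0.95))
    expect_equal(upperBoundary(m, cov)@interceptUpper, m@intercept,
                 tolerance = 1e-9)

  ## frozen residuals: offset is the ceiling(n * cov)-th order statistic
  m2 <- m
  m2@residuals <- c(-1, 0, 1, 2) - 0.5   # mean 0, sorted already
  m2@nTrain <- 4L
  b <- upperBoundary(m2, 0.85)
  expect_equal(b@interceptUpper - m2@intercept,
               sort(m2@residuals)[ceiling(0.85 * 4)], tolerance = 1e-12)
  expect_equal(b@slope, m2@slope)        # parallel translation

  ## normal theory: z(coverage) * residual SD
  set.seed(13)
  meas <- makeMeasurements(nPerSpecies = 100L, seed = 3)
  m3 <- fitSpeciesModel(meas, "snapdragon", seed = 6)
  b3 <- upperBoundary(m3, 0.85, method = "normal_theory")
  expect_equal(b3@interceptUpper - m3@intercept,
               qnorm(0.85) * sd(m3@residuals), tolerance = 1e-12)

  expect_error(upperBoundary(m, 0.3), class = "pluckvision_contract")
  expect_error(upperBoundary(m, 1.0), class = "pluckvision_contract")
})

test_that("training coverage at the boundary is at least the target, and the limit is the median", {
  set.seed(23)
  meas <- makeMeasurements(nPerSpecies = 80L, seed = 19)
  for (sp in c("pansy", "snapdragon", "marigold")) {
    m <- fitSpeciesModel(meas, sp, seed = 8)
    train <- meas[meas$species == sp, ][m@trainIdx, ]
    for (cov in c(0.6, 0.85, 0.9)) {
      b <- upperBoundary(m, cov)
      frac <- mean(train$h_mm <= predictH(b, train$d_mm) + 1e-12)
      expect_gte(frac, cov)
    }
    ## coverage -> 0.5+ approaches the median-residual translation
    b50 <- upperBoundary(m, 0.5 + 1e-9)
    expect_lt(abs((b50@interceptUpper - m@intercept) - median(m@residuals)),
              0.5)
  }
})

test_that("predictH evaluates packaged published lines exactly", {
  pansy <- loadPackagedCoefficients("pansy")
  expect_identical(predictH(pansy$boundary, 0), 43.20)
  expect_identical(predictH(pansy$model, 0), 26.33)
  marigold <- loadPackagedCoefficients("marigold")
  expect_identical(predictH(marigold$model, 0), 7.10)
  expect_equal(predictH(marigold$boundary, 1) -
                 predictH(marigold$boundary, 0), 0.66, tolerance = 1e-12)
  snap <- loadPackagedCoefficients("snapdragon")
  expect_identical(snap$model$slope, 0.38)
  expect_identical(snap$model$intercept, 5.33)
  expect_identical(snap$boundary@interceptUpper, 34.57)
  expect_error(loadPackagedCoefficients("rose"),
               class = "pluckvision_no_calibration")
  expect_error(predictH(pansy$boundary, -1), class = "pluckvision_contract")
  ## monotone in d for non-negative slopes
  d <- seq(0, 80, by = 5)
  expect_true(all(diff(predictH(pansy$boundary, d)) >= 0))
})

test_that("underestimation counts strictly-above-the-line flowers", {
  b <- new("BoundaryLine", species = "x", slope = 0.5, interceptUpper = 20,
           coverage = 0.85, method = "packaged")
  below <- data.frame(d_mm = c(10, 20, 30), h_mm = c(24, 29, 34))
  expect_identical(evaluateUnderestimation(b, below)$countUnder, 0L)
  mixed <- data.frame(d_mm = c(10, 20, 30, 40), h_mm = c(26, 29.5, 30, 45))
  ev <- evaluateUnderestimation(b, mixed)
  expect_identical(ev$countUnder, 2L)     # 26 > 25 and 45 > 40
  expect_identical(ev$n, 4L)
  expect_error(evaluateUnderestimation(b, below[0, ]),
               class = "pluckvision_contract")
})

test_that("held-out under-rate is near 1 - coverage for Gaussian residuals", {
  set.seed(33)
  under <- 0L; total <- 0L
  for (s in 1:20) {
    meas <- makeMeasurements(nPerSpecies = 240L, seed = 1000 + s)
    m <- fitSpeciesModel(meas, "marigold", seed = s)
    b <- upperBoundary(m, 0.85)
    ev <- evaluateUnderestimation(b, testMeasurements(m, meas))
    under <- under + ev$countUnder; total <- total + ev$n
  }
  rate <- under / total
  ci99 <- qnorm(0.995) * sqrt(0.15 * 0.85 / total)
  expect_lt(abs(rate - 0.15), ci99 + 0.02)  # quantile-estimation slack
})

test_that("parameter recovery sharpens with sample size", {
  set.seed(43)
  errAt <- function(n) {
    e <- vapply(1:25, function(s) {
      meas <- makeMeasurements(nPerSpecies = n, seed = 2000 + s)
      m <- fitSpeciesModel(meas, "marigold", seed = s)
      abs(m@slope - 0.66)
    }, numeric(1))
    mean(e)
  }
  expect_lt(errAt(240L), errAt(60L))
})
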