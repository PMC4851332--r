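test_that("calibration against the identity curve recovers the Gaussian limit", {
  tc <- toy_identity_curve(8000, 2000, sigma = 0)
  d <- calibrate(5000, 20, tc)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  expect_lt(abs(mean(d) - 5000), 0.5)
  sd_d <- sqrt(sum(d$prob * (d$calbp - mean(d))^2))
  expect_lt(abs(sd_d - 20) / 20, 0.05)

  d2 <- calibrate(5000, 10, tc)
  expect_lt(abs(sqrt(sum(d2$prob * (d2$calbp - mean(d2))^2)) - 10) / 10, 0.05)
  expect_lt(abs(mean(d2) - 5000), 0.5)
})

test_that("calibrated densities normalise, trim support and respect the floor", {
  wc <- toy_wiggle_curve(8000, 2000)
  set.seed(11)
  for (i in 1:25) {
    cra <- runif(1, 3000, 7000)
    err <- sample(c(20, 30, 50, 80), 1)
    d <- calibrate(cra, err, wc)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_true(all(d$prob >= 0))
    expect_equal(diff(d$calbp), rep(-1, length(d$calbp) - 1L))
    expect_gt(d$prob[1L], 0) # trimmed to first/last non-zero year
    expect_gt(d$prob[length(d$prob)], 0)
    expect_true(all(d$prob == 0 | d$prob >= 1e-5 * max(d$prob) / sum(d$prob)))
  }
  expect_error(calibrate(20000, 30, wc), "outside the curve")
  expect_error(calibrate(5000, 0, toy_identity_curve(8000, 2000, sigma = 0)),
               "error must be > 0")
})

test_that("calibrated quantiles match a 0.2-yr brute-force integration", {
  curves <- list(toy_identity_curve(8000, 2000, sigma = 5),
                 toy_wiggle_curve(8000, 2000, sigma = 10))
  set.seed(21)
  for (curve in curves) {
    for (i in 1:8) {
      cra <- round(runif(1, 3500, 6500))
      err <- sample(c(20, 30, 50), 1)
      d <- calibrate(cra, err, curve)
      for (p in c(0.25, 0.5, 0.75)) {
        expect_lt(abs(quantile(d, p)[[1L]] -
                      oracle_calibrate_quantile(cra, err, curve, p)), 1)
      }
    }
  }
})

test_that("calibrated densities serialise as two-column CSV", {
  d <- calibrate(5000, 20, toy_identity_curve(8000, 2000))
  f <- tempfile(fileext = ".csv")
  write_cal_density(d, f)
  back <- utils::read.csv(f)
  expect_equal(back$calbp, d$calbp)
  expect_equal(back$prob, d$prob)
})

test_that("uncalibrate is the curve lookup, exact at knots", {
  tc <- toy_identity_curve(8000, 2000, sigma = 4)
  u <- uncalibrate(5000, tc)
  expect_equal(u$mu, 5000)
  expect_equal(u$sigma, 4)
  expect_error(uncalibrate(9000, tc), "span")

  f <- tempfile()
  writeLines(c("calbp,c14age,error", "7000,6123,11", "6000,5234,13",
               "5000,4456,9"), f)
  knots <- read_calcurve(f, "simple")
  u2 <- uncalibrate(6000, knots)
  expect_equal(u2$mu, 5234)
  expect_equal(u2$sigma, 13)

  # round trip: re-calibrating the curve value at t peaks near t
  set.seed(31)
  wc <- toy_wiggle_curve(8000, 2000, sigma = 5, amplitude = 10)
  for (t in round(runif(20, 3200, 6800))) {
    d <- calibrate(uncalibrate(t, wc)$mu, 10, wc)
    mode_year <- d$calbp[which.max(d$prob)]
    expect_lt(abs(mode_year - t), 60) # within the local wiggle plateau
  }
})

test_that("sample_cra is seeded, unbiased and adds variances", {
  tc <- toy_identity_curve(8000, 2000, sigma = 30)
  set.seed(7)
  a <- sample_cra(rep(5000, 100), 40, tc)
  set.seed(7)
  b <- sample_cra(rep(5000, 100), 40, tc)
  expect_identical(a, b)
  expect_true(all(a == round(a)))

  set.seed(8)
  draws <- sample_cra(rep(5000, 10000), 40, tc)
  expect_lt(abs(mean(draws) - 5000), 3 * 50 / 100)
  expect_lt(abs(sd(draws) - sqrt(30^2 + 40^2)) / 50, 0.05)
  expect_error(sample_cra(5000, 0, tc), "> 0")
  expect_error(sample_cra(1000, 20, tc), "span")
})

test_that("calibration is invariant to grid ordering and translation", {
  inc <- calcurve(seq(2000, 8000), seq(2000, 8000),
                  rep(5, 6001), name = "increasing")
  dec <- toy_identity_curve(8000, 2000, sigma = 5)
  di <- calibrate(5000, 25, inc)
  dd <- calibrate(5000, 25, dec)
  expect_identical(di$calbp, dd$calbp)
  expect_identical(di$prob, dd$prob)

  shifted <- toy_identity_curve(9000, 3000, sigma = 5)
  ds <- calibrate(6000, 25, shifted)
  expect_identical(ds$prob, dd$prob)
  expect_identical(ds$calbp, dd$calbp + 1000)
})
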