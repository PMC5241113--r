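test_that("identity-curve calibration reduces to a Gaussian", {
  cv <- linear_calibration_curve(c(0, 500))
  cd <- calibrate(200, 30, cv)
  ref <- dnorm(cv$cal_bp, 200, 30)
  expect_equal(cd$density, ref / sum(ref), tolerance = 1e-12)
  expect_equal(sum(cd$density), 1, tolerance = 1e-9)
  # 95.4% HPD of N(200, 30) is about [141, 259] cal BP
  expect_lt(abs(cd$hpd95$from_bp - 141), 2.5)
  expect_lt(abs(cd$hpd95$to_bp - 259), 2.5)
  expect_lt(abs(cd$hpd68$from_bp - 170), 2.5)
  expect_lt(abs(cd$hpd68$to_bp - 230), 2.5)
})

test_that("curve uncertainty widens the posterior", {
  cv0 <- linear_calibration_curve(c(0, 500), sigma = 0)
  cv1 <- linear_calibration_curve(c(0, 500), sigma = 40)
  sd0 <- sqrt(sum(calibrate(250, 30, cv0)$density *
                    (cv0$cal_bp - 250)^2))
  sd1 <- sqrt(sum(calibrate(250, 30, cv1)$density *
                    (cv1$cal_bp - 250)^2))
  expect_equal(sd0, 30, tolerance = 0.01)
  expect_equal(sd1, 50, tolerance = 0.01)
})

test_that("support overflow errors name the offending end", {
  cv <- linear_calibration_curve(c(0, 500))
  expect_error(calibrate(490, 30, cv), "older end")
  expect_error(calibrate(5, 30, cv), "younger end")
})

test_that("a wiggle in the curve produces a matching bimodal posterior", {
  # non-monotone tent-shaped curve: the 14C age 120 BP is crossed at
  # cal 120 and cal 180, so the posterior must be bimodal
  grid <- 0:400
  mu <- ifelse(grid <= 150, grid,
               ifelse(grid <= 250, 300 - grid, grid - 100))
  cv <- calibration_curve(grid, mu, sigma = 0)
  cd <- calibrate(120, 15, cv)
  # brute-force oracle on a 0.2-y grid
  fine <- seq(0, 400, by = 0.2)
  mu_f <- approx(grid, mu, xout = fine)$y
  dens_f <- dnorm(120, mu_f, 15)
  dens_f <- dens_f / sum(dens_f)
  # split the two humps at the curve's local maximum (cal 150)
  mass_pkg <- c(sum(cd$density[cd$cal_bp <= 150]),
                sum(cd$density[cd$cal_bp > 150]))
  mass_ora <- c(sum(dens_f[fine <= 150]), sum(dens_f[fine > 150]))
  expect_gt(min(mass_pkg), 0.1)       # genuinely bimodal
  expect_equal(mass_pkg, mass_ora, tolerance = 0.01)
})

test_that("the posterior is stable under knot refinement", {
  grid5 <- seq(0, 500, by = 5)
  cv5 <- calibration_curve(grid5, 1.2 * grid5 + 10, sigma = 8)
  cv1 <- calibration_curve(0:500, 1.2 * (0:500) + 10, sigma = 8)
  cd5 <- calibrate(300, 25, cv5)
  cd1 <- calibrate(300, 25, cv1)
  mean5 <- sum(cd5$cal_bp * cd5$density)
  mean1 <- sum(cd1$cal_bp * cd1$density)
  expect_lt(abs(mean5 - mean1), 0.01)
  expect_equal(sum(cd5$density), sum(cd1$density), tolerance = 1e-9)
})

test_that("SPD sums densities and respects normalization", {
  cv <- linear_calibration_curve(c(0, 800))
  d1 <- calibrate(200, 30, cv)
  spd1 <- sum_probabilities(list(d1))
  expect_equal(spd1$density[match(d1$cal_bp, spd1$cal_bp)], d1$density)
  spd2 <- sum_probabilities(list(d1, d1), normalize = TRUE)
  expect_equal(spd2$density[match(d1$cal_bp, spd2$cal_bp)], d1$density,
               tolerance = 1e-12)
  cv_wide <- linear_calibration_curve(c(0, 1000))
  dates <- simulate_radiocarbon_dates(rep(c(1200, 1500), 4), cv_wide, 25,
                                      seed = 2)
  spd <- sum_probabilities(calibrate_dates(dates, cv_wide))
  expect_equal(sum(spd$density), 8, tolerance = 1e-6)
})

test_that("SPD of clustered dates recovers the cluster positions", {
  cv <- linear_calibration_curve(c(-100, 1200))
  yrs <- rep(c(1350, 1550, 1750), each = 21)
  dates <- simulate_radiocarbon_dates(yrs, cv, 30, seed = 19)
  spd <- sum_probabilities(calibrate_dates(dates, cv))
  pk <- spd_peaks(spd, min_height = 0.3, min_sep = 80)
  expect_equal(nrow(pk), 3)
  pk <- pk[order(pk$cal_ad), ]
  expect_true(all(abs(pk$cal_ad - c(1350, 1550, 1750)) <= 25))
})

test_that("SPD of a point source is centered on the true year", {
  cv <- linear_calibration_curve(c(0, 800))
  dates <- simulate_radiocarbon_dates(rep(1600, 500), cv, 30, seed = 8)
  spd <- sum_probabilities(calibrate_dates(dates, cv), normalize = TRUE)
  mean_ad <- sum(spd$cal_ad * spd$density)
  expect_lt(abs(mean_ad - 1600), 5)
})

test_that("outlier screening flags only the discordant date", {
  cv <- linear_calibration_curve(c(0, 1500))
  good <- data.frame(lab_id = c("A", "B", "C"),
                     c14_bp = c(500, 520, 490), sigma = 30)
  sc <- screen_outliers(good, cv)
  expect_false(any(sc$flagged))
  bad <- rbind(good, data.frame(lab_id = "X", c14_bp = 500 + 10 * 30,
                                sigma = 30))
  sc <- screen_outliers(bad, cv)
  expect_equal(sc$lab_id[sc$flagged], "X")
  # permutation invariance of the flag decisions
  perm <- bad[c(3, 1, 4, 2), ]
  sc_p <- screen_outliers(perm, cv)
  expect_equal(sc_p$flagged[match(sc$lab_id, sc_p$lab_id)], sc$flagged)
  expect_error(screen_outliers(good[1:2, ], cv), "at least 3")
})

test_that("BP/AD conversion is the 1950 pivot and self-inverse", {
  expect_equal(bp_ad_convert(1850, "ad_to_bp"), 100)
  expect_equal(bp_ad_convert(0, "bp_to_ad"), 1950)
  yrs <- c(-500, 0, 1000, 1950, 2020)
  expect_equal(bp_ad_convert(bp_ad_convert(yrs, "ad_to_bp"), "bp_to_ad"),
               yrs)
})

test_that("published-format curve files are parsed", {
  p <- tempfile(fileext = ".14c")
  writeLines(c("# synthetic curve, 5-column release format",
               "500,620,12,0,0", "400,505,10,0,0", "300,360,9,0,0",
               "200,240,8,0,0", "100,115,8,0,0", "0,5,8,0,0"), p)
  cv <- read_calibration_curve(p)
  expect_s3_class(cv, "calibration_curve")
  expect_equal(range(cv$cal_bp), c(0, 500))
  expect_equal(diff(cv$cal_bp)[1], 1)
  expect_equal(cv$c14_bp[cv$cal_bp == 350], (505 + 360) / 2)
})
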