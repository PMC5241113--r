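law_mean05 <- growth_law("mean", c(c = 0.5))

test_that("zero recruitment yields an empty inventory", {
  h <- recruitment_history(data.frame(start = 1000, end = 2000, rate = 0),
                           mortality_rate = 0, census_year = 2000)
  tr <- simulate_inventory(h, law_mean05, seed = 1)
  expect_equal(nrow(tr), 0)
})

test_that("constant recruitment with mean growth gives the analytic count", {
  # recruit years 1001..2000, c = 0.5: dbh >= 30 iff recruited by 1940,
  # so 940 of the 1000 recruit-years survive the threshold
  h <- recruitment_history(data.frame(start = 1000, end = 2000, rate = 10),
                           mortality_rate = 0, census_year = 2000)
  tr <- simulate_inventory(h, law_mean05, seed = 1, deterministic = TRUE)
  expect_equal(length(unique(tr$recruit_year)), 940)
  expect_equal(nrow(tr), 9400)
  expect_equal(tr$dbh_cm, 0.5 * tr$age_yr, tolerance = 1e-7)
  expect_true(all(tr$dbh_cm >= 30))
  expect_lte(max(tr$dbh_cm), 500 + 1e-6)
})

test_that("a halted pulse yields a front-loaded unimodal structure", {
  # pulse (1300, 1850], census 2000: youngest cohort is 150 y old,
  # 150 * 0.44 = 66 cm; survival decay makes class counts decrease above it
  h <- recruitment_history(data.frame(start = 1300, end = 1850, rate = 50),
                           mortality_rate = 0.005, census_year = 2000)
  tr <- simulate_inventory(h, growth_law("mean", c(c = 0.44)),
                           seed = 3, deterministic = TRUE)
  expect_equal(min(tr$dbh_cm), 66, tolerance = 1e-6)
  # the fullest class is the one holding the youngest cohort, and counts
  # trend downward with diameter (survival decays with age)
  cnt <- hist(tr$dbh_cm, breaks = seq(66, 326, 10), plot = FALSE)$counts
  expect_equal(which.max(cnt), 1)
  expect_lt(cor(seq_along(cnt), cnt, method = "spearman"), -0.9)
})

test_that("a law with non-positive growth at the start is rejected", {
  h <- recruitment_history(data.frame(start = 1800, end = 1900, rate = 5))
  bad <- growth_law("linear", c(a = -1, b = 0.001))
  expect_error(simulate_inventory(h, bad, seed = 1), "non-positive growth")
})

test_that("growth observations follow the law plus truncated noise", {
  obs <- simulate_growth_observations(growth_law("mean", c(c = 0.44)),
                                      c(35, 80, 120), seed = 1)
  expect_equal(obs$mai_cm_yr, rep(0.44, 3))
  obs <- simulate_growth_observations(
    growth_law("linear", c(a = 0.1, b = 0.01)), 40, seed = 1)
  expect_equal(obs$mai_cm_yr, 0.5)
  # Monte-Carlo: sample mean within 3 SE of the law's mean rate
  law <- growth_law("canham", c(gmax = 0.6, Dopt = 60, Sd = 1),
                    noise_sd = 0.1)
  D <- seq(10, 150, length.out = 500)
  obs <- simulate_growth_observations(law, D, seed = 11)
  expect_lt(abs(mean(obs$mai_cm_yr) - mean(growth_rate(law, D))),
            3 * 0.1 / sqrt(500))
  expect_true(all(obs$mai_cm_yr >= 0))
})

test_that("ring series match the shared ODE solution", {
  rs <- simulate_tree_ring_series(law_mean05, 1, seed = 1, max_age = 100)
  expect_equal(nrow(rs), 100)
  expect_equal(rs$dbh_cm[100], 50, tolerance = 1e-6)
  # noise-free series equals the chronology solver at 1-y resolution
  law <- growth_law("gompertz", c(a = 0.01, K = 200))
  rs <- simulate_tree_ring_series(law, 2, seed = 1, max_age = 60)
  ode <- age_to_diameter(law, 1:60)
  for (id in unique(rs$tree_id)) {
    expect_equal(rs$dbh_cm[rs$tree_id == id], ode, tolerance = 1e-6)
  }
  expect_equal(nrow(simulate_tree_ring_series(law, 0, seed = 1)), 0)
})

test_that("simulated radiocarbon ages track the curve", {
  cv <- linear_calibration_curve(c(0, 1000))
  d <- simulate_radiocarbon_dates(1750, cv, sigma = 1e-9, seed = 1)
  expect_equal(d$c14_bp, 200, tolerance = 1e-6)
  # empirical SD of replicate measurements within 10% of sigma
  d <- simulate_radiocarbon_dates(rep(1600, 1000), cv, sigma = 30,
                                  seed = 5)
  expect_lt(abs(sd(d$c14_bp) - 30) / 30, 0.10)
  expect_equal(nrow(simulate_radiocarbon_dates(numeric(0), cv, 30, 1)), 0)
  expect_error(simulate_radiocarbon_dates(3000, cv, 30, 1),
               "outside the calibration-curve support")
})

test_that("deterministic histories are exact and date the last recruit", {
  # zero noise, zero mortality: diameter is an exact function of recruit
  # year, and the youngest retained cohort dates the end of recruitment
  h <- recruitment_history(data.frame(start = 1300, end = 1850, rate = 5),
                           mortality_rate = 0, census_year = 2000)
  law <- growth_law("mean", c(c = 0.44))
  tr <- simulate_inventory(h, law, seed = 9, deterministic = TRUE)
  expect_equal(tr$dbh_cm, 0.44 * (2000 - tr$recruit_year),
               tolerance = 1e-7)
  last_year <- 2000 - min(tr$dbh_cm) / 0.44
  expect_lt(abs(last_year - 1850), 1)
})

test_that("higher mortality never increases the surviving count", {
  h0 <- data.frame(start = 1300, end = 1850, rate = 30)
  law <- growth_law("mean", c(c = 0.44))
  counts <- vapply(c(0, 0.005, 0.01, 0.02, 0.04), function(m) {
    h <- recruitment_history(h0, mortality_rate = m, census_year = 2000)
    nrow(simulate_inventory(h, law, seed = 77))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("generators are bit-reproducible under a fixed seed", {
  h <- halt_history(rate = 20)
  law <- growth_law("mean", c(c = 0.44), noise_sd = 0.15)
  expect_identical(simulate_inventory(h, law, seed = 123),
                   simulate_inventory(h, law, seed = 123))
  cv <- linear_calibration_curve(c(0, 1000))
  expect_identical(
    simulate_radiocarbon_dates(rep(1500, 5), cv, 30, seed = 4),
    simulate_radiocarbon_dates(rep(1500, 5), cv, 30, seed = 4))
})

test_that("scenario YAML round-trips into history and law", {
  p <- tempfile(fileext = ".yml")
  writeLines(c(
    "epochs:",
    "  - start: 1300",
    "    end: 1850",
    "    rate: 2000",
    "mortality_rate: 0.025",
    "census_year: 2000",
    "law:",
    "  model: mean",
    "  params: {c: 0.44}",
    "  noise_sd: 0.15",
    "seed: 11"), p)
  sc <- read_scenario(p)
  expect_equal(sc$history$epochs$rate, 2000)
  expect_equal(sc$law$model, "mean")
  expect_equal(sc$law$params$c, 0.44)
  expect_equal(sc$seed, 11)
})
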