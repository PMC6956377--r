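test_that("mass loss is exact arithmetic with the documented sign handling", {
  expect_equal(mass_loss_percent(gravimetric_sample(100, 90, 80)), 20)
  expect_equal(mass_loss_percent(gravimetric_sample(100, 110, 100)), 0)
  # the 4-week core-system measurement: 29.19% loss
  expect_equal(mass_loss_percent(gravimetric_sample(100, 80, 70.81)), 29.19)
  expect_warning(
    out <- mass_loss_percent(gravimetric_sample(100, 120, 104)),
    "negative mass loss")
  expect_equal(out, -4)
})

test_that("water uptake is exact, scale-invariant arithmetic", {
  expect_equal(water_uptake_percent(gravimetric_sample(100, 100, 100)), 0)
  # the 1-week core-system measurement: 135.9% uptake
  expect_equal(water_uptake_percent(gravimetric_sample(100, 235.9, 100)),
               135.9)
  a <- gravimetric_sample(100, 150, 90)
  b <- gravimetric_sample(100, 300, 180)
  expect_equal(water_uptake_percent(a), water_uptake_percent(b))
})

test_that("gravimetric formulas hold over random valid weights", {
  set.seed(42)
  for (i in 1:50) {
    w0 <- runif(1, 10, 500)
    wd <- runif(1, 0.1, 1) * w0
    ww <- wd * runif(1, 1, 4)
    s <- gravimetric_sample(w0, ww, wd)
    expect_gte(mass_loss_percent(s), 0)
    expect_lt(mass_loss_percent(s), 100)
    expect_gte(water_uptake_percent(s), 0)
    k <- runif(1, 0.5, 2)
    expect_equal(water_uptake_percent(gravimetric_sample(w0, k * ww, k * wd)),
                 water_uptake_percent(s))
  }
})

test_that("gravimetric invariants are enforced", {
  expect_error(gravimetric_sample(0, 1, 1), "w0")
  expect_error(gravimetric_sample(100, 80, 90), "wet weight")
})

test_that("burst fraction interpolates the 24 h cumulative amount", {
  cv <- cumulative_release(c(3600, 86400, 7 * 86400), c(50, 270, 400),
                           dose = 1000)
  expect_equal(burst_fraction(cv), 0.27)        # exact observation at 24 h
  # interpolated halfway between 1 h and 24 h observations
  mid <- (3600 + 86400) / 2
  expect_equal(burst_fraction(cv, window = mid),
               (50 + 270) / 2 / 1000)
  zero <- cumulative_release(c(3600, 86400), c(0, 0), dose = 1000)
  expect_equal(burst_fraction(zero), 0)
  late <- cumulative_release(c(2, 3) * 86400, c(10, 20), dose = 100)
  expect_error(burst_fraction(late), "before")
})

test_that("burst fraction is non-decreasing in window length", {
  cv <- cumulative_release((1:10) * 3600 * 6, cumsum(runif(10, 0, 30)),
                           dose = 500)
  w <- seq(6 * 3600, 60 * 3600, length.out = 8)
  b <- vapply(w, function(x) burst_fraction(cv, x), numeric(1))
  expect_true(all(diff(b) >= 0))
})

test_that("phase rate recovers linear slopes in amount per day", {
  tt <- (7:42) * 86400
  cv <- cumulative_release(tt, 500 + 70 * (tt / 86400 - 7), dose = 6000)
  expect_equal(phase_rate(cv, 7 * 86400, 42 * 86400), 70, tolerance = 1e-10)
  flat <- cumulative_release(tt, rep(500, length(tt)), dose = 6000)
  expect_equal(phase_rate(flat, 7 * 86400, 42 * 86400), 0)
  expect_error(phase_rate(cv, 0, 86400), "at least 2")
})

test_that("phase rate tolerates measurement noise in proportion", {
  set.seed(7)
  tt <- (7:42) * 86400
  noisy <- 500 + 60 * (tt / 86400 - 7) + rnorm(length(tt), sd = 10)
  cv <- cumulative_release(tt, pmax(noisy, 0), dose = 6000)
  expect_equal(phase_rate(cv, 7 * 86400, 42 * 86400), 60, tolerance = 0.05)
})
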