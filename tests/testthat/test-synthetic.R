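test_that("noiseless generated curves equal the forward model exactly", {
  sc <- builtin_scenarios(noise_sd = 0, n_replicates = 1L)$sls_aqueous
  cv <- simulate_release_curves(sc)[[1]]
  expect_equal(cv$fractions,
               fractional_release(sc$true_params, cv$times, quiet = TRUE))
  expect_true(all(diff(cv$fractions) >= 0))
  expect_gte(min(cv$fractions), 0.049)
  expect_lte(max(cv$fractions), 0.991)
})

test_that("generation is seeded and reproducible", {
  sc <- builtin_scenarios(seed = 9L)$meoh_water
  a <- simulate_release_curves(sc)
  b <- simulate_release_curves(sc)
  expect_identical(lapply(a, `[[`, "fractions"),
                   lapply(b, `[[`, "fractions"))
  sc2 <- builtin_scenarios(seed = 10L)$meoh_water
  expect_false(identical(simulate_release_curves(sc2)[[1]]$fractions,
                         a[[1]]$fractions))
})

test_that("builtin scenarios cover both media regimes and a low-Biot case", {
  scs <- builtin_scenarios()
  d <- vapply(scs, function(s) s$true_params$d_eff, numeric(1))
  expect_true(any(abs(d - 2.28e-15) / 2.28e-15 < 1e-12))
  expect_true(any(abs(d - 5.58e-16) / 5.58e-16 < 1e-12))
  L <- vapply(scs, function(s) biot_number(s$true_params), numeric(1))
  expect_true(any(abs(L - 1) < 0.01))
  for (s in scs) expect_s3_class(s$true_params, "model_params")
})

test_that("the half-release time of the slow-medium scenario matches the model", {
  sc <- builtin_scenarios(noise_sd = 0, n_replicates = 1L)$sls_aqueous
  cv <- simulate_release_curves(sc)[[1]]
  t50_model <- time_at_fraction(sc$true_params, 0.5)
  t50_interp <- stats::approx(cv$fractions, cv$times, xout = 0.5,
                              ties = "ordered")$y
  expect_equal(t50_interp, t50_model, tolerance = 0.05)
})

test_that("noise scales the residual spread proportionally", {
  spread <- function(sd) {
    sc <- builtin_scenarios(noise_sd = sd, n_replicates = 6L,
                            seed = 21L)$sls_aqueous
    curves <- simulate_release_curves(sc)
    clean <- fractional_release(sc$true_params, curves[[1]]$times,
                                quiet = TRUE)
    stats::sd(unlist(lapply(curves, function(cv) cv$fractions - clean)))
  }
  s1 <- spread(0.01)
  s2 <- spread(0.04)
  expect_equal(s2 / s1, 4, tolerance = 0.25)
})

test_that("round-trip: noiseless curves from every builtin scenario refit", {
  for (sc in builtin_scenarios(noise_sd = 0, n_replicates = 1L)) {
    cv <- simulate_release_curves(sc)[[1]]
    fit <- fit_release(cv, radius = sc$true_params$radius,
                       config = quick_config())
    expect_lt(abs(log10(coef(fit)[["d_eff"]] / sc$true_params$d_eff)),
              0.05)
    if (biot_number(sc$true_params) <= 100)
      expect_lt(abs(log10(coef(fit)[["h"]] / sc$true_params$h)), 0.05)
  }
})

test_that("gravimetric series round-trips its target percentages at zero noise", {
  days <- c(7, 28) * 86400
  gs <- simulate_gravimetric_series(300, days,
                                    loss_pct = c(18.85, 29.19),
                                    uptake_pct = c(135.9, 138.9),
                                    noise_sd = 0)
  expect_equal(vapply(gs, mass_loss_percent, numeric(1)), c(18.85, 29.19))
  expect_equal(vapply(gs, water_uptake_percent, numeric(1)),
               c(135.9, 138.9))
  # seeded reproducibility with noise
  g1 <- simulate_gravimetric_series(300, days, c(10, 20), c(100, 120),
                                    noise_sd = 0.05, seed = 5L)
  g2 <- simulate_gravimetric_series(300, days, c(10, 20), c(100, 120),
                                    noise_sd = 0.05, seed = 5L)
  expect_identical(g1, g2)
  for (g in g1) expect_gte(g$ww, g$wd)
})

test_that("invalid designs and profiles are rejected", {
  p <- model_params(1e-15, 1e-10)
  expect_error(release_scenario("x", p, time_design = c(1, 2)), "at least 3")
  expect_error(release_scenario("x", p,
                                time_design = list(n = 2, f_lo = 0.1,
                                                   f_hi = 0.9)),
               "at least 3")
  expect_error(release_scenario("x", p, noise_sd = -0.1))
  expect_error(simulate_gravimetric_series(100, 1, loss_pct = 110,
                                           uptake_pct = 10), "loss_pct")
  expect_error(simulate_gravimetric_series(100, 1, loss_pct = 10,
                                           uptake_pct = -5), "uptake_pct")
})
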