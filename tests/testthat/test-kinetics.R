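test_that("rate constants reproduce the closed-form anchor rates", {
  kp <- calibrate_kinetics()
  # oracle: k = -ln(fraction)/days at each calibration anchor
  expect_equal(rate_constant(35, kp), oracle_rate_from_anchor(0.80, 91),
               tolerance = 1e-9)
  expect_equal(rate_constant(45, kp), oracle_rate_from_anchor(0.20, 91),
               tolerance = 1e-9)
  # frozen magnitudes from the oracle run
  expect_equal(rate_constant(35, kp), 2.452127e-3, tolerance = 1e-6)
  expect_equal(rate_constant(45, kp), 1.768613e-2, tolerance = 1e-6)
  expect_gt(rate_constant(45, kp), rate_constant(35, kp))
  # strictly increasing across a fine temperature grid
  k <- rate_constant(seq(0, 50, by = 0.5), kp)
  expect_true(all(diff(k) > 0))
  expect_true(all(k > 0))
})

test_that("invalid temperatures and parameters are rejected", {
  expect_error(rate_constant(-300), "absolute zero")
  expect_error(rate_constant(NaN), "absolute zero")
  expect_error(kinetics_params(-1, 1e5), "arrhenius_A")
  expect_error(remaining_strength(1, 25, -3), ">= 0")
  expect_error(remaining_strength(1.2, 25, 3), "\\[0, 1\\]")
  expect_error(calibrate_kinetics(c(temp_c = 35, strength = 0.8, days = 91),
                                  c(temp_c = 35, strength = 0.2, days = 91)),
               "distinct temperatures")
  expect_error(calibrate_kinetics(c(temp_c = 35, strength = 0, days = 91)),
               "strictly in")
})

test_that("remaining strength hits the calibration anchors and decays monotonically", {
  kp <- calibrate_kinetics()
  expect_identical(remaining_strength(1, 40, 0, kp), 1)
  expect_equal(remaining_strength(1, 35, 91, kp), 0.80, tolerance = 1e-9)
  expect_equal(remaining_strength(1, 45, 91, kp), 0.20, tolerance = 1e-9)
  # printed quarter-decay consistency checks at the other two temperatures
  expect_lt(abs(remaining_strength(1, 40, 91, kp) - 0.60), 0.06)
  expect_lt(abs(remaining_strength(1, 30, 91, kp) - 0.90), 0.06)
  # non-increasing in both duration and temperature over a grid
  temps <- seq(0, 50, by = 5)
  days <- seq(0, 364, by = 7)
  s <- outer(temps, days,
             function(tc, dd) remaining_strength(1, tc, dd, kp))
  expect_true(all(apply(s, 1, function(row) all(diff(row) <= 0))))
  expect_true(all(apply(s, 2, function(col) all(diff(col) <= 0))))
})

test_that("exponential mode matches the closed form; discrete-linear is first-order close", {
  kp <- calibrate_kinetics()
  for (tc in c(20, 30, 40)) {
    k <- oracle_rate_from_anchor(0.80, 91) *
      exp(kp$activation_energy_Ea / kp$gas_constant_R *
            (1 / 308.15 - 1 / (tc + 273.15)))
    for (dd in c(7, 35, 91)) {
      expect_equal(remaining_strength(0.9, tc, dd, kp), 0.9 * exp(-k * dd),
                   tolerance = 1e-12)
      # per-week step error bound (7k)^2/2, accumulated over the weeks
      kt <- 7 * k
      if (kt < 0.1) {
        n <- dd / 7
        expect_lt(abs(remaining_strength(1, tc, dd, kp) -
                        remaining_strength(1, tc, dd, kp,
                                           mode = "discrete-linear")),
                  n * kt^2 / 2)
      }
    }
  }
  # discrete-linear floors at zero rather than going negative
  hot <- kinetics_params(1e30, 1e5)
  expect_identical(remaining_strength(1, 50, 70, hot,
                                      mode = "discrete-linear"), 0)
})

test_that("two-point calibration recovers the closed-form activation energy", {
  kp <- calibrate_kinetics()
  expect_equal(kp$activation_energy_Ea, oracle_Ea(35, 0.80, 45, 0.20),
               tolerance = 1e-9)
  expect_equal(kp$activation_energy_Ea, 1.611e5, tolerance = 1e-3)
  # equal anchor fractions mean no temperature dependence
  flat <- calibrate_kinetics(c(temp_c = 30, strength = 0.7, days = 91),
                             c(temp_c = 45, strength = 0.7, days = 91))
  expect_equal(flat$activation_energy_Ea, 0, tolerance = 1e-9)
  # round-trip through arbitrary anchors
  kp2 <- calibrate_kinetics(c(temp_c = 28, strength = 0.93, days = 60),
                            c(temp_c = 41, strength = 0.45, days = 120))
  expect_equal(remaining_strength(1, 28, 60, kp2), 0.93, tolerance = 1e-9)
  expect_equal(remaining_strength(1, 41, 120, kp2), 0.45, tolerance = 1e-9)
})

test_that("band rule converts stock to effective doses with floored division", {
  expect_identical(effective_doses(100, 0.90), 100)
  expect_identical(effective_doses(100, 0.70), 50)
  expect_identical(effective_doses(99, 0.40), 33)
  expect_identical(effective_doses(1000, 0.30), 0)
  # half-open boundaries: lower edge belongs to the stronger band
  expect_identical(effective_doses(90, 0.85), 90)
  expect_identical(effective_doses(90, 0.54), 45)
  expect_identical(effective_doses(90, 0.33), 30)
  expect_error(effective_doses(-1, 0.9), ">= 0")
  expect_error(strength_bands(full_min = 0.3), "triple_min < double_min")
})

test_that("effective doses are monotone in stock and in strength", {
  strengths <- seq(0, 1, by = 0.01)
  for (stock in c(7, 100, 1003)) {
    eff <- effective_doses(stock, strengths)
    expect_true(all(diff(eff) >= 0))
  }
  for (s in c(0.3, 0.45, 0.6, 0.9)) {
    eff <- effective_doses(0:300, s)
    expect_true(all(diff(eff) >= 0))
  }
})

test_that("temperature profiles validate, extend, and tabulate", {
  prof <- temperature_profile(c(0, 10, 30), c(25, 30, 27))
  expect_identical(temperature_at(prof, 0), 25)
  expect_identical(temperature_at(prof, 9), 25)
  expect_identical(temperature_at(prof, 10), 30)
  expect_identical(temperature_at(prof, 500), 27)  # last value extends
  expect_error(temperature_profile(c(0, 0), c(25, 26)),
               "strictly increasing")
  expect_error(temperature_profile(0, Inf), "finite")
  tab <- stability_table(c(30, 40), c(7, 91))
  expect_identical(names(tab), c("temp_c", "days", "strength"))
  expect_equal(tab$strength[tab$temp_c == 40 & tab$days == 91],
               remaining_strength(1, 40, 91), tolerance = 1e-12)
})
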