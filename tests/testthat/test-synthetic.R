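# Synthetic incubation generator: curve shape, determinism, noise and
# measurement model, and the electron-budget consistency check.

test_that("the modified-Gompertz curve has the advertised geometry", {
  t <- seq(0, 400, by = 0.01)
  y <- gompertzCurve(t, A = 28, Rmax = 1.4, lag = 13)
  expect_true(all(y >= 0 & y <= 28))
  expect_gt(max(y), 28 - 1e-4)                       # asymptote
  expect_lt(gompertzCurve(0, 28, 1.4, 13), 0.5)      # near zero before lag
  # numeric maximum slope equals Rmax within 1%
  slope <- diff(y) / diff(t)
  expect_lt(abs(max(slope) - 1.4) / 1.4, 0.01)
  # tangent through the inflection intercepts the baseline at the lag
  k <- which.max(slope)
  tk <- (t[k] + t[k + 1]) / 2
  intercept <- tk - y[k] / slope[k]
  expect_lt(abs(intercept - 13), 0.05)
  expect_identical(gompertzCurve(t[1:5], 0, 1, 5), rep(0, 5))
})

test_that("generation is bit-exact for a fixed scenario and seed", {
  sc <- suspendedSludgeScenario()
  a <- generateIncubation(sc, seed = 99)
  b <- generateIncubation(sc, seed = 99)
  expect_identical(a$data, b$data)
  c <- generateIncubation(sc, seed = 100)
  expect_false(identical(a$data, c$data))
  # ground truth travels with the data
  expect_s4_class(a$truth, "SyntheticScenario")
})

test_that("zero noise with full recovery reproduces the true curves", {
  sc <- suspendedSludgeScenario()
  sc@sigma[] <- 0
  ds <- generateIncubation(sc, seed = 1)
  m <- ds$data[ds$data$treatment == "M" & ds$data$analyte == "CH4" &
               ds$data$replicate == 1, ]
  expect_equal(m$conc, gompertzCurve(m$day, 28, 1.4, 13), tolerance = 1e-12)
  expect_false(any(ds$data$clamped))
})

test_that("noise is clamped at zero and flagged", {
  sc <- suspendedSludgeScenario()
  ds <- generateIncubation(sc, seed = 4)
  expect_true(all(ds$data$conc >= 0))
  early <- ds$data$analyte == "CH4" & ds$data$day == 0 &
    ds$data$treatment == "M"
  # with sigma = 0.3 and a near-zero mean, some day-0 draws clamp
  expect_true(any(ds$data$clamped[early] | ds$data$conc[early] == 0))
})

test_that("Fe(II) observations are scaled by the recoverable fraction", {
  sc <- enrichmentScenario()
  sc@sigma[] <- 0
  ds <- generateIncubation(sc, seed = 1)
  fe <- ds$data[ds$data$analyte == "FeII" & ds$data$replicate == 1, ]
  expect_equal(fe$conc, 0.65 * scenarioCurve(sc, "GS5", "FeII", fe$day),
               tolerance = 1e-12)
  # observed asymptote lands near 42 while the true pool approaches 65
  expect_lt(abs(max(fe$conc) - 42), 1)
})

test_that("the stoichiometry-driven scenario respects the electron budget", {
  st <- stoichiometricScenario(sigma = c(CH4 = 0, acetate = 0, FeII = 0))
  ds <- generateIncubation(st, seed = 1)
  cc <- stoichiometricConsistency(ds)
  expect_identical(sum(cc$violation), 0L)
  expect_true(all(cc$electronsUsed <= cc$budget + 1e-6))
  # the budget is approached as the substrate is exhausted
  expect_gt(max(cc$electronsUsed) / max(cc$budget), 0.95)
})

test_that("corrupted methane overdraws the electron budget", {
  st <- stoichiometricScenario(sigma = c(CH4 = 0, acetate = 0, FeII = 0))
  ds <- generateIncubation(st, seed = 1)
  ds$data$conc[ds$data$analyte == "CH4"] <-
    2 * ds$data$conc[ds$data$analyte == "CH4"]
  cc <- stoichiometricConsistency(ds)
  expect_gt(sum(cc$violation), 0)
})

test_that("noisy violation rate is consistent with the noise model", {
  # With noise, electrons-used at each day is approximately Gaussian around
  # the true usage with SD sqrt((8 sd_CH4)^2 + (8 sd_ac)^2 + sd_Fe^2)/sqrt(n)
  # (replicate means). Compare the observed violation rate over seeds with
  # the Monte-Carlo expectation from the true curves.
  st <- stoichiometricScenario()
  nSeeds <- 40
  viol <- total <- 0
  for (s in seq_len(nSeeds)) {
    cc <- stoichiometricConsistency(generateIncubation(st, seed = 300 + s))
    viol <- viol + sum(cc$violation)
    total <- total + nrow(cc)
  }
  rate <- viol / total
  sdComb <- sqrt((8 * 0.3)^2 + (8 * 0.7)^2 + 2^2) / sqrt(3)
  days <- st@schedule
  expected <- mean(vapply(c("M", "IR"), function(tr) {
    used <- 8 * scenarioCurve(st, tr, "CH4", days) +
      8 * scenarioCurve(st, tr, "acetate", days) +
      scenarioCurve(st, tr, "FeII", days)
    mean(stats::pnorm((used - 102 * 3) / sdComb))
  }, numeric(1)))
  expect_lt(abs(rate - expected), 0.03)
})

test_that("scenario validity rejects impossible parameters", {
  curves <- data.frame(treatment = "M", analyte = "CH4", A = 1, Rmax = 1,
                       lag = 5, sign = 1, baseline = 0)
  expect_error(syntheticScenario(curves, rho = 0), "rho")
  expect_error(syntheticScenario(curves, rho = 1.5), "rho")
  expect_error(syntheticScenario(curves, schedule = c(0, 2, 2)),
               "increasing")
  curves$A <- -1
  expect_error(syntheticScenario(curves), "nonnegative")
})

test_that("full pipeline recovers ground truth exactly when noiseless", {
  sc <- suspendedSludgeScenario()
  sc@sigma[] <- 0
  ds <- generateIncubation(sc, seed = 1)
  rep <- accountReport(ds, dose = 3)
  m <- rep[rep$treatment == "M", ]
  expect_lt(abs(m$maxCH4 - gompertzCurve(60, 28, 1.4, 13)), 1e-9)
  expect_lt(abs(m$lagDays - 13), 0.2)
  ir <- rep[rep$treatment == "IR", ]
  expect_lt(abs(ir$lagDays - 3), 0.5)
})
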