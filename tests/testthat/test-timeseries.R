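# Incubation curve descriptors: maximum, windowed rate, lag, replicate
# aggregation, and the TSV interface.

test_that("maximum cumulative product uses the replicate mean", {
  d <- rbind(curveSeries(0:5, c(0, 1, 4, 8, 9, 9)),
             transform(curveSeries(0:5, c(0, 1, 4, 8, 9, 11)),
                       replicate = 2))
  expect_identical(maxCumulative(d), 10)   # mean of 9 and 11 at the top
  # invariant under reordering of rows
  expect_identical(maxCumulative(d[sample(nrow(d)), ]), 10)
  # monotone under a later, larger observation
  d2 <- rbind(d, transform(d[d$day == 5, ], day = 6, conc = conc + 1))
  expect_gte(maxCumulative(d2), maxCumulative(d))
  expect_identical(maxCumulative(curveSeries(0:3, rep(0, 4))), 0)
  expect_error(maxCumulative(curveSeries(0:3, rep(0, 4))[0, ]), "empty")
})

test_that("windowed rate recovers an exact line to machine precision", {
  d <- curveSeries(28:35, 1.4 * (28:35 - 28), replicates = 3)
  wr <- windowRate(d, 28, 35)
  expect_equal(wr$mean, 1.4, tolerance = 1e-12)
  expect_equal(wr$sd, 0, tolerance = 1e-12)
  flat <- curveSeries(0:10, rep(5, 11))
  expect_equal(windowRate(flat, 0, 10)$mean, 0, tolerance = 1e-12)
  expect_error(windowRate(curveSeries(c(0, 20), c(0, 1)), 5, 15), "window")
})

test_that("windowed rate recovers a noisy slope within two standard errors", {
  set.seed(11)
  day <- seq(28, 44, 2)
  d <- do.call(rbind, lapply(1:3, function(r)
    data.frame(treatment = "IR", analyte = "CH4", replicate = r, day = day,
               conc = pmax(0.6 * (day - 28) + rnorm(length(day), 0, 0.2), 0))))
  wr <- windowRate(d, 28, 44)
  se <- wr$sd / sqrt(length(wr$slopes))
  expect_lt(abs(wr$mean - 0.6), 2 * max(se, 0.02))
  # slope bias shrinks with replication: n = 30 beats n = 3 on average
  errAt <- function(n, seed) {
    set.seed(seed)
    d <- do.call(rbind, lapply(seq_len(n), function(r)
      data.frame(treatment = "IR", analyte = "CH4", replicate = r, day = day,
                 conc = pmax(0.6 * (day - 28) + rnorm(length(day), 0, 0.2), 0))))
    abs(windowRate(d, 28, 44)$mean - 0.6)
  }
  e3 <- mean(vapply(1:20, function(s) errAt(3, s), numeric(1)))
  e30 <- mean(vapply(1:20, function(s) errAt(30, s), numeric(1)))
  expect_lt(e30, e3)
})

test_that("lag time matches the tangent parameter of a pure Gompertz curve", {
  day <- seq(0, 60, 2)
  for (lam in c(3, 13, 20)) {
    d <- curveSeries(day, gompertzCurve(day, A = 28, Rmax = 1.4, lag = lam))
    lt <- lagTime(d)
    expect_true(lt$defined)
    expect_lt(abs(lt$lag - lam), 2)   # within one sampling interval
  }
})

test_that("degenerate curves yield zero or undefined lag", {
  day <- seq(0, 30, 2)
  rising <- curveSeries(day, gompertzCurve(day, A = 20, Rmax = 2, lag = 0))
  lt <- lagTime(rising)
  expect_true(lt$defined)
  expect_lt(lt$lag, 2)
  flat <- curveSeries(day, rep(0.1, length(day)))
  expect_false(lagTime(flat)$defined)
  expect_true(is.na(lagTime(flat)$lag))
})

test_that("replicate statistics use the sample SD and format conventionally", {
  rs <- replicateStats(c(6.0, 6.6, 7.2))
  expect_equal(rs$mean, 6.6)
  expect_equal(rs$sd, 0.6)
  expect_identical(rs$formatted, "6.6 ± 0.6")
  expect_identical(replicateStats(c(5, 5, 5))$formatted, "5.0 ± 0.0")
  one <- replicateStats(4.2)
  expect_true(is.na(one$sd))
  expect_identical(one$formatted, "4.2")
  expect_error(replicateStats(numeric(0)), "value")
})

test_that("the TSV interface round-trips and validates its input", {
  ds <- generateIncubation(suspendedSludgeScenario(), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIncubationTSV(ds$data, path)
  back <- readIncubationTSV(path)
  expect_equal(back$conc, ds$data$conc, tolerance = 1e-9)
  expect_identical(back$treatment, ds$data$treatment)

  bad <- ds$data
  bad$day[1:2] <- bad$day[2:1]   # out-of-order times within a replicate
  expect_error(writeIncubationTSV(bad, path), "strictly increasing")
  dup <- ds$data
  dup$day[2] <- dup$day[1]       # duplicated time within a replicate
  expect_error(writeIncubationTSV(dup, path), "duplicated")
  neg <- ds$data; neg$conc[1] <- -1
  expect_error(writeIncubationTSV(neg, path), "negative")
})
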