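# Yield prediction, electron partitioning, blank correction and recovery.

net6 <- composeReactions(recipes$net6)
net7 <- composeReactions(recipes$net7)
net8 <- composeReactions(recipes$net8)
net9 <- composeReactions(recipes$net9)

test_that("theoretical product concentrations follow the net stoichiometry", {
  expect_identical(theoreticalProduct(3, net9, "CH4"), 38.25)
  expect_identical(theoreticalProduct(3, net8, "CH4"), 11.25)
  expect_identical(theoreticalProduct(0, net9, "CH4"), 0)
  expect_error(theoreticalProduct(3, net6, "CH4"), "product")
})

test_that("electron diversion scales the hydrogen-route methane affinely", {
  expect_identical(partitionedMethane(3, 1/3, net8), 7.5)
  expect_identical(partitionedMethane(3, 0, net8), 11.25)
  expect_identical(partitionedMethane(3, 1, net8), 0)
  # affine and decreasing in the fraction
  f <- seq(0, 1, by = 0.125)
  ch4 <- vapply(f, partitionedMethane, numeric(1), dose = 3, h2Route = net8)
  expect_equal(ch4, 11.25 * (1 - f))
  expect_true(all(diff(ch4) < 0))
  expect_error(partitionedMethane(3, 1.2, net8), "fraction")
  expect_error(partitionedMethane(3, -0.1, net8), "fraction")
})

test_that("acceptor demand reproduces the ferric hydroxide requirement", {
  expect_identical(acceptorDemand(26, rxSet[["r2"]]), 208)
  expect_identical(acceptorDemand(1, rxSet[["r2"]]), 8)
  expect_identical(acceptorDemand(0, rxSet[["r2"]]), 0)
  expect_error(acceptorDemand(26, rxSet[["r3"]]), "acceptor")
})

test_that("blank correction subtracts one-to-one and clamps at zero", {
  x <- blankCorrect(60, 23)
  expect_identical(as.numeric(x), 37)
  expect_false(attr(x, "clamped"))
  expect_identical(as.numeric(blankCorrect(105, 4)), 101)
  expect_identical(as.numeric(blankCorrect(5, 0)), 5)
  low <- blankCorrect(3, 7)
  expect_identical(as.numeric(low), 0)
  expect_true(attr(low, "clamped"))
})

test_that("substrate consumption is back-calculated from Fe(III) use", {
  expect_identical(inferSubstrateFromAcceptor(37, net6), 1.2)
  expect_identical(inferSubstrateFromAcceptor(30, net6), 1.0)
  expect_identical(inferSubstrateFromAcceptor(102, net7), 1.0)
  expect_error(inferSubstrateFromAcceptor(37, rxSet[["r3"]]), "FeOH3")
})

test_that("acceptor demand round-trips through substrate inference", {
  for (conc in c(0.5, 1.2, 2, 3)) {
    fe <- acceptorDemand(conc, net6, substrateId = "oleate")
    expect_equal(inferSubstrateFromAcceptor(fe, net6), round(conc, 1))
  }
})

test_that("methane electron fractions match under both scopes", {
  expect_identical(round(methaneElectronFraction(1.2, 1, "acetogenic", rxSet)),
                   32)
  expect_identical(round(methaneElectronFraction(1.2, 1, "full", rxSet)), 9)
  expect_equal(methaneElectronFraction(1.2, 1, "full", rxSet),
               8 * 1.2 / 102 * 100)
  expect_identical(methaneElectronFraction(0, 1, "full", rxSet), 0)
  expect_error(methaneElectronFraction(1.2, 0, "full", rxSet), "positive")
})

test_that("expected Fe(II) partitions the uncaptured electrons", {
  ef <- expectedFe2(1, 1.2, 3.4, rxSet)
  expect_equal(ef$fe2FromH2, 20.4)
  expect_equal(ef$acetateAvailable, 5.6)
  expect_equal(ef$fe2FromAcetate, 44.8)
  expect_false(ef$clamped)

  # everything routed to methane leaves nothing for iron
  all2ch4 <- expectedFe2(1, 3.75, 9, rxSet)
  expect_equal(all2ch4$total, 0)
  expect_equal(all2ch4$fe2FromH2, 0)

  # nothing consumed: the full electron content appears as potential Fe(II)
  none <- expectedFe2(1, 0, 0, rxSet)
  expect_equal(none$fe2FromH2, 30)
  expect_equal(none$acetateAvailable, 9)
  expect_equal(none$fe2FromAcetate, 72)
  expect_equal(none$total, electronContent("oleate", rxSet))

  # over-measured pools clamp and flag rather than going negative
  over <- expectedFe2(1, 4, 10, rxSet)
  expect_true(over$clamped)
  expect_equal(over$total, 0)
})

test_that("electron conservation holds across the ledger identity", {
  # 8 CH4 + Fe(II) + 8 residual acetate == 102 x substrate for any split
  for (ch4 in c(0, 0.6, 1.2, 2)) {
    for (ac in c(0, 3.4, 6)) {
      ef <- expectedFe2(1, ch4, ac, rxSet)
      if (ef$clamped) next
      expect_equal(8 * ch4 + ef$total + 8 * ac, 102)
    }
  }
})

test_that("recovery is a scale-invariant percentage and flags > 100", {
  expect_equal(methaneRecovery(22, 38.25)$recovery, 57.51634, tolerance = 1e-6)
  expect_equal(methaneRecovery(35, 38.25)$recovery, 91.50327, tolerance = 1e-6)
  expect_identical(methaneRecovery(0, 38.25)$recovery, 0)
  r <- methaneRecovery(22, 38.25)$recovery
  for (k in c(0.1, 2, 17)) {
    expect_equal(methaneRecovery(22 * k, 38.25 * k)$recovery, r)
  }
  expect_true(methaneRecovery(40, 38.25)$exceeds100)
  expect_error(methaneRecovery(22, 0), "positive")
})

test_that("the electron ledger allocates within the dose budget", {
  led <- electronLedger(1, ch4 = 1.2, fe2Corrected = 37, acetateResidual = 3.4,
                        scope = "full", reactions = rxSet)
  expect_identical(led$totalElectrons, 102)
  expect_equal(unname(led$allocation["CH4"]), 9.6)
  expect_false(led$overdrawn)
  expect_equal(sum(led$allocation) + led$unallocated, 102)
  over <- electronLedger(0.1, ch4 = 5, scope = "acetogenic", reactions = rxSet)
  expect_true(over$overdrawn)
})
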