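# Formula parsing, balance verification and exact composition.

test_that("formulas parse to exact element counts", {
  expect_equal(parseFormula("Fe(OH)3"), c(Fe = 1L, O = 3L, H = 3L))
  expect_equal(parseFormula("C18H33O2"), c(C = 18L, H = 33L, O = 2L))
  expect_equal(parseFormula("H"), c(H = 1L))
  expect_equal(parseFormula("Ca(NO3)2"), c(Ca = 1L, N = 2L, O = 6L))
  expect_error(parseFormula("Fe(OH"), "position")
  expect_error(parseFormula("(OH)3)"), "position")
  expect_error(parseFormula("h2o"), "position")
  expect_error(parseFormula(""), "empty")
})

test_that("every registered elementary reaction balances exactly", {
  for (nm in names(rxSet)) {
    rep <- checkBalance(rxSet[[nm]], spReg)
    expect_true(balanced(rep), label = sprintf("reaction %s balanced", nm))
    expect_true(all(elementResiduals(rep) == 0))
    expect_identical(chargeResidual(rep), 0)
  }
})

test_that("a perturbed coefficient is caught as an imbalance", {
  # beta-oxidation with the H2 yield altered from 15 to 14
  bad <- parseEquation("oleate + 16 H2O -> 9 acetate + 14 H2 + 8 H", spReg)
  rep <- checkBalance(bad, spReg)
  expect_false(balanced(rep))
  expect_true(elementResiduals(rep)[["H"]] != 0)
})

test_that("balance checking rejects unknown species", {
  r <- reaction(c("H2", "unobtainium"), c(-1, 1))
  expect_error(checkBalance(r, spReg), "unknown species")
})

test_that("composed net reactions reproduce the printed overall coefficients", {
  net6 <- composeReactions(recipes$net6)
  expect_false("H2" %in% reactionSpecies(net6))
  expect_identical(coefficient(net6, "FeOH3", exact = TRUE),
                   c(num = -30, den = 1))
  expect_identical(coefficient(net6, "H", exact = TRUE), c(num = -52, den = 1))
  expect_identical(coefficient(net6, "H2O", exact = TRUE), c(num = 74, den = 1))
  expect_identical(coefficient(net6, "acetate", exact = TRUE),
                   c(num = 9, den = 1))
  expect_identical(coefficient(net6, "Fe2", exact = TRUE), c(num = 30, den = 1))

  net7 <- composeReactions(recipes$net7)
  expect_false(any(c("H2", "acetate") %in% reactionSpecies(net7)))
  expect_identical(coefficient(net7, "FeOH3", exact = TRUE),
                   c(num = -102, den = 1))
  expect_identical(coefficient(net7, "H", exact = TRUE),
                   c(num = -187, den = 1))
  expect_identical(coefficient(net7, "HCO3", exact = TRUE),
                   c(num = 18, den = 1))
  expect_identical(coefficient(net7, "H2O", exact = TRUE),
                   c(num = 254, den = 1))

  net8 <- composeReactions(recipes$net8)
  expect_identical(coefficient(net8, "CH4", exact = TRUE),
                   c(num = 15, den = 4))          # 3.75
  expect_identical(coefficient(net8, "HCO3", exact = TRUE),
                   c(num = -15, den = 4))
  expect_identical(coefficient(net8, "H2O", exact = TRUE),
                   c(num = -19, den = 4))         # 4.75
  expect_identical(coefficient(net8, "H", exact = TRUE), c(num = 17, den = 4))

  net9 <- composeReactions(recipes$net9)
  expect_identical(coefficient(net9, "CH4", exact = TRUE),
                   c(num = 51, den = 4))          # 12.75
  expect_identical(coefficient(net9, "HCO3", exact = TRUE),
                   c(num = 21, den = 4))          # 5.25
  expect_identical(coefficient(net9, "H2O", exact = TRUE),
                   c(num = -55, den = 4))         # 13.75
  expect_identical(coefficient(net9, "H", exact = TRUE), c(num = 17, den = 4))

  # every composed net reaction still balances exactly
  for (net in list(net6, net7, net8, net9))
    expect_true(balanced(checkBalance(net, spReg)))
})

test_that("exact cancellation yields the empty reaction", {
  r3 <- rxSet[["r3"]]
  net <- composeReactions(reactionRecipe(list(r3, r3), c(1, -1)))
  expect_true(isEmptyReaction(net))
  expect_error(reactionRecipe(list(), numeric(0)), "multiplier|least one")
})

test_that("compose agrees with naive summation on random balanced reactions", {
  set.seed(202)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    rs <- replicate(k, randomToyReaction(), simplify = FALSE)
    rs <- Filter(Negate(isEmptyReaction), rs)
    if (!length(rs)) next
    mult <- sample(c(-3:-1, 1:3), length(rs), replace = TRUE) /
      sample(c(1, 2, 4), length(rs), replace = TRUE)
    net <- composeReactions(reactionRecipe(rs, lapply(
      seq_along(rs), function(j) c(mult[j] * 4, 4))))
    got <- stoichiometry(net)
    got <- got[order(names(got))]
    expect_equal(got, naiveCompose(rs, mult), tolerance = 1e-12)
  }
})

test_that("equation round-trips through format and parse", {
  for (nm in names(rxSet)) {
    r <- rxSet[[nm]]
    back <- parseEquation(formatReaction(r), spReg)
    expect_true(sameReaction(r, back), label = sprintf("round trip %s", nm))
  }
})
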