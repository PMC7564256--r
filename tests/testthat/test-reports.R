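# Report assembly and the pipeline configuration layer.

test_that("recipe specifications parse and compose", {
  rep9 <- composeReport("1 + 9*3 + 15*5", rxSet)
  expect_identical(rep9$deltaG0, -461.8)
  expect_identical(coefficient(rep9$reaction, "CH4"), 12.75)
  expect_match(rep9$equation, "12.75 CH4")

  rep6 <- composeReport("1 + 15*4", rxSet)
  expect_identical(coefficient(rep6$reaction, "FeOH3"), -30)

  cancel <- composeReport("3 + -1*3", rxSet)
  expect_true(isEmptyReaction(cancel$reaction))
  expect_identical(cancel$deltaG0, 0)

  expect_error(parseRecipeSpec("1 + 99*12", rxSet), "out of range")
  expect_error(parseRecipeSpec("", rxSet), "parse")
})

test_that("the balance report covers the whole shipped table", {
  br <- balanceReport(rxSet)
  expect_identical(nrow(br), length(rxSet))
  expect_true(all(br$balanced))
  expect_true(all(br$maxAbsResidual == 0))
  expect_true(all(br$chargeResidual == 0))
})

test_that("the prediction report assembles the headline expectations", {
  pr <- predictReport(3, acceptorDose = 100, reactions = rxSet)
  val <- function(q) pr$value[grepl(q, pr$quantity, fixed = TRUE)]
  expect_identical(val("complete conversion"), 38.25)
  expect_identical(val("hydrogen route"), 11.25)
  expect_identical(val("electrons to Fe(III)"), 7.5)
  expect_identical(val("stoichiometric acetate pool"), 27)
  expect_identical(val("Fe(OH)3 demand"), 216)  # 27 * 8
  expect_identical(val("electron content of dose"), 306)
  expect_true(all(nzchar(pr$provenance)))

  zero <- predictReport(0, reactions = rxSet)
  expect_true(all(zero$value[zero$quantity != "acceptor dose"] == 0))
})

test_that("the account report mirrors descriptor and recovery layout", {
  sc <- suspendedSludgeScenario()
  sc@sigma[] <- 0
  ds <- generateIncubation(sc, seed = 1)
  ar <- accountReport(ds, dose = 3)
  expect_setequal(ar$treatment, c("M", "IR"))
  m <- ar[ar$treatment == "M", ]
  expect_equal(m$theoreticalCH4, 38.25)
  expect_equal(m$recoveryPct, m$maxCH4 / 38.25 * 100)
  expect_true(all(grepl("maxCumulative", ar$provenance)))
  # a dataset without methane is rejected
  noCH4 <- ds$data[ds$data$analyte != "CH4", ]
  expect_error(accountReport(noCH4, dose = 3), "CH4")
})

test_that("simulation writes a reproducible TSV plus ground-truth sidecar", {
  outdir <- withr::local_tempdir()
  sc <- suspendedSludgeScenario()
  p1 <- simulateReport(sc, outdir = file.path(outdir, "a"), seed = 12)
  p2 <- simulateReport(sc, outdir = file.path(outdir, "b"), seed = 12)
  expect_identical(readLines(p1[["tsv"]]), readLines(p2[["tsv"]]))
  truth <- jsonlite::read_json(p1[["truth"]], simplifyVector = TRUE)
  expect_identical(truth$seed, 12L)
  expect_equal(truth$rho, 1)
  back <- readIncubationTSV(p1[["tsv"]])
  expect_identical(nrow(back), nrow(generateIncubation(sc, seed = 12)$data))
})

test_that("pipeline configuration applies defaults and validates paths", {
  cfg <- readPipelineConfig(NULL)
  expect_identical(cfg$dose$substrate, 3)
  expect_identical(cfg$window$start, 28)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(dose = list(substrate = 1, acceptor = 75),
                            seed = 7), path, auto_unbox = TRUE)
  cfg <- readPipelineConfig(path)
  expect_identical(cfg$dose$substrate, 1L)
  expect_identical(cfg$window$start, 28)
  jsonlite::write_json(list(reactions = "/nonexistent/file.tsv"), path,
                       auto_unbox = TRUE)
  expect_error(readPipelineConfig(path), "does not exist")
})
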