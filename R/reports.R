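# Report assembly tying the stages into a reproducible pipeline: balance
# verification, recipe composition, yield prediction, dataset accounting and
# simulation. Every reported number carries a provenance string naming the
# operation and the reaction labels it used.

#' Read a pipeline configuration
#'
#' YAML (or JSON) configuration with optional fields `species`, `reactions`,
#' `thermo` (paths; the shipped tables are used when omitted), `timeseries`
#' (TSV path), `dose` (`substrate`, `acceptor`, mmol/L), `window` (`start`,
#' `end`, days), `seed`, and `outdir`.
#'
#' @param file Path to the configuration file, or `NULL` for all defaults.
#' @return A list of class `"pipelineConfig"`.
#' @export
readPipelineConfig <- function(file = NULL) {
  cfg <- list()
  if (!is.null(file)) {
    cfg <- if (grepl("\\.json$", file)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configuration requires the 'yaml' package")
      yaml::read_yaml(file)
    }
    for (p in intersect(c("species", "reactions", "thermo", "timeseries"),
                        names(cfg))) {
      if (!file.exists(cfg[[p]]))
        stop(sprintf("configured %s file '%s' does not exist", p, cfg[[p]]))
    }
  }
  defaults <- list(dose = list(substrate = 3, acceptor = 100),
                   window = list(start = 28, end = 40),
                   seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "pipelineConfig")
}

.configReactions <- function(config) {
  reg <- if (!is.null(config$species)) readSpeciesRegistry(config$species)
         else oleateSpecies()
  if (!is.null(config$reactions)) readReactionTable(config$reactions, reg)
  else oleateReactions()
}

#' Balance report over a reaction table
#'
#' Runs [checkBalance()] on every registered reaction. Any imbalance in the
#' shipped elementary table would indicate a corrupted encoding.
#'
#' @param reactions A [ReactionSet-class], or a `"pipelineConfig"` from
#'   which one is loaded.
#' @return data.frame with columns `id`, `label`, `balanced`,
#'   `maxAbsResidual`, `chargeResidual`.
#' @export
balanceReport <- function(reactions = oleateReactions()) {
  if (inherits(reactions, "pipelineConfig"))
    reactions <- .configReactions(reactions)
  reg <- reactionRegistry(reactions)
  rows <- lapply(names(reactions), function(nm) {
    rep <- checkBalance(reactions[[nm]], reg)
    res <- elementResiduals(rep)
    data.frame(id = nm, label = reactionLabel(reactions[[nm]]),
               balanced = balanced(rep),
               maxAbsResidual = if (length(res)) max(abs(res)) else 0,
               chargeResidual = chargeResidual(rep))
  })
  do.call(rbind, rows)
}

#' Compose a recipe and report the result
#'
#' @param recipeSpec Recipe string, e.g. `"1 + 9*3 + 15*5"` (see
#'   [parseRecipeSpec()]).
#' @inheritParams balanceReport
#' @return List with the composed `reaction`, its `equation` string,
#'   `deltaG0` (kJ, combined when all elementary values exist) and a
#'   `provenance` string.
#' @export
composeReport <- function(recipeSpec, reactions = oleateReactions()) {
  if (inherits(reactions, "pipelineConfig"))
    reactions <- .configReactions(reactions)
  recipe <- parseRecipeSpec(recipeSpec, reactions)
  net <- composeReactions(recipe, label = sprintf("composed: %s", recipeSpec))
  dg <- tryCatch(combinedDeltaG(recipe), error = function(e) NA_real_)
  list(reaction = net, equation = formatReaction(net), deltaG0 = dg,
       provenance = sprintf("composeReactions('%s') over [%s]", recipeSpec,
                            paste(names(reactions), collapse = ", ")))
}

#' Theoretical yield and partitioning report for a substrate dose
#'
#' Assembles the headline expectations for an oleate dose: theoretical
#' methane via the overall methanogenic conversion, methane from the
#' hydrogen route alone, methane under 1/3 electron diversion to Fe(III),
#' the ferric hydroxide demand of the stoichiometric acetate pool, and the
#' electron content of the dose.
#'
#' @param dose Substrate dose (mmol/L); or a `"pipelineConfig"`.
#' @param acceptorDose Acceptor dose (mmol/L), reported alongside.
#' @param divertedFraction Electron fraction diverted to Fe(III) in the
#'   partitioned expectation (default 1/3).
#' @param reactions A [ReactionSet-class].
#' @return data.frame with `quantity`, `value`, `unit`, `provenance`.
#' @examples
#' predictReport(3)
#' @export
predictReport <- function(dose = 3, acceptorDose = 100,
                          divertedFraction = 1/3,
                          reactions = oleateReactions()) {
  if (inherits(dose, "pipelineConfig")) {
    config <- dose
    reactions <- .configReactions(config)
    acceptorDose <- config$dose$acceptor
    dose <- config$dose$substrate
  }
  rec <- oleateRecipes(reactions)
  net9 <- composeReactions(rec$net9); net8 <- composeReactions(rec$net8)
  r1 <- reactions[["r1"]]; r2 <- reactions[["r2"]]
  acetatePool <- dose * abs(coefficient(r1, "acetate") / coefficient(r1, "oleate"))
  rows <- rbind(
    data.frame(quantity = "theoretical CH4 (complete conversion)",
               value = theoreticalProduct(dose, net9, "CH4"), unit = "mmol/L",
               provenance = "theoreticalProduct, recipe 1*r1 + 9*r3 + 15*r5"),
    data.frame(quantity = "CH4 expected from hydrogen route",
               value = theoreticalProduct(dose, net8, "CH4"), unit = "mmol/L",
               provenance = "theoreticalProduct, recipe 1*r1 + 15*r5"),
    data.frame(quantity = sprintf("CH4 with %.3g of electrons to Fe(III)",
                                  divertedFraction),
               value = partitionedMethane(dose, divertedFraction, net8),
               unit = "mmol/L",
               provenance = "partitionedMethane over the hydrogen route"),
    data.frame(quantity = "stoichiometric acetate pool",
               value = acetatePool, unit = "mmol/L",
               provenance = "reaction r1 stoichiometry"),
    data.frame(quantity = "Fe(OH)3 demand of the acetate pool",
               value = acceptorDemand(acetatePool, r2), unit = "mmol/L",
               provenance = "acceptorDemand, reaction r2"),
    data.frame(quantity = "acceptor dose", value = acceptorDose,
               unit = "mmol/L", provenance = "configured dose"),
    data.frame(quantity = "electron content of dose",
               value = dose * electronContent("oleate", reactions),
               unit = "mmol e-/L",
               provenance = "electronContent, complete oxidation composition"))
  rows
}

#' Descriptor and recovery report for an incubation dataset
#'
#' Per (non-blank) treatment: maximum cumulative methane, methane recovery
#' against the theoretical expectation for the dose, lag time and windowed
#' production rate.
#'
#' @param dataset A `"generatedDataset"`, a long-format incubation
#'   data.frame, or a path to a time-series TSV.
#' @param dose Substrate dose (mmol/L).
#' @param window `c(start, end)` days for the rate window.
#' @param reactions A [ReactionSet-class].
#' @return data.frame, one row per treatment, mirroring the layout of a
#'   maximum-production/recovery table, with provenance strings.
#' @export
accountReport <- function(dataset, dose = 3, window = c(28, 40),
                          reactions = oleateReactions()) {
  if (inherits(dataset, "generatedDataset")) {
    if (missing(dose)) dose <- dataset$truth@doseSubstrate
    df <- dataset$data
  } else if (is.character(dataset)) {
    df <- readIncubationTSV(dataset)
  } else {
    df <- dataset
  }
  .checkSeries(df)
  theo <- theoreticalProduct(
    dose, composeReactions(oleateRecipes(reactions)$net9), "CH4")
  treatments <- setdiff(unique(df$treatment),
                        grep("-blank$", unique(df$treatment), value = TRUE))
  rows <- lapply(treatments, function(tr) {
    ch4 <- df[df$treatment == tr & df$analyte == "CH4", ]
    if (nrow(ch4) == 0L)
      stop(sprintf("treatment '%s' has no CH4 series", tr))
    mx <- maxCumulative(ch4)
    rec <- methaneRecovery(mx, theo)
    lg <- lagTime(ch4)
    rate <- tryCatch(windowRate(ch4, window[1], window[2]),
                     error = function(e) NULL)
    data.frame(treatment = tr,
               maxCH4 = mx,
               theoreticalCH4 = theo,
               recoveryPct = rec$recovery,
               lagDays = lg$lag,
               rate = if (is.null(rate)) NA_real_ else rate$mean,
               rateSD = if (is.null(rate)) NA_real_ else rate$sd,
               provenance = sprintf(
                 "maxCumulative/methaneRecovery vs %.2f (recipe 1*r1+9*r3+15*r5); lagTime (%s); windowRate [%g, %g]",
                 theo, lg$method, window[1], window[2]))
  })
  do.call(rbind, rows)
}

#' Simulate a dataset and write it to disk
#'
#' Generates a synthetic incubation dataset and writes the time-series TSV
#' plus a JSON ground-truth sidecar (scenario parameters and seed).
#'
#' @param scenario A [SyntheticScenario-class].
#' @param outdir Output directory (created if needed).
#' @param seed Random seed; defaults to the scenario's.
#' @param stem File stem for `<stem>.tsv` / `<stem>_truth.json`.
#' @return Invisibly, the paths written (named character vector).
#' @export
simulateReport <- function(scenario = suspendedSludgeScenario(),
                           outdir = ".", seed = NULL, stem = "incubation") {
  ds <- generateIncubation(scenario, seed = seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(outdir, paste0(stem, ".tsv"))
  truth <- file.path(outdir, paste0(stem, "_truth.json"))
  writeIncubationTSV(ds$data, tsv)
  jsonlite::write_json(
    list(seed = ds$seed,
         replicates = scenario@replicates,
         sigma = as.list(scenario@sigma),
         rho = scenario@rho,
         doseSubstrate = scenario@doseSubstrate,
         doseAcceptor = scenario@doseAcceptor,
         schedule = scenario@schedule,
         curves = scenario@curves),
    truth, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, truth = truth))
}
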