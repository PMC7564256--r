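# Electron-equivalent accounting: theoretical yields, partitioning between
# the Fe(III) and methane electron sinks, blank correction, acceptor demand
# and recovery metrics. All helpers read their stoichiometric ratios from
# Reaction objects rather than hard-coding them.

#' Theoretical product concentration from a substrate dose
#'
#' The yield implied by a net conversion: `dose * |product coeff /
#' substrate coeff|`. With the overall oleate-to-methane conversion
#' (12.75 CH4 per oleate) a 3 mmol/L dose gives 38.25 mmol/L; via the
#' hydrogen route alone (3.75 CH4 per oleate) it gives 11.25 mmol/L.
#'
#' @param dose Substrate concentration (mmol/L).
#' @param netReaction A [Reaction-class] consuming the substrate and
#'   producing the product.
#' @param productId Product species id.
#' @param substrateId Substrate species id (default `"oleate"`).
#' @return Product concentration in mmol/L.
#' @examples
#' rx <- oleateReactions()
#' net9 <- composeReactions(oleateRecipes(rx)$net9)
#' theoreticalProduct(3, net9, "CH4")  # 38.25
#' @export
theoreticalProduct <- function(dose, netReaction, productId,
                               substrateId = "oleate") {
  stopifnot(is.numeric(dose), dose >= 0)
  ps <- coefficient(netReaction, productId)
  ss <- coefficient(netReaction, substrateId)
  if (ps == 0)
    stop(sprintf("reaction does not involve product '%s'", productId))
  if (ss == 0)
    stop(sprintf("reaction does not involve substrate '%s'", substrateId))
  dose * abs(ps / ss)
}

#' Methane expected when electrons are diverted to Fe(III) reduction
#'
#' Hydrogen released by beta-oxidation can feed either hydrogenotrophic
#' methanogenesis or iron reduction. With a fraction `fraction` of the
#' hydrogen-borne electron equivalents diverted to the Fe(III) sink, the
#' expected methane is `(1 - fraction)` of the hydrogen-route expectation.
#' For a 3 mmol/L oleate dose, diverting 1/3 lowers the expectation from
#' 11.25 to 7.5 mmol/L.
#'
#' @param dose Substrate concentration (mmol/L).
#' @param fraction Fraction of generated electrons diverted to the
#'   acceptor, in `[0, 1]`.
#' @param h2Route A [Reaction-class]: the composed acetogenic +
#'   hydrogenotrophic conversion (substrate to acetate with all H2 to CH4).
#' @inheritParams theoreticalProduct
#' @return Expected methane concentration (mmol/L).
#' @examples
#' rx <- oleateReactions()
#' net8 <- composeReactions(oleateRecipes(rx)$net8)
#' partitionedMethane(3, 1/3, net8)  # 7.5
#' @export
partitionedMethane <- function(dose, fraction, h2Route,
                               substrateId = "oleate") {
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a number in [0, 1]")
  # treat the fraction as exact rational so that e.g. 1/3 of 11.25 gives
  # 7.5 without floating drift
  f <- .ratFromNumeric(fraction)
  base <- theoreticalProduct(dose, h2Route, "CH4", substrateId)
  base * (f$d - f$n) / f$d
}

#' Electron-acceptor demand for complete oxidation of a product pool
#'
#' Ferric hydroxide required to oxidise an accumulated pool completely,
#' from the coupled oxidation stoichiometry: `conc * |Fe(OH)3 coeff /
#' substrate coeff|`. Oxidising 26 mmol/L acetate (8 Fe(OH)3 per acetate)
#' demands 208 mmol/L.
#'
#' @param conc Pool concentration (mmol/L).
#' @param oxidationReaction A [Reaction-class] coupling the pool species to
#'   Fe(OH)3.
#' @param substrateId Pool species id (default `"acetate"`).
#' @param acceptorId Acceptor id (default `"FeOH3"`).
#' @return Acceptor demand (mmol/L).
#' @examples
#' rx <- oleateReactions()
#' acceptorDemand(26, rx[["r2"]])  # 208
#' @export
acceptorDemand <- function(conc, oxidationReaction, substrateId = "acetate",
                           acceptorId = "FeOH3") {
  stopifnot(is.numeric(conc), conc >= 0)
  fe <- coefficient(oxidationReaction, acceptorId)
  ss <- coefficient(oxidationReaction, substrateId)
  if (fe == 0)
    stop(sprintf("reaction does not involve acceptor '%s'", acceptorId))
  if (ss == 0)
    stop(sprintf("reaction does not involve '%s'", substrateId))
  conc * abs(fe / ss)
}

#' Blank correction of a measured concentration
#'
#' Subtracts the blank-assay signal one-to-one from the treatment signal
#' (the assumption that residual-substrate turnover is equivalent in blank
#' and treatment), clamping at zero. The result carries a `clamped`
#' attribute flagging when the blank exceeded the treatment value.
#'
#' @param treatment,blank Concentrations (mmol/L), both nonnegative.
#' @return `max(treatment - blank, 0)` with attribute `clamped`.
#' @examples
#' blankCorrect(60, 23)  # 37
#' @export
blankCorrect <- function(treatment, blank) {
  stopifnot(all(treatment >= 0), all(blank >= 0))
  out <- treatment - blank
  clamped <- out < 0
  out[clamped] <- 0
  attr(out, "clamped") <- clamped
  out
}

#' Infer substrate consumption from acceptor consumption
#'
#' Back-calculates the substrate consumed from the (blank-corrected)
#' Fe(III) reduction it explains: `fe3Consumed * |substrate coeff /
#' Fe(OH)3 coeff|`, reported at one decimal. With the oleate-to-acetate
#' Fe(III)-reducing conversion (30 Fe(OH)3 per oleate), 37 mmol/L of
#' Fe(III) corresponds to 1.2 mmol/L oleate.
#'
#' @param fe3Consumed Acceptor consumption (mmol/L).
#' @param coupledReaction A [Reaction-class] consuming both substrate and
#'   Fe(OH)3.
#' @inheritParams theoreticalProduct
#' @param acceptorId Acceptor id (default `"FeOH3"`).
#' @return Substrate concentration (mmol/L), one decimal.
#' @examples
#' rx <- oleateReactions()
#' net6 <- composeReactions(oleateRecipes(rx)$net6)
#' inferSubstrateFromAcceptor(37, net6)  # 1.2
#' @export
inferSubstrateFromAcceptor <- function(fe3Consumed, coupledReaction,
                                       substrateId = "oleate",
                                       acceptorId = "FeOH3") {
  stopifnot(is.numeric(fe3Consumed), fe3Consumed >= 0)
  fe <- coefficient(coupledReaction, acceptorId)
  ss <- coefficient(coupledReaction, substrateId)
  if (fe == 0) stop(sprintf("zero %s coefficient", acceptorId))
  if (ss == 0) stop(sprintf("reaction does not consume '%s'", substrateId))
  round(fe3Consumed * abs(ss / fe), 1)
}

#' Fraction of available electron equivalents captured in methane
#'
#' Methane carries 8 electron equivalents per mole. The denominator is the
#' electron content of the substrate dose under the declared scope:
#' `"acetogenic"` counts only the hydrogen-borne electrons of the
#' beta-oxidation step (2 e- per H2, 30 e- per oleate), `"full"` counts
#' complete oxidation to bicarbonate (102 e- per oleate). For the
#' enrichment-culture observation of 1.2 mmol/L CH4 from a 1 mmol/L oleate
#' dose this gives 32% (acetogenic) and 9.4% (full; 9% at integer
#' precision).
#'
#' @param ch4 Measured methane (mmol/L).
#' @param substrateConc Substrate dose (mmol/L), positive.
#' @param scope `"acetogenic"` or `"full"`.
#' @param reactions A [ReactionSet-class]; defaults to [oleateReactions()].
#' @param substrateId Substrate id (default `"oleate"`).
#' @return Percentage (unrounded; headline values are conventionally
#'   reported at integer precision).
#' @examples
#' round(methaneElectronFraction(1.2, 1, "acetogenic"))  # 32
#' round(methaneElectronFraction(1.2, 1, "full"))        # 9
#' @export
methaneElectronFraction <- function(ch4, substrateConc,
                                    scope = c("acetogenic", "full"),
                                    reactions = oleateReactions(),
                                    substrateId = "oleate") {
  scope <- match.arg(scope)
  stopifnot(is.numeric(ch4), ch4 >= 0)
  if (!is.numeric(substrateConc) || substrateConc <= 0)
    stop("substrate concentration must be positive")
  ePerCH4 <- electronContent("CH4", reactions)
  eSub <- if (scope == "full") {
    electronContent(substrateId, reactions)
  } else {
    h2Yield <- abs(coefficient(.acetogenicReaction(substrateId, reactions), "H2") /
                   coefficient(.acetogenicReaction(substrateId, reactions), substrateId))
    h2Yield * electronContent("H2", reactions)
  }
  ePerCH4 * ch4 / (substrateConc * eSub) * 100
}

# the registered reaction oxidising `id` to acetate + H2 (no Fe, no CH4)
.acetogenicReaction <- function(id, reactions) {
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    if (coefficient(r, id) < 0 && coefficient(r, "H2") > 0 &&
        coefficient(r, "FeOH3") == 0)
      return(r)
  }
  stop(sprintf("no acetogenic (H2-releasing) reaction registered for '%s'", id))
}

#' Fe(II) expected from the electrons not captured in methane
#'
#' Given a substrate dose and the measured methane and residual acetate,
#' predicts the Fe(II) that the remaining reducing equivalents could
#' generate: the hydrogen surplus (H2 released by beta-oxidation minus H2
#' consumed by the measured methane) yields 2 Fe(II) per H2, and the
#' acetate consumed beyond what remains in the medium yields 8 Fe(II) per
#' acetate. Negative intermediate pools (possible under measurement noise)
#' are clamped to zero and flagged.
#'
#' For the enrichment culture (1 mmol/L oleate, 1.2 mmol/L CH4, 3.4 mmol/L
#' acetate): 20.4 mmol/L Fe(II) from surplus H2, 5.6 mmol/L acetate
#' available, 44.8 mmol/L Fe(II) from acetate.
#'
#' @param substrateConc Substrate dose (mmol/L).
#' @param ch4Measured Measured methane (mmol/L).
#' @param acetateMeasured Residual acetate in the medium (mmol/L).
#' @param reactions A [ReactionSet-class]; defaults to [oleateReactions()].
#' @param substrateId Substrate id (default `"oleate"`).
#' @return List with `fe2FromH2`, `acetateAvailable`, `fe2FromAcetate`,
#'   `total` (all mmol/L), `surplusH2`, and a logical `clamped` flag.
#' @examples
#' expectedFe2(1, 1.2, 3.4)$fe2FromH2  # 20.4
#' @export
expectedFe2 <- function(substrateConc, ch4Measured, acetateMeasured,
                        reactions = oleateReactions(),
                        substrateId = "oleate") {
  stopifnot(substrateConc >= 0, ch4Measured >= 0, acetateMeasured >= 0)
  r1 <- .acetogenicReaction(substrateId, reactions)
  h2PerSub <- abs(coefficient(r1, "H2") / coefficient(r1, substrateId))
  acPerSub <- abs(coefficient(r1, "acetate") / coefficient(r1, substrateId))
  r5 <- .hydrogenotrophicReaction(reactions)
  h2PerCH4 <- abs(coefficient(r5, "H2") / coefficient(r5, "CH4"))
  fe2PerH2 <- electronContent("H2", reactions)
  fe2PerAc <- electronContent("acetate", reactions)

  clamped <- FALSE
  surplusH2 <- h2PerSub * substrateConc - h2PerCH4 * ch4Measured
  if (surplusH2 < 0) { surplusH2 <- 0; clamped <- TRUE }
  acetateAvailable <- acPerSub * substrateConc - acetateMeasured
  if (acetateAvailable < 0) { acetateAvailable <- 0; clamped <- TRUE }
  fe2FromH2 <- fe2PerH2 * surplusH2
  fe2FromAcetate <- fe2PerAc * acetateAvailable
  list(surplusH2 = surplusH2,
       fe2FromH2 = fe2FromH2,
       acetateAvailable = acetateAvailable,
       fe2FromAcetate = fe2FromAcetate,
       total = fe2FromH2 + fe2FromAcetate,
       clamped = clamped)
}

# the registered reaction producing CH4 from H2
.hydrogenotrophicReaction <- function(reactions) {
  for (nm in names(reactions)) {
    r <- reactions[[nm]]
    if (coefficient(r, "H2") < 0 && coefficient(r, "CH4") > 0)
      return(r)
  }
  stop("no hydrogenotrophic methanogenesis reaction registered")
}

#' Methane recovery relative to the theoretical expectation
#'
#' `recovery = measured / theoretical * 100`. Values above 100% (possible
#' on blanks or noisy maxima) are flagged, not clamped. Headline values are
#' conventionally rounded to integer percent; the unrounded percentage is
#' returned.
#'
#' @param measuredMax Measured maximum cumulative product (mmol/L).
#' @param theoretical Theoretical expectation (mmol/L), positive.
#' @return List with `measured`, `theoretical`, `recovery` (percent,
#'   unrounded) and logical `exceeds100`.
#' @examples
#' methaneRecovery(35, 38.25)$recovery  # 91.5
#' @export
methaneRecovery <- function(measuredMax, theoretical) {
  stopifnot(is.numeric(measuredMax), measuredMax >= 0)
  if (!is.numeric(theoretical) || theoretical <= 0)
    stop("theoretical expectation must be positive")
  rec <- measuredMax / theoretical * 100
  list(measured = measuredMax, theoretical = theoretical,
       recovery = rec, exceeds100 = rec > 100)
}

#' Electron-equivalent ledger for a substrate dose
#'
#' Summarises where the reducing equivalents of a dose end up: electrons in
#' measured methane, in blank-corrected Fe(II), and in residual acetate,
#' against the total the dose can supply under the declared scope.
#'
#' @param substrateConc Substrate dose (mmol/L).
#' @param ch4 Measured methane (mmol/L).
#' @param fe2Corrected Blank-corrected Fe(II) attributable to the substrate
#'   (mmol/L); each Fe(II) carries one electron equivalent.
#' @param acetateResidual Residual acetate (mmol/L).
#' @param scope `"acetogenic"` or `"full"` (see
#'   [methaneElectronFraction()]). Under acetogenic scope the residual
#'   acetate is not part of the available pool and is excluded from the
#'   allocation.
#' @param reactions A [ReactionSet-class]; defaults to [oleateReactions()].
#' @param substrateId Substrate id.
#' @return List with `totalElectrons`, named `allocation` (mmol e-/L),
#'   `unallocated`, and `overdrawn` flag (allocation exceeding the total).
#' @export
electronLedger <- function(substrateConc, ch4, fe2Corrected = 0,
                           acetateResidual = 0,
                           scope = c("full", "acetogenic"),
                           reactions = oleateReactions(),
                           substrateId = "oleate") {
  scope <- match.arg(scope)
  stopifnot(substrateConc >= 0, ch4 >= 0, fe2Corrected >= 0,
            acetateResidual >= 0)
  eCH4 <- electronContent("CH4", reactions)
  eAc <- electronContent("acetate", reactions)
  total <- if (scope == "full") {
    substrateConc * electronContent(substrateId, reactions)
  } else {
    r1 <- .acetogenicReaction(substrateId, reactions)
    substrateConc * abs(coefficient(r1, "H2") / coefficient(r1, substrateId)) *
      electronContent("H2", reactions)
  }
  alloc <- c(CH4 = eCH4 * ch4, FeII = fe2Corrected)
  if (scope == "full") alloc <- c(alloc, acetate = eAc * acetateResidual)
  list(totalElectrons = total, allocation = alloc,
       unallocated = total - sum(alloc),
       overdrawn = sum(alloc) > total,
       scope = scope)
}
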