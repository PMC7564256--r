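#' @include species.R
NULL

#' @title Chemical reaction with exact rational stoichiometry
#'
#' @description Signed stoichiometric map over species identifiers. Negative
#' coefficients denote consumption, positive production; coefficients are
#' reduced integer fractions so that composed reactions (e.g. the overall
#' oleate-to-methane conversion with its 12.75 CH4) are exact. An optional
#' standard transformed Gibbs energy change dG0' (kJ per reaction as
#' written, at 1 mol/L solutes, 1e5 Pa gas, 25 C, pH 7) and a condition tag
#' (`IR` iron-reducing, `M` methanogenic, `neutral`) are carried along.
#'
#' @slot species character vector of species ids.
#' @slot num,den numeric vectors: reduced numerators/denominators.
#' @slot label free-text description.
#' @slot conditionTag one of `"IR"`, `"M"`, `"neutral"`.
#' @slot deltaG0 dG0' in kJ per reaction as written, or `NA` if not set.
#' @export
setClass("Reaction",
  slots = c(species = "character", num = "numeric", den = "numeric",
            label = "character", conditionTag = "character",
            deltaG0 = "numeric"))

setValidity("Reaction", function(object) {
  msgs <- character(0)
  k <- length(object@species)
  if (length(object@num) != k || length(object@den) != k)
    msgs <- c(msgs, "species, num and den must have equal length")
  if (anyDuplicated(object@species))
    msgs <- c(msgs, "duplicate species in reaction")
  if (any(object@num == 0))
    msgs <- c(msgs, "zero coefficients must not be stored")
  if (any(object@den <= 0))
    msgs <- c(msgs, "denominators must be positive")
  if (!object@conditionTag %in% c("IR", "M", "neutral"))
    msgs <- c(msgs, "conditionTag must be one of IR, M, neutral")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a reaction from species ids and rational coefficients
#'
#' @param species Character vector of species ids.
#' @param num,den Numerators and denominators of the signed coefficients
#'   (negative = consumed, positive = produced). `den` defaults to 1 and is
#'   recycled.
#' @param label Free-text label.
#' @param conditionTag `"IR"`, `"M"` or `"neutral"`.
#' @param deltaG0 Optional dG0' in kJ per reaction as written.
#' @return A [Reaction-class] object with reduced, zero-free coefficients.
#' @examples
#' # H2 + 2 Fe(OH)3 + 4 H+ -> 2 Fe2+ + 6 H2O
#' r4 <- reaction(c("H2", "FeOH3", "H", "Fe2", "H2O"),
#'                c(-1, -2, -4, 2, 6), deltaG0 = -34.4, conditionTag = "IR")
#' @export
reaction <- function(species, num, den = 1, label = "",
                     conditionTag = "neutral", deltaG0 = NA_real_) {
  den <- rep_len(den, length(num))
  r <- .ratReduce(num, den)
  keep <- r$n != 0
  methods::new("Reaction",
    species = as.character(species)[keep],
    num = r$n[keep], den = r$d[keep],
    label = label, conditionTag = conditionTag,
    deltaG0 = as.numeric(deltaG0))
}

#' @describeIn reaction Named numeric vector of coefficients (decimal form).
#' @param x A [Reaction-class] object.
#' @export
stoichiometry <- function(x) stats::setNames(x@num / x@den, x@species)

#' @describeIn reaction Species ids appearing in a reaction.
#' @export
reactionSpecies <- function(x) x@species

#' @describeIn reaction Coefficient of one species. Returns 0 when the
#' species is absent; with `exact = TRUE` returns `c(num, den)`.
#' @param id Species id.
#' @param exact Return the exact fraction instead of a double.
#' @export
coefficient <- function(x, id, exact = FALSE) {
  i <- match(id, x@species)
  if (is.na(i)) {
    if (exact) return(c(num = 0, den = 1)) else return(0)
  }
  if (exact) c(num = x@num[i], den = x@den[i]) else x@num[i] / x@den[i]
}

#' @describeIn reaction dG0' in kJ per reaction as written (`NA` if unset).
#' @export
deltaG0 <- function(x) x@deltaG0

#' @describeIn reaction Free-text label.
#' @export
reactionLabel <- function(x) x@label

#' @describeIn reaction Condition tag (`IR`/`M`/`neutral`).
#' @export
conditionTag <- function(x) x@conditionTag

#' @describeIn reaction TRUE when the reaction has no species (e.g. an
#' exactly self-cancelling composition).
#' @export
isEmptyReaction <- function(x) length(x@species) == 0L

#' Do two reactions have identical net stoichiometry?
#'
#' Compares species sets and exact rational coefficients, ignoring labels,
#' tags and dG0'. Used for Hess path-independence checks, where the same net
#' conversion is composed from different elementary recipes.
#'
#' @param a,b [Reaction-class] objects.
#' @return Logical.
#' @export
sameReaction <- function(a, b) {
  sa <- order(a@species); sb <- order(b@species)
  identical(a@species[sa], b@species[sb]) &&
    all(.ratEq(a@num[sa], a@den[sa], b@num[sb], b@den[sb]))
}

#' Render a reaction as an equation string
#'
#' Consumed species on the left, produced on the right, coefficients in the
#' decimal/fraction form the reaction tables print (unit coefficients
#' omitted).
#'
#' @param x A [Reaction-class] object.
#' @return A single string such as
#'   `"oleate + 13.75 H2O -> 5.25 HCO3 + 12.75 CH4 + 4.25 H"`.
#' @export
formatReaction <- function(x) {
  if (isEmptyReaction(x)) return("(empty reaction)")
  side <- function(idx, sign) {
    n <- sign * x@num[idx]
    terms <- vapply(seq_along(idx), function(k) {
      co <- .formatRational(n[k], x@den[idx][k])
      if (co == "1") x@species[idx][k] else paste(co, x@species[idx][k])
    }, character(1))
    paste(terms, collapse = " + ")
  }
  lhs <- which(x@num < 0)
  rhs <- which(x@num > 0)
  paste(if (length(lhs)) side(lhs, -1) else "",
        "->",
        if (length(rhs)) side(rhs, 1) else "")
}

setMethod("show", "Reaction", function(object) {
  tag <- if (object@conditionTag == "neutral") "" else
    sprintf(" [%s]", object@conditionTag)
  dg <- if (is.na(object@deltaG0)) "" else
    sprintf("  (dG0' = %.1f kJ)", object@deltaG0)
  if (nzchar(object@label)) cat(object@label, tag, "\n", sep = "")
  cat(formatReaction(object), dg, "\n", sep = "")
})

#' Parse a reaction equation string
#'
#' Understands the `"A + 2 B -> 3 C"` dialect with integer, decimal or
#' fractional coefficients, species referred to by registry id.
#'
#' @param text Equation string.
#' @param registry [SpeciesRegistry-class] used to validate ids.
#' @inheritParams reaction
#' @return A [Reaction-class] object.
#' @examples
#' reg <- oleateSpecies()
#' parseEquation("H2 + 0.25 HCO3 + 0.25 H -> 0.25 CH4 + 0.75 H2O", reg)
#' @export
parseEquation <- function(text, registry, label = "",
                          conditionTag = "neutral", deltaG0 = NA_real_) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop(sprintf("equation '%s' must contain exactly one '->'", text))
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(list(species = character(0), num = numeric(0),
                                den = numeric(0)))
    terms <- strsplit(s, "\\s\\+\\s")[[1]]
    sp <- character(0); nn <- numeric(0); dd <- numeric(0)
    for (term in terms) {
      toks <- strsplit(trimws(term), "\\s+")[[1]]
      if (length(toks) == 1L) {
        co <- list(n = 1, d = 1); id <- toks[1]
      } else if (length(toks) == 2L) {
        co <- .parseRational(toks[1]); id <- toks[2]
      } else {
        stop(sprintf("cannot parse term '%s' in '%s'", term, text))
      }
      sp <- c(sp, id); nn <- c(nn, sign * co$n); dd <- c(dd, co$d)
    }
    list(species = sp, num = nn, den = dd)
  }
  l <- parseSide(sides[1], -1)
  r <- parseSide(sides[2], +1)
  .assertSpecies(registry, c(l$species, r$species))
  # merge duplicated ids across/within sides exactly
  sp <- unique(c(l$species, r$species))
  num <- numeric(length(sp)); den <- rep(1, length(sp))
  addTerm <- function(i, n, d) {
    s <- .ratAdd(num[i], den[i], n, d)
    num[i] <<- s$n; den[i] <<- s$d
  }
  for (k in seq_along(l$species)) addTerm(match(l$species[k], sp), l$num[k], l$den[k])
  for (k in seq_along(r$species)) addTerm(match(r$species[k], sp), r$num[k], r$den[k])
  reaction(sp, num, den, label = label, conditionTag = conditionTag,
           deltaG0 = deltaG0)
}

#' @title Balance report for a reaction
#'
#' @description Exact per-element and charge residuals (sum of coefficient
#' times element count / charge over all species) computed in rational
#' arithmetic. A reaction is balanced iff every residual is exactly zero.
#'
#' @slot elementNum,elementDen named numerators/denominators of per-element
#'   residuals.
#' @slot chargeNum,chargeDen charge residual.
#' @slot balanced logical.
#' @export
setClass("BalanceReport",
  slots = c(elementNum = "numeric", elementDen = "numeric",
            chargeNum = "numeric", chargeDen = "numeric",
            balanced = "logical"))

#' Verify elemental and charge balance of a reaction
#'
#' @param x A [Reaction-class] object.
#' @param registry [SpeciesRegistry-class] providing composition and charge.
#' @return A [BalanceReport-class]; see [balanced()], [elementResiduals()],
#'   [chargeResidual()].
#' @examples
#' reg <- oleateSpecies()
#' r1 <- parseEquation("oleate + 16 H2O -> 9 acetate + 15 H2 + 8 H", reg)
#' balanced(checkBalance(r1, reg))
#' @export
checkBalance <- function(x, registry) {
  .assertSpecies(registry, x@species)
  elements <- sort(unique(unlist(lapply(x@species, function(id)
    names(speciesFormula(registry, id))))))
  en <- stats::setNames(numeric(length(elements)), elements)
  ed <- stats::setNames(rep(1, length(elements)), elements)
  cn <- 0; cd <- 1
  for (i in seq_along(x@species)) {
    f <- speciesFormula(registry, x@species[i])
    for (el in names(f)) {
      s <- .ratAdd(en[[el]], ed[[el]], x@num[i] * f[[el]], x@den[i])
      en[[el]] <- s$n; ed[[el]] <- s$d
    }
    ch <- speciesCharge(registry, x@species[i])
    s <- .ratAdd(cn, cd, x@num[i] * ch, x@den[i])
    cn <- s$n; cd <- s$d
  }
  methods::new("BalanceReport",
    elementNum = en, elementDen = ed, chargeNum = cn, chargeDen = cd,
    balanced = all(en == 0) && cn == 0)
}

#' @describeIn checkBalance TRUE when all residuals are exactly zero.
#' @param report A [BalanceReport-class] object.
#' @export
balanced <- function(report) report@balanced

#' @describeIn checkBalance Named numeric vector of per-element residuals.
#' @export
elementResiduals <- function(report)
  stats::setNames(report@elementNum / report@elementDen,
                  names(report@elementNum))

#' @describeIn checkBalance Charge residual.
#' @export
chargeResidual <- function(report) report@chargeNum / report@chargeDen

setMethod("show", "BalanceReport", function(object) {
  cat(if (object@balanced) "balanced" else "NOT balanced", "\n")
  if (length(object@elementNum)) {
    res <- elementResiduals(object)
    cat("  element residuals:",
        paste(sprintf("%s=%s", names(res),
                      .formatRational(object@elementNum, object@elementDen)),
              collapse = ", "), "\n")
  }
  cat("  charge residual:",
      .formatRational(object@chargeNum, object@chargeDen), "\n")
})

#' @title An ordered collection of reactions sharing one species registry
#'
#' @description Container for the elementary half-reactions of a study
#' (e.g. beta-oxidation, the Fe(III)-reducing and methanogenic sinks) plus
#' the registry they are written over. Reactions are retrieved by id with
#' `[[`.
#'
#' @slot reactions named list of [Reaction-class] objects.
#' @slot registry the shared [SpeciesRegistry-class].
#' @export
setClass("ReactionSet",
  slots = c(reactions = "list", registry = "SpeciesRegistry"))

setValidity("ReactionSet", function(object) {
  if (!all(vapply(object@reactions, methods::is, logical(1), "Reaction")))
    return("all elements must be Reaction objects")
  if (is.null(names(object@reactions)) || anyDuplicated(names(object@reactions)))
    return("reactions must be uniquely named")
  TRUE
})

#' Construct a reaction set
#'
#' @param reactions Named list of [Reaction-class] objects.
#' @param registry The shared [SpeciesRegistry-class].
#' @return A [ReactionSet-class].
#' @export
reactionSet <- function(reactions, registry) {
  methods::new("ReactionSet", reactions = reactions, registry = registry)
}

#' @export
setMethod("length", "ReactionSet", function(x) length(x@reactions))

#' @export
setMethod("names", "ReactionSet", function(x) names(x@reactions))

#' @export
setMethod("[[", "ReactionSet", function(x, i, ...) {
  r <- x@reactions[[i]]
  if (is.null(r)) stop(sprintf("no reaction '%s' in set", as.character(i)))
  r
})

#' @describeIn reactionSet The registry shared by a reaction set.
#' @param x A [ReactionSet-class].
#' @export
reactionRegistry <- function(x) x@registry

setMethod("show", "ReactionSet", function(object) {
  cat(sprintf("ReactionSet with %d reactions\n", length(object@reactions)))
  for (nm in names(object@reactions)) {
    r <- object@reactions[[nm]]
    dg <- if (is.na(r@deltaG0)) "" else sprintf("  dG0' %.1f kJ", r@deltaG0)
    cat(sprintf("  %-5s [%s] %s%s\n", nm, r@conditionTag,
                formatReaction(r), dg))
  }
})

#' Read a reaction table from delimited text
#'
#' Expects a tab-separated file with header columns `id`, `condition`
#' (IR/M/neutral), `label`, `equation` (see [parseEquation()]) and an
#' optional `deltaG0` column (kJ per reaction; empty or NA when not
#' reported, as for oxidation half-reactions written with free electrons).
#'
#' @param file Path to the TSV file.
#' @param registry A [SpeciesRegistry-class].
#' @return A [ReactionSet-class].
#' @seealso [oleateReactions()] for the shipped table.
#' @export
readReactionTable <- function(file, registry) {
  tb <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("id", "condition", "label", "equation")
  if (!all(need %in% names(tb)))
    stop(sprintf("reaction table '%s' must have columns %s",
                 file, paste(need, collapse = ", ")))
  dg <- if ("deltaG0" %in% names(tb)) suppressWarnings(as.numeric(tb$deltaG0))
        else rep(NA_real_, nrow(tb))
  rx <- lapply(seq_len(nrow(tb)), function(i)
    parseEquation(tb$equation[i], registry, label = tb$label[i],
                  conditionTag = tb$condition[i], deltaG0 = dg[i]))
  names(rx) <- tb$id
  reactionSet(rx, registry)
}

#' Species registry of the oleate degradation system
#'
#' The shipped registry covering the species of the elementary reactions:
#' oleate (C18H33O2-), acetate, H2, CH4, bicarbonate, ferric hydroxide,
#' Fe2+ (id `Fe2`), water, the proton (id `H`) and the formal electron
#' (id `e`).
#'
#' @return A [SpeciesRegistry-class].
#' @export
oleateSpecies <- function() {
  readSpeciesRegistry(system.file("extdata", "species.tsv", package = "OleFe",
                                  mustWork = TRUE))
}

#' Elementary reactions of anaerobic oleate degradation
#'
#' The shipped reaction table: beta-oxidation of oleate to acetate + H2
#' (`r1`, +325.7 kJ), acetate and hydrogen oxidation coupled to Fe(III)
#' reduction (`r2` -32.9, `r4` -34.4), acetoclastic and hydrogenotrophic
#' methanogenesis (`r3` -31.0, `r5` -33.9), and the acetate oxidation
#' half-reaction written with free electrons (`eq10`, no dG0'). dG0' values
#' are standard transformed energies (25 C, pH 7) in kJ per reaction as
#' written. The overall conversions are obtained by composition, see
#' [oleateRecipes()].
#'
#' @return A [ReactionSet-class].
#' @examples
#' rx <- oleateReactions()
#' rx[["r1"]]
#' @export
oleateReactions <- function() {
  reg <- oleateSpecies()
  readReactionTable(system.file("extdata", "table1_reactions.tsv",
                                package = "OleFe", mustWork = TRUE), reg)
}
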