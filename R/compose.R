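#' @include reaction.R
NULL

#' @title Linear composition recipe over reactions
#'
#' @description An ordered list of (reaction, rational multiplier) terms
#' whose exact sum defines a net conversion. The elementary-to-overall
#' identities of the oleate system are such recipes: the overall
#' methanogenic conversion is 1 x beta-oxidation + 9 x acetoclastic + 15 x
#' hydrogenotrophic methanogenesis, with acetate and H2 cancelling exactly.
#' Reversal is expressed by a negative multiplier.
#'
#' @slot reactions list of [Reaction-class] objects.
#' @slot multNum,multDen numerators/denominators of the multipliers.
#' @export
setClass("ReactionRecipe",
  slots = c(reactions = "list", multNum = "numeric", multDen = "numeric"))

setValidity("ReactionRecipe", function(object) {
  k <- length(object@reactions)
  if (length(object@multNum) != k || length(object@multDen) != k)
    return("multipliers must match the number of reactions")
  if (k == 0) return("recipe must contain at least one term")
  if (any(object@multNum == 0)) return("multipliers must be nonzero")
  if (any(object@multDen <= 0)) return("multiplier denominators must be positive")
  if (!all(vapply(object@reactions, methods::is, logical(1), "Reaction")))
    return("all terms must be Reaction objects")
  TRUE
})

#' Construct a composition recipe
#'
#' @param reactions List of [Reaction-class] objects (a single reaction is
#'   wrapped automatically).
#' @param multipliers Numeric vector, character vector of rationals
#'   (`"9"`, `"15"`, `"-1"`, `"1/3"`), or a list of `c(num, den)` pairs.
#' @return A [ReactionRecipe-class].
#' @examples
#' rx <- oleateReactions()
#' rec <- reactionRecipe(list(rx[["r1"]], rx[["r5"]]), c(1, 15))
#' composeReactions(rec)
#' @export
reactionRecipe <- function(reactions, multipliers) {
  if (methods::is(reactions, "Reaction")) reactions <- list(reactions)
  k <- length(reactions)
  if (length(multipliers) != k)
    stop("need one multiplier per reaction")
  num <- numeric(k); den <- numeric(k)
  for (i in seq_len(k)) {
    m <- if (is.list(multipliers)) multipliers[[i]] else multipliers[i]
    if (is.character(m)) {
      r <- .parseRational(m)
    } else if (length(m) == 2L) {
      r <- .ratReduce(m[1], m[2])
    } else {
      # numeric: recover the exact simple fraction (15, -1, 0.25, 1/3, ...)
      r <- .ratFromNumeric(m)
    }
    num[i] <- r$n; den[i] <- r$d
  }
  methods::new("ReactionRecipe", reactions = reactions,
               multNum = num, multDen = den)
}

#' @describeIn reactionRecipe Multipliers as doubles.
#' @param x A [ReactionRecipe-class].
#' @export
recipeMultipliers <- function(x) x@multNum / x@multDen

setMethod("show", "ReactionRecipe", function(object) {
  cat(sprintf("ReactionRecipe with %d term(s)\n", length(object@reactions)))
  for (i in seq_along(object@reactions)) {
    m <- .formatRational(object@multNum[i], object@multDen[i])
    lb <- object@reactions[[i]]@label
    cat(sprintf("  %s x %s\n", m,
                if (nzchar(lb)) lb else formatReaction(object@reactions[[i]])))
  }
})

#' Compose reactions by exact linear combination
#'
#' Computes the exact rational sum of multiplier x coefficient per species
#' and removes species whose net coefficient is zero (cancelled
#' intermediates such as H2 or acetate in the overall oleate conversions).
#'
#' @param recipe A [ReactionRecipe-class].
#' @param label Label for the composed reaction.
#' @param conditionTag Condition tag for the composed reaction.
#' @return A [Reaction-class]; empty if everything cancels. Its `deltaG0`
#'   is set from [combinedDeltaG()] when every term carries one, else `NA`.
#' @examples
#' rx <- oleateReactions()
#' # overall oleate oxidation to methane: 1 r1 + 9 r3 + 15 r5
#' composeReactions(reactionRecipe(list(rx[["r1"]], rx[["r3"]], rx[["r5"]]),
#'                                 c(1, 9, 15)))
#' @export
composeReactions <- function(recipe, label = "", conditionTag = "neutral") {
  stopifnot(methods::is(recipe, "ReactionRecipe"))
  sp <- character(0); num <- numeric(0); den <- numeric(0)
  for (i in seq_along(recipe@reactions)) {
    r <- recipe@reactions[[i]]
    for (j in seq_along(r@species)) {
      contrib <- .ratMul(recipe@multNum[i], recipe@multDen[i],
                         r@num[j], r@den[j])
      k <- match(r@species[j], sp)
      if (is.na(k)) {
        sp <- c(sp, r@species[j])
        num <- c(num, contrib$n); den <- c(den, contrib$d)
      } else {
        s <- .ratAdd(num[k], den[k], contrib$n, contrib$d)
        num[k] <- s$n; den[k] <- s$d
      }
    }
  }
  keep <- num != 0
  dg <- tryCatch(combinedDeltaG(recipe), error = function(e) NA_real_)
  if (!any(keep))
    return(methods::new("Reaction", species = character(0),
                        num = numeric(0), den = numeric(0), label = label,
                        conditionTag = conditionTag, deltaG0 = dg))
  reaction(sp[keep], num[keep], den[keep], label = label,
           conditionTag = conditionTag, deltaG0 = dg)
}

#' Combine dG0' values along a composition recipe
#'
#' Returns the multiplier-weighted sum of the elementary dG0' values,
#' rounded to one decimal to match the precision at which such tables are
#' printed. By Hess's law the result is path-independent up to the rounding
#' already present in the one-decimal inputs (about 0.6 kJ for the recipes
#' of the oleate system).
#'
#' @param recipe A [ReactionRecipe-class]; every term must carry a dG0'.
#' @return dG0' of the composed reaction in kJ, one decimal.
#' @examples
#' rx <- oleateReactions()
#' combinedDeltaG(reactionRecipe(list(rx[["r1"]], rx[["r5"]]), c(1, 15)))
#' # -182.8
#' @export
combinedDeltaG <- function(recipe) {
  stopifnot(methods::is(recipe, "ReactionRecipe"))
  dg <- vapply(recipe@reactions, deltaG0, numeric(1))
  if (anyNA(dg)) {
    bad <- vapply(recipe@reactions[is.na(dg)], function(r)
      if (nzchar(r@label)) r@label else formatReaction(r), character(1))
    stop(sprintf("missing dG0' for reaction(s): %s",
                 paste(bad, collapse = "; ")))
  }
  round(sum(recipeMultipliers(recipe) * dg), 1)
}

#' @title Standard transformed formation-energy table
#'
#' @description Maps species ids to standard transformed Gibbs energies of
#' formation (kJ/mol, 25 C, pH 7) with a provenance string per entry. Used
#' only as a cross-check of printed per-reaction dG0' values; the exact
#' formation energies behind a printed table are usually not reproduced
#' verbatim, so comparisons carry a tolerance.
#'
#' @slot table data.frame with columns `id`, `dGf0`, `citation`.
#' @export
setClass("ThermoTable", slots = c(table = "data.frame"))

setValidity("ThermoTable", function(object) {
  need <- c("id", "dGf0", "citation")
  if (!all(need %in% names(object@table)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@table$id)) return("species ids must be unique")
  if (!is.numeric(object@table$dGf0)) return("dGf0 must be numeric")
  TRUE
})

#' Read a formation-energy table from delimited text
#'
#' Tab-separated with header columns `id`, `dGf0` (kJ/mol) and `citation`.
#'
#' @param file Path to the TSV file.
#' @return A [ThermoTable-class].
#' @seealso [oleateThermoTable()] for the shipped table.
#' @export
readThermoTable <- function(file) {
  tb <- utils::read.delim(file, stringsAsFactors = FALSE)
  tb$dGf0 <- as.numeric(tb$dGf0)
  methods::new("ThermoTable", table = tb)
}

#' @describeIn readThermoTable Formation energy of one species (kJ/mol).
#' @param x A [ThermoTable-class].
#' @param id Species id.
#' @export
formationEnergy <- function(x, id) {
  i <- match(id, x@table$id)
  if (anyNA(i))
    stop(sprintf("no formation energy for species: %s",
                 paste(id[is.na(i)], collapse = ", ")))
  x@table$dGf0[i]
}

setMethod("show", "ThermoTable", function(object) {
  cat(sprintf("ThermoTable with %d entries (kJ/mol, 25 C, pH 7)\n",
              nrow(object@table)))
  print(object@table, row.names = FALSE)
})

#' Shipped formation-energy table for the oleate system
#'
#' Transformed formation energies at 25 C, pH 7 in the style of the
#' classical anaerobe bioenergetics compilations for water, bicarbonate,
#' methane, hydrogen, acetate and the proton, completed with derived
#' entries for Fe(OH)3/Fe2+ (fixed by the Fe(OH)3/Fe2+ redox couple implied
#' by the printed hydrogen oxidation value) and for oleate (fixed by the
#' printed beta-oxidation value). The `citation` column records which
#' entries are compilation values and which are derived.
#'
#' @return A [ThermoTable-class].
#' @export
oleateThermoTable <- function() {
  readThermoTable(system.file("extdata", "thermo_formation.tsv",
                              package = "OleFe", mustWork = TRUE))
}

#' dG0' of a reaction from formation energies
#'
#' Computes the coefficient-weighted sum of transformed formation energies.
#' Intended as a consistency cross-check of printed per-reaction values
#' (agreement within about 1 kJ given independently rounded inputs).
#'
#' @param x A [Reaction-class].
#' @param table A [ThermoTable-class] covering every species of `x`.
#' @return dG0' in kJ per reaction as written.
#' @examples
#' rx <- oleateReactions()
#' deltaGFromFormation(rx[["r3"]], oleateThermoTable())  # about -31.0
#' @export
deltaGFromFormation <- function(x, table) {
  if (isEmptyReaction(x)) return(0)
  sum(stoichiometry(x) * formationEnergy(table, x@species))
}

#' Electron content of a species, in single-electron equivalents
#'
#' Number of electron equivalents released on complete oxidation of one
#' mole of the species to bicarbonate, with Fe(OH)3 -> Fe2+ as the
#' reference one-electron couple. The complete-oxidation conversion is
#' composed automatically from the registered half-reactions by cancelling
#' every intermediate (acetate, H2, CH4, ...) that is not a terminal
#' species; the electron content is then the Fe(OH)3 coefficient of the
#' composed net reaction. For the shipped system: H2 = 2, acetate = 8,
#' CH4 = 8, oleate = 102.
#'
#' @param id Species id to oxidise.
#' @param reactions A [ReactionSet-class] holding the half-reactions.
#' @param terminal Species allowed in the net reaction besides `id`;
#'   defaults to water, proton, the Fe couple and bicarbonate.
#' @return Electron equivalents per mole (a nonnegative number).
#' @examples
#' rx <- oleateReactions()
#' electronContent("oleate", rx)  # 102
#' electronContent("acetate", rx) # 8
#' @export
electronContent <- function(id, reactions,
                            terminal = c("H2O", "H", "FeOH3", "Fe2", "HCO3")) {
  stopifnot(methods::is(reactions, "ReactionSet"))
  .assertSpecies(reactions@registry, id)
  if (id %in% terminal) {
    if (id == "Fe2" || id == "FeOH3") return(1)
    return(0)
  }
  rec <- .oxidationRecipe(id, reactions, terminal)
  net <- composeReactions(rec)
  abs(coefficient(net, "FeOH3"))
}

# Greedy elimination: build the complete-oxidation recipe for `id` by
# successively cancelling non-terminal species with registered reactions.
# Candidate reactions that run under iron-reducing conditions are preferred;
# reversal (negative multiplier) is allowed, as for methane. Reactions
# containing the formal electron are skipped (half-reactions cannot close
# the balance on the Fe couple).
.oxidationRecipe <- function(id, reactions, terminal) {
  rxs <- reactions@reactions
  rxs <- rxs[!vapply(rxs, function(r) "e" %in% r@species, logical(1))]
  ord <- order(vapply(rxs, function(r) r@conditionTag != "IR", logical(1)),
               names(rxs))
  rxs <- rxs[ord]

  terms <- list()      # list of (name, num, den)
  # net coefficients tracked exactly
  sp <- id; num <- -1; den <- 1
  applyReaction <- function(nm, mNum, mDen) {
    terms[[length(terms) + 1L]] <<- list(name = nm, num = mNum, den = mDen)
    r <- rxs[[nm]]
    for (j in seq_along(r@species)) {
      contrib <- .ratMul(mNum, mDen, r@num[j], r@den[j])
      k <- match(r@species[j], sp)
      if (is.na(k)) {
        sp <<- c(sp, r@species[j])
        num <<- c(num, contrib$n); den <<- c(den, contrib$d)
      } else {
        s <- .ratAdd(num[k], den[k], contrib$n, contrib$d)
        num[k] <<- s$n; den[k] <<- s$d
      }
    }
  }

  # first make the net consume exactly one mole of `id`
  start <- NULL
  for (nm in names(rxs)) {
    co <- coefficient(rxs[[nm]], id, exact = TRUE)
    if (co["num"] != 0) { start <- nm; break }
  }
  if (is.null(start))
    stop(sprintf("no registered reaction involves species '%s'", id))
  co <- coefficient(rxs[[start]], id, exact = TRUE)
  # multiplier m with m * co = -1  =>  m = -den/num
  m <- .ratReduce(-co["den"], co["num"])
  # cancel the seeded -1 before applying
  num[1] <- 0
  applyReaction(start, m$n, m$d)

  for (iter in seq_len(50L)) {
    open <- which(num != 0 & !(sp %in% c(terminal, id)))
    if (!length(open)) break
    s <- sp[open[1]]
    cand <- NULL
    for (nm in names(rxs)) {
      co <- coefficient(rxs[[nm]], s, exact = TRUE)
      if (co["num"] != 0 && !(id %in% rxs[[nm]]@species)) { cand <- nm; break }
    }
    if (is.null(cand))
      stop(sprintf("no composition path: cannot cancel intermediate '%s' while oxidising '%s'", s, id))
    co <- coefficient(rxs[[cand]], s, exact = TRUE)
    cur <- .ratReduce(num[open[1]], den[open[1]])
    # multiplier m with m * co + cur = 0  =>  m = -cur/co
    m <- .ratMul(-cur$n, cur$d, co["den"], co["num"])
    applyReaction(cand, m$n, m$d)
  }
  open <- which(num != 0 & !(sp %in% c(terminal, id)))
  if (length(open))
    stop(sprintf("no composition path for '%s' (unresolved: %s)",
                 id, paste(sp[open], collapse = ", ")))
  reactionRecipe(lapply(terms, function(t) rxs[[t$name]]),
                 lapply(terms, function(t) c(t$num, t$den)))
}

#' Standard composition recipes of the oleate system
#'
#' The fully multiplied recipes behind the overall conversions: the
#' elementary-to-overall identities read, with multipliers made explicit,
#'
#' * `net6` = 1 r1 + 15 r4 (oleate to acetate, Fe(III)-reducing)
#' * `net7` = 1 r1 + 9 r2 + 15 r4 (complete oxidation, Fe(III)-reducing)
#' * `net8` = 1 r1 + 15 r5 (oleate to acetate, methanogenic)
#' * `net9` = 1 r1 + 9 r3 + 15 r5 (complete conversion to methane)
#'
#' Only these multiplied forms cancel the H2 and acetate intermediates and
#' reproduce the printed overall coefficients.
#'
#' @param reactions A [ReactionSet-class]; defaults to [oleateReactions()].
#' @return Named list of [ReactionRecipe-class] objects.
#' @export
oleateRecipes <- function(reactions = oleateReactions()) {
  r <- function(ids, mult) reactionRecipe(lapply(ids, function(i) reactions[[i]]), mult)
  list(
    net6 = r(c("r1", "r4"), c(1, 15)),
    net7 = r(c("r1", "r2", "r4"), c(1, 9, 15)),
    net8 = r(c("r1", "r5"), c(1, 15)),
    net9 = r(c("r1", "r3", "r5"), c(1, 9, 15))
  )
}

#' Parse a recipe specification string
#'
#' Understands the compact dialect `"1 + 9*3 + 15*5"`: terms separated by
#' `+`, each either a reaction id/index or `multiplier*id`, multipliers
#' being integers, decimals or fractions (negative allowed, e.g.
#' `"3 + -1*3"` for exact self-cancellation).
#'
#' @param spec Specification string.
#' @param reactions A [ReactionSet-class]; bare numbers in `spec` refer to
#'   positions in the set, names to reaction ids.
#' @return A [ReactionRecipe-class].
#' @examples
#' rx <- oleateReactions()
#' composeReactions(parseRecipeSpec("1 + 9*3 + 15*5", rx))
#' @export
parseRecipeSpec <- function(spec, reactions) {
  terms <- strsplit(spec, "+", fixed = TRUE)[[1]]
  terms <- trimws(terms)
  if (!length(terms) || any(!nzchar(terms)))
    stop(sprintf("cannot parse recipe spec '%s'", spec))
  rxs <- list(); mult <- list()
  for (term in terms) {
    parts <- strsplit(term, "*", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    if (length(parts) == 1L) {
      m <- c(1, 1); ref <- parts[1]
    } else if (length(parts) == 2L) {
      r <- .parseRational(parts[1]); m <- c(r$n, r$d); ref <- parts[2]
    } else {
      stop(sprintf("cannot parse recipe term '%s'", term))
    }
    rx <- if (grepl("^[0-9]+$", ref)) {
      i <- as.integer(ref)
      if (i < 1 || i > length(reactions))
        stop(sprintf("reaction index %d out of range", i))
      reactions[[i]]
    } else {
      reactions[[ref]]
    }
    rxs[[length(rxs) + 1L]] <- rx
    mult[[length(mult) + 1L]] <- m
  }
  reactionRecipe(rxs, mult)
}
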