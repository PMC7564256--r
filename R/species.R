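#' @include rational.R
NULL

#' Parse a chemical formula into element counts
#'
#' Parses formulas of the kind used to encode the reaction table species
#' (e.g. `"Fe(OH)3"`, `"C18H33O2"`) into a named integer vector of element
#' counts. Parenthesised groups with integer multipliers are supported.
#'
#' @param text A single chemical formula string.
#' @return Named integer vector mapping element symbol to count.
#' @examples
#' parseFormula("Fe(OH)3")   # Fe 1, O 3, H 3
#' parseFormula("C18H33O2")  # C 18, H 33, O 2
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  chars <- strsplit(text, "")[[1]]
  pos <- 1L
  n <- length(chars)
  if (n == 0L) stop("formula is empty")

  peek <- function() if (pos <= n) chars[pos] else NA_character_
  fail <- function(msg) {
    stop(sprintf("malformed formula '%s' at position %d: %s", text, pos, msg))
  }
  readInt <- function() {
    start <- pos
    while (!is.na(peek()) && grepl("[0-9]", peek())) pos <<- pos + 1L
    if (pos == start) return(1L)
    as.integer(paste(chars[start:(pos - 1L)], collapse = ""))
  }
  # returns named integer vector; stops at ')' or end
  readGroup <- function() {
    counts <- integer(0)
    addCounts <- function(x) {
      for (el in names(x)) {
        counts[el] <<- (if (el %in% names(counts)) counts[[el]] else 0L) + x[[el]]
      }
    }
    repeat {
      ch <- peek()
      if (is.na(ch) || ch == ")") break
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- readGroup()
        if (is.na(peek()) || peek() != ")") fail("unclosed '('")
        pos <<- pos + 1L
        mult <- readInt()
        addCounts(inner * mult)
      } else if (grepl("[A-Z]", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (!is.na(peek()) && grepl("[a-z]", peek())) {
          sym <- paste0(sym, peek())
          pos <<- pos + 1L
        }
        cnt <- readInt()
        x <- stats::setNames(cnt, sym)
        addCounts(x)
      } else {
        fail(sprintf("unexpected character '%s'", ch))
      }
    }
    counts
  }

  counts <- readGroup()
  if (!is.na(peek())) fail("unexpected ')'")
  if (length(counts) == 0L) stop(sprintf("formula '%s' contains no elements", text))
  counts
}

#' @title Species registry
#'
#' @description An S4 container mapping short species identifiers (e.g.
#' `oleate`, `FeOH3`, `Fe2`) to parsed elemental composition, charge, and an
#' informational phase note. Reactions refer to species by id; balance
#' checking looks composition and charge up here.
#'
#' A species must contain at least one element, with one exception: the
#' formal electron (empty formula, charge -1) used by oxidation
#' half-reactions written with explicit `e-`. An element-free species is
#' accepted only when its charge is nonzero.
#'
#' @slot table data.frame with columns `id`, `formula`, `charge`, `phase`.
#' @slot formulas named list of element-count integer vectors, one per id.
#' @export
setClass("SpeciesRegistry",
  slots = c(table = "data.frame", formulas = "list"))

setValidity("SpeciesRegistry", function(object) {
  tb <- object@table
  msgs <- character(0)
  need <- c("id", "formula", "charge", "phase")
  if (!all(need %in% names(tb)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tb$id)) msgs <- c(msgs, "species ids must be unique")
  if (!identical(sort(names(object@formulas)), sort(tb$id)))
    msgs <- c(msgs, "formulas must cover exactly the registered ids")
  for (id in tb$id) {
    f <- object@formulas[[id]]
    if (length(f) > 0 && any(f < 0))
      msgs <- c(msgs, sprintf("negative element count for '%s'", id))
    if (length(f) == 0 && tb$charge[tb$id == id] == 0)
      msgs <- c(msgs, sprintf(
        "species '%s' has no elements and no charge (only the formal electron may be element-free)", id))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a species registry
#'
#' @param id Character vector of unique species identifiers.
#' @param formula Chemical formula strings (see [parseFormula()]); the empty
#'   string or `"-"` denotes the formal electron and is only accepted with
#'   nonzero charge.
#' @param charge Integer charges in elementary units.
#' @param phase Optional phase notes (aqueous/solid/gas), informational only.
#' @return A [SpeciesRegistry-class] object.
#' @examples
#' reg <- speciesRegistry(c("H2", "H2O"), c("H2", "H2O"), c(0, 0))
#' speciesCharge(reg, "H2O")
#' @export
speciesRegistry <- function(id, formula, charge, phase = NULL) {
  if (is.null(phase)) phase <- rep("", length(id))
  stopifnot(length(id) == length(formula), length(id) == length(charge),
            length(id) == length(phase))
  formulas <- lapply(seq_along(id), function(i) {
    f <- trimws(formula[i])
    if (!nzchar(f) || f == "-") integer(0) else parseFormula(f)
  })
  names(formulas) <- id
  methods::new("SpeciesRegistry",
    table = data.frame(id = as.character(id), formula = as.character(formula),
                       charge = as.numeric(charge), phase = as.character(phase),
                       stringsAsFactors = FALSE),
    formulas = formulas)
}

#' Read a species registry from delimited text
#'
#' Expects a tab-separated file with header columns `id`, `formula`,
#' `charge` and optionally `phase`.
#'
#' @param file Path to the TSV file.
#' @return A [SpeciesRegistry-class] object.
#' @seealso [oleateSpecies()] for the shipped registry.
#' @export
readSpeciesRegistry <- function(file) {
  tb <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "formula", "charge")
  if (!all(need %in% names(tb)))
    stop(sprintf("species registry '%s' must have columns %s",
                 file, paste(need, collapse = ", ")))
  speciesRegistry(tb$id, tb$formula, as.numeric(tb$charge),
                  if ("phase" %in% names(tb)) tb$phase else NULL)
}

#' @describeIn speciesRegistry Registered species identifiers.
#' @param registry A [SpeciesRegistry-class] object.
#' @export
speciesIds <- function(registry) registry@table$id

#' @describeIn speciesRegistry Charge of one species (elementary units).
#' @export
speciesCharge <- function(registry, id) {
  .assertSpecies(registry, id)
  registry@table$charge[match(id, registry@table$id)]
}

#' @describeIn speciesRegistry Element-count vector of one species.
#' @export
speciesFormula <- function(registry, id) {
  .assertSpecies(registry, id)
  registry@formulas[[id]]
}

.assertSpecies <- function(registry, id) {
  bad <- setdiff(id, registry@table$id)
  if (length(bad))
    stop(sprintf("unknown species id(s): %s", paste(bad, collapse = ", ")))
  invisible(TRUE)
}

setMethod("show", "SpeciesRegistry", function(object) {
  cat(sprintf("SpeciesRegistry with %d species: %s\n",
              nrow(object@table),
              paste(object@table$id, collapse = ", ")))
})
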