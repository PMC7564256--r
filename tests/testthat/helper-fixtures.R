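# Shared fixtures: the shipped reaction system plus a toy registry for
# property-style tests of the composition algebra.

rxSet <- oleateReactions()
spReg <- oleateSpecies()
recipes <- oleateRecipes(rxSet)
thermo <- oleateThermoTable()

# toy species over formal elements X, Y and a balanced reaction basis;
# random rational combinations of these are balanced by construction
toyRegistry <- speciesRegistry(
  id = c("X", "X2", "Y", "XY", "X2Y"),
  formula = c("X", "X2", "Y", "XY", "X2Y"),
  charge = c(0, 0, 0, 0, 0))

toyBasis <- list(
  parseEquation("2 X -> X2", toyRegistry),
  parseEquation("X + Y -> XY", toyRegistry),
  parseEquation("X2 + 2 Y -> 2 XY", toyRegistry),
  parseEquation("X2Y -> X2 + Y", toyRegistry))

# a random balanced toy reaction: small rational combination of the basis
randomToyReaction <- function() {
  k <- sample(1:2, 1)
  picks <- sample(seq_along(toyBasis), k)
  mults <- lapply(seq_len(k), function(i)
    c(sample(c(-3:-1, 1:3), 1), sample(c(1, 2, 4), 1)))
  composeReactions(reactionRecipe(toyBasis[picks], mults))
}

# independent oracle: naive term-by-term summation in plain named doubles
naiveCompose <- function(reactions, multipliers) {
  acc <- numeric(0)
  for (i in seq_along(reactions)) {
    co <- stoichiometry(reactions[[i]]) * multipliers[i]
    for (sp in names(co)) {
      acc[sp] <- (if (sp %in% names(acc)) acc[[sp]] else 0) + co[[sp]]
    }
  }
  acc <- acc[abs(acc) > 1e-9]
  acc[order(names(acc))]
}

# long-format series from a deterministic curve
curveSeries <- function(day, conc, treatment = "M", analyte = "CH4",
                        replicates = 1) {
  do.call(rbind, lapply(seq_len(replicates), function(r)
    data.frame(treatment = treatment, analyte = analyte, replicate = r,
               day = day, conc = conc)))
}
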