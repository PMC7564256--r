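# OleFe

Stoichiometric and thermodynamic accounting for anaerobic oleate
degradation when ferric hydroxide competes with methanogenesis for
reducing equivalents.

## The problem

Long-chain fatty acids (LCFA) such as oleate (C18:1, `C18H33O2^-`) are
degraded anaerobically through syntrophic beta-oxidation,

```
r1:  C18H33O2- + 16 H2O -> 9 C2H3O2- + 15 H2 + 8 H+     dG0' = +325.7 kJ
```

a step that is endergonic at standard conditions and runs only when a
hydrogen-scavenging partner keeps H2 low. The scavengers can be
methanogens (`r5`: H2 + 0.25 HCO3- + 0.25 H+ -> 0.25 CH4 + 0.75 H2O;
`r3`: acetate + H2O -> HCO3- + CH4) or iron-reducing bacteria when
amorphous Fe(OH)3 is supplied (`r4`: H2 + 2 Fe(OH)3 + 4 H+ -> 2 Fe2+ +
6 H2O; `r2`: acetate + 8 Fe(OH)3 + 15 H+ -> 2 HCO3- + 8 Fe2+ + 20 H2O).
Interpreting such incubations — how much methane a dose should give,
how much ferric hydroxide a pool of acetate demands, what fraction of
the electron equivalents the measured methane captured — is exact
bookkeeping over linear combinations of these half-reactions, with one
electron per Fe(III) -> Fe(II) as the accounting unit (H2 = 2 e-,
acetate = 8 e-, CH4 = 8 e-, oleate = 102 e-).

OleFe is aimed at anaerobic digestion and microbial bioenergetics work:
it provides the reaction algebra (exact rational coefficients, elemental
and charge balance with zero tolerance, dG0' combination with Hess-law
consistency checks), the electron ledger (theoretical yields,
partitioning between sinks, blank correction, recovery percentages),
incubation curve descriptors (tangent-intercept lag, windowed rates,
maxima), and a synthetic incubation generator for testing every stage.

## Worked example

```r
library(OleFe)

rx <- oleateReactions()           # the five elementary reactions + the
recipes <- oleateRecipes(rx)      # acetate oxidation half-reaction

# The overall methanogenic conversion: 1 r1 + 9 r3 + 15 r5.
composeReactions(recipes$net9)
#> oleate + 13.75 H2O -> 4.25 H + 5.25 HCO3 + 12.75 CH4  (dG0' = -461.8 kJ)

# Everything the algebra implies for a 3 mmol/L oleate dose:
predictReport(3, acceptorDose = 100)
#>                                quantity  value      unit
#>   theoretical CH4 (complete conversion)  38.25    mmol/L
#>        CH4 expected from hydrogen route  11.25    mmol/L
#>  CH4 with 0.333 of electrons to Fe(III)   7.50    mmol/L
#>             stoichiometric acetate pool  27.00    mmol/L
#>      Fe(OH)3 demand of the acetate pool 216.00    mmol/L
#>                           acceptor dose 100.00    mmol/L
#>                electron content of dose 306.00 mmol e-/L
```

Reading the block: complete conversion of the dose would give 38.25
mmol/L methane (12.75 per oleate); if only the beta-oxidation hydrogen
reaches the methanogens, 11.25; if iron reduction diverts a third of
those electrons, 7.5. The 27 mmol/L acetate the dose can transiently
accumulate would need 216 mmol/L ferric hydroxide for complete
oxidation — more than the 100 mmol/L supplied, which is why acetate in
such assays ends up consumed by methanogens instead.

Measured (or generated) curves feed the same ledger:

```r
ds <- generateIncubation(suspendedSludgeScenario(), seed = 3)
accountReport(ds, dose = 3)[, 1:7]
#>   treatment   maxCH4 theoreticalCH4 recoveryPct   lagDays      rate     rateSD
#> 1        IR 21.14873          38.25     55.2908  4.732298 0.3711014 0.03465564
#> 2         M 27.72475          38.25     72.4830 13.141615 0.5597345 0.02881777
```

i.e. the methanogenic series recovers ~72% of the theoretical methane
with a fitted tangent lag of ~13 days, while the iron-amended series
plateaus lower (electrons diverted to Fe(II)) but starts days earlier.

A thin command-line wrapper over the same functions ships in
`inst/scripts/olefe` (subcommands `balance`, `compose`, `predict`,
`account`, `simulate`).

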