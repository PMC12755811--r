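# hyaflux

Constraint-based modeling and strain design for microbial hyaluronic
acid (HA) production.

HA is a glycosaminoglycan of alternating D-glucuronic acid and
N-acetyl-D-glucosamine units, condensed by hyaluronan synthase from the
activated precursors UDP-GlcA and UDP-GlcNAc. Industrial producers fall
into two camps with very different metabolism: fastidious fermentative
streptococci that make HA natively, and engineered respiring hosts such
as *Corynebacterium glutamicum* carrying the pathway heterologously. In
both, HA competes with biomass formation for carbon (glucose-6-phosphate
and fructose-6-phosphate), energy (five ATP equivalents per disaccharide
unit) and redox (two NAD), so rational strain design is a flux-routing
problem. This package implements the standard constraint-based toolkit
for that problem — for modelers who want a small, fully inspectable,
dependency-light implementation with a built-in pair of test networks.

## What it does

Given a stoichiometric model with gene–protein–reaction (GPR) rules
(`MetabolicModel`, readable from a TSV+JSON table or an SBML Level 3
subset), the package provides:

* **FBA** — `fba()` maximizes an objective flux subject to steady state
  `S v = 0` and bounds `lb ≤ v ≤ ub`, on a built-in bounded-variable
  simplex; `fixGrowthFraction()`, `robustnessAnalysis()`,
  `rescaleToUptake()`, `chemostatFlux()` (`q = D·(C_sup − C_feed)/X`)
  and `atpYieldPerGlucose()` cover the derived analyses.
* **MOMA** — `moma()` predicts a knockout phenotype as the feasible
  point minimizing `Σ (v_i − v_i^ref)²` (quadratic programming; an L1
  mode is included), projecting from the deterministic minimal-flux
  wild-type state of `referenceState()`.
* **Deletion screens** — `singleGeneDeletion()` / `doubleGeneDeletion()`
  compute relative growth rates `Rgr = μ_mutant / μ_wild` through GPR
  logic and classify lethal, sick, synthetic-lethal and synthetic-sick
  outcomes; `summarizeInteractions()` reduces them to per-gene
  percentages.
* **Strain design** — `iterativeKnockoutSearch()` stacks up to three
  MOMA-evaluated deletions, discarding round-one candidates that lose
  more than 40% of wild-type growth; `sampleAlternateOptima()` +
  `regulationTargets()` compare many optima of maximized versus
  minimized product flux at 95% of optimal growth and nominate up- and
  down-regulation targets.
* **Biomass construction** — `dnaComposition()` (genome FASTA, double-
  strand counting), `proteinComposition()` (CDS translation or codon
  usage), `assembleBiomass()` (with growth-associated maintenance,
  default 39.4 mmol ATP/gDCW), `ngamReaction()` and `haPathway()` (the
  5 ATP / 1 acetyl-CoA / 2 NAD cost report per HA disaccharide).
* **Validation** — `growthError()`, `essentialityScreen()`,
  `carbonSourceScreen()`, `confusionMetrics()` (precision, accuracy,
  sensitivity, specificity, NPV, F-score at printed two-decimal
  precision) and `modelStats()`.
* **Synthetic model pair** — `makeNativeModel()` (EMP glycolysis,
  mixed-acid fermentation, truncated TCA, five amino-acid auxotrophies,
  HA branch) and `makeRecombinantModel()` (oxidative pentose-phosphate
  pathway, full Krebs cycle, electron transport, prototrophic), both
  elementally and charge-balanced, fully deterministic, and generated in
  code — no downloads.

## Worked example

```r
library(hyaflux)

m <- makeNativeModel()                     # anaerobic defined medium
objectiveValue(fba(m))
#> [1] 1.076891                             # growth rate, 1/h

bounds(m, "EX_o2_e") <- c(-10, 1000)       # aerate
ref <- referenceState(m)
fluxes(ref)[["EX_ha_e"]]
#> [1] 0                                    # wild type makes no HA

sol <- moma(knockout(m, "asd_syn"), ref)   # aspartate-pathway knockout
fluxes(sol)[["BIOMASS"]]; fluxes(sol)[["EX_ha_e"]]
#> [1] 0.7792208                            # growth drops ...
#> [1] 0.8491061                            # ... and HA flux appears

cfg <- searchConfig("EX_ha_e", maxDepth = 2)
head(iterativeKnockoutSearch(m, cfg), 3)
#>           knockouts round    growth growthRatioToWild productRate
#> 1  asd_syn,pykF_syn     2 0.1101191         0.0879559    4.545243
#> 2 acnA_syn,pykF_syn     2 0.1101191         0.0879559    4.545243
#> 3  icd_syn,pykF_syn     2 0.1101191         0.0879559    4.545243
```

The first lines mirror the native producer's behavior: maximum growth
leaves the HA branch idle, and precursor-drain knockouts divert carbon
into HA at a growth cost. The HA production rate is in mmol/gDCW/h;
`growthRatioToWild` is the mutant growth relative to wild type.

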