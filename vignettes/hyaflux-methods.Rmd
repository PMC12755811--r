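---
title: "Constraint-based analysis of hyaluronic acid producers with hyaflux"
author: "hyaflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of hyaluronic acid producers with hyaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyaflux)
```

## The modeling problem

Hyaluronic acid (HA) is polymerized from UDP-glucuronate (UDP-GlcA) and
UDP-N-acetylglucosamine (UDP-GlcNAc), both derived from upper
glycolysis. Per disaccharide unit the route from glucose consumes five
ATP equivalents (two hexose phosphorylations, two UTP activations
regenerated at one ATP each, and one glutamine regenerated at one ATP),
one acetyl-CoA and two NAD. HA therefore competes head-on with biomass
formation for carbon, energy and redox, and questions about improving
HA production are questions about rerouting flux.

This package works with the standard constraint-based abstraction: a
metabolic network is a stoichiometric matrix $S$ (metabolites by
reactions) with flux bounds $lb \le v \le ub$, and a phenotype is a
steady-state flux vector $S v = 0$. Exchange reactions follow the usual
sign convention (uptake negative, secretion positive); reversible
internal reactions carry bounds $(-1000, 1000)$ and irreversible ones
$(0, 1000)$, in mmol/gDCW/h. Gene deletions act through
gene-protein-reaction (GPR) rules, infix boolean expressions in which
AND joins subunits of a complex and OR joins isozymes; a reaction whose
rule evaluates false with the deleted genes removed has its bounds
closed to $(0,0)$, and a reaction with no known gene is untouched by
any knockout.

## Flux balance analysis and its solver

`fba()` maximizes one flux — by default the biomass pseudo-reaction,
whose flux is the specific growth rate $\mu$ (1/h) — by linear
programming. The package carries its own dense bounded-variable primal
simplex rather than an external LP library. That choice is deliberate:
the models this package targets are small (tens to a few hundred
reactions), a simplex returns exact basic solutions, and a fully
deterministic pivoting rule (Dantzig with smallest-index tie-breaks,
falling back to Bland's rule after thirty degenerate steps, so cycling
is impossible) makes every analysis bit-reproducible. Alternate optima
are pervasive in FBA; the package does not pretend otherwise, and
reproducibility comes from fixed solver settings and input ordering,
not from uniqueness. Steady-state feasibility is accepted at
$\|S v\|_\infty \le 10^{-6}$ (the LP noise floor; solutions are
refactorized at termination and typically reach $10^{-12}$), and growth
below $10^{-6}$/h counts as "no growth" wherever a binary growth call
is needed.

Derived analyses follow the field's conventions. `robustnessAnalysis()`
sweeps one reaction's allowed flux and re-optimizes a target at each
grid point; by default the grid value replaces the varied exchange's
lower bound — an uptake *allowance* — rather than pinning the flux,
which is the conservative reading when one asks "what could the cell do
with up to this much oxygen"; `fixed = TRUE` pins instead. An
infeasible grid point is recorded as `NA`, not an error.
`atpYieldPerGlucose()` fixes growth to zero and glucose uptake to one
unit, then maximizes flux through the ATP-maintenance hydrolysis
reaction: the optimum is mol ATP per mol glucose, a pure measure of
catabolic capacity uncontaminated by growth stoichiometry.
`rescaleToUptake()` multiplies a solution by
$100/|v_{\text{uptake}}|$ so flux maps obtained at different measured
uptake rates can be drawn on a common 100-mmol-glucose basis;
`chemostatFlux()` converts chemostat measurements into specific fluxes
via $q_i = D (C_{i,\text{sup}} - C_{i,\text{feed}}) / X_{\text{biomass}}$.

## MOMA: predicting knockout phenotypes

A fresh knockout strain has not re-regulated toward a new optimum, so
its flux state is better predicted by minimization of metabolic
adjustment: the feasible point of the perturbed model closest to the
wild-type state,
$\min \sum_i (v_i - v_i^{\text{ref}})^2$ subject to $S v = 0$ and the
perturbed bounds. Three design choices deserve a note.

*The reference is pinned down deterministically.* The wild-type FBA
optimum is degenerate, and MOMA predictions inherit any arbitrariness
in the reference. `referenceState()` therefore fixes growth at its
optimum and minimizes total absolute flux (a linear program on split
positive/negative parts) — the parsimonious state — making every
downstream mutant phenotype reproducible without any seed.

*The QP is solved in the null space.* The quadratic program is passed
to `quadprog` after re-parametrizing $v = v_0 + N z$, where $v_0$ is a
feasible point and $N$ an orthonormal null-space basis of $S$ augmented
with unit rows for fixed variables (knocked-out reactions). This keeps
the solver away from two failure modes of the naive formulation:
linearly dependent equality rows (conserved moieties make $S$
row-deficient) and exactly degenerate opposing inequalities at fixed
variables. A $10^{-9}$ slack on the box constraints guards against
degenerate active sets at the LP-vertex starting point; the solution is
clipped back into the box, an error three orders of magnitude below the
feasibility tolerance.

*Distance includes all reactions.* Exchange fluxes are part of the
adjustment in the original formulation, and by default here too.
Quadratic mode is the default (its solution is unique); an L1 mode is
available. The mutant's growth and product rates are read off the
projection.

## Deletion screens and interaction classes

`singleGeneDeletion()` reports $R_{gr} = \mu_{\text{mutant}} /
\mu_{\text{wild}}$ for every gene: lethal when $R_{gr} < 10^{-6}$, sick
when $R_{gr} < 1 - 10^{-3}$ (numerical guards on "zero" and "below
one"). In `doubleGeneDeletion()` two genes interact when the double
mutant grows strictly worse than either single; an interacting pair is
synthetic-lethal when the double $R_{gr}$ is zero although both singles
grow, synthetic-sick when it is positive but below both singles. Pairs
containing a lethal single are classified without solving (their double
is lethal with no new information), which keeps the quadratic screen
affordable. `summarizeInteractions()` reports percentages of the total
gene count; the "with 1 interaction" columns count genes with exactly
one synthetic partner and the "≥ 5" columns genes with five or more —
degree distributions over the interaction graph, recomputable from an
adjacency matrix.

## Strain design

`iterativeKnockoutSearch()` implements the iterative single-gene
deletion heuristic: round one evaluates every single knockout by MOMA
against the wild-type reference and keeps those that improve the
product rate by at least 1% relative (the configurable
`improvementThreshold`; the 1% default operationalizes "no significant
improvement" exclusions); later rounds repeat single-gene deletion in
each surviving mutant's genetic background, always projecting from the
wild-type reference, to the default depth of three. A round-one
candidate losing more than 40% of wild-type growth is reported but not
expanded — the growth rule is applied to round-one candidates only,
deliberately a literal reading; such a gene may still enter later as a
second or third knockout in another background. Knockout sets are
deduplicated, and results are sorted by product rate with
lexicographic tie-breaks, so the search is exactly reproducible.

For hosts where single deletions cannot force the product,
`sampleAlternateOptima()` characterizes the optimal face instead:
growth is constrained to at least 95% of optimum, the product flux is
pinned at its maximum (or minimum), and the face is scanned with
randomly weighted secondary objectives — each sample is the vertex
optimal for one random direction, under a fixed seed. The default of
5000 samples matches common practice for genome-scale networks;
the toy networks here have small optimal faces and stabilize far
earlier, so examples and tests use tens to hundreds.
`regulationTargets()` then nominates a reaction as an up-regulation
target when its entire flux range across max-product optima lies
strictly above its range across min-product optima (separation greater
than $10^{-6}$), and symmetrically for down-regulation: such a reaction
*must* carry more (or less) flux whenever the product is made,
independent of which alternate optimum the cell occupies.

## Biomass and HA pseudo-reactions

`dnaComposition()` counts bases under double-strand pairing (each A
implies a T opposite, so dAMP and dTMP fractions are both
$(A+T)/2N$), skipping ambiguous bases and reporting their count.
`proteinComposition()` translates coding sequences with the standard
code (internal stops skip the sequence with a warning) or expands a
codon-usage table. `assembleBiomass()` converts mass fractions and
molar fractions into mmol/gDCW coefficients — mass fraction times
molar fraction over the composition-weighted monomer weight — and
appends the growth-associated maintenance term
(ATP + H2O → ADP + Pi + H), 39.4 mmol ATP per gram biomass by default.
GAM is per gram of biomass formed; the per-hour dimension arises
through the growth flux. Polymerization water is folded into the
monomer coefficients so that consumed mass equals the declared mass
fractions exactly; `biomassMassCheck()` verifies a biomass reaction
drains ≈ 1 g per unit flux. Non-growth-associated maintenance is a
hydrolysis reaction with its lower bound pinned at NGAM;
`ngamFromMaintenanceUptake()` computes NGAM as maintenance-state
glucose uptake times the network's ATP yield. No literature NGAM value
is assumed; the synthetic models ship with 1.0 mmol/gDCW/h as an
explicit placeholder.

`haPathway()` locates the hyaluronan synthase condensation
(UDP-GlcA + UDP-GlcNAc → HA unit + 2 UDP, elementally balanced against
the C14H20NO11⁻ disaccharide anion) and the HA exchange, and prices one
unit by summing stoichiometry over the elementary route from glucose.
ATP equivalents count direct ATP, UTP at one ATP each (regeneration
from UDP by nucleoside-diphosphate kinase), and glutamine at one ATP
(regeneration by glutamine synthetase); on the default route this
yields exactly 5 ATP equivalents, 1 acetyl-CoA and 2 NAD.

## The synthetic model pair

Because the genome-scale reconstructions of real producers are not
shipped here, the package generates a faithful *pair of caricatures*
whose contrasts carry the biology:

* the **native producer** is a fastidious fermenter: glucose by PTS or
  permease+hexokinase, EMP glycolysis, lactate dehydrogenase, pyruvate
  formate-lyase with an ethanol branch (anaerobic acetyl-CoA is
  impossible without it: in a homolactic network every pyruvate is
  needed to reoxidize glycolytic NADH), a water-forming NADH oxidase as
  the aerobic redox valve, a TCA cycle truncated after isocitrate
  dehydrogenase (the sole NADPH source), non-oxidative pentose
  phosphate reactions only, uracil salvage beside de novo UMP
  synthesis, five strict amino-acid auxotrophies (His, Trp, Phe, Tyr,
  Cys), alternative sugars (fructose, sucrose, maltose, lactose), and
  the HA branch sharing UDP-glucose and UDP-GlcNAc with the cell-wall
  share of biomass;
* the **recombinant host** is a prototrophic respirer: oxidative
  pentose-phosphate branch (G6P dehydrogenase analog `zwf_syn`), full
  Krebs cycle, electron transport written as lumped oxidative
  phosphorylation at fixed P/O ratios (2 ATP per NADH, 1 per quinol) —
  a pumped-proton formulation in a two-compartment model admits a
  futile proton loop, so the lumped form is the honest one — an
  NADPH-linked glutamate dehydrogenase, and the same HA branch as a
  heterologous module.

Every metabolite carries a real elemental formula and pH-7 charge, and
every internal and transport reaction balances exactly; lumped
biosynthesis steps (lysine, valine, de novo UMP) conserve the atoms of
the true pathways. Charge balancing is report-only: `checkBalance()`
flags, it never edits.

The default media are the study conditions: glucose at 18.56 mmol/gDCW/h
(native, anaerobic by default) and 4.67 (recombinant, aerobic minimal
medium). Amino-acid supplementation in the native medium is
transport-capped — 0.30 mmol/gDCW/h for most synthesizable amino acids,
0.05 for aspartate, 0.27 for uracil — emulating the transport-limited
uptake of supplemented defined media. These caps are what give
knockouts their phenotypes: deleting a biosynthesis gene leaves the
capped import as sole supply, so the mutant grows slower while its
glucose intake persists, and MOMA redistributes the surplus carbon
partly into the HA branch. The cap values were chosen once so that the
growth penalties span the 40% pruning rule — aspartate-family drains
(the `ppc_syn` analog) collapse growth and are pruned, single
amino-acid drains (`asd_syn`, `ilvE_syn`, `asnA_syn`) lose ~35-40% and
survive to seed deeper rounds, and the pyrimidine drain (`pyrD_syn`)
is pruned in round one yet re-enters as a later knockout.

What the toys do *not* emulate: genome-scale redundancy (hundreds of
isozymes and alternate routes), regulatory effects, byproduct spectra
beyond lactate/formate/acetate/ethanol, maintenance energetics fitted
to data, or the real models' flux values. Tests passing on this pair
demonstrate that the algorithms behave correctly on networks with the
right structural contrasts — they say nothing quantitative about real
organisms.

## Numerical conventions and limitations

* LP feasibility tolerance $10^{-6}$; values below it are reported as
  zero in summaries. Bland's-rule fallback guarantees simplex
  termination; the basis inverse is maintained by product-form updates
  and refactorized every 60 pivots or on small pivots.
* Screen metrics are cut (not rounded) to two decimals, matching the
  truncation evident in published validation tables (11/13 prints as
  84.61%, 522/2049 as 25.47%); pass `printed = FALSE` for full
  precision. The growth-error percentage is reported at one decimal.
* Growth labels use G iff growth exceeds $10^{-6}$/h; growth (G) is the
  positive class in confusion tables, so an experimentally non-growing
  condition predicted to grow is a false positive.
* Problem sizes used in the shipped tests and the acceptance script:
  the full native (114 reactions, 56 genes) and recombinant (77
  reactions) models for screens and searches; 20 random ≤15-reaction
  models for LP solver cross-checks; 10 small knockouts for the QP
  cross-check; 50–200 alternate-optima samples; knockout search to
  depth 2 in tests and depth 3 in the acceptance script. These sizes
  were chosen as the smallest at which every qualitative contrast of
  interest is exercised.
* The SBML support is a deliberate subset (species with charge and
  formula, reactions with bounds, GPR and reaction kind in notes,
  gene products, one maximization objective); full FBC fidelity is out
  of scope, though exports parse cleanly in standard SBML libraries.
* Exhaustive triple-and-higher deletion screens, flux variability
  analysis as a user-facing mode, thermodynamic constraints and
  regulatory modeling are out of scope.
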