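---
title: "Constraint-based analysis of a motile, light-harvesting marine heterotroph"
author: "RoseoFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of a motile, light-harvesting marine heterotroph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RoseoFBA)
```

## The model

RoseoFBA works with constraint-based metabolic models: a stoichiometric
matrix $S$ (metabolites $\times$ reactions), flux bounds
$l \le v \le u$ in mmol/(gDW·h), and gene–protein–reaction (GPR)
associations. Flux balance analysis (FBA) maximizes the flux through a
biomass pseudo-reaction under the steady-state constraint $S v = 0$;
that flux is the predicted growth rate in 1/h. Flux variability
analysis (FVA) then minimizes and maximizes each reaction's flux with
the biomass flux pinned at (a fraction of) its optimum. Because these
models have large optimal faces, no single optimal flux vector is
trustworthy for a degenerate reaction; all headline analyses in this
package therefore work from FVA extremes, and the campaign machinery
can canonicalize flux vectors onto FVA midpoints before grouping so
that alternate optima of the same face are not counted as distinct
states.

The intended organisms are marine aerobic anoxygenic phototrophs of
the *Roseobacter* clade, typified by *Dinoroseobacter shibae*: Gram-negative
heterotrophs that harvest light for ATP without evolving oxygen, swim
with a proton-driven flagellar motor, respire oxygen, nitrate or DMSO,
and degrade the osmolyte DMSP through two competing routes, one of
which releases the cloud-seeding volatile DMS.

## Physiological states

A `PhysiologicalState` is one cell of a condition grid: carbon source
(26 choices), nitrogen source (ammonia, urea, nitrate), terminal
electron acceptor set ({O2}, {NO3}, {DMSO}, {O2,NO3}, {O2,DMSO}),
carbon uptake tier, illumination, and motile fraction. The full
cross-product is 7,020 states. `applyState()` translates a state into
model bounds:

* **Carbon-atom normalization.** Uptake bounds are tier / (carbon
  atoms of the source), so every source delivers the same carbon per
  hour at a given tier. The tiers are 1, 12 and 39.2 mmol carbon
  atoms/(gDW·h): an oligotrophic floor plus values derived from
  measured glucose and succinate uptake. Non-selected carbon exchanges
  are closed in both directions: the grid provides no secretion route
  for partially oxidized carbon, which would otherwise act as a
  spurious electron sink.
* **Illumination.** The photon exchange is bounded at 34.6 mmol
  photons/(gDW·h) in the light (0 in the dark). The bound is an upper
  bound on uptake, not an equality, by default: forcing full photon
  uptake would require futile dissipation cycles that a reduced
  network need not contain, and an upper bound preserves the natural
  monotonicity that light can never hurt growth. An equality mode
  (`photonEquality = TRUE`) is available. An alternative calibration
  of 33.8 is accepted the same way, as a plain argument.
* **Motility.** The flagellar motor is a fixed proton drain from the
  external/periplasmic pool into the cytosol. The closed-form motor
  estimate (1200 protons/rotation × 10 rotations/s ÷ 300 fg dry mass)
  evaluates to about 0.24 mmol/(gDW·h) per fully motile culture —
  three orders of magnitude below the operating point of 24
  mmol/(gDW·h) for a 10% motile culture that the flux constraint is
  anchored at. Both numbers are exposed (`motilityFlux()` versus
  `motilityFluxFromPhysics()`); the imposed constraint follows the
  operating point and scales linearly with the motile fraction.
* **Nitrogen.** Nitrate as nitrogen source and nitrate as electron
  acceptor share one exchange; assimilation and respiration are
  distinguished by reaction tags, not by separate pools. Nitrogen
  exchanges are uptake-only, since excreting ammonia produced from
  nitrate would otherwise implement an uncapped dissimilatory electron
  sink.
* **Biomass variant.** Aerobic anoxygenic phototrophs synthesize
  bacteriochlorophyll *a* only in the dark under aerobic conditions,
  so the objective switches to the bacteriochlorophyll-containing
  biomass variant exactly then.

## Biomass construction

`buildBiomassReactions()` converts macromolecule mass fractions
(protein 45.34%, DNA 3.22%, RNA 4.11%, lipids 14.02%, PHB 24.70%,
bacteriochlorophyll 0.08%, LPS 4.00%, peptidoglycan 2.50%, unknown
0.10%, soluble pool = remainder) into monomer coefficients, fraction ×
share / residue mass, in mmol/gDW. The tabulated rows sum to 98.07%,
so the exact soluble-pool remainder is 1.93%; a printed 1.91% carries
0.02% of rounding that the package does not reproduce. Consumed
monomer mass closes to 1 g per gDW within 1% by construction. The
growth-associated maintenance (GAM, 53.95 mmol ATP/gDW) rides inside
both biomass reactions; the non-growth-associated maintenance (nGAM,
3.15 mmol ATP/(gDW·h)) is a standalone always-on hydrolysis with a
positive lower bound, so that it binds even at zero growth — this is
what makes energy-starved states infeasible rather than merely
non-growing, and those cells are recorded as growth 0. The
bacteriochlorophyll term is tied to protein content (4 nmol per mg
protein, i.e. 1.81 µmol/gDW) rather than to its own mass row; the two
accountings agree to within the closure tolerance. Monomer
compositions for DNA, RNA and protein can be estimated from genome
base counts and codon usage (`monomerFractionsFromGenome()`), with
strand symmetry enforced for DNA. Components of unknown identity map
onto a generic 1 g/mmol pool so that mass closes without inventing
chemistry; the soluble pool is spread over a configurable
small-metabolite list with uniform mass shares.

## The synthetic core network

`generateCoreModel()` builds a ~190-reaction, fully mass-balanced core
network that stands in for a genome-scale reconstruction in every
test. It grew past an initial ~100-reaction sketch because the full
condition grid demands a catabolic route for each of the 26 carbon
sources; it remains small enough for exhaustive oracle testing. What
it emulates:

* the proton-translocating stoichiometries of oxidative
  phosphorylation (NADH:ubiquinone reductase 4 H⁺ out; cytochrome-c
  oxidase and ubiquinol oxidase; the bc1 complex; the 4-H⁺ two-sector
  ATPase; the Na⁺/2H⁺ antiporter; the flagellar motor), which give
  exactly 10 exported protons per NADH along the bc1/oxidase route and
  hence 2.5 ATP per NADH;
* a two-reaction photosystem: a cyclic reaction centre consuming two
  photons plus the proton-translocating bc1 step, i.e. two protons
  exported per photon;
* glucose catabolism through an Entner–Doudoroff route, with the
  phosphofructokinase present but constrained to (0, 0) — the enzyme
  is genomically present yet inactive — and re-openable as a genotype
  toggle;
* both DMSP branches: demethylation through
  tetrahydrofolate/methanethiol with the C1 unit assimilated via the
  glycine/serine cycle and serine ammonia-lyase, and cleavage to DMS
  plus acrylate; both volatiles have export routes. The demethylase
  carries an enzyme-capacity bound (default 1 mmol/(gDW·h)), which
  makes the demethylated fraction a sharp, testable quantity
  (capacity/uptake) and reproduces the observed decline of that
  fraction with rising uptake tier;
* capacity-limited respiratory denitrification (default 0.05
  mmol/(gDW·h)) alongside uncapped DMSO reduction and an uncapped
  assimilatory nitrate branch. The capacity is chosen so that the
  reducing equivalents of an illuminated oligotrophic state exceed the
  oxygen-independent disposal routes — precisely the construction
  under which parallel oxygen/nitrate use ("aerobic denitrification")
  appears on the optimal face in the light and not in energy-limited
  darkness;
* plasmid-tagged genes: the dTDP-rhamnose pathway (an essential LPS
  precursor with no alternative route) on an "86 kb" replicon, whose
  loss is lethal everywhere, and a catalase on a "153 kb" replicon
  backed up by a metabolically more expensive cytochrome-c peroxidase;
* a corrinoid branch with an oxygen-dependent aerobic route (also the
  model's peroxide source) and an oxygen-independent but ATP-costlier
  anaerobic route, making the anaerobic-route gene essential exactly
  in anaerobic states — a planted "multifaceted" knockout phenotype;
* a dedicated, always-open oxygen exchange that exclusively supplies
  the lower-ligand synthase of the corrinoid pathway, for which no
  anaerobic alternative is known;
* by-product sinks (folate-pathway glycolaldehyde, thiamin-pathway
  leftovers, the lower-ligand by-product) with small bounds, so that
  sink carbon export stays orders of magnitude below carbon input;
* decoy OR-paralog pairs (seeded placement) plus a planted paralog
  pair on the phosphoglucose isomerase, giving known "no effect"
  knockouts; and a planted two-reaction dead-end pathway, which —
  together with the constrained phosphofructokinase and the strictly
  cycled sodium exchange — is exactly the blocked-reaction set.

Formula conventions are internally consistent rather than textbook:
NADH carries one hydrogen more than NAD (the hydride), both cytochrome
states are element-identical (the electron rides the iron), coenzyme A
is a pseudo-element plus its thiol hydrogen, and every internal
reaction balances all elements exactly, with cytosolic protons closing
the hydrogen bookkeeping. The external proton pool exchanges freely
(fixed medium pH); energy accounting survives because the cytosolic
pool has no exchange and can only be cleared by the pumps — which is
also why the motility drain costs what it should.

What the generator does **not** emulate: genome-scale gene coverage
(~190 reactions versus ~1500), thermodynamic or regulatory
constraints, fermentative overflow metabolism, sulfur assimilation
beyond a single lumped route, or realistic secretion spectra. Passing
the synthetic suite therefore demonstrates that the *pipeline*
computes the right quantities on a network whose ground truth is known
by construction, not that a genome-scale reconstruction would
reproduce any particular measured number.

## Numerical choices

* The LP engine is a dense bounded-variable two-phase primal simplex
  (Rcpp/Armadillo): steady state to 1e-6, bound feasibility 1e-7,
  zero-flux threshold 1e-6, reduced-cost tolerance 1e-9, unbounded
  directions clamped at ±1000 mmol/(gDW·h). Nonbasic variables may
  start at interior values (zero flux is nearly feasible when
  $b = 0$), Bland's rule engages after degenerate stalls, and every
  reported solution is verified against the constraints — on any
  violation the instance is re-solved conservatively with
  per-iteration refactorization. A reference tableau simplex (from
  boot) is wired in as an alternative backend and serves as the
  independent oracle on small fixtures.
* FVA adds the objective-fixing row once (through a slack variable)
  and solves one LP per reaction per direction in deterministic id
  order.
* Flux-distribution grouping rounds vectors to the comparison
  tolerance (default 1e-6); with per-cell FVA ranges available,
  fluxes of degenerate reactions are first snapped to the FVA
  midpoint.
* Knockout phenotype classification uses a relative growth-equality
  tolerance of 1e-4.
* The DMS screen closes the DMSO reductase outright, so that all
  reported DMS originates from DMSP; maximal DMS export is reported as
  the FVA maximum at the mutant's optimal growth (both extremes are
  stored).

## Known limitations

* The denitrification capacity trades off two behaviors: small enough
  to force parallel oxygen use in illuminated oligotrophic states, it
  leaves nitrate-only anaerobic states barely viable (they grow only
  without the motility drain). DMSO respiration is the unconstrained
  anaerobic route.
* "Aerobic denitrification only in the light" holds wherever darkness
  is energy-limited. Carbon-limited darkness on a highly reduced
  substrate at high uptake (ethanol at the 12-atom tier) also admits
  parallel acceptor use — surplus electrons must go somewhere
  regardless of the energy budget — so the dark-exclusion property is
  asserted over energy-limited dark states.
* On glycolate/glyoxylate the core network assimilates C2 units
  through the glycerate pathway (malate synthase alone cannot yield
  net carbon), so isocitrate branch fractions differ from a
  genome-scale model in which the glyoxylate shunt carries that flux.
* The knockout phenotype split is computed over the paralog-free gene
  set on a reduced representative state list; a ~190-reaction network
  is necessarily denser in essential single-copy routes than a
  genome-scale one, so its "no effect" share is smaller.
* Problem sizes in the shipped tests and the acceptance script: the
  full 7,020-state wild-type campaign; knockout classification over
  all paralog-free genes × 48 protocol states; FVA restricted to the
  reactions each analysis needs. On one CPU the whole test suite and
  the acceptance script each run in minutes.

## A worked example

```{r example, eval = FALSE}
gen <- generateCoreModel()
m <- gen$model

state <- list(carbon_source = "DMSP", n_source = "ammonia",
              e_acceptors = "O2", uptake_tier = 12,
              illumination = 34.6, motile_fraction = 0.1)

solveFBA(applyState(m, state))
demethylationContribution(m, state)
dmsOverproductionScreen(m, as.data.frame(state), "dmdA")
```
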