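---
title: "Modelling cardiomyocyte energy metabolism with an explicit proton motive force"
author: "mitoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cardiomyocyte energy metabolism with an explicit proton motive force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoflux)
```

## The model

`mitoflux` implements a two-compartment (cytosol / mitochondrial matrix)
constraint-based model of human central metabolism, optimised for
cardiomyocytes, and the flux balance analysis (FBA) machinery to simulate it.
As in any constraint-based model, reaction fluxes $v$ are constrained by
steady-state mass balance $S v = 0$ over the internal metabolites and by flux
bounds $l \le v \le u$; a linear objective (here almost always maximal flux
through the ATP-hydrolysis demand reaction) is optimised by linear
programming.

What distinguishes this model from generic reconstructions is the explicit
bookkeeping of the proton motive force (PMF). Oxidative phosphorylation is
driven by an electrochemical proton gradient with two components: the
membrane potential $\Delta\Psi$ and the pH gradient $\Delta\text{pH}$.
Generic models track only protons as chemical species, which misses the
energetic cost of electrogenic transport entirely and invites artefacts in
which scalar protons produced by ordinary chemistry inflate ATP production.
Here the PMF is a pseudo-metabolite present in both compartments (`pmf_c`,
`pmf_m`). The respiratory complexes convert `pmf_m` to `pmf_c` (pumping);
every consumer converts it back. A transport step that moves net charge $z$
into the matrix and $p$ protons electroneutrally carries the coefficient

$$k \;=\; 0.82\,|z| \;+\; 0.18\,p,$$

the two weights being the relative contributions of $\Delta\Psi$ and
$\Delta\text{pH}$ to the total gradient. A pumped (vectorial) proton affects
both components and carries exactly $0.82+0.18 = 1$. Two canonical examples,
written as the package builds them:

* adenine nucleotide translocase (electrogenic ATP$^{4-}$/ADP$^{3-}$
  exchange): `atp_m + adp_c + 0.82 pmf_c -> atp_c + adp_m + 0.82 pmf_m`;
* phosphate carrier (electroneutral Pi/H$^+$ symport): consumes `0.18 pmf_c`
  per phosphate imported.

The respiratory chain pumps 10 PMF per matrix NADH and 6 per ubiquinol,
split 4/2/4 over complexes I, III and IV (`pmf_parameters()`; a 4/4/2 split
is selectable — only the totals affect ATP yields). The ATP synthase
consumes 2.7 PMF per ATP, reflecting the c-ring stoichiometry of the
mammalian enzyme (8 c subunits and 3 catalytic sites give 8/3 protons per
ATP, plus the scalar proton accounted on the phosphate carrier). A fraction
$10^{-5}$ (0.001%) of complex-I flux is diverted to superoxide, embedded
directly in the complex-I stoichiometry because FBA cannot otherwise couple
the fluxes of two separate reactions; the resulting peroxide is reduced at
the expense of matrix NADPH (NADP-isocitrate dehydrogenase is the matrix
NADPH source, and the NADH and NADPH pools are otherwise kept strictly
separate).

The flavin prosthetic groups of succinate dehydrogenase and the
electron-transfer flavoprotein (ETF) system are *bound* cofactors: no free
FAD/FADH species exists anywhere in the model. Complex II and the
ETF:ubiquinone oxidoreductase reduce the quinone pool directly, so
beta-oxidation electrons cannot leak between enzymes through a fictitious
shared FAD pool.

### Energy arithmetic

These conventions make ATP yields exact consequences of small-integer
pathway counts. One cytosolic ATP regenerated by the synthase costs
$2.7 + 0.82 + 0.18 = 3.7$ PMF (synthesis + export + phosphate return); a
matrix substrate-level ATP costs 1 PMF to export; a cytosolic NADH pays 1
PMF to the malate–aspartate shuttle (the aspartate/glutamate carrier is
electrogenic and proton-coupled, hence 1.0 per cycle; the
oxoglutarate/malate carrier is electroneutral). Per matrix NADH the chain
delivers $10(1-10^{-5})$ PMF, so a minimal oxidative-phosphorylation
micro-model exports

$$\frac{10\,(1-10^{-5})}{3.7} \approx 2.703 \text{ ATP per matrix NADH},$$

which the test suite verifies against the package to $10^{-6}$.

## Transport categories

Each mitochondrial transport step belongs to one of four categories:

* **CARRIER** — characterised transporters, modelled with their counter-
  exchange and proton coupling. Proton-coupled importers whose reversal
  would artificially pump protons (pyruvate and phosphate carriers) are
  split into two irreversible reactions, with the proton + PMF only on the
  downhill direction. The phosphate-carrier split matters quantitatively:
  left reversible, the backward reaction would mint 0.18 PMF per exported
  phosphate from a concentration gradient the model does not track, and
  every yield involving the malate/phosphate antiporter would inflate by
  0.18 PMF per pyruvate. The ATP/ADP carrier and the ATP synthase stay
  genuinely reversible: their reversal consumes cytosolic ATP and is exactly
  the physiology observed under extreme proton leak.
* **UNIPORT_UNKNOWN** — metabolites with unidentified transporters, as
  uniport. A cation moving inward dissipates $\Delta\Psi$ and carries
  $0.82|z|$. An *uncompensated* anion import would have to create PMF, which
  transport is forbidden to do (only the respiratory complexes move PMF from
  matrix to cytosol); such metabolites are modelled proton-compensated
  (electroneutral, 0.18) instead — the package refuses to build the
  PMF-creating variant.
* **DIFFUSION** — O2, CO2, water, ammonia and (as neutral acids) the ketone
  bodies: reversible uniport, no PMF.
* **FLIPPASE** — ATP-hydrolysis-coupled insertion of lipid into the inner
  membrane; construction fails if the ATP coupling is omitted.

## The bundled reduced network

`build_reduced_model()` assembles a 96-reaction, 89-metabolite network:
glycolysis, lactate oxidation, the glycerophosphate shuttle, pyruvate
dehydrogenase, the TCA cycle, the malate–aspartate shuttle, carnitine
shuttle plus (lumped) beta-oxidation of hexadecanoate, ketolysis,
degradation routes for alanine, aspartate, glutamate and glutamine
(mitochondrial transaminases, glutamate dehydrogenase with ammonia efflux,
and the mitochondrial PEPCK / NAD-malic-enzyme routes for four-carbon exit),
the full respiratory chain with the ROS branch, the UCP2 proton leak
(`HtmB_MitoCore`), boundary exchanges for all fuels plus O2, CO2, water,
ammonia, fumarate and phosphate, and four pseudo demand reactions (ATP
hydrolysis, heme, membrane lipid, amino acid biosynthesis) usable as FBA
objectives. The same network ships as a TSV fixture
(`load_bundled_model()`), and the test suite asserts the fixture equals the
programmatic build.

Reaction identifiers follow the reference-database form where one exists;
reactions rewritten for the PMF representation or newly introduced carry the
`_MitoCore` suffix. Bounds are $\pm1000$ for reversible and $[0, 1000]$ for
irreversible reactions, in µmol/min/gDW throughout.

Deliberate scope reductions: no pentose phosphate pathway, no urea cycle
(amino-acid nitrogen leaves as ammonia), no synthesis pathways beyond the
pseudo sinks, and only the four amino acids with printed reference yields
among the substrates. Glycine appears solely as a heme precursor. Uptaken
boundary pyruvate is grouped with lactate in acetyl-CoA attribution (both
enter through the monocarboxylate pool).

### Scalar protons

Free H$^+$ species are deliberately absent. Proton coupling is carried
entirely by the PMF coefficients; chemistry that would produce or consume
scalar protons is written without them. The alternative — tracking `h_c` and
`h_m` explicitly — adds a conservation constraint that either blocks flux or
requires an arbitrary proton sink, and it contributes nothing to the
quantities the model is built to predict, which depend only on the PMF
bookkeeping. The cost is that charge balances of individual reactions can
show a delta equal to the omitted protons; `validate_balance()` therefore
*reports* charge and hydrogen deltas informationally and only counts
non-hydrogen elemental imbalances as issues. The PMF species and the pseudo
reactions are exempt and flagged as such (the PMF is bookkeeping, not
chemistry — it carries no nominal charge).

## Simulation machinery

* `fba()` solves the LP with the package's dense bounded-variable two-phase
  simplex (primal/dual tolerances $10^{-9}$; solutions are re-derived from a
  fresh factorisation of the final basis, so steady-state residuals sit at
  rounding level). The solver is validated in the test suite against an
  independent brute-force vertex-enumeration oracle on small networks.
  Solver failures surface as a `status`, never silently.
* `fva()` computes per-reaction flux ranges at a fraction (1.0 or 0.98 in
  routine use) of the optimum. All sub-problems share one feasible region,
  so they are solved in one warm-started batch.
* `geometric_fba()` returns a deterministic, well-centred optimum: it
  iteratively computes the FVA bounding box at the optimum, solves a minimax
  LP towards the box midpoints and shrinks the box until its width falls
  below `epsilon` (default $10^{-4}$ µmol/min/gDW, a width far below any
  reported flux; `flex_rel` optionally relaxes the optimum constraint; the
  iteration cap default is 60, and non-convergence is an error carrying the
  last iterate). Tiny numerical guards (a $10^{-9}$ feasibility pad on the
  shrinking box, clamping the minimax value at zero) keep the boxes strictly
  feasible under floating-point rounding. Reported flux distributions always
  come from geometric FBA; plain FBA vertices can include zero-cost futile
  cycles (e.g. the fumarase/dicarboxylate-carrier water loop) that geometric
  FBA centres away.
* `knockout()` zeroes every reaction associated with a target gene; protein
  complexes are single reactions, so one subunit gene disables the whole
  step. `scan_bound()` re-solves over a series of bound values, reporting
  infeasible points rather than stopping.

## Protocols

**ATP yields** (`atp_yield()`): all degradable-fuel uptakes closed, oxygen
at 50 µmol/min/gDW (never limiting; asserted), the fuel of interest at
1 µmol/min/gDW, geometric FBA maximising ATP hydrolysis. At unit uptake the
objective is mol ATP per mol fuel. The suite pins all eight bundled
reference fuels to an independent proton-accounting oracle computed from
pathway counts, to $10^{-6}$.

**Fumarase deficiency** (`simulate_fumarase_deficiency()`): the FH gene
encodes both the cytosolic and mitochondrial enzyme, so a single gene
knockout disables both reactions; uptakes stay at their defaults. The model
reproduces the qualitative disease signature: the TCA cycle runs to
fumarate, which is effluxed; oxaloacetate is replenished by pyruvate
carboxylase and the malate–aspartate machinery; maximal ATP production
collapses by well over half.

**Proton leak** (`proton_leak_scan()`): a minimum flux is forced through
`HtmB_MitoCore` (vectorial protons re-entering the matrix, dissipating 1 PMF
each) over an increasing series. Maximal ATP decreases linearly at 1/3.7 ATP
per unit leak while the chain is oxygen-limited; the synthase flux falls,
crosses zero and reverses (hydrolysing matrix ATP to sustain the gradient),
and at the highest feasible leak the ATP/ADP carrier and the net phosphate
carrier reverse too, importing glycolytic ATP. Beyond the chain's and the
reversed machinery's joint capacity the LP is infeasible and the scan
truncates with a notice.

**Acetyl-CoA attribution** (`attribute_acetyl_coa()`): FBA carries no tracer
information, so shared pools (triose phosphates, PEP, cytosolic and matrix
pyruvate) are resolved by proportional mixing — each pool passes its inflow
source fractions on pro rata, solved as a small linear system. Malic-enzyme
and PEP-carrier inflows are tagged as amino-acid-derived, a convention
justified in this network because only the amino-acid routes use the
four-carbon exit pathways.

## Default uptake configuration

The paper-grade default bounds of the published full-size model are not
reproducible from printed sources, so `default_uptake_config()` ships an
*approximate, editable* configuration chosen once to emulate a well-perfused
heart: a fatty-acid-dominant fuel mix (glucose 0.6, lactate 0.4, pyruvate
0.1, hexadecanoate 0.45, 3-hydroxybutanoate 0.15, acetoacetate 0.05,
alanine 0.15, glutamate/glutamine 0.1 each, aspartate 0.05, glycerol 0.05,
glycine 0.05 µmol/min/gDW) supplied in slight excess of what 16 µmol/min/gDW
of oxygen can oxidise, so oxygen limits overall flux. Under these defaults
the model produces ~82 µmol ATP/min/gDW with ~53% of acetyl-CoA from
beta-oxidation and the remainder from glucose, lactate, ketone bodies, amino
acids and glycerol — the physiological regime reported for heart (60–90%
fatty-acid-derived acetyl-CoA in perfusion studies). Quantitative case
studies should replace these with measured uptakes; the ATP-yield protocol,
which is fully specified, does not depend on them.

## What the bundled network does and does not show

The bundled model is a reduced, curated network with exact decimal
stoichiometries and hand-assigned bounds. Passing its tests shows that the
PMF representation, the simulation protocols and the QC machinery behave as
designed under controlled conditions. It does not show that the reduced
network captures everything a 400-reaction curated reconstruction captures:
pathways outside its scope (pentose phosphate, most amino-acid routes,
nucleotide metabolism) simply do not exist here, the default uptake bounds
are approximate, and FBA itself predicts capabilities, not kinetics or
concentrations — a maximal yield is an upper bound achieved under optimal
enzyme usage, not a measured rate.

## Quality control

`qc_report()` automates the release tests a curated model must pass: every
reaction can carry flux with the boundary open (batch FVA with uptakes at
±1000); no metabolite is producible-only or consumable-only; and with every
exchange closed the maximal flux through ATP hydrolysis — and through
temporary PMF, NADH and NADPH sinks, since an erroneous loop may launder
energy through any currency — is exactly zero. The test suite additionally
keeps three deliberately broken variants failing their targeted checks,
including the classic artefact this design exists to prevent: strip the PMF
terms from the ATP/ADP carrier, let the leak run backwards, and the
closed-system ATP optimum becomes positive.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| $\Delta\Psi$ / $\Delta\text{pH}$ weights | 0.82 / 0.18 | relative contributions to the PMF; stored as exact decimals |
| Synthase stoichiometry | 2.7 PMF/ATP | mammalian c-ring structure |
| Chain pumping | 10 per NADH, 6 per QH2, split 4/2/4 | charge-based bookkeeping; only totals affect yields |
| ROS diversion | $10^{-5}$ of complex-I flux | printed 0.001%, embedded in the stoichiometry |
| Default bounds | ±1000 / [0, 1000] µmol/min/gDW | conventional large-M caps |
| LP tolerances | $10^{-9}$ | residuals at rounding level after basis refresh |
| Geometric `epsilon` | $10^{-4}$ | box width far below reported fluxes |
| Yield reporting | 1 decimal | convention for yield tables |
| Blocked/zero tolerance | $10^{-6}$ | separates structural zeros from rounding |

## A worked example

```{r example, eval = FALSE}
model <- build_reduced_model()
qc_report(model)                     # passes: no blocked, no dead ends, 0 energy
atp_yield_table(model, c("glc", "hdca", "lac"))
fd <- simulate_fumarase_deficiency(model)
fd$percent_atp_reduction             # > 50% ATP loss
fd$fumarate_efflux                   # fumarate appears in the effluent
```

Problem sizes used throughout the examples, tests and the acceptance script
are the bundled 96-reaction network and toy networks of at most 8 reactions
for oracle comparisons; a full QC pass plus all eight yield protocols
completes in a few seconds on one CPU.
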