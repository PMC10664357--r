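---
title: "Methods: comparative dynamic and enzyme-constrained FBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative dynamic and enzyme-constrained FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynefba)
```

## Scope

`dynefba` implements the constraint-based workflow used to compare a
respiratory yeast (carrying proton-pumping Complex I) against a
fermentative one (carrying only the non-pumping Type II NADH
dehydrogenase): steady-state and lexicographic flux balance analysis
(FBA), batch dynamic FBA (dFBA) by the static optimization approach,
sMOMENT-style enzyme-constrained models with a finite protein pool,
majority-vote consensus over reconstruction ensembles, and the screens
that localize phenotype differences — cumulative knockouts, reaction
transplantation, Complex I proton-stoichiometry editing, and chemostat
growth fitting. A generator builds a matched pair of compartmentalized
core models carrying the structural features these analyses probe.

## The optimization layer

FBA solves `max c'v` subject to `S v = 0` and `lb <= v <= ub`. The LP is
solved by a bounded-variable two-phase primal simplex implemented in
compiled code inside the package. Phase 1 drives artificial variables out
of the basis; phase 2 optimizes the true objective with the artificials
pinned at zero. Pricing is Dantzig with an automatic switch to Bland's
rule after an iteration budget, which guards against cycling under
degeneracy; pivot and feasibility tolerances are `1e-9` and `1e-7`.
Optimal solutions satisfy `max |S v| <= 1e-6 * max(1, |v|)` — the mass
balance property asserted in the test suite, where the solver is also
checked against an independent vertex-enumeration oracle on random
networks of up to a dozen reactions.

FBA optima over secreted products are usually degenerate. Everywhere
fluxes are reported, the package therefore uses the five-stage
lexicographic ordering as the tie-breaker: maximize growth; minimize
glucose consumption; maximize ethanol, then acetate, then glycerol
excretion. After each stage the optimized flux is fixed to its optimum
within a relative slack `fix_tolerance` before the next stage is solved.
The default slack is `1e-6`; it makes successive stages numerically
feasible while changing stage optima by at most that relative amount.
Stage 1 is bitwise the plain FBA problem, so the lexicographic growth
rate equals the plain optimum exactly. "Minimize glucose consumption" is
implemented as maximization of the signed exchange flux: in any batch
medium the glucose exchange's upper bound is zero, so the least negative
flux is the smallest uptake.

## Batch dynamic FBA

The static optimization approach treats the culture as
`dX/dt = mu X`, `dC_i/dt = v_i X`, where `mu` and the tracked exchange
fluxes `v_i` are stage optima of the lexicographic inner problem at the
current state. Using stage optima (rather than an arbitrary member of the
optimal face) makes the right-hand side a deterministic function of the
state. The system is stiff near substrate exhaustion, so integration uses
the BDF method via `deSolve::ode` at absolute and relative tolerance
`1e-2`, with output resampled on a uniform 0.1 h grid (the grid is a
reporting choice; halving the tolerances moves the final biomass of the
fixtures by well under 1%, a property the test suite checks).

Default conditions of a batch run: 10 mmol/L glucose, 0.1 gDW/L biomass,
12 h horizon; glucose uptake bounded by Michaelis-Menten kinetics with
`V_max` 10 mmol/gDW/h and `K_M` 5 mmol/L; oxygen supplied at a fixed
10 mmol/gDW/h; the wasteful mitochondrial proton leak closed; tracked
fermentation products (ethanol, acetate, glycerol) secretion-only, which
excludes diauxic re-consumption that the framework does not model.
Fructose batches reuse the glucose kinetics on the corresponding
exchange.

Termination: the toy models carry a non-growth ATP maintenance demand
(1 mmol/gDW/h). When glucose can no longer cover it, the inner problem
goes infeasible; the simulation then freezes the state and pads the
trajectory with the terminal state up to the horizon, and flags
`terminated_early`/`padded` accordingly. Without a maintenance demand a
Michaelis-Menten batch never terminates (glucose decays asymptotically),
so the maintenance term is what gives batch runs a well-defined end.

## Enzyme constraints (sMOMENT)

`augment_with_pool()` adds a protein-pool pseudo-metabolite delivered by
a single reaction bounded by `p_tot` (g protein/gDW). Each reaction
flagged as drawing from the pool consumes `MW / (kcat * saturation)`
grams of pool per unit flux; reversible pooled reactions are split into
irreversible forward/backward halves (bounds partitioned as
`[max(0, lb), ub]` and `[0, -lb]`) so each direction carries its own
cost. The saturation convention is full saturation (`sigma = 1`);
`equivalent_pool()` converts a literature `(P_tot, sigma)` pair to this
convention by simple multiplication. Turnover numbers are stored in 1/h
to match flux units; the table reader converts from 1/s by 3600 and
collapses duplicate rows to their median, a documented rule for ambiguous
parameter sets. Reactions without parameters carry no protein cost —
mirroring automated reconstructions, where unannotated reactions
(notably mitochondrially encoded respiratory subunits) are free — and a
strict mode turns that into an error instead.

The default pool scan covers `{0.1, 0.25, 1.0}` g/gDW, spanning
scarce to effectively unconstraining protein. At a very
generous pool the augmented model reproduces the unaugmented optimum,
and `p_tot = 1e3` reproduces the plain dFBA trajectories, which is how
the enzyme-constrained path is validated against the plain one.

## The generated model pair

The generator emulates the comparative situation the screens are meant to
discover, with every non-exchange reaction balanced for C, H, N, O, P and
charge (protons tracked per compartment; the biomass macromolecule is
assigned the exactly balancing formula, which makes trajectory-level
carbon accounting closed by construction):

* a lumped glycolysis (2 ATP + 2 NADH per glucose), pyruvate
  fermentation branches to ethanol and (NADP-linked) acetate, an
  ATP-costing glycerol branch that is never optimal under the default
  medium, pyruvate oxidation through a lumped TCA, a quinone pool, a
  proton-translocating terminal oxidase (6 H+ per QH2) and an ATP
  synthase importing 4 H+ per ATP (3 translocated, 1 chemical);
* the respirer additionally carries Complex I (4 H+ per NADH), a
  mitochondrial folate-cycle analog (an ATP-free route to biomass formyl
  units whose cytosolic counterpart costs one ATP), and both
  compartmental placements of the NADP-linked glutamate dehydrogenase
  (GDH) and isocitrate dehydrogenase (IDP);
* the fermenter is a strict reaction subset: NDH-2 only, GDH cytosolic
  only, IDP mitochondrial only. No reaction carries alpha-ketoglutarate
  out of the mitochondrion, so the fermenter's only cytosolic NADPH
  source is the acetate branch: nitrogen assimilation through cytosolic
  GDH forces acetate secretion proportional to growth. That is the
  planted fermentation differentiator, and it is small by design — the
  two models differ in *how* NADPH is made long before they differ much
  in growth.

**The two-regime design.** Ammonium supply is capped (0.19 mmol/gDW/h by
default), placing nitrogen-limited growth (0.38 1/h at the default
biomass composition) strictly between the two species' ATP-limited
growth capacities. With Complex I present, growth is nitrogen-limited
and glucose is in excess: the folate analog and both shuttle placements
then have exactly zero marginal growth value (their resources are
non-binding, so the LP shadow prices vanish), which is why transplanting
Complex I into the fermenter reproduces the respirer's growth rate to
machine precision, and why the growth screen stays silent on those
reactions while Complex I is intact. Without Complex I, growth is
ATP-limited: removing Complex I drops growth to the fermenter's level
(up to the small residual value of the folate/shuttle routes, below 1%),
and the folate analog now alters growth when knocked out — reproducing a
context-dependent screen flag. A consequence worth stating plainly: the
set of growth-altering reactions depends on where Complex I falls in the
cumulative order. The default candidate order (the model's reaction
order, shuttle placements before the respiratory chain before the folate
routes) yields exactly the Complex I + folate-analog pair; under
arbitrary permutations only the Complex I flag is order-invariant, and
the permutation test asserts exactly that.

Because growth rates under Complex I are equal by shadow-price
degeneracy, the proton-stoichiometry scan (4, 2, 0 H+ per NADH)
differentiates final biomass through *yield*: the glucose-minimizing
lexicographic stage makes more-efficient chains consume less glucose per
unit growth, so glucose lasts longer and final biomass is strictly
ordered in protons pumped, while the forced fermentation (the
oxygen-limited ATP shortfall) is strictly decreasing. Setting the
translocation to zero makes Complex I stoichiometrically identical to
NDH-2, and the resulting trajectories coincide exactly with the
Complex I knockout.

**What the fixtures do not emulate.** Genome-scale size (the pair has
about fifty reactions), gene-protein-reaction rules, regulatory effects
(Crabtree switching), oxygen transfer limits, and measured biomass
compositions. Passing the planted-truth tests demonstrates that the
screens recover structural differences a model pair actually contains —
not that any particular organism pair differs this way.

## Screens

The cumulative knockout screen disables candidates in order, reinserting
any knockout that drops growth below the essentiality threshold
(`1e-9` 1/h; the analysis is indifferent to values many orders of
magnitude around this). The growth metric is the stage-1 optimum; the
fermentation metric is the summed ethanol + acetate stage optima of the
full lexicographic solve on the starting medium. A steady-state metric
was chosen as the default over a batch-endpoint metric because it is
deterministic and cheap; an endpoint mode (`dfba_endpoint = TRUE`)
exists for cross-checking. Flagging uses a relative change threshold:
`1e-6` for growth (a single LP optimum, noise-floor limited) and `1e-3`
for fermentation (a fourth-stage quantity that accumulates the fixing
slack of four earlier stages, so its numerical floor is larger). On the
fixture pair the joint shuttle-removal signal is about 0.6% of the
metric, several times the threshold, while single removals sit below
`1e-4` relative.

Reaction identity for model comparison defaults to id matching — the
intended use is same-pipeline reconstructions sharing a universal
namespace — with canonicalized-stoichiometry signature matching as an
opt-in for cross-pipeline comparisons.

`set_proton_stoichiometry()` recognizes the translocated proton pair as
the proton species appearing with opposite signs on the two membrane
sides and rescales only it, leaving the chemical proton of the redox
half-reaction untouched; the reference stoichiometry (4) returns the
model unchanged.

## Chemostat fitting and its validation

`chemostat_growth()` locks each measured exchange inside a relative band
(default ±5%, the measurement-uncertainty allowance; the band is
intersected with the model's own bounds, since a measurement cannot
relax a physiological capacity) and maximizes growth, per protein-pool
level, reporting infeasible levels as `NA`.

The validation design is parameter recovery on synthetic observations.
The generator fixes growth at a dilution rate, solves lexicographically,
and perturbs the measured exchanges with multiplicative noise. The noise
decomposes into a factor shared by all fluxes of one observation (by
default 70% of the variance) plus independent per-flux errors — the
error structure of chemostat specific rates, which are concentrations
divided by the same measured biomass. Fully independent per-flux noise
would routinely make the locked problem infeasible, because exchange
fluxes are stoichiometrically coupled. Noiseless observations are
recovered exactly (band 0). The noisy Monte-Carlo is evaluated near the
respirer's nitrogen-limited ceiling, where the physiological cap
truncates upward errors and the growth fit inherits the noise with
leverage close to one; away from such a ceiling the max-growth estimator
adds the band allowance on top of the full noise and exceeds ±10% more
often, a limitation stated here rather than hidden.

## Ensemble consensus

"Included in at least half" is read inclusively: with an even ensemble
size N, a reaction present in exactly N/2 members is included (a ceiling
rule would differ there, so this is worth making explicit). Bounds of an
included reaction are merged to the widest interval over the members
containing it, preserving every member's feasible space — the merge rule
also covers members that disagree on reversibility. The biomass reaction
is always included. Conflicting stoichiometry under one id is an error,
not silently resolved.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| LP pivot / feasibility tolerance | 1e-9 / 1e-7 | dense double-precision simplex |
| mass-balance acceptance | 1e-6 relative | solver contract, tested |
| `fix_tolerance` (lexicographic) | 1e-6 relative | stage feasibility vs. fidelity |
| ODE tolerances (BDF) | 1e-2 abs and rel | coarse but grid-invariant (tested) |
| output grid | 0.1 h | reporting only |
| essentiality threshold | 1e-9 1/h | any near-machine-zero cutoff works |
| screen flag threshold | 1e-6 (growth), 1e-3 (fermentation) | per-metric noise floors |
| chemostat band | ±5% | measurement allowance |
| maintenance ATP | 1 mmol/gDW/h | yeast-typical; terminates batches |
| ammonium cap | 0.19 mmol/gDW/h | places the two-regime switch |

## Known limitations

The simplex re-solves basis systems densely each iteration; it is sized
for core-scale models (hundreds of reactions), not genome-scale LPs.
Batch oxygen supply is a fixed specific rate, which overestimates
transfer at high biomass. The screens' fermentation metric inherits
lexicographic slack, hence the coarser flag threshold. The
fermenter-vs-respirer growth equality after a Complex I knockout is
approximate (sub-1%), not exact, because the respirer's extra routes
retain small value in the ATP-limited state — the transplant direction
is the exact one. SBML output writes fractional biomass formula
subscripts and charge, which strict FBC validators may flag; the
package's own reader round-trips them exactly.
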