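---
title: "Constraint-based analysis of fish metabolism, growth, and feeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis of fish metabolism, growth, and feeds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaflux)
```

## The model and its assumptions

aquaflux analyzes genome-scale and core metabolic models with flux balance
analysis (FBA). A model is a stoichiometric matrix $S$ (metabolites by
reactions) with flux bounds $l \le v \le u$ and a linear objective, usually
the biomass reaction. FBA assumes a metabolic steady state, $S v = 0$, and
predicts the flux vector that maximizes growth within the bounds. Exchange
reactions move single metabolites across the system boundary with the
convention that negative flux is import and positive flux is export.
Parsimonious FBA (pFBA) resolves the degeneracy of alternative optima by
fixing growth at its FBA optimum and minimizing total absolute flux
$\sum_j |v_j|$, reflecting the assumption that organisms operate their
networks economically.

The LP core is an exact bounded-variable two-phase primal simplex
(`lp_solve()`), which also returns row duals and per-reaction reduced
costs. Reduced costs are reported as $\partial z^* / \partial v_j$ in the
stated optimization sense; they drive the limiting-nutrient analysis. pFBA
is solved exactly by splitting each flux into non-negative forward and
reverse parts rather than by objective-weight heuristics, so the minimized
$L_1$ norm is testable against independent solvers. The L1 minimum is
unique as a value but not as a flux vector; all package results that feed
downstream analyses (objective values, limiting sets, secretion totals)
are invariant across alternative optima, and individual fluxes should not
be over-interpreted.

Numerical choices: the simplex runs at a pivot/optimality tolerance of
1e-9, validation checks (mass balance of returned solutions, limiting
detection, growth-zero classification) use 1e-6, and basic variable values
are recomputed exactly from the factorized basis every 40 iterations and
at termination so that incremental-update drift cannot accumulate into
spurious infeasibility at small flux scales. Degenerate ties in the ratio
test break on the smallest variable index, with a Bland-rule fallback
against cycling.

## The synthetic salmon-like core model

`generate_toy_model()` builds a compact (roughly 80 reactions, three
compartments) model whose ground truth is known by construction, so every
analysis in the package can be exercised and verified offline:

* **Amino acids.** The ten amino acids that are dietarily essential for
  salmonids (Arg, His, Ile, Leu, Lys, Met, Phe, Thr, Trp, Val) have
  uptake and catabolism but no synthesis route; non-essential amino acids
  are synthesized from pyruvate and ammonia at an ATP cost. The defaults
  (10 essential + 8 non-essential) keep the model small; analyses that
  need all 20 amino acids request `n_nonessential_aa = 10`.
* **Energy.** Lumped glycolysis (2 ATP per glucose) plus mitochondrial
  pyruvate oxidation (2.5 O2 and 5 ATP per pyruvate, CO2 out). The
  deliberately modest P:O ratio means surplus feed carbon can be fully
  respired within the oxygen budget, so CO2 and ammonia remain the
  dominant secretions under oxygen limitation, as observed for fish.
  An optional lactate fermentation branch provides oxygen-independent
  carbon disposal and, with glucose, anaerobic growth.
* **Nitrogen.** Ammonia export is free; urea arises only from an
  arginase-style, ATP-costly arginine catabolism whose carbon backbone is
  not tracked. Excess non-arginine nitrogen therefore has no route into
  urea, which makes ammonia secretion structurally irreplaceable — the
  ammoniotelic physiology of fish — while urea secretion remains
  possible.
* **Biomass.** `build_biomass_reaction()` assembles the biomass reaction
  from whole-body macromolecule mass fractions (defaults: protein 0.55,
  lipid 0.30, carbohydrate 0.10, nucleic acid 0.05, a fatty-fish-like
  composition) and per-macromolecule monomer mass fractions; protein uses
  a fish-protein amino-acid profile. Monomer coefficients are mass
  fraction over residue molar mass (free monomer minus water — the paper
  convention chosen here and used consistently), scaled so one unit of
  biomass flux consumes exactly 1 g of precursors per gDW h. Protein
  polymerization is charged 40 mmol ATP per g protein by default; this
  energy cost is a free parameter of the recipe, not a measured value.

The toy network uses simplified "pseudo-elemental" bookkeeping: each
amino acid carries one nitrogen (arginine two), carbon is lumped into
pyruvate equivalents, and full elemental balance is not claimed. What is
guaranteed, and tested, is exact steady-state mass balance $S v = 0$ of
every optimal solution and the 1-g normalization of biomass and feed
pseudo-reactions.

What passing tests on this model do and do not show: they validate the
*methods* (solver correctness against independent oracles, screens
recovering constructed truth, enumeration matching exhaustive search,
monotonicity and calibration properties) on a network whose answers are
known. They do not validate any particular full-genome reconstruction;
real models have far more routes, and quantities like absolute growth
rates or feed efficiencies carry units only relative to the toy's
simplified composition.

## Randomized conditions

`sample_condition()` mirrors uncertainty in environments and enzyme
capacities: feed-nutrient ratios for a minimal feed (essential amino
acids plus choline) are drawn uniformly from [1, 100], and every internal
and transport reaction receives a flux-bound sample per direction with
$\ln b \sim N(0, \sigma^2)$, $\sigma = 2$ by default — the lognormal form
follows from bounds being products of turnover numbers and enzyme
concentrations, both approximately lognormal. Reversible reactions are
sampled separately per direction. One master seed spawns per-condition
child seeds so whole sweeps are reproducible from a single integer.

## The oxygen-limited growth sweep

`run_sweep()` fixes the feed-uptake reaction (coefficients normalized to
1 g of nutrients per unit flux; total feed mass defaults to
100 g gDW$^{-1}$ h$^{-1}$, which is arbitrary but large enough that feed
is never the binding constraint — only relative growth is interpreted),
allows unlimited phosphate, disables all other uptakes and the secretion
of feed nutrients, and solves pFBA across oxygen uptake rates. For each
condition the oxygen reference is computed first: $\mu_{max}$ at
unconstrained oxygen and $r_{max}$, the *minimal* oxygen uptake that
still supports $\mu_{max}$. The grid is logarithmic over three decades up
to and including $r_{max}$; the top point is included deliberately so
relative growth reaches exactly 1 (a half-open grid excluding the top
would leave the curve anchorless). Grid positions are interpreted
relative to each condition's own $r_{max}$ so conditions are comparable.

Because the minimal feed contains no glucose and lactate fermentation
yields no ATP from amino-acid carbon, the sweep is run on the
obligate-aerobe model variant (`include_anaerobic_route = FALSE`):
anaerobic growth on the minimal feed is zero either way, and the variant
avoids parsimonious solutions that dump surplus carbon as lactate merely
because that path is shorter. For feeds that do support anaerobic growth
(e.g. with glucose), `aerobic_correction()` subtracts the zero-oxygen
growth rate and renormalizes, yielding purely aerobic curves.

Infeasible sweep points are recorded with their status and excluded from
means — dropping them silently would bias the bootstrap bands. Bands are
percentile bootstrap over conditions (resampling condition ids with
replacement, 1000 samples by default) at each oxygen level. A reaction is
*limiting* in a solution when its flux sits within 1e-6 of one of its
non-zero bounds; bounds at zero never flag, since a closed reaction is a
modeling choice, not a capacity limit.

Flux clustering follows the convention: absolute pFBA fluxes, normalized
per reaction by the maximum within each condition (all-zero profiles map
to 0), Ward minimum-variance clustering on Euclidean distances
(`hclust` method `ward.D2`, the squared-distance Ward criterion), cut at
a fixed k = 8 by default. Pathway enrichment is a one-sided
hypergeometric test against the model's genes as background with
Benjamini–Hochberg adjustment, computed in-package so analyses are
reproducible offline; recall is the fraction of a pathway's genes found
in a cluster.

## Growth-versus-saturation models

Three forms map water oxygen saturation $x$ (fraction of air saturation)
to relative growth:

* metabolic: $\mu/\mu_{max} = f\!\big(r/r_{max}(x)\big)$ where
  $r/r_{max}$ is a piecewise-linear ramp between the saturations $x_0$
  (zero growth) and $x_1$ (maximal growth) and $f$ linearly interpolates
  model-predicted relative growth against relative oxygen uptake,
  anchored at $f(0)=0$, $f(1)=1$;
* logistic with asymptotes $-1$ and $1$:
  $\mu/\mu_{max} = 2/(1+e^{k(x_0-x)}) - 1$;
* Monod extended with an x-intercept:
  $\mu/\mu_{max} = (x-x_0)/(K_s + x - x_0)$, so $x_0 + K_s$ is the
  half-maximal saturation.

`fit_growth()` uses Levenberg–Marquardt nonlinear least squares with
data-driven starting values ($x_0$: smallest $x$ with growth above 0.05;
$x_1$: smallest $x$ above 0.95; $k = 4/(x_1-x_0)$; $K_s = (x_1-x_0)/2$),
standard errors from the Jacobian-based covariance at the optimum, and
$R^2 = 1 - SS_{res}/SS_{tot}$. Non-convergence is flagged, never
silently papered over. Observations are used unweighted; reproducing
published fits to experimental hypoxia studies requires the digitized
observations from those studies, which the package accepts as a CSV but
does not ship.

## Limiting amino acids in feeds

The bundled composition table gives the mass percentage of each amino
acid relative to total amino-acid mass for fish meal, soybean meal, and
insect (black soldier fly larvae) meal. Entries combined in feed
formulation (Asn/Asp, Gln/Glu) are split equally. `build_feed_reaction()`
turns a composition into a boundary reaction supplying amino acids in
feed proportions, scaled to 1 g per unit flux. Free amino-acid molar
masses are used for feed mass accounting (compositions are measured on
hydrolysates).

With growth fixed at an arbitrary rate (default 1 — only relative
quantities matter, and the package tests that limitation *order* is
invariant to this choice), glucose uptake unlimited (so limitation
reflects protein synthesis rather than energy), other amino-acid imports
disabled and surplus export open, the package minimizes total consumed
mass and multiplies each amino-acid exchange reaction's reduced cost by
its molar mass; the largest negative mass-weighted value marks the
limiting amino acid. Because reduced costs at degenerate optima can point
along blocked directions, each candidate is confirmed (best first) by
re-solving with a small unpenalized import before being reported; if no
candidate yields a real saving the result is "none limiting".
`supplement_iteratively()` opens the limiting amino acid's import,
penalizes it in the objective at its molar mass (cost parity with feed
mass; a higher penalty is available via `penalty_factor`), and repeats
until no limitation remains, recording feed efficiency (gDW biomass per
g consumed, and its inverse in mg/gDW) at every step. Reduced costs at
later iterations are taken from the current penalized objective.

## Capability screening and minimal sets

`essentiality_screen()` disables each nutrient's uptake separately and
classifies it essential when FBA growth falls below 1e-6 (the numeric
reading of "required for growth"). `evaluate_task()` closes all
exchanges, opens a task's required uptakes and minimum secretions
(metabolites from compartments absent from the model are remapped to the
cytosol; a rate of 0 marks an allowed but unforced output), and tests
steady-state feasibility. `minimal_uptake_sets()` and
`minimal_secretion_sets()` enumerate support-minimal growth-supporting
sets with an indicator-variable MILP (branch and bound over the LP core)
plus exclusion cuts, then explicitly verify support-minimality of every
set by single-removal feasibility checks — minimality here means set
inclusion, not merely cardinality. Uptake sets are enumerated first; the
union of their metabolites is then allowed as uptake when enumerating
secretion sets. Default requirement thresholds (growth at least 1,
forced secretions at least 1e-3) are package choices, documented here,
not literature values.

## Model comparison

`reaction_matrix()` restricts to intracellular metabolic reactions in
compartments shared by all models and records binary presence.
Sixteen dissimilarity measures on binary profiles (Jaccard, Dice,
matching, Rogers–Tanimoto, Sokal–Sneath, Russell–Rao, Yule, Kulsinski,
Euclidean, squared Euclidean, city-block, Chebyshev, Canberra,
Bray–Curtis, cosine, correlation) times five linkages (single, complete,
average, weighted/McQuitty, Ward as ward.D2) give an 80-tree sweep;
`clade_support()` reports the fraction of trees in which a model group
forms a clade. Note that Russell–Rao and Kulsinski are not semimetrics —
identical profiles need not be at distance zero — which is why planted
identical pairs are only guaranteed full support when neither pair's
reaction set nests inside the other's. The cophenetic correlation
coefficient is computed from the centered cross-product sums of the
strict upper triangles of the input dissimilarities and the merge-height
distances; by default it correlates the dendrogram against the same
dissimilarity that built it (pass Euclidean distances explicitly for the
literal Euclidean reading). Degenerate variance raises an error rather
than propagating NaN. Ward rescales merge heights by cluster size, so
only the four combinatorial linkages reproduce an ultrametric input
exactly.

## Problem sizes and reproducibility

The test-suite and acceptance-script simulation sizes are chosen as the
package's own desk-scale study conditions: a 100-condition by 20-level
sweep for the monotonicity and secretion-dominance checks in the tests, a
40-condition by 12-level sweep plus 10-condition limiting-reaction union
in the acceptance script, 1000 bootstrap samples, 50 random feeds for
the limiting-amino-acid oracle comparison, and 200–500 replicates for
the noise-calibration of the growth fits. All randomness flows from a
single seed through per-condition child seeds.

## Known limitations

The toy model is a caricature: lumped energy metabolism, one-step amino
acid synthesis and catabolism, pseudo-elemental bookkeeping, and no
vitamin, glycan, or detailed lipid chemistry. The dense-matrix simplex
targets models up to a few hundred reactions; genome-scale models with
thousands of reactions would need a sparse LP backend. Minimal-set
enumeration is exponential in the worst case and intended for boundary
sets of a few dozen metabolites. Pathway enrichment requires
user-supplied pathway-to-gene maps; no external annotation service is
consulted.
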