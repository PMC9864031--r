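---
title: "Constraint-based modelling of medulloblastoma versus healthy cerebellum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling of medulloblastoma versus healthy cerebellum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbgem)
```

## The model and its assumptions

`mbgem` analyses genome-scale metabolic models (GEMs) of cerebellar tissue
in two states - healthy and medulloblastoma (MB) - under the steady-state
assumption of constraint-based modelling: for a stoichiometric matrix $S$
(metabolites $\times$ reactions) every admissible flux vector $v$
(mmol/gDW/h) satisfies

$$ S\,v = 0, \qquad lb \le v \le ub. $$

The tissue is modelled as two coupled cell compartments, neurons (metabolite
tag `N`) and astrocytes (tag `A`), sharing an extracellular cerebellum pool
(tag `C`). Nutrient uptake bounds are tissue-level magnitudes split
multiplicatively between the cells by the cerebellar cell-type proportions,
97% neurons / 3% astrocytes. The default context bounds carried by
`scenario_config()` are glucose 0.852, glutamine 0.080, oxygen 0.142,
leucine 0.034 (the glucose bound divided by the 25-fold glucose:leucine
uptake ratio), tryptophan 0.0074, tyrosine 0.0028, methionine 0.008, and
zero for glycogen and ketone bodies, all in mmol/gDW/h.

Reaction availability is controlled by boolean gene-protein-reaction (GPR)
rules over `and`/`or`; a gene deletion disables exactly the reactions whose
rule evaluates inactive. Growth is a biomass pseudo-reaction draining
precursors in fixed proportions.

### Solving: FBA, the canonical solution, and MOMA

Flux balance analysis (`fba()`) maximizes an objective (biomass by default;
gross ATP production or lactate excretion for the alternative screens) over
the flux polytope. Linear programs are solved by a bounded-variable
two-phase revised simplex written for this package (dense arithmetic;
Dantzig pricing with a Bland's-rule fallback after runs of degenerate
pivots; basis refactorization every 60 iterations; optimality and
feasibility tolerances $10^{-9}$). Because FBA optima are typically
degenerate, the reported flux vector is canonicalized: a quadratic polish
returns the *minimum-norm* point of the optimal face, so downstream numbers
do not depend on pivot order.

Minimization of metabolic adjustment (`moma()`) finds the flux state of a
perturbed model closest in Euclidean distance
$D(h, m) = \sqrt{\sum_i (h_i - m_i)^2}$ to a reference state $h$, via a dual
active-set quadratic program (feasibility tolerance $10^{-9}$). Reactions
absent from the reference (cross-model comparisons) do not enter the
distance; a vanishing ridge ($10^{-9}$) on unreferenced fluxes keeps the
program strictly convex.

The package pairs the two methods the way the analysis intends: FBA first
determines the attainable objective of the perturbed model, and MOMA then
selects, *among states achieving that objective*, the one closest to the
reference (`fix_objective` in `moma()`). This matters: the unconstrained
adjustment is free to trade growth for flux similarity, and on the packaged
MB model it zeroes biomass under glutamine deprivation even though the
deprived model can grow at the baseline rate. The scenario runner
(`scenario_run()`) and the deletion screens therefore report values from
the objective-constrained adjustment, while `moma()` itself defaults to the
classic unconstrained operation.

### Energy accounting

`energy_accounting()` attributes gross ATP production to pathways through
the `atp_yield` annotation (the stoichiometric coefficient of the ATP
species): a pathway's production is $\sum \max(0, \text{yield}\times v)$
over its reactions, so only reactions running in their producing direction
count. Two Warburg-effect indicators are derived: ATPG/ATPOP, the ratio of
glycolytic to oxidative ATP production, and LacR/OCR, the ratio of lactate
excretion to oxygen uptake. Which reactions count as "energy generation" is
not canonical; yield-annotation is the package's operationalization, and a
zero OXPHOS denominator is reported as `Inf` rather than an error.

### Transcriptome integration (GIMME)

`binarize_expression()` classifies each gene Present/Absent against a
single threshold: a configurable fraction of the grand mean of per-gene
mean expression in the condition (linear scale). Ties are Present - the
conservative choice, since Present genes keep reactions in the model. The
fractions used for the emulated expression series are shipped as
`gimme_threshold_presets` (e.g. 0.723 for the MB series, 0.725/0.747/
0.9024/0.7634 for the WNT/SHH/GR3/GR4 subgroups, 0.30 and 0.45/0.50/0.55
for the other two series).

`gimme_reduce()` implements the classic GIMME program: reactions whose GPR
is inactive under the Absent genes are penalized, and an LP minimizes total
penalized absolute flux subject to retaining a required fraction of the FBA
growth optimum (`growth_fraction`, default 0.9 - the GIMME literature
default; the analysis source does not state one). Penalty weights are
uniform: no expression-distance weighting is defined for the binarized
calls. A penalized reaction is removed when it carries no flux at the
optimum *and* cannot carry flux anywhere in the penalty-optimal,
growth-feasible space (a flux-variability check with the inconsistency
objective pinned at its optimum). Without pinning the penalty, an optional
low-expression branch always retains capacity and nothing would ever be
removed.

### Flux sampling (ACHR) and differential flux

`achr_sample()` draws flux profiles with an artificially-centered
hit-and-run chain. Warmup points are the $2n$ flux-variability vertices
(per-reaction min/max LPs); directions are differences between a randomly
chosen stored point (warmup plus accepted samples) and the running center,
which adapts proposals to the elongated geometry of flux polytopes. Two
reparametrizations keep the chain honest:

* coordinates whose realized flux span is zero (blocked reactions, forced
  uptakes) are frozen and removed from the walk - otherwise rescaling
  amplifies rounding noise on them into direction components that collapse
  every chord;
* the remaining coordinates are whitened by their flux-variability span, so
  the polytope has comparable extents in every direction. Without this the
  chain mixes so slowly that two seeds give detectably different means even
  at 1,000 steps per sample.

The iterate is re-projected onto the affine slice $\{S v = b\}$ every 25
steps and at every record, so mass balance cannot drift ($\|Sv\|_\infty$
stays below $10^{-6}$ over 10,000 profiles, typically near $10^{-12}$).
Defaults: thinning 100 steps per recorded sample, box cap $10^3$ on
unbounded directions, and a single root seed controlling warmup and chain.
With these settings the recorded samples are nearly independent (lag-1
autocorrelation around 0.01 on the packaged model), which is what makes the
two-seed null comparison below meaningful.

`differential_flux_test()` applies Welch's unequal-variance t-test to the
per-reaction sampled flux distributions of two models, restricted to their
shared reaction set, with Benjamini-Hochberg correction at
$\alpha = 0.05$. Degenerate columns (zero variance, equal means) get
$p = 1$ by convention.

### Regulation classification (ZF/ZG)

The exact score formulas used by the source analysis are not printed; the
package implements standardized mean differences.
`compute_z_scores()` sets
$ZF = (\bar v_B - \bar v_A)/\sqrt{s_A^2 + s_B^2}$ from the sampled flux
distributions, and per-gene $ZG$ as the Welch-type standardized difference
of expression between the two conditions' sample groups.
A reaction's $ZG_{total}$ *sums* the scores of all genes in its GPR - the
stated convention, even though it inflates magnitude for large rules; a
mean-normalized variant sits behind `zg_aggregate = "mean"`. Expression
enters on the linear scale by default with a `log2` option, since the
original scale is unstated. Classification at the two-sided 5% critical
value 1.96: reactions with $|ZF| > z_{crit}$ are flux-altered; those also
showing $|ZG_{total}| > z_{crit}$ are transcriptionally regulated (TR), the
rest not transcriptionally regulated (NTR). Sign concordance between ZF and
ZG is recorded but *not* required for TR - discordant pairs are
biologically meaningful (post-transcriptional control) and are left in.

### Flux coupling

Coupling is a property of the steady-state cone
$\{v : Sv = 0, v \ge 0\text{ in irreversible form}\}$, not of the finite
bounds; reversible reactions are split first and results are mapped back to
original identifiers with the strongest class among split variants. For a
pair, two LPs per orientation compute the extremes of $v_i$ with $v_j$
normalized to 1 (box cap $10^3$ as the proxy for infinity); classes follow
the standard taxonomy (fully, partially, directionally, uncoupled, blocked)
with tolerance $10^{-6}$ on the equality of ratio extremes. Since the
"directly coupled to growth" phrasing of the source is ambiguous between
fully and directionally coupled, `biomass_coupled_set()` reports every
class and the summary counts both.

### Deletion screens

`single_deletion()` removes genes or reactions one at a time; the knockout
value comes from the FBA-then-MOMA pairing above, an infeasible knockout
scores zero, and a target is essential when the reduction fraction strictly
exceeds 0.40 ("more than 40%" - the source also contains a "less than"
phrasing once, but its methods and results sections consistently use the
more-than reading, which is implemented). The same strict cutoff serves all
three objectives (biomass, ATP, lactate).

`double_deletion_synthetic_lethals()` excludes single-essential genes
first (the screening rule of the analysis), then tests all remaining
unordered pairs; deletion outcomes are cached by the disabled reaction set,
which collapses the many gene pairs that disable identical reactions.

`common_essential_screen()` intersects the essential sets of the three
objectives on the MB model and re-tests survivors on the healthy model. The
source quantifies the healthy side only as "minimum toxic effects"; the
package operationalizes safety symmetrically with the disease criterion: a
candidate must reduce neither healthy biomass nor healthy ATP production by
more than 0.40 (configurable). Checking ATP alongside biomass matters: a
glycolysis knockout can leave healthy growth intact while collapsing
healthy energy production.

### Antimetabolite screen

Fingerprints are hashed circular substructures (extended-connectivity,
radius 2) computed through Open Babel and folded to 2048 bits; path-based
FP2 and MACCS keys are available alternates. The fingerprint family behind
the published similarity values is unstated and Tanimoto scores are
family-dependent, so no published similarity value is asserted anywhere -
only the $> 0.90$ gate is fixed. `competitive_inhibition_screen()` then
simulates inhibition of the enzymes consuming each annotated metabolite:
the bound nearest each consuming reaction's baseline flux is lowered to 0.1
times that flux (toward zero, for either sign) in both models, and growth
reductions are re-scored with the same FBA+MOMA pairing. Reactions with
zero baseline flux are left untouched - scaling zero would be a full
knockout and overstate inhibition. Ubiquitous cofactors (ATP, NAD(P)H,
water, ...) are excluded through a configurable stop-list; without it every
screen hits energy metabolism. A hit requires all three gates: Tanimoto
$> 0.90$, disease growth reduction $> 0.40$, and healthy safety.

## The synthetic study system

The genuine MB reconstruction (753 reactions, 601 genes) is not published
as data, so the package ships a generator (`generate_toy_models()`) for a
small but topologically faithful two-cell cerebellum model: 65 reactions,
52 metabolites, 26 genes across glycolysis, PPP, lumped TCA, OXPHOS, the
glutamine/glutamate/GABA system, taurine, glycogen, fatty-acid, mevalonate/
cholesterol, sphingolipid/ganglioside and cardiolipin pathways, with real
branch points, isoenzymes and per-cell compartment copies. Stoichiometry is
lumped (e.g. glycolysis is one reaction yielding 2 pyruvate + 2 NADH +
2 ATP per glucose) and biomass uses uniform placeholder precursor demands,
since cerebellar composition coefficients are not printed.

The healthy and MB variants share every identifier and differ only in
bounds, which is what the designed disease phenotype rests on:

* MB forces avid glucose and glutamine uptake (exchange lower bound =
  upper bound), the metabolic signature PET imaging shows in tumors;
* MB caps OXPHOS capacity (mitochondrial impairment), so the NADH produced
  by forced glycolysis must be re-oxidized by lactate dehydrogenase -
  lactate excretion at least twice the glucose uptake is then a
  *stoichiometric necessity*, not an objective choice;
* the healthy variant instead carries a small ATP maintenance demand that
  keeps its oxidative machinery active.

Growth is tyrosine-limited (the tightest context bound), which makes the
biomass optimum independent of glutamine - glutamine deprivation leaves
growth unchanged while glucose deprivation abolishes it, as designed.

The generator's ground-truth report lists what was planted and therefore
what every screen must find: 17 biomass-essential genes; two isoenzyme
synthetic-lethal pairs (HK1/HK2 on glycolysis, LDHA/LDHB on lactate
dehydrogenase); three Absent-only prunable side branches (GABA shunt,
taurine synthesis, glycogen synthesis - one controlling gene each, two cell
compartments, hence six removable reactions); and the glutamine-addiction
genes GLS and GLUD1 as the pan-essential but healthy-dispensable drug
targets (forced glutamine uptake makes their loss lethal to MB under every
objective, while the healthy model simply stops importing glutamine). The
antimetabolite ground truth is a compound table fixture
(`inst/extdata/compounds_synthetic.tsv`) whose synthetic glutamine mimic is
the only compound passing the similarity gate against a metabolite whose
inhibition is MB-lethal and healthy-safe; meglutol and phytosphingosine are
present as realistic near-miss analogs and aspirin/caffeine as decoys.

`generate_expression_series()` emulates the series-matrix expression data:
lognormal baselines (listed genes at mean 300, filler genes drawn from a
broad lognormal), planted fold changes (4-fold up for a regulated gene set,
0.05 for the Absent branches), multiplicative lognormal replicate noise
(sdlog 0.3), ten samples per condition, fully seed-reproducible. With these
defaults the planted Absent genes sit several noise standard deviations
below the binarization threshold, so recovery is reliable across seeds.

What the generator does *not* emulate: microarray probe structure and
platform annotation, realistic expression value distributions beyond the
lognormal, thermodynamics, kinetic regulation, and the actual reaction
inventory of the published reconstruction. Passing the packaged tests
demonstrates that the machinery recovers planted truth under the designed
conditions - it says nothing about reproducing the published headline
counts, which depend on the unpublished 753-reaction model.

## Numerical choices and degenerate inputs

* LP: hand-written bounded simplex (no functioning LP solver exists among
  the available dependencies); validated in the test suite against
  exhaustive vertex enumeration on small networks. Infinite bounds are not
  accepted by the kernel; callers cap boxes (sampler: $10^3$).
* QP: dual active-set method with equality rows reduced to a full-rank set
  first; bound constraints are relaxed by $10^{-9}$ and solutions clamped
  back, which sidesteps spurious "inconsistent constraints" failures on
  degenerate active sets.
* Alternate optima: min-norm canonicalization after every FBA; deletion
  caching keyed by disabled-reaction sets; ties at the binarization
  threshold resolved to Present; the sampler freezes zero-span coordinates.
* Degenerate statistics: zero pooled variance gives $ZF = 0$ and $p = 1$;
  empty fingerprints are an error, never a silent similarity of 1; a
  metabolite nothing consumes yields no inhibition targets and cannot be a
  hit.

## Problem sizes

The shipped analyses run on the 65-reaction fixture: unit tests sample a
few hundred to a few thousand profiles; the end-to-end acceptance run uses
the full 10,000 ACHR profiles per model, a 5,000-profile two-seed null
comparison, all 26 single gene deletions under three objectives, 36 double
deletions, and the complete coupling and antimetabolite screens. The whole
acceptance computation completes in well under a minute on one core.

## Worked example

```{r example, eval = FALSE}
library(mbgem)

tm <- generate_toy_models()
cfg <- scenario_config()

fm <- fba(tm$mb, config = cfg)
acct <- energy_accounting(tm$mb, fm)
c(biomass = unname(fm$fluxes["BIOMASS"]),
  lac_over_glc = unname(fm$fluxes["EX_lac_C"]) /
    sum(fm$fluxes[c("EX_glc_N", "EX_glc_A")]),
  atpg_over_atpop = acct$atpg_over_atpop)

screen <- common_essential_screen(tm$mb, tm$healthy, cfg)
screen$gene[screen$candidate]
```

## Known limitations

* The toy model's lumped stoichiometry makes absolute flux values
  interpretable only relative to each other; units are carried but the
  biomass rate is not a literal cerebellar growth rate.
* ACHR provides a mean-drift warning but no formal convergence diagnostic;
  strongly anisotropic user models beyond the whitening's reach may still
  mix slowly.
* The simplex is dense; models beyond a few thousand reactions would need a
  sparse kernel.
* SBML support targets Level 3 FBC bounds and gene associations; kinetic
  laws and rules are ignored with a warning.
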