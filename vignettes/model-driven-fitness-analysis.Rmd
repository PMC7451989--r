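---
title: "Model-driven analysis of pooled mutant fitness data"
author: "fluxfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven analysis of pooled mutant fitness data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxfit)
```

# The problem

Pooled barcoded transposon mutant libraries measure, for each gene, a
*fitness score*: the average log2 change in abundance of that gene's
mutant over a pooled growth experiment. Strongly negative scores mean
the mutant failed to grow. A genome-scale metabolic model predicts,
for the same genes, whether their deletion abolishes growth *in
silico*. `fluxfit` confronts the two: it finds where the model is wrong
(false predictions worth investigating), and uses the correlation
structure of the fitness data across hundreds of experiments to
validate metabolic modules and to propose genes for reactions that
lack a gene assignment.

The package implements five connected analyses:

1. **Essentiality prediction** — flux balance analysis (FBA) with gene
   deletions applied through gene–protein–reaction (GPR) boolean logic.
2. **Phenotype classification and confusion analysis** — binarising
   fitness scores at a cutoff, choosing the cutoff that minimises the
   total disagreement with model predictions, and testing the
   association with a chi-squared test.
3. **Flux coupling analysis (FCA)** — partitioning the network into
   modules of reactions forced to carry flux together.
4. **Cofitness analysis** — Pearson correlation of fitness profiles,
   averaged within modules and calibrated against a resampling null;
   candidate genes for orphan reactions are ranked by mean cofitness
   with the module.
5. **Network diagnosis** — minimal-additions gap filling (MILP),
   steady-state diagnosis of imbalanced metabolite nodes, and
   conditional-essentiality host designs for selection-based gene
   discovery.

# Models and the constraint-based core

A model is a stoichiometric matrix $S$ (metabolites × reactions), flux
bounds $l \le v \le u$ in mmol/gDW/h, and GPR boolean trees (`and` =
complex subunits, `or` = isozymes). FBA solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

with $c$ selecting the biomass reaction; the optimum is the growth
rate in 1/h. Flux variability analysis (FVA) then reports each
reaction's attainable flux range with the objective held at a fraction
of its optimum (1.0 by default — variability *at* the optimal growth
rate). A gene is called essential when the maximal biomass flux after
deleting it is zero; "zero" means below $10^{-9}$ 1/h, a numeric floor
for the binary growth/no-growth rule. Infeasibility (no steady state at
all, as when a secretion route is missing) also counts as no growth.

All linear programs are solved by an internal two-phase
bounded-variable primal simplex with an explicitly maintained basis
inverse (eta updates, periodic refactorisation, Bland's-rule fallback
against cycling). The problems in this package are small and dense —
tens to hundreds of variables — and the solver is validated in the test
suite against brute-force vertex enumeration on randomly generated
programs. Gap filling minimises the *number* of activated candidate
reactions subject to a growth threshold; the binaries are handled by
depth-first branch and bound over the LP relaxation and verified
against exhaustive subset enumeration. Determinism: identical inputs
give identical solutions; no randomised pivoting is used.

Two model dialects are supported: SBML Level 3 with the `fbc` package,
and a tabular dialect (a reactions TSV with human-readable equation
strings, a metabolites TSV, and a key/value TSV for biomass /
maintenance bookkeeping). Mass and charge balance can be audited with
`checkBalance()`; proton/water imbalances are reported, never
auto-corrected.

Media are sets of exchange-reaction bounds; uptake is a negative lower
bound. `applyMedium()` closes every unlisted uptake and opens all
secretion to 1000 mmol/gDW/h, so any extracellular compound may leave
the cell. Non-growth-associated maintenance (NGAM, mmol ATP/gDW/h) is
the lower bound of the ATP maintenance reaction; growth-associated
maintenance (GAM, mmol ATP/gDW) lives inside the biomass equation.

# Phenotype classification and the error-minimising cutoff

A mutant "grows" when its fitness score is strictly above a cutoff
$c$; with replicate experiments, a gene is `Growth` if all available
replicates are above $c$, `NoGrowth` if all are at or below it,
`Inconsistent` when replicates disagree, `Unavailable` when no scores
exist. Crossing these calls with model predictions gives the confusion
cells GG, GNG, NGG, NGNG (prediction first, experiment second), with
inconsistent and unavailable genes tallied separately and excluded
from agreement statistics.

`errorCurve()` scans $c$ over a grid (default $-3$ to $0$ in steps of
0.01, bracketing the operating range of log2 fitness cutoffs) and
selects the $c$ minimising the total error — false-positive fraction
plus false-negative fraction over consistently classified genes. Ties
are resolved toward the most negative cutoff, the conservative choice
that calls more mutants "growing". On well-separated bimodal data the
error is zero on a plateau and the tie-break selects the plateau's
most negative edge. Association between predictions and phenotypes is
tested with Pearson's chi-squared on the 2×2 consistent-cell table, one
degree of freedom, no continuity correction.

# Flux coupling analysis

Coupling is computed on *directional components*: each reversible
reaction is split into non-negative forward and reverse parts (the
reverse part has negated stoichiometry). For components $i, j$, the
extremes of the flux ratio $v_i / v_j$ over the steady-state cone
$\{S v = 0,\ v \ge 0\}$ decide the pair's class:

* **fully coupled** — $R_{\min} = R_{\max} > 0$ (fixed ratio);
* **partially coupled** — $0 < R_{\min} < R_{\max} < \infty$;
* **directionally coupled** — activity of one forces the other
  ($R_{\min} = 0$ with finite $R_{\max}$, or $R_{\min} > 0$ with
  $R_{\max} = \infty$);
* **uncoupled** — otherwise.

The extremes are two LPs after normalising $v_j = 1$, valid because
components are non-negative and ratios are scale-invariant; flux caps
are irrelevant on the cone since every ray scales into the capped
polytope. Ratio equality and zero use a relative tolerance of
$10^{-6}$, matched to LP numerics. An unbounded maximum is reported as
`Inf`. Blocked components (maximal flux zero on the opened network) are
removed first by an iterative max-sum prefilter.

`couplingAll()` exploits transitivity: full coupling is an equivalence
relation, so each component is tested against one representative per
existing class. Fully coupled modules are the classes of size ≥ 2.
Partially coupled modules are maximal groups connected by partial
edges (tested between class representatives — partial coupling is
class-invariant) that contain at least one partially coupled pair;
directional couplings are computed but do not form modules.

**Sink protocol.** Before coupling analysis the model is prepared with
`couplingModel()`: every exchange is opened to $[-1000, 1000]$ (a full
in-silico medium), one sink reaction is added per biomass precursor
(and per configured terminal product), and the aggregate biomass
reaction is retired. Without sinks, every precursor pathway is forced
through the single biomass equation and the analysis returns one large
biomass-coupled module; per-precursor sinks let each biosynthetic
pathway couple to its own end product instead. Retiring biomass is
what makes the chain→sink coupling exact — with the aggregate demand
still active, the last pathway step would split its flux between sink
and biomass and only partial couplings would remain. The sink list is
configurable; module counts on real models are sensitive to it.

Module genes are the union of GPR genes over member reactions,
excluding reactions without a GPR (orphans) and genes under a
top-level OR (isozymes — their mutants' phenotypes are masked by the
alternative enzyme). Condition-dependent coupling recomputes the
partition under extra constraints (e.g. closing the oxygen exchange)
and reports components newly fully coupled into each baseline module;
tightening constraints can only shrink the cone, so couplings are
gained, never lost — components the condition *blocks* outright are
reported as unavailable rather than uncoupled.

# Cofitness and the resampling null

Cofitness of two genes is the Pearson correlation of their fitness
vectors across experiments, on pairwise-complete observations. Pairs
with fewer than 10 overlapping experiments are undefined (small
overlaps give unstable correlations), as are pairs involving a
zero-variance profile. A module's average cofitness is the mean over
all $\binom{k}{2}$ gene pairs.

Significance is calibrated by resampling: draw $k$ genes (without
replacement) from a pool — by default the model's genes present in the
fitness data — compute the average cofitness, repeat (100,000 draws in
the reference analysis; 10,000 reproduces thresholds within about
0.01), and take the 95th percentile as the threshold $\tau_k$.
Percentiles interpolate linearly between order statistics
(`quantile()` type 7) so that $\tau_k$ is exactly reproducible given
the seed. A module is significant when its average is strictly above
$\tau_k$. $\tau_k$ decreases with $k$ on null data: averaging more
pairs shrinks the upper tail.

Candidate genes for a module containing an orphan reaction are ranked
by mean cofitness with the module's known genes, missing pairs dropped
from the mean, ties broken by locus tag for determinism. Low-cofitness
members within a module (`outlierGenes()`) flag polar effects,
mixed-genotype mutants and mis-mapped barcodes.

# Node diagnosis and gap filling

Some metabolite nodes are imbalanced by construction: reactions whose
products feed nucleotide or amino-acid demands run at a fixed ratio to
biomass, and the remaining free reactions must absorb the difference.
`fumarateNodeReport()` makes this operational: it adds virtual
source/sink reactions for the node metabolite (relaxing the node's own
balance), fixes growth, and scans variability — reactions still
flux-determined are locked to biomass by demands *elsewhere*, while
reactions whose determination came only from closing the node's
balance become free. Without the relaxation a sole free consumer would
be misclassified as locked. The report gives the net locked production
the free reactions must carry. If deleting the only free consumer
leaves the network infeasible, `minAdditionsGapfill()` with a pool of
secretion reactions finds the minimal repair (e.g. a single fumarate
secretion route); its growth threshold, $10^{-3}$ 1/h, is strictly
positive but small — what is certified is feasibility restoration, not
a particular growth rate.

`megsDesign()` searches gene-knockout sets (exhaustive up to 2 by
default — verifiable at desk scale) crossed with a media catalog for
host/medium pairs under which a target reaction becomes conditionally
essential: the host grows, and disabling the target abolishes growth.
Such designs turn gene discovery into a growth selection.

# The synthetic-data generator

`makeToyModel()` plants known structure: linear pathways (one gene per
reaction) feeding per-pathway biomass precursors from a shared hub or
private substrates, optional orphan reactions (no GPR, with a hidden
true gene) and isozyme reactions (OR of two genes). The expected fully
coupled modules under the sink protocol are recorded as ground truth.
Generated models are growth-feasible by construction.

`simulateFitness()` emulates the statistical structure of pooled
Bar-seq fitness data:

* per experiment, each pathway module is essential with probability
  0.3 (conditions vary which pathways matter);
* genes of an essential module draw scores from
  $\mathcal N(-4, 0.5)$ — a strong log2 defect — others from
  $\mathcal N(0, 0.3)$; per-gene measurement noise
  $\mathcal N(0, 0.2)$ is added on top, giving the bimodal
  score distribution characteristic of real datasets;
* isozyme genes are never essential (the partner covers the loss);
* 5% of mutants carry **mixed genotypes** (wild-type plus disrupted
  copies, as expected in a polyploid host): their phenotype signal is
  multiplied by 0.2 *before* noise — attenuation shrinks the biology,
  not the measurement error (a constant rescaling of the whole row
  would be invisible to correlation);
* 1% of mutants are **mis-mapped** and inherit another random gene's
  trajectory — the rarest corruption mode in sequence-verified
  barcoded libraries;
* 5% of mutants are **missing** from the matrix (genes essential in
  the rich medium used to build the library have no mutant);
* planted orphan genes are exempt from the mis-mapping and missing
  draws: they are the recovery targets, and the ground truth asserts
  they are present and correctly mapped (they remain eligible for
  mixed-genotype attenuation);
* experiments are flagged anaerobic with probability 0.25, supporting
  condition-subset analyses.

Everything is bit-reproducible given the seed.

What the generator does *not* emulate: read-level barcode counting
noise (scores are drawn directly), batch effects and experiment-level
correlations, cross-feeding between mutants in the pool, polar effects
of insertions on downstream genes, and media-specific essentiality
structure beyond the per-module Bernoulli switch. Passing recovery
tests on synthetic data therefore demonstrates the statistical
machinery — not that any particular real dataset satisfies these
assumptions.

# Problem sizes used by the automated checks

The test suite and acceptance script run entirely on generated data,
at sizes chosen to exercise the mathematics while staying desk-scale:
random networks of at most 12 components for oracle comparisons (50
networks), 5-pathway planted networks for module recovery (20
layouts), 200 genes × 100 experiments for cofitness recovery (100
replicates; null thresholds at 10,000 resamples), and candidate pools
of at most 12 reactions for gap-fill minimality (50 instances, checked
against exhaustive enumeration). Reproduction of the published
genome-scale summary statistics requires the externally distributed
supplementary model file and runs only when that file is supplied
under `inst/extdata/iZM4_478.xml`.

# Known limitations

* The simplex core is dense and refactorises small bases; it is built
  for correctness at toy-to-moderate scale, not for genome-scale FVA
  in tight loops (a genome-scale essentiality screen is minutes, not
  seconds).
* Partial-module composition (but not full-module composition) can
  depend on the configured sink list; reproducing a published module
  *count* exactly requires the same sink configuration.
* The tabular dialect requires whitespace-separated equation terms
  (`"a_c + b_c -> c_c"`), and SBML ids containing characters outside
  `[A-Za-z0-9_]` are mangled on export.
* Gap filling weights all candidates equally (cardinality, not
  plausibility); ranking among equal-size fills is not defined.

# A worked toy example

```{r example}
toy <- makeToyModel(nPathways = 3, pathwayLength = 3,
                    orphanAt = data.frame(pathway = 2, position = 2))
sim <- simulateFitness(toy, nGenes = 60, nExperiments = 60, seed = 1)
cof <- cofitness(sim$fitness)
known <- setdiff(sim$truth$moduleGenes[[2]], sim$truth$orphans$gene)
head(rankCandidates(cof, intersect(known, rownames(cof$r))), 3)
```

The planted orphan gene should head the ranking, exactly as a real
orphan-reaction gene is expected to correlate with the rest of its
pathway.
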