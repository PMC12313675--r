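---
title: "Quantifying microbial succession under heavy-metal stress: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial succession under heavy-metal stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`succ` implements the quantitative machinery used to characterise microbial
community succession along heavy-metal pollution gradients, of the kind
studied in mine-tailings primary succession: pollution indices on soil metal
concentrations, diversity and permutation statistics, thresholded
co-occurrence networks with a composite complexity score and cohesion, and
phylogenetic null models that partition community assembly into deterministic
and stochastic processes.  This vignette explains each model, the tunable
parameters, and the design decisions taken where the methodology is genuinely
open.

## Heavy-metal pollution indices

Three standard indices summarise soil contamination from a sample-by-metal
concentration table (mg/kg):

* **Geo-accumulation index**, $I_{geo} = \log_2\!\big(C_n / (1.5\,B_n)\big)$,
  where $C_n$ is the measured concentration and $B_n$ a geochemical
  background value; the factor 1.5 absorbs natural background fluctuation.
  $I_{geo} > 0$ flags anthropogenic enrichment.
* **Single pollution index**, $PI = C_i / S_i$, the concentration relative to
  an environmental-quality screening value $S_i$ (for Chinese agricultural
  soils, GB 15618-2018 risk screening values).
* **Nemerow integrated pollution index**,
  $NIPI = \sqrt{(PI_{ave}^2 + PI_{max}^2)/2}$, a per-sample composite that
  up-weights the single worst metal.  The max term guarantees
  $NIPI \ge PI_{max}/\sqrt 2$, so one badly contaminated metal cannot be
  averaged away.

NIPI is computed **per sample** and then summarised per group; computing it
from per-metal group means is not equivalent (the maximum does not commute
with averaging) and generally disagrees with per-sample computation.
Background and screening values are user-supplied tables;
`default_metal_references()` ships Chinese soil background means and the
published GB 15618-2018 screening values for Cu, Zn, Cd and Pb.  GB
15618-2018 publishes no screening values for Fe, Mn or Al, so the defaults
used by the simulator for those metals are synthetic placeholders flagged in
the `synthetic` column; replace them for real data.

Group contrasts use Welch's *t*-test by default (the pooled test is a flag),
with Benjamini–Hochberg adjustment across whichever family of indices is
tested together.

## Diversity and permutation statistics

Alpha diversity reports richness, Shannon entropy (nats), Pielou evenness
($H/\ln S$, defined as 0 when $S \le 1$), and Chao1 in its bias-corrected
form $S + F_1(F_1-1) / (2(F_2+1))$ so that zero doubletons remain
well-defined (the classic $S + F_1^2/2F_2$ form is available by flag).

Bray–Curtis dissimilarity is computed on relative abundances by default
(raw-count mode by flag).  The Mantel test correlates lower triangles of two
distance matrices, with a one-sided (greater) permutation p-value
$(1 + \#\{r_{perm} \ge r_{obs}\})/(1 + n_{perm})$ under simultaneous
row/column permutation; 999 permutations by default.  The partial Mantel
statistic is implemented on **residuals**: both lower triangles are regressed
on the control matrix and the residuals correlated.  This is numerically
identical to the textbook first-order partial correlation in non-degenerate
cases (cross-checked against `vegan::mantel.partial` in the test suite) but
remains well-defined at the edges: a constant control matrix reduces to the
plain Mantel test, and a (near-)zero-variance residual vector yields $r = 0$
rather than 0/0.

One-way PERMANOVA is delegated to `vegan::adonis2`.  Note a design-size
caveat that matters for tiny studies: the pseudo-F depends on the group
*partition* only, so with two groups of three samples there are just 10
distinct partitions and the smallest attainable p-value is 0.1, regardless
of effect size.  Claims of significance at $p < 0.05$ require larger designs
(the 6-vs-6 comparison of a full two-mine layout is fine).

Environment variables are screened against the community distance with
per-variable Mantel tests (z-scored Euclidean distances by default) and BH
adjustment across the variable family.  Missing environmental values are
excluded pairwise, never imputed.

## Co-occurrence networks

Networks are built per group from the `n_top` most abundant taxa (ties at
the cutoff break towards the lexicographically smaller taxon id).  Pairwise
Pearson correlations are computed on $\ln(1+x)$-transformed counts (relative
abundances or untransformed values by flag), with two-sided p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$.  An edge is kept iff $|\rho| > 0.3$ and
$p < 0.05$ (both thresholds configurable).  Correlation signs are stored on
the edges: negative associations are part of the cohesion analysis, so a
positive-only criterion is available by flag but is not the default.  Edge
p-values are **not** multiplicity-corrected by default, matching the common
raw-threshold practice; a BH-corrected mode exists for conservative use.
Isolated nodes are dropped before any metric is computed, matching the node
counts such studies report from graph exports.

The metric suite: node and edge counts, connectance $2E/(n(n-1))$, average
degree $2E/n$, global clustering coefficient (3 × triangles / connected
triples), average local clustering (nodes of degree < 2 contribute 0),
average neighborhood connectivity (mean over nodes of the mean degree of
their neighbours — on the 3-node path this is $(2+1+2)/3 = 5/3$ by direct
enumeration), Freeman degree centralization
$\sum_i (d_{max}-d_i)/((n-1)(n-2))$, and eigenvector centralization.
Eigenvector centralities are taken from a dense symmetric eigen
decomposition (deterministic, unlike ARPACK with a random start) and
unit-normalised; the centralization sum is divided by the value attained by
the star graph of the same order, computed numerically per $n$, because no
closed form is universally agreed for this normalisation.

**Cohesion** quantifies how strongly a sample is built from correlated taxa.
Observed taxon–taxon Pearson correlations of relative abundances are
corrected by a taxa-shuffle null (each taxon's abundances permuted
independently across samples; 200 replicates by default; pairwise mean
subtracted).  A taxon's positive (negative) connectedness is the mean of its
positive (negative) corrected correlations, and per-sample cohesion is the
relative-abundance-weighted sum of connectedness.  Two caveats are inherent
to the construction: row-normalisation induces a compositional correlation
of about $-1/(k-1)$ between $k$ taxa that the shuffle null does not
reproduce, so corrected correlations of sparse tables retain a small
negative offset; and because connectedness averages a *selected* (positive
or negative) subset, finite-sample noise keeps cohesion away from exactly
zero even for independent taxa.  Both effects shrink with more samples and
more taxa and are covered by tolerance-based tests.

**Modules** come from Louvain on absolute edge weights (seeded, hence
reproducible), relabelled by decreasing size; modules with at least 15 nodes
are flagged for the module–environment analysis, where module abundance (sum
of member relative abundances — the mean differs only by a constant factor
and leaves correlations unchanged) is correlated with each environment
variable, BH-adjusted over the full module × variable family.

**Complexity** min-max standardises each topological property across the set
of networks being compared, $(X - X_{min})/(X_{max} - X_{min})$, and averages
the standardized scores (node count, edges, connectance, average degree,
GCC, ACC, AN, CD, EC and positive cohesion).  The score is only defined
across $\ge 2$ networks; properties with no contrast across the set are
dropped with a warning rather than contributing 0/0.

## Community assembly null models

The deterministic/stochastic partition follows the now-standard two-stage
logic on every pair of samples:

1. **betaMNTD / betaNTI.**  Abundance-weighted between-sample mean nearest
   taxon distance,
   $\beta MNTD = \tfrac12\big[\sum_{i\in A} f_i \min_{j\in B} d_{ij} +
   \sum_{j\in B} f_j \min_{i\in A} d_{ij}\big]$, with $f$ the within-sample
   relative abundances and $d$ cophenetic tree distances (a shared taxon
   contributes distance 0).  The null shuffles taxon identities across *all*
   tree tips ("taxa-labels" null), recomputing betaMNTD per replicate (999
   by default); $\beta NTI$ is the z-score.  The Monte-Carlo null is
   validated against exhaustive enumeration of all tip relabellings on small
   trees.  $|\beta NTI| \ge 2$ is read as selection: $\beta NTI < -2$
   homogeneous selection, $\beta NTI > +2$ heterogeneous selection.  (A flag
   `inverted` swaps the two subtype labels for comparison with
   texts that print the inverted assignment; the default follows the
   standard convention, which is also the only one consistent with
   interpreting less-than-expected turnover as homogenising.)  If every
   shuffle returns the same betaMNTD (e.g. a star phylogeny) the z-score is
   undefined: the pair is flagged `NA`, warned about, and excluded from
   fraction denominators.
2. **Raup–Crick (Bray–Curtis).**  For pairs not assigned to selection, each
   null replicate rebuilds both samples with their observed richness and
   depth: members drawn without replacement proportional to occupancy, one
   individual seeded per member, remaining individuals multinomial
   proportional to metacommunity relative abundance.
   $RC_{bray} = 2\big[(\#\{BC_{null} < BC_{obs}\} + \tfrac12\#\{BC_{null} =
   BC_{obs}\})/n_{null}\big] - 1 \in [-1, 1]$.  Bray–Curtis is evaluated on
   relative abundances in both the observed and null pairs so unequal depths
   do not leak into the index.  $RC > 0.95$ is dispersal limitation,
   $RC < -0.95$ homogenising dispersal, $|RC| < 0.95$ undominated (drift);
   the boundary $|RC| = 0.95$ falls to undominated.  The Monte-Carlo
   estimate is validated against exact enumeration of all feasible null
   assemblies on tiny tables.

Per-group process fractions are computed over within-group pairs; `NA`
pairs are excluded from the denominator and reported separately.  Null
replicate counts default to 999 for both stages, and every randomised stage
derives its stream from one recorded seed.

The betaMNTD kernel is compiled (Rcpp) because the null loop evaluates the
pairwise minimum-distance sums roughly a thousand times; the tip shuffle is
expressed through an index vector so the distance matrix is never copied.
A pure-R reference implementation lives in the test suite and the observed
statistic is additionally cross-checked against `picante::comdistnt`.

## The synthetic-community generator

Downstream methods are exercised on synthetic data with known ground truth,
shaped like a two-mine tailings study: 2 pollution groups × 2 succession
stages × 3 replicates (12 samples), 400 taxa, 20,000 reads per sample.

* **Phylogeny**: pure-birth (Yule) tree rescaled to unit crown depth.
* **Niche traits**: Brownian motion from a root value of 0 with rate
  $\sigma^2$ (default 1, so tip traits have unit standard deviation on the
  unit-depth tree); closely related taxa share similar niches, which is what
  makes selection phylogenetically detectable.
* **Metacommunity**: one log-series abundance per taxon, with the
  distribution parameter implied by Fisher's $\alpha$ (default 20) and the
  taxon count through $J = \alpha(e^{S/\alpha}-1)$, $x = J/(J+\alpha)$;
  sampling uses Kemp's O(1) generator.  This yields the realistic heavy
  rank-abundance skew that makes "top-N by abundance" filtering meaningful.
* **Regimes**: `filtering` draws each sample multinomially with weights
  proportional to metacommunity abundance times a Gaussian niche factor
  $\exp(-(t_i - e_s)^2/2\omega^2)$ (niche breadth $\omega$, default 0.5
  trait SD; per-sample optima configurable); `neutral` draws every sample
  from the same metacommunity; `dispersal_limited` places samples on a chain
  where each local pool mixes the neighbour's realised composition with the
  metacommunity at migration rate $m$.
* **Environment**: nutrient-style variables (pH, SM, TOC, TN, NH4, NO3, TP,
  TS) are linear in the selection gradient plus Gaussian noise, so Mantel
  screens have recoverable signal; metal concentrations are group-structured
  lognormals, $C = B_k \cdot mult_{g,k} \cdot e^{N(0,\sigma_{log})}$, with
  default multipliers chosen so the two groups reproduce the published
  magnitude contrast of a copper-mine versus rare-earth-mine comparison
  (strong Cu enrichment in the high group).

What the generator deliberately does **not** emulate: sequencing error and
chimeras, spatially explicit landscapes, and — importantly — *local drift*.
Each sample is a single multinomial draw, so at a depth of 20,000 reads
replicate samples from identical weights are nearly identical (Bray–Curtis
≈ 0.02–0.03).  Real communities assembled under shared selection still
drift apart among the selected clades; the one-shot multinomial design
cannot produce that turnover.  Consequently, shared-environment filtering
yields betaNTI values only mildly shifted negative (the shift relative to
the neutral regime is real and tested), while *divergent* selection (opposed
niche optima ±2 trait SD) is recovered sharply, with betaNTI > +2 for
essentially all between-group pairs.  Passing tests therefore demonstrate
correct null-model machinery and recovery of divergent selection and
stochasticity, but say nothing about detecting homogeneous selection from
drift-free replicate draws — that signal is absent from the generated data
by construction, not missed by the estimator.

## Numerical choices and problem sizes

* Ties: $|\beta NTI| = 2$ counts as selection; $|RC| = 0.95$ as undominated;
  top-N abundance ties break lexicographically; Bray–Curtis ties in the RC
  null count half, with equality at tolerance $10^{-12}$.
* Degenerate inputs: all-zero samples are rejected by name; zero-variance
  taxa are skipped in correlation networks and cohesion with a message;
  degenerate betaNTI nulls yield flagged `NA`s.
* Seeds: every randomised stage (tree, traits, draws, nulls, permutations,
  Louvain) takes an explicit seed; the pipeline derives per-stage streams
  from one master seed and its outputs are byte-reproducible.
* Rarefaction is available (`rarefy_table()`) but off by default; diversity
  and network stages run on the table as provided.
* Test problem sizes were chosen to keep the full suite to a few minutes:
  exhaustive betaNTI enumeration uses 6 tips (720 relabellings) against
  10,000 Monte-Carlo draws; Raup–Crick enumeration uses 3-taxon tables;
  parameter-recovery runs use 8–12 samples, 150–400 taxa and 199–999 nulls;
  calibration checks use 100–1000 replicates.  The acceptance script runs
  the full study-shaped fixture (12 × 400 × 20,000, 999 nulls) in about two
  minutes.

## Known limitations

* The cohesion null does not remove compositional closure, a property
  inherited from the published method; interpret small cohesion values on
  tables with few taxa cautiously.
* PERMANOVA significance is bounded below by the permutation geometry of
  tiny designs (minimum p = 0.1 at 3 + 3).
* The complexity score is relative to the set of networks supplied; it is
  not comparable across analyses standardised over different sets.
* BIOM support covers the JSON (biom 1.0) dialect only, via the biomformat
  package; HDF5 BIOM is out of scope.
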