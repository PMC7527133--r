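---
title: "Consensus co-occurrence networks and primary cohorts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus co-occurrence networks and primary cohorts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortnet)
```

## The problem

Abundant freshwater bacterioplankton — minimalist, streamlined lineages —
persist in lakes despite extensive auxotrophies, which suggests they rely
on partner taxa for common goods. One observational handle on such
partnerships is the co-occurrence network: OTUs whose abundances co-vary
across many samples are candidates for ecological interaction, and the
first neighbors of a target taxon (its 1° or *primary cohort*) are the
candidate partner set. Because single correlation estimators on
compositional sequencing data are notoriously unreliable, the pipeline
implemented here demands agreement between independent estimators before
calling an edge.

`cohortnet` implements that pipeline end to end — normalization,
filtering, four association estimators, consensus voting, network
statistics, cohort extraction, and the supporting univariate screens —
together with a seeded synthetic-community generator that provides
ground-truth interaction networks, so every stage is validated against
data whose answer is known.

## Compositionality and the estimators

Sequencing counts are compositional: each sample is constrained to its
sequencing depth, so naive correlations between proportions are
systematically biased. The pipeline therefore runs several estimators
with different failure modes and keeps only pairs on which at least two
agree:

* **Pearson** on relative abundances, two-sided p-values, BH step-up
  adjustment over the upper triangle (`pearson_matrix()`). Simple and
  sensitive, but subject to compositional artefacts.
* **SparCC** (`sparcc()`): fractions are estimated by averaging
  `max_iter` Dirichlet(counts + 1) posterior draws; the log-ratio
  variation matrix $t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$ is then
  computed once. Under the sparsity approximation the basis variances
  $\omega_i$ solve the linear system $t_{ij} \approx \omega_i +
  \omega_j$ (matrix $\mathbf{1}\mathbf{1}' + (D-2)I$), and
  $\rho_{ij} = (\omega_i + \omega_j - t_{ij}) / 2\sqrt{\omega_i\omega_j}$,
  clipped to $[-1, 1]$. Up to `exiter` exclusion rounds remove the
  currently strongest pair with $|\rho| >$ `th` from the solve (the pair
  itself keeps its $\rho$, computed from the full variation matrix). If
  an exclusion would make the system singular — possible on small
  bootstrap tables — the loop stops at the last solvable state.
  Significance comes from `sparcc_pvalues()`: each OTU's counts are
  resampled independently across samples (destroying cross-OTU
  association), SparCC is re-run per bootstrap, and the two-sided
  pseudo-p is $(\#\{|\rho_b| \ge |\rho_{obs}|\} + 1)/(B + 1)$.
* **Dice–Sørensen** (`dice_sorensen()`) on presence/absence,
  $2|a \cap b| / (|a| + |b|)$ — the natural measure for the sparse
  mixed-culture table, where co-detection itself is the signal.
* **Neighborhood selection** (`mb_network()`): after a centered
  log-ratio transform (pseudocount 1), each OTU is lasso-regressed on
  all others along a 20-point geometric penalty path spanning a
  $10^{-2}$ ratio, and StARS picks the penalty: over 50 random
  subsamples of size $10\sqrt n$ (or $0.8n$ for small $n$), per-edge
  instability $2\theta(1-\theta)$ is averaged per penalty, monotonized
  by its running supremum along the sparse-to-dense path, and the
  densest penalty whose monotonized instability stays at or below
  `beta = 0.05` is selected. Neighborhoods are OR-symmetrized; the edge
  sign is the sign of the mean of the two regression coefficients. This
  estimator targets *conditional* dependence and contributes detection
  and sign but no correlation coefficient.

**Consensus** (`build_consensus()`): coefficient-bearing methods retain
pairs with $|r| > 0.3$ (strictly, per the retention rule; an inclusive
flag exists), the neighborhood method retains its entire support. An
edge needs at least two supporting methods; its weight is the mean of
the available coefficients (the neighborhood method votes but
contributes no coefficient); conflicting signs are kept and flagged
rather than dropped, since both signs are ecologically interpretable.
The time-series trio is {pearson, sparcc, mb}; the mixed-culture trio is
{pearson, dice, mb}.

Design choices worth making explicit:

* *BH vs BY*: the adjustment is Benjamini–Hochberg step-up, with a
  `method = "BY"` switch for the more conservative variant.
* *StARS selection*: "densest penalty with monotonized instability
  ≤ β" (the canonical reading); β defaults to 0.05.
* *No p-value gate before the 0.3 threshold*: retention is
  coefficient-only by default, with an optional `max_p_adj` argument in
  `threshold_edges()`.
* *`max_iter`* is the number of Dirichlet draws averaged into the
  fraction estimate. Averaging fractions (rather than averaging
  per-draw variation matrices) avoids adding the Dirichlet sampling
  variance — roughly trigamma(count + 1) per cell — to every $t_{ij}$,
  which would systematically attenuate $|\rho|$ for rare OTUs.

## Normalization and filtering

Tables are rarefied (`rarefy()`) to an even depth — 1500 reads for the
time series, 500 for mixed cultures; shallower samples are dropped, not
up-sampled. The network-ready time-series table comes from a filter
sweep (`filter_sweep()`) over detection frequency × total relative
abundance: each grid point is scored by sparsity (fraction of zero
cells) and mean inverse-Simpson $n_{\mathrm{eff}} = 1/\sum p_i^2$, and
among points achieving sparsity ≤ 50% and mean $n_{\mathrm{eff}} \ge
10$ the one retaining the most OTUs wins (ties: lower detection cutoff,
then lower abundance cutoff). "Total relative abundance" is the sum of
per-sample proportions, so at even depth $D$ a cutoff of $k$ reads is
$k/D$; the preset configuration expresses it as a percentage of total
reads (0.1%). Whether the cutoffs are strict or inclusive is
configurable (`strict`), inclusive by default. The mixed-culture table
is instead cleaned of singletons (total count ≤ 1). Prevalence is
computed on the rarefied table, matching the order of operations of the
original analysis.

## Network statistics

`nominal_assortativity()` implements Newman's categorical assortativity
$r = (\sum_i e_{ii} - \sum_i a_i b_i)/(1 - \sum_i a_i b_i)$ from the
edge-endpoint mixing matrix at a chosen rank, undirected, signs
ignored (sign-aware variants are out of scope; the default is
documented because the original statistic is ambiguous on this point).
Note that $r$ has a small negative bias under random labeling of a
fixed graph — order $1/m$ — so permutation nulls should be compared
against their own expectation (the test suite enumerates all labelings
of a toy graph as the oracle) rather than against zero.
`modularity_stats()` uses greedy agglomerative community detection on
the unsigned, unweighted graph (the tool used by the original study
does not name its algorithm; greedy agglomeration is the conventional
choice and is checked against exhaustive partition search for
$n \le 8$). `first_neighbors()` extracts primary cohorts, annotating
each neighbor with its strongest-|weight| connecting edge;
`cohort_overlap()` reports directional shared fractions
$|A \cap B|/|A|$ and per-neighbor sign agreement. Cohort subgroup
splits (e.g. basal vs core members of a genus) are supplied by the user
as explicit OTU id lists, mirroring the manual split in the original
analysis.

## Univariate screens

`prune_collinear()` removes environmental parameters with > 40%
missingness, then iteratively removes parameters with VIF > 10 or
pairwise |corr| > 0.7, starting with the most missing values — the
standard vifstep/vifcor-style procedure. `env_screen()` correlates
clade abundances with the retained parameters over pairwise-complete
observations (listwise deletion would discard most samples), BH-adjusts
over all tests, and flags |r| > 0.3 with adjusted p < 0.001 — the
display filter applied after adjustment. `phase_kw()` runs
Kruskal–Wallis per clade over the six phase labels and, when
significant, an all-pairs comparison of mean rank sums with the
normal-approximation (Siegel–Castellan) critical difference; phases
differing from at least two others are flagged.
`pd_vs_correlation()` relates patristic distance to consensus edge
weight over *network-connected* (target, cohort member) pairs — the
connected-pairs reading of the distance-versus-correlation comparison;
an unconnected-pairs-as-zero variant was considered and rejected as the
default because absent edges are censored, not zero.
`cross_dataset_corr()` compares log10 mean relative abundance (OTUs at
zero abundance excluded — log base and zero handling are the package's
choice) and prevalence across datasets.

## The synthetic community

The generator exists to give every estimator a target whose answer is
known; it emulates the statistical structure the analysis assumes, not
lake biology.

* `make_taxonomy()` builds a random nested 7-rank hierarchy and an
  ultrametric tree consistent with it (each rank's splits sit at a
  fixed height, phylum splits at the root), yielding patristic
  distances for the distance-decay analyses.
* `make_truth_network()` plants a chosen number of signed edges;
  `assortative_bias` oversamples within-phylum pairs (weight
  $e^{bias}$), planting taxonomic assortativity.
* `simulate_timeseries()` builds latent log abundances = baseline
  (N(0, 1)) + seasonal sinusoid (per-OTU amplitude U(0.2, 0.6), random
  phase) + per-edge shared Gaussian factors scaled by
  `strength * coupling_sd` (anti-phase for negative edges) + N(0, 1)
  noise, then draws multinomial counts at the even depth. Latent-factor
  coupling was chosen over Lotka–Volterra dynamics deliberately: it
  maps edge strength directly onto the pairwise latent correlation
  ($\rho_{latent} = s^2 c^2 / (s^2 c^2 + \sigma^2)$, ≈ 0.72 at the
  benchmark's $s = 0.8$, $c = 2$, $\sigma = 1$), which is exactly the
  quantity the estimators are tested on. The default noise and
  amplitude scales were fixed once so that seasonal co-variation alone
  stays below the 0.3 edge threshold while planted edges sit above it.
  Phase labels follow the sample date (winter, spring, autumn by
  month; summer samples cycle through the three stratification
  layers).
* `simulate_cultures()` emulates the dilution design: founder cells
  per culture ~ Poisson(10) assigned to OTUs by the lake composition
  (exposed as a parameter — the inoculum's composition at founding is
  not observable, so the simulator does not hard-wire the lake table),
  lognormal growth of founded OTUs, optional obligate-partner rule
  (off by default), multinomial reads at depth 500, and detection
  censoring: a culture is detected when its total grown biomass times
  a lognormal culture-level yield exceeds `detection_fraction` of the
  expected biomass. The default 0.67 with yield SD 1.5 was calibrated
  once so that roughly 60 of 98 cultures pass, mirroring the
  visible-band yield of the emulated experiment. With no dependency
  rule, per-OTU occupancy follows $1 - e^{-\lambda f}$ exactly — the
  closed form the tests check.
* `simulate_env()` builds seasonal-plus-AR(1) parameters, optionally
  linked to a chosen OTU's abundance series at a target correlation,
  with missing cells at a chosen rate.

What the generator does *not* emulate: sequence-level artefacts,
mechanistic growth kinetics, grazing/viral dynamics, non-stationary
seasonality, and abundance distributions heavier-tailed than the
lognormal baseline. Passing tests therefore show the estimators recover
planted pairwise structure under realistic counting noise and
compositional closure — not that they would recover interactions in any
real lake.

## Numerical choices and degenerate inputs

* All generators and the pipeline are deterministic given a seed
  (stage seeds are derived from the master seed); consensus edge lists
  are byte-identical across reruns.
* Zero-variance OTUs get `NA` correlations and are excluded from the
  BH adjustment count; all-absent OTU pairs are undefined for
  Dice–Sørensen.
* Negative solved basis variances are floored at $10^{-10}$ and
  flagged; $\rho$ is always clipped to $[-1, 1]$.
* Single-label networks return `NA` assortativity (degenerate
  denominator); empty predictions against empty truth score precision
  and recall 1 by convention.
* Zero-read samples have undefined $n_{\mathrm{eff}}$ and are excluded
  from its mean.

## Problem sizes

The validation suite runs the full benchmark — 100 OTUs in 6 phyla, 30
planted edges at strength 0.8, 200 samples at depth 1500 — over five
seeds, the null calibration on a 50-OTU edge-free community, the
bootstrap calibration on 105 independent pairs with 100 bootstraps, and
the occupancy check on 1000 cultures. These sizes give stable medians
and tight Monte-Carlo error at desk scale; the same code runs unchanged
on larger tables.

## Known limitations

* SparCC's basis solve assumes most pairs are uncorrelated; dense
  planted networks (or real communities with pervasive structure) bias
  $\omega$ and attenuate $\rho$.
* The mb estimator's StARS selection is conservative by construction;
  under weak signal it prefers empty graphs.
* Culture networks built from co-founding alone carry no information
  about planted interactions (the analysis scripts therefore score
  recovery only on the time series); enabling the obligate-dependency
  rule plants recoverable structure.
* The Kruskal–Wallis post hoc uses the normal approximation; for very
  small groups an exact permutation variant would be preferable.
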