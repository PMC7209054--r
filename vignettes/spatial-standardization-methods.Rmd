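---
title: "Methods: spatially standardized regional palaeodiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially standardized regional palaeodiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeoreg)
```

## Why standardize space

The worldwide fossil record is a heterogeneous mosaic of regional
assemblages whose number, identity and spatial extent change from one
geological interval to the next. A species count computed over that
mosaic confounds diversity with the geography of collecting: as the
sampled area expands, new regional faunas enter the pool and the
"global" curve rises even if no region ever became more diverse.
Sampling-standardization methods that equalize *intensity* (coverage,
sample size) do not correct this, because the bias operates through
*extent*. The approach implemented here therefore compares like with
like: species richness is estimated only within palaeogeographical
regions of approximately equal spatial spread, and the through-time
signal is read from those standardized regions.

## The procedure

**Spatial points.** Occurrences are binned on an equal-area spherical
grid with ~100 km spacing. Any approximately equal-area discrete global
grid works for this role; the package uses latitude rings of
near-constant height divided into integer numbers of cells so that every
cell area is within a few percent of `spacing_km^2` (asserted in the
test suite to be within ±15% of the mean; the construction typically
achieves ±5%). Cells are identified with their centres for all distance
computations. The grid's orientation is fixed and deterministic; cell
assignment of a coordinate is a two-step index lookup, so binning is
reproducible across runs and platforms.

**Region enumeration.** Within each time bin, every occupied cell seeds
a region that grows by repeatedly adding the unsampled cell with the
smallest great-circle distance to the current member set (single
linkage: the minimum over members). Every intermediate set of size two
or more is saved; duplicate member sets from different starts are
discarded. Equidistant candidates are chosen uniformly at random under a
recorded seed, so reruns are bit-identical. Two useful facts follow from
this rule being Prim's algorithm: the saved prefix trees are minimum
spanning trees of their member sets (verified against brute-force
spanning-tree enumeration in the tests), and enumeration therefore
yields each candidate region's MST length for free. Distance ties are
resolved to within 1e-9 km, far below palaeocoordinate accuracy.

**Standardization criteria.** A region survives at a spatial scale when
all four hold: MST total within ±10% of the target (1000–4000 km in
500 km steps); longest single MST branch at most 40% of the total
(rejecting dumbbell regions made of widely separated locality
clusters); at least 20 distinct literature references (a floor on study
effort); multiton ratio at least 0.25 (a conservative completeness
floor — Good's u can look deceptively high in tiny samples). Regions
whose member collections span palaeogeographic barriers
(South America + Africa after 120 Ma, Australia + New Zealand after
70 Ma, Europe + Africa after 66 Ma, shipped as editable configuration)
are removed by bin midpoint.

**Clustering.** Because the enumeration is exhaustive, surviving regions
overlap heavily. Two regions are linked when they share more than 25% of
the spatial points of the *smaller* region; clusters are connected
components of that relation. The overlap denominator and the accretion
order are not dictated by the procedure's verbal description, so the
package makes both canonical: min-size denominator (guaranteeing a
nested region is absorbed by its superset) and a deterministic
processing order (descending member count, then lexicographic member
key) used only for labelling — membership itself is order-invariant, and
the tests shuffle inputs to prove it. Per cluster, every variable is
summarized as the median and interquartile range (linear-interpolation
quartiles, missing values ignored).

## Richness estimators

All estimators consume a frequency vector of per-species occurrence
counts within a region (abundance-type data, the normal situation for
PBDB occurrences; collection-incidence is used only by Chao 2).

*Coverage-based rarefaction / SQS.* The estimate is the expected species
richness at the sample size whose estimated coverage equals the quorum
`q`. Below the reference sample the hypergeometric expectations are
used; at the reference sample the estimate is exactly `S_obs`; above it
the standard extrapolation based on the estimated number of undetected
species `f0_hat` applies, with the coverage extrapolation solved in
closed form for the target size. Fractional target sizes are resolved by
linear interpolation between adjacent integer sizes (the continuous
formula already covers the extrapolation side). Numerical choices: all
binomial ratios are computed via `lchoose` differences to avoid
overflow; the smallest admissible sample size is one occurrence, so a
single observed species yields 1 at any quorum; estimates extrapolated
beyond twice the reference size are flagged
(`extrapolated_beyond_2n`), and an all-singleton vector (f1 = n) has no
defined extrapolation and returns NA with `undefined_fallback`.
Estimator failures are data, not exceptions — NAs propagate into the
region tables and are ignored by the cluster summaries.

*Chao 2* uses collections as sampling units (the natural replication
unit of fossil data); the classical form applies when doubletons exist
and the bias-corrected form (flagged) when `q2 = 0`. *Squares* is the
frequency-based asymptotic estimator given in the README; it degenerates
(NA, flagged) only when every species is a singleton. *Face value* is
the raw species count, kept because its behaviour under spatial
standardization is itself informative.

*Grid-cell rarefaction (GCR)* additionally standardizes the packing
density of localities inside equal-extent regions: occupied 200-km cells
are drawn down to `round(quota_per_1000km * MST/1000)` cells (quotas 3,
5, 8), occurrences pooled, SQS computed, and the mean over 50 seeded
trials reported; regions below quota return NA. GCR is off by default in
the pipeline, matching the estimator-comparison configuration, because it
multiplies the SQS cost by the trial count.

## Trend models

Bias regressions use first differences of log series (old to young),
dropping incomplete pairs and optionally excluding named outlier bins;
at least four paired differences are required. Diversification regimes
are compared with five least-squares models of log richness — intercept;
time; time + phase; time × phase; phase — where the phase indicator
switches at 66 Ma (configurable) and time enters as megayears before
present, negated so positive slopes mean increase toward the present.
AICc follows the least-squares convention
`n log(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with the residual variance counted
in `k` (so the intercept model has k = 2); this affects all models
equally and leaves AICc differences identical to the likelihood
formulation. The five-model set is the full lattice of the three
ingredients; models whose phase term is inestimable (all data in one
phase) or whose small-sample correction is undefined are skipped and
flagged rather than silently refitted. Data points entering the fits are
cluster medians, one per cluster. Autocorrelation-aware fits use
maximum-likelihood GLS with an AR(1) correlation structure (via `nlme`);
with the autoregressive coefficient pinned at zero this reproduces OLS,
which the tests assert to six decimals.

## The synthetic fossil record

The generator separates biology from observation. `simulate_world()`
builds per-bin species pools in latent geographic regions (disc
neighbourhoods on the sphere) under one of three trajectories: flat;
expansionist (pool size multiplied by `exp(growth_rate * bin_length)`
per bin); or constrained-with-shift (constant, times `shift_factor` for
bins younger than `boundary_ma`). Species identities persist across bins
with configurable turnover (default 25% per bin), and roughly 10% of new
recruits are shared between regions, giving non-trivial beta diversity.
Abundance weights come from a log-series distribution by default — its
heavy singleton tail is deliberately hard on coverage estimators — with
a lognormal alternative for evenness sensitivity.

`sample_fossil_record()` observes that world: latent regions whose
centres fall inside a spherical-cap window around an anchor are sampled;
the window radius can grow exponentially toward the present, which is
the spatial bias under study. Each sampled region yields a budget of
collections (Gaussian scatter, default sd 200 km, around its centre);
collections are budgeted *per region* rather than globally, because real
fossil collections are clustered — an expanding record adds new locality
clusters rather than diluting a fixed worldwide collecting effort, and a
global budget would artificially starve late-bin regions of references.
Occurrences per collection are 1 + Poisson; collections are partitioned
into publication groups of mean size `collections_per_reference`
(default ~1.2, reflecting that most vertebrate-palaeontology references
report one or few localities — this makes the 20-reference filter
meaningfully exercisable); age ranges get uniform slop up to 20% of bin
length so the majority-overlap binning rule is exercised; small
configurable fractions of genus-rank and excluded-group records exercise
the cleaning stage. True per-bin pool sizes are exported as a sidecar
that the pipeline never sees.

The packaged scenarios are the study conditions used by the validation
analyses: `flat`, `constrained_shift` (x2.5 at 66 Ma) and
`expansionist` (rate 0.012 per Myr) use 16 ten-Myr bins, two latent
regions and 40 collections per region per bin — small enough that a
hundred seeded replicates of the model-selection analysis run in
minutes, large enough that per-bin frequency vectors support SQS at
q = 0.6. `bias_demo` uses 10 bins, six latent regions spread to 9000 km,
130 collections per region, and a window growing from 1600 km diameter
at ~2.7% per Myr, so the sampled world expands roughly tenfold while
true regional pools stay at 150 species.

What the generator does **not** emulate: taphonomic or lithification
biases, plate motion (palaeocoordinates are generated directly),
phylogenetic structure in turnover, abundance change within species, and
spatial gradients in the species-abundance distribution. Passing the
validation suite therefore shows that the pipeline recovers known
regional diversity under realistic *sampling* structure — not that real
tetrapod data are free of other biases.

## Performance design

Enumeration from all starts is O(P^3) per bin in the worst case and is
comfortable for P up to a few hundred occupied cells. Characterization
is the expensive stage, so `run_pipeline()` characterizes only regions
whose enumeration-time MST total falls inside a requested scale window
(target ± tolerance); since the extent filter is the first conjunct of
the standardization criteria, the filtered, clustered and summarized
outputs are identical to characterizing everything. Dense great-circle
distance matrices are computed once per bin. Replicated model-selection
analyses run on per-bin pooled SQS from spatially uniform worlds — with
a full-coverage window, pooled and regional standardized richness
coincide up to estimator noise, and this keeps a hundred replicates
inside a few minutes where the full spatial pipeline per replicate
would be disproportionate.

## Known limitations

Cluster medians within a bin are not independent across bins when the
same underlying locality clusters persist, so slope tests on cluster
points can overstate certainty; the clustering step reduces, but does
not remove, this pseudo-replication. The equal-area grid is not
hexagonal; only the equal-area property matters downstream, but exact
cell boundaries differ from ISEA-style grids, so occupied-cell counts
are comparable within, not across, grid implementations. The barrier
rules operate at the granularity of the supplied region codes. SQS here
is abundance-based; an incidence-mode variant would require a different
reference-sample definition. And the multiton ratio is species-based
(share of species seen more than once); an occurrence-based variant
would need its own threshold calibration.
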