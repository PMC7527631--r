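---
title: "Assembly-free association mapping from pooled allele frequencies: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free association mapping from pooled allele frequencies: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scafqtl)
```

## The problem scafqtl addresses

Orphan crops are routinely genotyped without a chromosome-level genome. A
draft assembly offers only scaffolds — tens of thousands of fragments with no
relative order — so the usual apparatus of GWAS (Manhattan plots along
chromosomes, window-based QTL boundaries, positional LD pruning) is not
available. A second complication is pooled genotyping: when accessions are
heterogeneous seed lots rather than inbred lines, DNA from several
individuals per accession is pooled and sequenced together, so a "genotype"
is not 0/1/2 but an allele frequency estimated from the pool.

`scafqtl` implements a complete analysis chain for this setting: each marker
is scored per accession as the proportion of the panel-wide major allele; a
genomic relationship matrix built from those proportions controls population
structure in a linear mixed model scan; a collinearity threshold calibrated
from within-scaffold LD decay groups significant markers into QTLs without
genome coordinates; and QTLs are matched across trial locations through
correlations between their representative markers. A synthetic-panel
generator with ground truth makes the whole chain testable.

## Marker scoring and the four selection rules

With a pool of `p` diploids per accession, every sample carries `2p` alleles
(16 at the default pool size of 8), so pool frequencies live exactly on the
grid `{0, 1/2p, ..., 1}`. From per-accession nucleotide frequencies (%A, %C,
%G, %T per site), markers are selected by four rules applied in order, each
rejection labelled with the first rule violated:

1. **call rate** — the marker must be called in 100% of accessions. No
   imputation is attempted; downstream algebra assumes complete columns.
2. **minor-allele frequency** — panel-level bounds `[0.02, 0.98]` on the
   major allele: markers with panel minor frequency below 2% (equivalently
   major above 98%) carry almost no information at pool resolution.
3. **biallelic content** — the two most frequent alleles must together reach
   95% of panel frequency; sites segregating three or four nucleotides are
   not representable by a single proportion.
4. **allelic variation** — the sample standard deviation (denominator
   `n − 1`) of the per-accession major-allele frequency must be at least
   0.1, so the score column varies enough to be a usable predictor.

The surviving marker is scored as the per-accession frequency of the
panel-wide major allele, the allele with the largest panel mean frequency;
exact ties break lexicographically (A < C < G < T). One further
canonicalization keeps scoring idempotent: if, after scoring, a column's
panel mean falls below 0.5 (possible when a third allele shifts the raw
nucleotide ranking), the column is flipped to track the complementary
allele. Re-running QC on its own scored output is then exactly a no-op, a
property the test suite asserts over a thousand random tables.

## Kinship on the frequency scale

The genomic relationship matrix is the VanRaden construction adapted to
frequency-scale genotypes. With `X` the accession-by-marker score matrix and
`Z` its column-centred version,

    K = Z Z' / s,    s = sum_j pbar_j (1 - pbar_j),

where `pbar_j` is the panel mean score of marker `j`. For 0/1/2 dosages the
classical scaling is `2 sum p(1-p)`; pool frequencies halve the per-marker
variance scale, and `s` is its direct analogue, keeping `K` on a
heritability-friendly scale regardless of panel composition. Constant
columns contribute nothing (they center to zero).

Structure is summarized three ways: principal coordinates (eigendecomposition
of the double-centred `K`, percent variance relative to the positive
spectrum), an average-linkage dendrogram, and Wright's FST between the
clusters of the dendrogram cut. For the dendrogram the similarity must
become a distance; the default is the Gram-induced form
`d(i,j) = K_ii + K_jj − 2 K_ij`, chosen because it is a true squared
Euclidean distance in the feature space of `Z` — in particular two
accessions with identical marker profiles are at distance zero and merge
first. The simpler `max(K) − K_ij` conversion, which does not have that
property (its self-distances are nonzero wherever diagonals differ), is kept
as an option for comparability.

FST between clusters follows Wright's variance decomposition: per marker,
with cluster frequencies `p_i`, cluster weights `c_i` and
`pbar = sum c_i p_i`,

    FST = (pbar(1-pbar) - sum_i c_i p_i (1-p_i)) / (pbar(1-pbar)).

The multi-marker value is the ratio of summed numerators to summed
denominators rather than the mean of per-marker ratios: single markers carry
little information and their ratios are wildly dispersed, while the ratio of
sums is the stable (Weir-style) estimator; per-marker ratios are still
reported. Markers monomorphic across the pair (`pbar` of 0 or 1) are
skipped.

## LD decay and the collinearity threshold

Squared Pearson correlation between score columns is the collinearity
measure. Within each profiled scaffold all marker pairs are tabulated with
their physical distance (positions are 1-based; distance `|pos_a − pos_b|`);
the decay curve is summarized by medians in log-spaced distance bins. The
long-range floor — the `r²` level reached far from the diagonal — is
estimated as the median `r²` of the most distal 25% of pairs per scaffold,
averaged over scaffolds. The collinearity threshold used by the MultiQTL
stage is the larger of this baseline and the conventional floor `r² = 0.1`.

Collinearity is evaluated as `|r| >= 0.3` (equivalently `r² >= 0.09`):
because all columns are polarized to the panel major allele, a strong
*negative* correlation is physically meaningful linkage of the repulsion
phase, and discarding it would split QTLs arbitrarily. The `r` and `r²`
formulations are exactly equivalent under the magnitude convention, which
the suite asserts.

## The mixed-model scan

For one trait in one location the phenotype is the accession value `y`
(block-level inputs are aggregated to accession means before analysis). The
null model is

    y = mu + g + e,   g ~ N(0, sigma2_g K),   e ~ N(0, sigma2_e I),

fitted by REML through the spectral decomposition `K = U D U'`: after
rotating by `U'`, the restricted likelihood is a one-dimensional function of
the variance ratio `delta = sigma2_e / sigma2_g`, maximized on a 64-point
log grid over `[1e-8, 1e8]` followed by local refinement
(`stats::optimize`, tolerance 1e-8). The grid-then-refine scheme cannot be
beaten by an independent grid search, which the tests verify on random
toys; `sigma2_g` collapsing to the boundary is flagged, not an error.

Each marker is then tested as a fixed effect by generalized least squares
with `delta` held at the null estimate — the P3D/EMMAX strategy: one REML
fit per trait, closed-form 2x2 normal equations per marker, all markers
vectorized through one rotation. The residual scale is re-estimated per
marker from the GLS residual sum of squares, so with `K = I` the Wald
statistic `(alpha_hat / se)²` equals the squared OLS t statistic exactly.
Significance uses the asymptotic chi-square(1) reference. A marker's
explained variance is reported as the squared marginal correlation between
its scores and the phenotype.

An exact per-marker REML refit is deliberately not the default: at hundreds
of thousands of markers it buys little (variance components move negligibly
when a single marker enters the model) and costs three orders of magnitude
more time.

### Effective number of tests

The genome-wide threshold is `alpha / M_eff` with `M_eff` the
eigenvalue-based effective test count: per block, the eigenvalues `lambda`
of the marker correlation matrix are mapped through
`f(lambda) = I(lambda >= 1) + (lambda − floor(lambda))` and summed. Blocks
are scaffolds — the only linkage unit a fragmented assembly offers — and a
whole-panel eigendecomposition is avoided both for cost and because
cross-scaffold correlation is (mostly) population structure, which the
kinship already absorbs. Eigenvalues are rounded to 8 decimals before
flooring: an eigenvalue of 2 computed as `2 − 1e-15` would otherwise
contribute `f ≈ 2` instead of 1, a numerical trap of the published formula.

### Structure-correction diagnostic

For a random subsample of markers (3,000 by default) the scan is run twice —
with the kinship model and with simple regression — and observed `−log10 p`
values are paired with uniform-null expectations. The inflation statistic is
the median observed Wald chi-square over `qchisq(0.5, 1)`. On structured
polygenic panels the simple model inflates severely (≈ 3.5 at the default
null-simulation conditions) while the kinship model stays at 1 within a few
percent, reproducing the expected contrast.

## MultiQTL models

A QTL is a group of significant, mutually collinear markers represented by
the member explaining the most phenotypic variance. Forward selection
iterates: pick the candidate with the largest explained variance conditional
on the representatives already selected (ties: smaller p, then marker id);
absorb all remaining candidates with `|r| >= 0.3` *to the representative*
into its group; repeat on the rest. Two stop rules are implemented:

* **conditional** (default): stop when the best candidate's conditional
  t-test no longer passes the same genome-wide threshold as the scan. This
  is the conservative choice — a marker that adds no signal beyond the
  model should not found a new QTL.
* **marginal**: keep going until every significant marker is grouped. This
  reproduces procedures that rank markers by marginal association only.

The threshold-sensitivity scan (`collinearity_scan`) deliberately runs in
marginal mode: its purpose is to show how grouping granularity alone
reshapes the model as the `r` threshold moves, and under the conditional
stop rule the effect is invisible (a marker collinear with a selected
representative is never conditionally significant, so the model hardly
changes with `r`). Model explained variance is the squared correlation
between the least-squares fitted values on the representatives and the
observed phenotype, uncorrected for kinship — it approximates heritability
and is reported alongside an adjusted version accounting for the number of
representatives.

The significant-marker PCA treats markers as observations and accessions as
variables, so markers tagging one locus cluster; plotted against `−log10 p`
this substitutes for Manhattan peak tops when no coordinates exist.

## QTL regions across locations

Per trait, representative markers from the per-location models form a graph
with edges between markers of *different* locations at `|r| >= 0.3` (the
same marker id in two locations is trivially connected); regions are
connected components touching at least two locations. Components are a
single-linkage construction, so a region may contain a pair of markers whose
direct correlation is below threshold (connected through a chain); such
regions are flagged rather than split, since any split rule would be more
arbitrary than the flag. Within a location representatives are non-collinear
by construction, so no within-location edges exist at the default threshold.
A cross-trait report lists region pairs sharing representative markers or
scaffolds, the signature of co-localized QTLs for correlated traits.

## The synthetic panel generator

The generator reproduces the statistical features the analysis relies on,
with defaults chosen to mirror a realistic pooled-accession panel: 150
accessions in 5 subpopulations at pairwise FST 0.04 (weak differentiation,
as crop panels typically show), 200 scaffolds of 20–600 kb carrying 25
markers each, pool size 8, three trial locations.

* **Differentiation.** Ancestral frequencies are uniform on `[0.05, 0.95]`;
  subpopulation frequencies are Balding–Nichols beta draws with
  per-subpopulation drift parameters solved (least squares over pairs) so
  pairwise FST targets are met in expectation; a 50,000-marker draw lands
  within ±0.01 of target.
* **LD.** Haplotypes come from a Gaussian copula whose correlation between
  markers at distance `d` is `(1−c) exp(−d / 50 kb) + c`. The floor weight
  `c` is calibrated by numerically inverting the thresholded-Gaussian
  (tetrachoric) correlation, averaged over the ancestral frequency
  distribution, so the *allele-level* `r²` floors at the configured 0.1; a
  closed form at `p = 0.5` under-shoots by a third. A configurable minority
  of markers (2%) copies its haplotypes, with 5% flips, from a marker on
  another scaffold — the strong long-range correlations that drift and
  selection create in real panels.
* **Pooling.** An accession's score is the count of the tracked allele
  among its `2p` haplotypes over `2p`, hence exactly on the grid. One
  latent "founder" path per accession, blended at weight `accession_f`
  (default 0.2), makes haplotypes within a seed lot resemble each other —
  the within-accession heterogeneity knob the data themselves do not pin
  down.
* **Phenotypes.** Causal markers are drawn from the QC-eligible panel under
  mutual `|r| < 0.3`; each explains exactly its configured share of
  phenotypic variance per location (effects scaled by realized score SD).
  The polygenic background is drawn with covariance proportional to the
  realized kinship; the residual is standardized, orthogonalized to the
  genetic component, and scaled so realized per-location broad-sense
  heritability equals the target exactly. G×E is a latent correlation of
  per-location effect *directions* (and of the polygenic draws): at 1,
  genetic effects are identical across locations; below 1, effect signs may
  flip between locations while each QTL keeps its variance share.

The recovery experiment plants 5 QTLs of 11% variance each under `H² = 0.6`
(the remaining 5% polygenic), the middle of the feasible band once 5 QTLs of
at least 8% must fit under 0.6. Power arithmetic worth knowing when reading
the acceptance report: an 11%-variance QTL in 150 accessions carries a Wald
noncentrality near 18.5, while the Bonferroni threshold at
`M_eff ≈ 2500` sits near a critical chi-square of 18 — per-location
detection probability is therefore only ≈ 0.35–0.5 (kinship correction
absorbs part of the causal signal on top), union-over-three-locations power
≈ 0.6–0.9, and two-location region recovery ≈ 0.3–0.5. These are properties
of the study conditions, not of the estimator; the same scan detects a
15%-variance QTL in over 90% of replicates.

What the generator does **not** emulate: sequencing and SNP-calling error,
unequal pool contributions, within-scaffold assembly errors, admixture
gradients (subpopulations are discrete), missing phenotypes, and selection.
Passing tests therefore certify the statistical machinery under the stated
structure, not performance on any particular real panel.

## Numerical choices and degenerate inputs

* Positions are 1-based; distances are plain coordinate differences.
* All thresholds are validated into `[0, 1]` (`alpha` into `(0, 1)`).
* Tables are TSV with a header; floats are written with 6 significant
  digits, and every writer/reader pair round-trips to that precision.
* Frequency rows not summing to 1 within 0.01 are flagged, not dropped.
* `pchisq(..., log.p = TRUE)` underpins `−log10 p`, so extreme associations
  keep exact exponents; reported p-values are floored at the smallest
  positive double.
* A zero-variance marker column is an error after QC and `NA` in `r²`.
* Empty QC survivor sets warn and return an empty panel; empty significant
  sets produce an empty MultiQTL model with explained variance 0; region
  matching with fewer than two location models is an error.
* Test and acceptance problem sizes (panels of 120–150 accessions and
  1,500–5,000 markers, 20–50 replicates per experiment) were chosen so each
  experiment's Monte-Carlo error is small relative to its assertion band
  and the full suite completes in minutes.

## Known limitations

* P3D variance components are not refit per marker; for very large marker
  effects the Wald statistic is slightly conservative relative to an exact
  refit.
* The chi-square(1) reference ignores the finite-sample t correction; at
  `n = 123`-scale panels this is a few percent anti-conservative in the far
  tail, one reason the family-wise null hit rate reported by the acceptance
  script runs above nominal while the marker-level rate stays far below
  `alpha`.
* Li–Ji effective-test counts under floor-level LD undercount mildly,
  compounding the previous point; both are reported transparently rather
  than hidden behind a recalibrated threshold.
* Explained variances of forward-selected models are winner's-curse-biased
  upward, as in any selected-model fit; the adjusted value mitigates but
  does not remove this.
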