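---
title: "Methods: from 2DE gel images to sample clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 2DE gel images to sample clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelclust)
```

# The problem

Two-dimensional electrophoresis separates a protein mixture by isoelectric
point and molecular weight; after staining, each protein species appears
as a spot on the gel, and each biological sample yields one image. With no
clinical labels, analysis is unsupervised: reduce each gel to a spot list,
align spot identities across gels, and ask whether the samples form
groups — and whether those groups agree with an external partition of the
same samples obtained by an entirely different assay.

Silver staining, the sensitive stain used for gels of this kind, is
notoriously variable in intensity between technical runs. The pipeline
therefore treats *intensity* as a quality-control and secondary-testing
quantity, and clusters on *presence/absence* only: the data object at the
centre of the package is the binary matrix $D$ with $d_{ij} = 1$ iff spot
$j$ was called on gel $i$.

# Spot detection

`detect_spots()` is a scale-normalized Laplacian-of-Gaussian (LoG) blob
detector, the standard scale-space construction for round bright blobs:

* The image is polarity-corrected so spots carry high values
  (dark-on-light scans are inverted as $\max(I) - I$; using the observed
  maximum keeps raw intensities proportional under image rescaling).
* The response $\sigma^2 (\nabla^2 G_\sigma * I)$ (sign-flipped so blobs
  are maxima, mean-subtracted kernel so flat images respond exactly zero)
  is evaluated on a geometric ladder of `n_scales` scales in
  `[sigma_min, sigma_max]`.
* Candidates are local maxima of the 3-D (x, y, scale) response above
  `threshold_rel` times the global maximum. The threshold is *relative*,
  which makes detection invariant to multiplying the image by a constant.
* Overlaps are suppressed greedily by descending response; a candidate
  within $\sqrt{2}\sigma$ of an accepted spot (the LoG zero-crossing
  radius at the accepted scale) is dropped. Ties are ordered by scale,
  then row, then column, so detection is fully deterministic.
* A spot's region is the disk of radius $\sqrt{2}\sigma$ clipped to the
  image; its raw intensity is the pixel sum over the region. Disk regions
  are a reproducible stand-in for manual outlining, which cannot be
  replayed; a recorded manual edit can be applied with
  `apply_spot_patch()`.

Defaults: `sigma_min = 2`, `sigma_max = 8` pixels (spot radii of roughly
3–11 px at typical mid-format gel scans), `n_scales = 6`,
`threshold_rel = 0.1`. On synthetic gels with 200 planted spots the
detector is exact (recall = precision = 1) down to a signal-to-noise
ratio of 10; the test suite asserts $\ge 0.95$ for both.

# Matching and matrix assembly

`match_to_master()` pairs each gel's spots with a designated master gel by
greedy one-to-one assignment in ascending Euclidean distance, keeping
pairs within `tolerance` (default 3 px; ties broken by ascending spot
ids). A similarity-transform pre-registration (closed-form SVD fit,
consensus over random minimal samples) is available but off by default:
spot lists produced from scans that were already aligned by hand must not
be silently re-warped.

`build_matrices()` turns correspondences into the binary and intensity
matrices. Columns are the master spots; optionally, unmatched spots that
co-locate across at least two distinct gels (greedy centroid
agglomeration within the tolerance) open additional *union* columns. This
reflects how a master-gel alignment accumulates more columns than any
single gel carries — an 18-gel series averaging ~271 spots per gel can
legitimately span a 389-column universe — while refusing to create a
column for every singleton noise detection. Both modes (master-only and
union) are provided because either assembly convention is defensible;
union is the default. Intensities are normalized per gel over its matched
spots, so each row of the intensity matrix sums to 1 over present cells;
absent cells are `NA`, never zero.

# Replicate quality control

`qc_report()` summarizes a replicates-by-spots intensity matrix:

* **Pearson r** between runs is computed on the common-presence subset
  (spots detected in both runs), not on zero-imputed vectors: imputing
  zeros manufactures correlation out of detection agreement. The mean r
  is reported with a $1.96\,\mathrm{SD}/\sqrt{\#\text{pairs}}$ half-width
  (a mean ± 95% CI convention).
* **Q–Q points** pair order statistics after interpolating both samples
  to the shorter length on the `ppoints` grid.
* **CV** per spot is the sample (n−1) SD over the mean, over spots
  present in all replicates; with four replicates the (n−1) choice
  matters and is the convention small replicate series use.
* **Consensus counts**: spots present in ≥ k replicates for each k.
* **Intensity classes**: fractions below 0.02, in [0.02, 0.04), in
  [0.04, 0.1) and at ≥ 0.1 relative units, left-closed at each boundary.

# Clustering and concordance

`hamming_dist()` computes bit-difference counts between gel rows. For 0/1
vectors the Hamming distance *is* the squared Euclidean distance, which
makes Ward's minimum-variance criterion a natural partner: `ward_linkage()`
applies the Lance–Williams recurrence with
$\alpha_i = (n_i + n_k)/(n_i + n_j + n_k)$, $\beta = -n_k/(n_i+n_j+n_k)$,
$\gamma = 0$ to the distances *as given* — the classic `ward.D`
convention of R's hierarchical clustering, which this package's analysis
lineage used. A `ward.D2` flag squares the input and square-roots the
heights for users who prefer the other convention; on Hamming input the
two can order merges differently, so the choice is explicit.

The linkage is implemented in the package rather than delegated, for one
reason: determinism under ties. Binary data produce exactly tied
dissimilarities routinely; merges here resolve ties by the smallest
(minimum original leaf index, second leaf index) pair, with a relative
$10^{-9}$ tolerance deciding what counts as tied. `stats::hclust` leaves
tie order unspecified, so it serves as an independent cross-check on
tie-free data in the tests (where the two agree merge-for-merge), and an
$O(n^4)$ brute-force agglomerator that re-derives every cluster-pair Ward
distance from the raw rows via the centroid form
$D(A,B) = \tfrac{2|A||B|}{|A|+|B|}\lVert \bar{x}_A - \bar{x}_B \rVert^2$
is the oracle on random binary matrices.

`cut_tree()` relabels `stats::cutree` output in order of first sample
appearance, so a given tree always yields the same labels.
`silhouette_widths()` (via the **cluster** package) and
`permutation_validity_test()` assess cluster validity: the permutation
test shuffles cluster labels `n_perm` times and reports
$p = (1 + \#\{\text{permuted mean silhouette} \ge \text{observed}\})/(n_\text{perm}+1)$.
This is a generic exchangeability test, chosen because silhouette-based
"confidence" procedures in the literature are rarely specified precisely
enough to reconstruct; it is a stand-in, labelled as such, not a
reconstruction of any particular published procedure.

`compare_partitions()` computes the Hubert–Arabie *adjusted* Rand index
from the pair-count contingency table. On the two published 18-sample
partitions this gives 0.5817 → 0.58 at two decimals; the unadjusted Rand
index would be 0.79, so the printed 0.58 identifies the adjusted form as
the statistic actually used, and that is what the package reports.

# Differential spots

`cluster_specific_spots()` applies the qualitative rule: spot $j$ is
exclusive to cluster $c$ iff its presence frequency is $\ge \tau_{present}$
in $c$ and $\le \tau_{absent}$ elsewhere, defaulting to the strict 1/0
("present only in…") reading. `intensity_difference_test()` handles the
quantitative side for spots present in at least `min_presence` gels per
cluster (default 3): Welch's unequal-variance t-test — chosen over the
pooled-variance test because the cluster sizes are unequal (11 vs 7) and
nothing supports variance homogeneity — with Bonferroni correction across
the tested spots, matching the correction convention of the analysis this
package descends from. Absent spots are excluded, not zero-imputed: a
non-detection is censoring, and the qualitative rule already handles it.

# The synthetic-data generator

The generator defines the study conditions the package is tested under:

* **Universe and groups**: 389 master-spot columns; 18 gels in planted
  clusters of 11 and 7; 3 spots exclusive to cluster 1 and 12 to
  cluster 2.
* **Shared fraction** 0.68: not a printed quantity; chosen once so a
  typical simulated gel carries ~271 present spots, the reported per-gel
  mean of the emulated experiment (0.68 × 389 ≈ 265 shared + exclusives).
* **Flip rate** (default 0.02): each presence bit toggles independently —
  the simplest exchangeable noise on a binary matrix. Mean within-cluster
  Hamming distance is then $2p(1-p)\times 389$, which the tests verify in
  closed form.
* **Intensities**: per present spot, a class is drawn from the fractions
  0.96 / 0.02 / 0.01 / 0.01 (the third class is not separately reported
  anywhere; 0.01 is the value that makes the printed fractions sum to 1,
  and is flagged as an inference in the configuration docs), then a
  lognormal value with median inside the class (0.028 / 0.065 / 0.15 for
  the upper classes, sdlog 0.15). The lowest-class median is solved per
  gel so the expected pre-normalisation total is 1; per-gel
  renormalisation then barely moves values across class boundaries, which
  keeps the realised fractions on target (the tests check 3-SD
  multinomial agreement at 10,000+ draws). This construction degrades if
  a gel carries more than ~375 present spots (the upper classes alone
  then exceed the budget; the solved median floors at $10^{-5}$) — far
  outside the emulated regime.
* **Replicates**: multiplicative lognormal noise with
  $\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}/c_4(n)$ — the $c_4$
  small-sample factor inflates the generating sigma so that sample CVs
  *measured* from `n_replicates` runs center on `replicate_cv` instead of
  sitting ~15% below it — plus Bernoulli dropout (default 0.1) for spot
  non-detection, then per-replicate renormalisation. With the default
  CV 0.5 a clear majority of fully-present spots show CV < 0.6, and
  run-to-run Pearson r lands around 0.7, both matching the reproducibility
  regime the generator emulates.
* **Images**: spot centers are placed uniformly with a minimum separation
  of $3\sigma_{psf}$ by rejection sampling (closer pairs are exactly the
  cases a manual analysis would have resolved by hand) inside a
  $4\sigma_{psf}$ margin; the image is background + Gaussian bumps +
  optional white noise, clipped to [0, 1] and inverted for dark-on-light
  polarity.
* **Determinism**: every stage uses the configuration seed plus a fixed
  stage offset (prototypes +0, flips +1, intensities +2, replicates +3),
  so artifacts are bit-reproducible individually and jointly.

What the generator does *not* emulate: spatial warping between gels
(pH-gradient nonlinearity), streaks and background gradients, staining
chemistry, correlated spot dropout, or intensity correlation structure
between neighbouring spots. Passing the pipeline's recovery benchmarks on
synthetic data therefore demonstrates correctness of the algorithms under
the stated noise model, not performance on warped or artifact-laden real
scans — the matching stage in particular sees geometrically clean spot
lists here.

# Numerical choices and edge cases

* Probabilities and class fractions are validated on construction; class
  fractions must sum to 1 within $10^{-9}$.
* A gel with zero present spots cannot be normalized and errors.
* Zero-variance runs make Pearson r undefined; it is returned as `NA`
  with a warning rather than silently dropped.
* `t.test` failures on degenerate (essentially constant) inputs yield
  `NA` p-values, which Bonferroni propagates and the `significant` flag
  treats as not significant.
* Ward tie tolerance is relative ($10^{-9}$); Hamming distances are
  integers, so mathematically distinct Lance–Williams values at $n \le 8$
  are separated by far more than the tolerance.
* Coordinates are 0-based pixel centers throughout; distances are
  Euclidean in pixels.

# Problem sizes used in the checks

The test suite exercises the planted-recovery claim over 100 seeds at
flip rate 0.05 (expected recovery ≥ 95%; observed 99%), the Ward oracle
on 200 random matrices with up to 8 gels, detection on 448×448 images
with 200 spots at noiseless and SNR-10 conditions, and family-wise error
control over 500 null simulations of the full 18×389 design. These sizes
were chosen to give the Monte-Carlo assertions comfortable margins at
desk scale.

# Limitations

* Master-gel matching is nearest-neighbour within a tolerance; it has no
  elastic registration, so strongly warped gels need external alignment
  first.
* The 389-column assembly convention of the emulated study (master-only
  vs union columns) is not recorded anywhere; both modes exist and
  default to union.
* The relationship between automatic detection counts and manually
  curated counts on the same gel (687 vs 449 in the emulated study) is
  unresolvable without the original scans; the detector's thresholds are
  free parameters, not calibrated to either number.
* The permutation validity test is a stand-in for an unspecified
  published procedure and should be reported as such.
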