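---
title: "Statistical methods for BLA population imaging and spatial mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for BLA population imaging and spatial mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blamap)
```

## What the package analyses

Genetically defined neuron populations of the basolateral amygdala (BLA)
respond differentially to appetitive cues (food), social stimuli and aversive
events (footshocks). `blamap` implements the statistical machinery used to
quantify those responses from single-cell calcium imaging — deconvolved spike
trains aligned to a behaviour trajectory — together with the transcriptomic
side of the problem: selecting marker genes from a clustered single-nucleus
expression matrix and mapping spatially resolved smFISH cells onto those
clusters. Every analysis can be exercised end to end on seeded synthetic data
with known ground truth.

## Distance tuning: model and test

For a recording at 15 frames/s, each frame carries the Euclidean distance
between the animal and a target (food container or wired social cage),
normalized by the chamber radius and clipped to $[0,1]$. The normalized
distance axis is split into $B = 31$ equal-width bins (left-closed,
right-open, last bin closed), and a neuron's tuning profile is the mean
inferred spike count per frame within each bin. The preferred distance is the
bin with the highest mean rate (ties go to the nearest bin; the bin center,
converted back to cm, is the neuron's peak distance). Zones follow the
behavioural definitions: a peak at or inside the inner radius is *pro*
(5 cm for food, 10 cm for social), strictly beyond the outer radius is *anti*
(17 cm / 20 cm), otherwise *neutral*.

Significance is assessed with a rotary-shuffle permutation test. A circular
shift of the spike train by a uniformly drawn offset $k \in \{1,\dots,T-1\}$
preserves the train's values and autocorrelation but breaks its alignment
with behaviour. The test statistic is the maximum binned mean rate; the null
distribution is that statistic over 1,000 shuffles of the neuron's own train
against the fixed distance series, and the add-one p-value
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{shuffles})$ is never
exactly zero, so Benjamini–Hochberg correction (FDR 5%, applied across the
neurons of one recorded population) is well defined. A constant or all-zero
train yields $p = 1$ by construction.

### Numerical choices

* **Minimum bin occupancy.** The mean rate of a bin visited for only a
  handful of frames is so noisy that it dominates the maximum for both the
  observed and the shuffled trains; under a random-walk trajectory the bins
  nearest the target hold as few as 5 of 9,000 frames. Bins with fewer than
  `min_occupancy` frames (default 20, about 1.3 s at 15 Hz) are therefore
  excluded from the peak statistic — identically for the observed statistic
  and every shuffle, so the permutation test remains exact. Setting
  `min_occupancy = 1` restores the all-occupied-bins statistic. Unoccupied
  bins are always excluded.
* **Fast null evaluation.** The binned sums of a circularly shifted train,
  for *all* offsets at once, are circular cross-correlations of the train
  with the bin indicator vectors and are computed via FFT, then subset at the
  sampled offsets; this is algebraically identical to explicit shifting
  (`method = "direct"`, kept and tested) and two orders of magnitude faster.
  Null-versus-observed comparisons use a $10^{-9}$ tolerance: distinct exact
  statistics are ratios of bounded counts separated by far more than FFT
  round-off, so the tolerance only converts exact ties (e.g. constant
  trains) into ties.
* **Reproducible per-neuron streams.** Each neuron's shuffle offsets derive
  from the seed and a hash of the neuron id, so p-values do not depend on
  neuron order or on which other neurons are present.
* **Clipping.** Distances beyond the normalizer (rectangle corners) clip to
  1.0, keeping the bin domain fixed.

## Population composition test

To compare the fraction of, say, pro-food neurons across genetically defined
populations, the per-neuron zone labels of all populations are pooled. For a
target population of size $N$, the null draws $N$ labels from the pool
without replacement, 1,000 times, and records the zone percentage of each
draw; the observed percentage is called *above*/*below* when it exceeds the
empirical $1-\alpha$ / falls below the $\alpha$ quantile with
$\alpha = 0.025$ (a two-tailed test at the 2.5% level per tail). Labels are
fixed once and only resampled — significance is not recomputed within
resamples. On small pools this decision agrees with the exact hypergeometric
quantile rule, which the test suite checks.

## Event-locked response scores

All response scores share one contrast,
$\mathrm{score} = (F_A - F_B)/(F_A + F_B) \in [-1, 1]$, defined as 0 when
both rates vanish; $+1$ means activity only under condition $A$ (maximal
activation), $-1$ maximal inhibition.

* **SRC (shock response score).** $F_\text{during}$ and $F_\text{before}$
  are mean rates in the 2 s from and before each shock onset (30 frames at
  15 Hz; half-open windows $[t-2\,\mathrm{s}, t)$ and $[t, t+2\,\mathrm{s})$).
  The neuron's score is the unweighted mean of per-event contrasts; events
  with truncated windows are skipped. Responder classification shuffles the
  whole train rotary-wise, recomputes the mean SRC per shuffle, and calls
  *pro* / *anti* when the observed score passes the upper / lower 2.5%
  empirical quantile of the null.
* **SoRC (social response score).** Contrast between social-interaction and
  non-social frames. A frame is social when the animal is within 10 cm of
  the container center *and* its heading points at the container within 45°.
  The angular threshold is configurable; 45° is a conventional head-direction
  cone, and no published value constrains it. Strictly positive scores are
  *social ON*, all others *OFF*.
* **Freezing score.** The same contrast over a freezing frame mask. Masks
  are inputs (video-based freezing detection is out of scope); bouts shorter
  than 2 s are dropped before scoring, matching the usual minimum-duration
  convention.

Linear relationships between such statistics (e.g. SRC vs SoRC, or freezing
frequency vs fraction of pro-shock neurons) are summarized by ordinary least
squares with a two-sided t-test on the slope.

## Marker selection and cluster profiles

For each (gene, cluster) pair, one-vs-rest separability is the area under
the ROC curve, computed from mid-rank Mann–Whitney statistics, alongside the
percentage of expressing cells (count > 0) inside and outside the cluster. A
gene passes when AUC > 0.5 (strict, so an uninformative gene never passes),
pct_in ≥ 20 and pct_out ≤ 20 — strictness mirrors the documented behaviour
of the standard marker-screening tools; the top 5 passing genes per cluster
are ranked by AUC. Candidate reporting is where the automated step ends:
picking the final panel is curation.

Cluster reference profiles aggregate (sum) raw counts per cluster and gene,
then scale each gene by its maximum across clusters, giving values in
$[0,1]$ with every expressed gene peaking at exactly 1. Sums rather than
means keep the aggregation faithful to read counts; the per-gene max-scaling
makes profiles comparable across genes of very different absolute
expression. The cluster dendrogram is average-linkage agglomeration on
Euclidean distances between profile rows; only the metric is fixed by
convention, so the linkage is a configurable option.

## smFISH quantification and cluster assignment

* **Positive-cell calling.** The original workflow thresholds fluorescence
  per gene by double-blind visual inspection; the package substitutes a
  reproducible automatic default — per-gene Otsu thresholding on log1p
  values (exhaustive between-class-variance search), with quantile or fixed
  per-gene overrides. A cell is positive when its raw value strictly exceeds
  the threshold.
* **Subregion fractions.** Percentages of positive cells per gene within
  each of the eight BLA subregions (aLA, pLA, ppLA, amBA, alBA, acBA, pBA,
  ppBA across four coronal sections). Cells positive for several genes count
  once per gene, so per-subregion sums may exceed 100%. Empty subregions are
  flagged and excluded from the Pearson cross-correlation between subregion
  fraction vectors (ordered by average-linkage clustering of $1-r$).
* **Eigen-images.** Per gene and section, positive cells are rasterized
  onto a 50 µm pixel grid and Gaussian-smoothed (σ = 1 px); the pixels ×
  genes matrix is column-centered and the gene-gene covariance
  eigendecomposed, so variance fractions over all gene dimensions sum to 1
  exactly. PC score maps are the eigen-images; the cumulative variance of
  the top 4 PCs summarizes how compactly the marker maps are described.
  Pixel size and smoothing are explicit configuration because the upstream
  description of the images fixes neither.
* **Local normalization and assignment.** Each cell's feature vector is the
  sum of raw values over all same-section cells within 50 µm (boundary
  inclusive, self included), z-scored per gene across the section's cells.
  The phrase "normalized z-scores within a radius of 50 µm" admits two
  readings — neighbourhood smoothing followed by global z-scoring, or
  z-scoring against local statistics; the first is the default here because
  it is stable for sparse neighbourhoods, and the radius/reading are
  configurable. Z-scoring is per section (whether it should span sections is
  unstated upstream; per section avoids section-to-section intensity
  batch effects). Cells are assigned to the transcriptomic cluster whose
  scaled profile row has the highest Pearson correlation with their feature
  vector; ties break to the lowest cluster id, no minimum-correlation
  threshold is applied, and zero-variance feature vectors stay unassigned.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known ground truth:

* **Trajectories.** A reflected Gaussian random walk inside a circular or
  rectangular arena at 15 frames/s (default step SD 1.5 cm ≈ 22 cm/s RMS
  speed, a realistic free-exploration pace). Reflection keeps long runs
  ergodic over the arena, so all distance bins stay occupied. Real mice
  hover near goals and freeze; the walk has no goal-directed statistics, so
  near-target occupancy is *lower* than in real feeding assays.
* **Spike trains.** Poisson counts per frame with rate
  $\lambda(t) = b + a\,\exp(-(d(t)-d_0)^2/2\sigma^2)$ in normalized
  distance (σ default 0.1 — the minimal shape making "peak distance" well
  defined), or with a multiplicative gain (default 3×) inside event windows
  for planted responders. Counts are integers even though spike inference
  yields reals; all analyses accept nonnegative reals.
* **Expression and smFISH.** Negative-binomial counts around per-cluster
  scaled means; smFISH cells are placed uniformly in rectangular subregion
  tiles over the four sections, draw a true cluster from a per-subregion
  mixture, and take profile-proportional raw values plus truncated Gaussian
  noise.

Passing recovery tests on these data shows the *statistics* behave as
designed (calibrated false-discovery control, sensitivity to planted
effects, exact oracle agreement); it does not validate the biological
assumptions of any particular recording, nor calibrate the generators to
real occupancy statistics, GCaMP kinetics or transcriptome-wide structure.

## Problem sizes used in the shipped checks

The calibration checks run at the study scale the analysis is designed for:
9,000 frames (10 min at 15 Hz), 31 bins, 1,000 shuffles, 200 neurons per
replicate and 20 replicates for false-discovery calibration; 2,000
replicates of the composition test's exchangeable null; 100 seeds for
responder-classification recovery. Oracle-equivalence checks use small
instances where brute force is exact.

## Known limitations

* The permutation test conditions on the recorded trajectory; it does not
  model session-to-session behavioural variability.
* BH grouping is per recorded population and session type; other groupings
  change which neurons share the correction.
* The composition test treats zone labels as fixed when resampling; it does
  not propagate uncertainty from the upstream significance calls.
* Subregion labels of smFISH cells are inputs; the package draws no
  anatomical boundaries and performs no section registration.
* `ols_fit` is deliberately plain two-variable least squares; anything
  richer should go through `stats::lm` directly.
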