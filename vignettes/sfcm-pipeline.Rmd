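---
title: "Semi-automated gating, grouping and biovolume estimation for scanning flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-automated gating, grouping and biovolume estimation for scanning flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A scanning flow cytometer (SFCM) records, for every particle that crosses
its lasers, a time-resolved intensity pulse on each of six optical channels:
forward and sideward scatter (`FWS`, `SWS`) and four fluorescence bands
(`FL.Red`, `X2.FL.Red`, `FL.Orange`, `FL.Yellow`) that respond mainly to
chlorophyll-a, phycocyanin (642-nm-stimulated red), phycoerythrin, and
carotenoids or decaying pigments. Each pulse is summarized into scalar
pulse-shape traits, so a monitoring campaign yields, per water sample, a
table with one row per particle and tens of trait columns. Most recorded
particles are not live phytoplankton at all — bacteria, detritus, dead
cells and electronic noise dominate — and no images are available to sort
this out by eye at scale.

`sfcmflow` implements a repeatable, semi-automated protocol for such data:

1. **Cleaning.** Separate live cells from everything else.
2. **Grouping.** Assign live cells to phytoplankton functional groups
   (cyanobacteria, chrysophytes, cryptophytes, green algae) from their
   pigment signatures.
3. **Quantification.** Estimate each cell's biovolume (um^3) with a
   regression forest trained on lab cultures, and aggregate per-sample cell
   densities (cells/mL) and biovolumes (um^3/mL) for the whole community and
   each group.

The design rests on two tools used in three roles: an unsupervised
density-peak clusterer finds trait clusters in a pooled data subset, and
random forests (i) rank trait importance, (ii) classify every particle into
those clusters, and (iii) regress biovolume on the trait vector.

## Pulse-shape traits

For each channel the package derives `Maximum`, `Minimum`, `First`, `Last`,
`Total` (area, mV um), `Average`, `Range` (Maximum − Minimum), `Length`
(samples x step, um), `Fill.factor` (area over bounding-rectangle area),
`Gradient` (mean absolute first difference per um) and `Number.of.cells`
(count of local maxima with topographic prominence of at least a quarter of
the pulse range), plus the `Red1Red2.ratio` of the two red fluorescence
areas — 67 traits per particle. The instrument's own parameter definitions
are not public; these are explicit, testable reconstructions, each exposed
as its own function so an instrument-exact definition can be substituted.
Three choices deserve note:

* `Range` is Maximum − Minimum rather than Maximum alone, so it behaves
  sensibly under a baseline offset.
* `Red1Red2.ratio` uses pulse areas, not maxima; areas are more robust to
  single-sample noise. The ratio of 488-nm to 642-nm stimulated red
  fluorescence is the key cyanobacteria marker: phycocyanin-rich cells
  fluoresce strongly under the 642 nm laser and show low values.
* The peak-prominence threshold for `Number.of.cells` defaults to 0.25 x
  Range: low enough to resolve the cells of a colony (adjacent bells in
  single file dip well below 75% of the peak), high enough to reject
  sampling noise.

## Preprocessing

Traits whose minimum is strictly positive are log10-transformed (pulse
traits are strongly right-skewed; the decade scale is the cytometry
convention, and the flagged set is recorded so the transform is exactly
invertible). Then one member of every trait pair with |Pearson r| > 0.8 is
removed — later column in input order, a deterministic and documented rule —
because collinear traits destabilize both importance rankings and
clustering. Finally, because a season of monitoring is too large to cluster
at once and per-sample clustering would not be comparable across samples,
an equal number of particles is drawn from every sample into a pooled
subset of about 100,000 rows.

## Cleaning and grouping passes

Both passes share one template. A forest with 10,001 trees is trained on a
lab-culture table (live vs other signals for cleaning; functional group for
grouping, live rows only) and traits are ranked by Gini mean-decrease
importance, ties broken lexicographically. The top 10 (cleaning) or top 8
(grouping) traits are kept — enough to separate the classes while staying
clear of the curse of dimensionality that afflicts density clustering. The
pooled subset, restricted to those traits, is clustered (next section).
In the cleaning pass, clusters whose median log10 `FL.Red.Range` — the
chlorophyll proxy — exceeds the dimmest reference cluster's by at least one
decade (`live_margin_log10 = 1`) are flagged as live. The reference is
restricted to clusters holding at least 1% of the subset
(`live_reference_min_fraction`): the pooled non-cell cluster is always
large, whereas a micro-cluster of dead-flat pulses can have a zero median
range (no finite log) and must not hijack the reference. A config override
(`live_clusters_override`) is the codified form of the manual-inspection
escape hatch. A 1,001-tree forest is then trained on the cluster labels and
classifies *every* particle of *every* sample; its out-of-bag error is the
pipeline's internal accuracy check. Particles in live clusters are
retained; the retained fraction per sample is the live fraction used later
for densities.

In the grouping pass, clusters holding at least 5% of the subset
(`min_group_fraction`) are assigned to groups by ordered rules distilled
from the pigment physiology:

1. lowest `Red1Red2.ratio` (below `cyano_ratio_ceiling = 1`) →
   cyanobacteria;
2. jointly lowest `X2.FL.Red.Gradient` and `FL.Red.First` (lowest rank sum),
   with an intermediate ratio → cryptophytes;
3. highest remaining ratio (high `FL.Red.Range` recorded in the rationale)
   → green algae;
4. most abundant remaining cluster → chrysophytes.

Rarer clusters stay `unassigned`: they are kept in whole-community totals
but excluded from per-group totals. Every assignment records a
human-readable rationale, ties break toward the lower cluster id with a
warning, and rules for groups absent from the system (diatoms,
dinoflagellates) are deliberately not invented. Only the cyanobacteria rule
has a strong a-priori basis; the other assignments are heuristics whose
thresholds are exposed in the configuration.

## Density-peak clustering

The clusterer follows the overcluster-then-merge idea of density-peak
k-means merging. On standardized data (zero mean, unit SD per selected
trait — the traits live on mixed log scales and the `tol` distance needs a
common unit):

1. k-means overclusters into `k0 = max(8, floor(sqrt(n)/2))` components
   (capped at 200), with k-means++ seeding, 10 restarts, best inertia kept
   (Lloyd iterations, `iter.max` 100);
2. each component gets a smoothed covariance `h S_k + h0 Lambda k0^(-2/d)`,
   where `S_k` is the component covariance and `Lambda` the diagonal of the
   overall covariance — `h` scales within-component structure, `h0` a
   floor that keeps tiny components full-rank;
3. the density is the resulting Gaussian mixture; every component mean is
   hill-climbed to its peak by gradient ascent on the log density with
   backtracking line search, stopping when the accepted step falls below
   `tol/100` or after `max_climb_iters = 100` iterations;
4. components merge when their peaks are within Euclidean distance `tol`,
   or when the minimum density along their connecting segment (20 sample
   points) is at least `(1 - tol)` times the lower peak density (no dip
   between them); merging is transitive, and final clusters are relabeled
   by descending size so cluster 1 is always the largest.

Defaults `tol = 0.25`, `h0 = 0.05`, `h = 2` are the working values for this
protocol; the best values are data-dependent and exposed in
`cluster_params()`. Numerical details: singular smoothed covariances are
regularized by adding `1e-6 Lambda` with a warning; densities are computed
in log space throughout (the dip test compares `log f` against
`log(1 - tol)` plus the lower peak's log density), so nothing underflows in
ten dimensions; a constant column is left unscaled with a warning.

Two known limitations. First, the merge rule is designed for the regime the
pipeline operates in — clusters separated by several within-cluster SDs.
When components overlap heavily (separations around 3 SD and below) and the
bandwidth is small, hill climbs stall on low-contrast local bumps and the
pairwise dip test can chain across genuine valleys, so the cluster count is
no longer monotone in `h`; the monotonicity property is therefore tested at
4 SD separation, and results on strongly overlapping data should be read
with care. Second, this is a behavioral reconstruction: it recovers
well-separated structure exactly and responds to `tol`/`h0`/`h` in the
expected directions, but it is not bit-compatible with any particular
implementation of the published algorithm; the `ClusterModel` contract
isolates it so a different engine can be swapped in.

## Biovolume and aggregation

A 10,001-tree regression forest is trained on all 67 traits of the live
lab-culture rows against log10 biovolume. The log scale matters: training
biovolumes span 13.4 to 15,478.7 um^3, three orders of magnitude, and a
linear-scale fit would be dominated by the largest species; the out-of-bag
R^2 is reported on the log10 scale for the same reason. Predictions are
back-transformed to um^3, are strictly positive, and — being forest means —
lie within the training target range. Odd tree counts (10,001 / 1,001 /
10,001) avoid voting ties.

Aggregation is deliberately elementary: community density = particle
concentration (particles/uL) x 1000 x live fraction; group density =
community density x the group's fraction of retained cells (computed from
the classifier labels of *all* retained particles); total biovolume =
density x arithmetic mean predicted biovolume of the sample's cells, and
likewise per group. These identities conserve exactly: group contributions
plus the unassigned contribution reproduce the total to 1e-9 relative, and
the tests assert it.

`validate_loglog()` implements the comparison against an independent
(microscopy-style) estimate: Pearson r and OLS of log10(SFCM) on
log10(reference) with 95% CIs, read against the 1:1 line. Zeros in the
reference are replaced by half the detection limit (28 cells/mL is the
working default for microscopy counts; the factor is configurable), and an
optional rule excludes points with leverage above three times the average
(hat value > 6/n) and reports them — a codified form of "a small number of
high-leverage points were excluded".

## The synthetic data generator

The generator stands in for instrument and lab data; it is first-class,
tested code. Each species archetype is a pulse-level generative model: per
channel, a particle is one or more Gaussian intensity bells whose amplitude
is lognormal around the archetype's channel signature (mV) and whose width
scales with the equivalent-sphere cell diameter, so transit length grows
with biovolume^(1/3); colonies are six overlapping bells (with rare 5- and
7-cell exceptions) and filaments a geometric number; a positive baseline
noise floor sits under everything; and the recorded window is truncated to
where sideward scatter exceeds the 99.7 mV trigger, as in the instrument.
The spatial step is 0.125 um per sample, chosen so that the recorded window
length stays quasi-continuous even for the smallest (~3 um) cells — at a
coarser step the integer sample count makes transit-length traits visibly
discrete and can split a species into artificial clusters.

Channel signatures encode the pigment physiology the grouping rules rely
on, so those rules are recoverable by construction: cyanobacteria have
strong `X2.FL.Red` (ratio about 0.5), cryptophytes carry phycoerythrin
(high `FL.Orange`) with narrow chlorophyll bells and smooth, weak `X2`
pulses (low `FL.Red.First` and `X2.FL.Red.Gradient`, ratio about 2.5),
green algae have almost no phycocyanin (ratio about 9), chrysophytes sit in
between (about 4.4). Ten archetypes with lab-measured mean biovolumes
(13.4 um^3 *Synechococcus* to 15,478.7 um^3 *Anabaena*) make up the
training panel; within-species biovolume jitter is lognormal with CV 0.15,
and channel noise adds a further 10% CV.

The default field scenario is 50 samples of 10,000 particles at six cycled
depths: 95% of particles come from a single low-fluorescence, high-variance
noise component (bacteria, detritus and electronic noise pooled — the data
give no basis to separate them, so one component stands for all three), and
5% from seven live species across the four major groups, four abundant
(42/21/18/14% of live cells) and three rare. All seven are
compact-morphology species, so each forms a single tight component: the
filament archetype belongs to the training panel but not the default lake
community, because its geometric cell count spreads transit length over
about a decade and a sparse ridge of that width is not one separable
component. This yields the eight-component raw structure (7 live + 1
noise) the cleaning narrative expects, with component separation of at
least 4 SD in log-trait space, and abundant-group clusters totalling
comfortably over 90% of cleaned cells.
Composition and live fraction drift sinusoidally across samples so the
community actually changes over the series. The paired "microscopy" truth
is the realized per-sample truth perturbed by lognormal error (CV 0.3,
chosen so the end-to-end correlation against noisy microscopy lands in a
realistic moderate band rather than at 1) with values below the detection
limit recorded as zero.

What the generator does *not* emulate: optical first-principles scattering,
environmental plasticity of traits (a cell's signature is stable here;
field pigmentation responds to nutrients and light), trait covariance
between channels beyond the shared size/biovolume factor, and any
quantitative model of real non-cell signals (the noise component's
distribution is our construction). Passing tests therefore demonstrate that
the pipeline recovers structure *of the kind it assumes*, with honest
sampling noise — not that it would reach the same accuracy on any real
lake's data.

## Problem sizes and determinism

The shipped checks run the full default study: a 500,000-particle field
series, 100,000-row pooled subsets, 9,600-row training table, and the
10,001 / 1,001 / 10,001-tree forests; the complete pipeline runs in
minutes on a single core. Every stochastic step takes an explicit seed
(forests run single-threaded through `ranger` with a fixed seed; subsetting
and generation use R's RNG), and end-to-end determinism under a fixed seed
is itself a tested property. Pipeline stages log input, output and
discarded counts so the cleaning audit trail can be reconstructed.
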