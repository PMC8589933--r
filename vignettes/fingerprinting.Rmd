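---
title: "Functional fingerprinting of calcium traces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional fingerprinting of calcium traces: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catrace)
```

`catrace` analyzes cell-by-frame fluorescence trace matrices from calcium
imaging after signal extraction. It answers two complementary questions:

* **Fingerprinting** — which cells have similar *overall* dynamics, even
  when their recordings are not temporally aligned? This is addressed by
  clustering frequency-domain representations of the traces under the
  Earth Mover's Distance (EMD).
* **Composition** — what discrete building blocks (peak motifs) make up a
  trace, and how are they organized in time? This is addressed by k-Shape
  clustering of detected peaks and Markov chains over the resulting motif
  sequences.

A third group of functions handles stimulus-locked analysis (tuning
curves, linear-discriminant state projections), and a seeded synthetic
generator provides ground-truth data for every stage.

## Spectral fingerprinting

Each trace is min-max normalized to $[0,1]$ (a constant trace maps to
zeros: silent cells get a well-defined "no energy" spectrum rather than
an error). The discrete Fourier transform of each normalized row is
stored in the *packed real* layout
$[X_0,\ \mathrm{Re}\,X_1,\ \mathrm{Im}\,X_1,\ \mathrm{Re}\,X_2,\ \dots]$,
so one packed slot is one "frequency domain" and slot $j$ belongs to
harmonic $\lfloor (j+1)/2 \rfloor$, i.e. frequency
$\lfloor (j+1)/2\rfloor \cdot f_s/N$ Hz. At $N = 3000$ frames and
$f_s = 10$ Hz the first 1000 domains span 0–1.67 Hz, the default
clustering band. The feature vector is $\log(|\cdot| + \varepsilon)$ of
the first `cutoff_index` packed values, with $\varepsilon = 10^{-12}$
guarding the exact zeros of silent traces.

The cutoff can also be chosen from the data: for each candidate cutoff
the truncated packed spectrum is treated as the spectrum of a shorter
series, inverse transformed, linearly interpolated back onto the
original frame grid, and scored by the sum of squared differences (SOSD)
against the raw trace. `select_frequency_cutoff()` picks the smallest
candidate whose cumulative share of the total mean SOSD reaches
`fraction` (default 0.945). Two numerical notes: the truncated spectrum
is rescaled by $k/N$ so the shorter inverse preserves amplitude, and
with the cutoff equal to $N$ the reconstruction is exactly the inverse
transform, so the SOSD is zero to machine precision (this identity is
tested).

## The Earth Mover's Distance

`emd_1d(u, v)` is the minimum transportation work between two
non-negative weight vectors on the integer line (ground distance
$|i-j|$, unit bin spacing), divided by the total flow
$\min(\sum u, \sum v)$. Unequal masses follow the partial-matching
convention: the surplus of the heavier signature simply stays where it
is, placed to minimize the work. Internally the problem is reduced to a
convex piecewise-linear dynamic program over the cumulative discarded
mass and solved exactly in $O(n \log n)$ compiled code; the test suite
pins it against an explicit transportation linear program on hundreds of
random signatures, and against the closed form
$\sum_i |\,\mathrm{cumsum}(u)_i - \mathrm{cumsum}(v)_i\,| / \sum u$ for
equal masses.

Unlike the Euclidean distance, the EMD depends on *where* along the
frequency axis spectral weight sits: similar weights in neighboring
domains cost little, the same weights far apart cost much. A joint
shuffle of both feature vectors leaves the Euclidean distance exactly
unchanged but generally changes the EMD
(`shift_sensitivity_check()`), which is why the EMD is the right metric
for spectra and why it can compare recordings that are not temporally
aligned.

### Negative log-magnitudes and the mass convention

EMD transports non-negative mass, but log-magnitude features dip
negative wherever $|X_j| < 1$. `pairwise_distances()` supports two
conversions:

* `weights = "magnitude"` (default): transport $\exp(\text{feature})$,
  i.e. the linear magnitude spectrum — the square-root-of-energy profile
  of the trace.
* `weights = "shift"`: jointly shift each pair of rows by
  $-\min(\text{both rows})$.

The default was chosen after measuring both on the package's synthetic
archetype benchmark. The joint shift adds a flat pedestal to every bin;
on realistic features the pedestal is the large majority of the total
mass, so it inflates the flow normalizer and compresses the contrast
between cell populations — to the point that the EMD pipeline separated
archetypes *worse* than the Euclidean one, inverting the property the
metric is used for. Transporting the magnitude spectrum concentrates
mass in the signal band, restores the expected ordering (EMD clustering
clearly stronger than Euclidean), and needs no arbitrary offset. The
log features themselves remain the Euclidean feature vectors.

## Hierarchical clustering and validity scores

`hierarchical_complete()` performs complete-linkage agglomeration on a
precomputed distance matrix. Ties in the minimal inter-cluster distance
are broken toward the lowest (row, column) pair so the merge sequence is
deterministic across platforms; heights are non-decreasing by the
linkage's monotonicity. The tree carries the agglomerative coefficient

$$\alpha = \frac{1}{n}\sum_i \left(1 - \frac{h(i)}{h_{\max}}\right),$$

the classical agglomerative-nesting coefficient ($h(i)$ = height of the
first merge containing leaf $i$); $\alpha \in [0,1]$, is invariant to
uniform rescaling of the distances, and is defined as 0 when all items
are identical. The implementation is pinned against `stats::hclust`
(heights and partitions) and `cluster::agnes` (the coefficient).

Cuts are scored by the mean silhouette from the precomputed distances
(singletons contribute 0), and `select_k_silhouette()` returns the
silhouette-maximal number of clusters, ties toward the smaller k. A
Davies–Bouldin index adapted to the EMD is also provided: cluster
centroids are elementwise means of member feature rows, within-cluster
scatter is the mean EMD from members to their centroid, and separation
is the EMD between centroids (with magnitude masses, a mean of log
features is a geometric-mean magnitude profile). This adaptation is this
package's own construction; with `metric = "euclidean"` it reduces to
the textbook index, which is how it is validated.

## Peaks, k-Shape motifs and Markov chains

`detect_peaks()` finds local maxima by topographic prominence (default
0.1 in normalized units, minimum segment length 3 frames); each peak
curve spans the flanking minima between neighboring retained peaks and
carries its half-width measured at half-prominence. Peaks are linearly
resampled to the median peak length and z-normalized before shape
comparison.

The shape-based distance is
$\mathrm{SBD}(x, y) = 1 - \max_s \mathrm{NCC}(x, y, s)$ with
coefficient-normalized, zero-padded cross-correlation over all integer
shifts; it lies in $[0, 2]$ and is zero iff the shapes agree up to
positive scaling and shift. `kshape_fit()` alternates SBD assignment
with shape extraction (the dominant eigenvector of the centered Gram
matrix of shift-aligned members), capped at 100 iterations; an empty
cluster is re-seeded with the worst-fitting peak.

`kshape_gridsearch()` searches the number of clusters over 2–14: for
each candidate k the peaks are ordered by half-peak width, partitioned
into k blocks, and one random seed is drawn per block; restarts keep the
minimum-inertia fit, and candidates ending with an empty cluster are
discarded. Because raw inertia decreases monotonically with k,
minimizing it across k would always favor the largest k; the default
selection therefore takes, per k, the best restart and then the smallest
k whose inertia improvement over k−1 falls below 10% (an elbow rule),
with `k_select = "min-inertia"` available for the literal rule. Motifs
are lettered `a`, `b`, … by ascending centroid half-peak width (ties by
cluster index), traces are discretized into letter sequences by mapping
each peak to its nearest centroid in temporal order, and `fit_markov()`
estimates a first-order chain by maximum likelihood: counts pooled
across sequences with no transitions across sequence boundaries,
rows normalized where they have outgoing counts, terminal states keeping
an all-zero row (no smoothing unless `pseudocount > 0`). For display,
`prune_transitions()` drops edges below a probability threshold
(conventionally 0.1).

One boundary case worth noting: two pure impulses at different offsets
have SBD ≈ 0.008 rather than exactly 0, because z-normalization gives
them a negative baseline whose overlap is lost under zero-padded
shifting. The tests assert the recovered shift and a small bound rather
than exact zero.

## Stimulus tuning and state projections

`tuning_curves()` averages each cell over all frames of all intervals
per stimulus label (plain mean, no baseline subtraction — the averaging
window is exactly the stated stimulus periods) and labels the cell by
the argmax, ties to the lexicographically first label. Intervals are
0-based and half-open, so back-to-back trials concatenate exactly; the
tuning result is invariant to interval order and to splitting an
interval into contiguous same-label pieces.

`lda_states()` treats every timepoint as a feature vector of all cells'
intensities, fits linear discriminants on the frames inside the class
intervals, and reports accuracy on those same training frames (there is
no held-out split in this design). The pooled within-class covariance
can be shrunk toward its average variance times the identity
(`shrinkage` in $[0,1]$); shrinkage defaults to 0.1 whenever the
training frames number fewer than five per cell, which keeps the
estimate invertible when cells outnumber frames. Timepoints are
classified by the nearest class mean in the discriminant space (equal
priors); with well-conditioned data and `shrinkage = 0` the predictions
match `MASS::lda`, which is the cross-check used in the tests.

## The synthetic generator

`generate_traces()` emulates traces as they come out of a
deconvolution / matrix-factorization signal extractor: per cell, a
homogeneous Poisson event train at the archetype's rate, each event a
double-exponential transient (difference of exponentials normalized to
unit peak) with normally distributed amplitude, plus a small Gaussian
noise floor (default SD 0.01 — extracted traces are largely denoised
model reconstructions, so the noise is well below event amplitude).
Defaults mirror a typical acquisition: 10 Hz sampling and 3000-frame
(five-minute) recordings.

The default four archetypes form an activity gradient in which event
rate and kinetics vary together — 0.02/0.12/0.35/0.7 events/s with
decay constants 12/2.5/0.9/0.4 s and rises 0.5/0.12/0.06/0.03 s. Two
design constraints shaped these values. First, rate alone cannot
separate normalized spectra: the expected magnitude spectrum of a
Poisson train of identical kernels is the kernel's spectrum scaled by
the event count, and min-max normalization plus the log discard that
scale — distinct populations need distinct kinetics. Second, the
separations between *neighboring* archetypes should be comparable; a
geometric gradient (each step much bigger than the last) makes the
silhouette rightly merge the two closest populations and report three
clusters. Rates are also high enough that essentially every cell
expresses at least one event, since a zero-event cell is pure noise and
its planted label is meaningless.

`generate_stimulus_session()` interleaves labeled stimulus intervals
(default the three-state heat-stimulus design) and adds a
transient response at the onset of each interval matching the cell's
planted preferred label, scaled by `response_gain` in units of the
noise SD. `generate_peak_library()` jitters three base shapes with
well-separated half-widths (sharp spike, asymmetric transient, broad
wave) in amplitude and width. All generators are pure functions of
their parameters and seed.

What the generator does **not** emulate: correlated network activity
(events are independent across cells), photobleaching and slow drifts,
movement artifacts, signal-extraction cross-talk between neighboring
ROIs, and heavy-tailed noise. Passing the recovery tests therefore
shows the pipeline is correct and sensitive under clean, well-specified
population structure; it does not by itself guarantee the same
separation on real recordings, where within-population variability is
richer.

## Problem sizes and numerical choices used by the test suite

The recovery tests run at desk scale, chosen to exercise the same
regimes as a real session while keeping the suite fast: 4 archetypes ×
25 cells × 3000 frames with the first 1000 frequency domains for the
fingerprinting benchmark; 3 × 30 jittered peaks for motif recovery with
the full 2–14 gridsearch; 10⁴ pooled transitions for Markov recovery;
the EMD solver is checked against a transportation LP on signatures of
length ≤ 12 and against the cumulative-sum closed form up to length 40.
Key numerical conventions, collected in one place: log floor
$\varepsilon = 10^{-12}$; merge tie-break lowest (row, col); silhouette
singleton contribution 0; argmax ties lexicographic; k-Shape iteration
cap 100 with empty clusters re-seeded from the worst fit; gridsearch
elbow threshold 10%; transition rows without outgoing counts stay zero.

## Provenance

Every container carries version-4 UUIDs, and `provenance_log()` /
`record_provenance()` keep an append-only record of operations with
parameters, input and output UUIDs and ISO-8601 UTC timestamps. Inputs
must already be known to the log, which keeps the dependency graph
acyclic; `trace_lineage()` walks any result back to its raw-data roots,
and the log round-trips losslessly through JSON.

## Known limitations

* The EMD Davies–Bouldin adaptation is one reasonable construction, not
  a canonical definition; scores should be compared within a dataset,
  not across software.
* The gridsearch elbow rule involves a threshold (10%) that trades
  parsimony against fit; very gradual cluster structure can defeat any
  such rule.
* `lda_states()` reports training accuracy by design; it is a
  descriptive state-separation summary, not an estimate of
  generalization.
* Peak detection assumes min-max normalized traces; prominence values
  are in normalized units and need rescaling for raw fluorescence.
```{r example, eval = FALSE}
g  <- generate_traces(seed = 1)
ts <- normalize_minmax(g$traces)
sf <- dft_log_magnitude(ts, 1000)
d  <- pairwise_distances(sf, "emd")
tr <- hierarchical_complete(d)
k  <- select_k_silhouette(tr, d, 2:8)
cut_tree(tr, k)
```
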