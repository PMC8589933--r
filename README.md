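# catrace

Functional fingerprinting of calcium-imaging traces.

After motion correction, segmentation and signal extraction, a calcium
imaging experiment reduces to a matrix of fluorescence traces — one row
per cell — plus whatever the experimenter knows about each cell and each
moment in time. `catrace` is for the downstream half of that analysis:
deciding which cells share the same *kind* of activity even when they
were not recorded simultaneously, what discrete peak motifs their
activity is built from, and how cells respond to mapped stimuli. It is
aimed at systems-neuroscience and cell-biology users working with
genetically encoded calcium (or other) indicator recordings.

## What it computes

**Spectral fingerprinting.** Traces are min-max normalized and
transformed to packed real-DFT log-magnitude feature vectors, truncated
at a frequency cutoff (packed slot *j* maps to frequency
⌊(*j*+1)/2⌋·*f*ₛ/*N*; with *N* = 3000 frames at 10 Hz, the first 1000
domains span 0–1.67 Hz). A data-driven cutoff is available via the
cumulative sum-of-squared-differences between raw traces and truncated
inverse-transform reconstructions. Cells are compared with the
**Earth Mover's Distance**: the minimal work to rearrange one spectral
mass profile into the other (ground distance = bin separation), divided
by the flow, with exact partial matching for unequal masses

  EMD(u, v) = min_T Σᵢⱼ Tᵢⱼ·|i−j| / min(Σu, Σv),

computed by an exact O(n log n) solver and equal to
Σ|cumsum(u)−cumsum(v)|/Σu for equal masses. Unlike the Euclidean
distance, the EMD is sensitive to *where* along the frequency axis
energy sits, which is what lets it group cells by overall dynamics
without temporal alignment. Complete-linkage hierarchical clustering on
the distance matrix carries the agglomerative coefficient
α = mean(1 − h(i)/h_max) ∈ [0, 1]; cuts are chosen by silhouette maxima
and also scored by an EMD-adapted Davies–Bouldin index.

**Motifs and sequences.** Peaks detected by topographic prominence are
clustered with **k-Shape** (shape-based distance
SBD = 1 − max-shift normalized cross-correlation), with a 2–14
gridsearch using half-peak-width partition seeding and a no-empty-cluster
constraint. Motifs are lettered `a`, `b`, … by ascending half-peak
width, traces become letter sequences, and first-order **Markov chains**
are fit by maximum likelihood (counts pooled within, never across,
sequences), with probability-threshold pruning for graph export.

**Stimulus analysis.** Mean-response tuning curves over labeled frame
intervals (argmax tuning per cell) and linear-discriminant projections
of population state, one feature vector per timepoint, with optional
covariance shrinkage.

**Synthetic ground truth.** Seeded generators for archetype trace sets
(Poisson events × double-exponential transients), stimulus sessions
with planted tuning, and jittered peak libraries — every stage of the
pipeline is testable without any external data.

## Worked example

```r
library(catrace)

g  <- generate_traces(seed = 1)          # 4 archetypes x 25 cells, 3000 frames
ts <- normalize_minmax(g$traces)
sf <- dft_log_magnitude(ts, 1000)
sf
#> <spectral_features> 100 cells x 1000 packed domains (0 - 1.667 Hz), N = 3000, fs = 10 Hz

d  <- pairwise_distances(sf, "emd")
tr <- hierarchical_complete(d)
tr
#> <linkage_tree> 100 leaves, complete linkage (emd), alpha = 0.996, top height 235.9

k  <- select_k_silhouette(tr, d, 2:8)    # -> 4
cl <- cut_tree(tr, k)
silhouette_precomputed(d, cl)            # 0.86
table(planted = g$labels, cluster = cl$labels)
#>           cluster
#> planted     1  2  3  4
#>   active    0  0  0 25
#>   moderate  0  0 25  0
#>   silent   24  1  0  0
#>   sparse    1 24  0  0
```

The tree's α ≈ 0.996 says the EMD geometry is strongly hierarchical;
the silhouette-selected cut recovers the four planted populations with
two borderline cells swapped between the two sparsest archetypes
(98/100 correct). The same features clustered with Euclidean distances
give a much weaker tree (α ≈ 0.49 on this data) — the property that
motivates the EMD here.

The motif branch works the same way:

```r
lib <- generate_peak_library(seed = 1)   # 3 shape families x 30 peaks
m   <- kshape_gridsearch(lib$peaks, k_range = 2:14, restarts = 3, seed = 1)
m
#> <motif_model> k = 3 motifs (length 60), inertia 0.2411
#>   a: half-width 3.99 frames, 30 peaks
#>   b: half-width 16.09 frames, 30 peaks
#>   c: half-width 25.96 frames, 30 peaks
```

`discretize()` then turns each trace's peaks into letter sequences and
`fit_markov()` estimates the transition structure; see the vignette
(`vignettes/fingerprinting.Rmd`) for the full methods account.

A thin command-line front end over the same functions is installed at
`inst/cli/catrace.R`:

```sh
Rscript inst/cli/catrace.R simulate --kind traces --seed 7 --out-dir demo/
Rscript inst/cli/catrace.R spectral --traces demo/traces.csv --fs 10 --cutoff 1000 --out demo/features.csv
Rscript inst/cli/catrace.R distances --features demo/features.csv --metric emd --out demo/dist.csv
Rscript inst/cli/catrace.R cluster --dist demo/dist.csv --k auto --out demo/labels.csv
```

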