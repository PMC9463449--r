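---
title: "Identifying morphological states and phenotype trajectories in 3D culture time-lapse data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying morphological states and phenotype trajectories in 3D culture time-lapse data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotraject)
```

## The problem

Label-free time-lapse imaging of 3D cultures (spheroids, organoids) yields
thousands of tracked objects, each described at every frame by size
(`Area`), shape (Zernike moments, bounding-box aspect ratio) and movement
features (`Displacement`, `DistanceTraveled`, `IntegratedDistance`,
`Linearity`). Within one well, genuinely different morphogenesis programmes
run in parallel: some objects stay round, others spread or elongate, and
the same end-state can be reached through different intermediate states.
Snapshot analyses average over this heterogeneity. phenotraject instead

1. identifies **morphological states** — co-occurring modes in feature
   space, with no reference atlas and no temporal information;
2. restores each tracked object's **temporal state sequence** and clusters
   the sequences into recurring **trajectories**;
3. summarises each trajectory (motifs, state transitions, a representative
   object and a representative outline); and
4. compares state/trajectory frequencies between samples with statistics
   that respect the experimental replicate structure.

The package consumes tracked-object feature tables (e.g. CellProfiler
`ExportToSpreadsheet` output); segmentation and tracking themselves are out
of scope.

## Pipeline and model

### Pre-processing

Measurement tables are merged with an experimental key mapping each well to
its sample and replicate, truncated at 96 h by default (beyond which object
merging dominates in the system this pipeline was built for), and Z-scored
per measurement column over the *pooled* dataset — states must be
comparable across samples, so standardisation is global, with the sample
(n−1) standard deviation.

**Tracking-label correction.** Trackers give every daughter of a split the
parent's label, so one label can denote several concurrent objects.
`correct_tracks()` assigns a corrected `track_id` per lineage branch: when
k > 1 records share a raw label in one frame, the largest-area record
inherits the parent's id and each other record gets a fresh id that
follows its branch thereafter. The published rule defines only the split
event; for continuity of already-split branches across later frames we
match records to branches by nearest centroid (greedy), ties on area keep
the parent id on the earlier row. This is an interpretation the data
format forces, and it is deliberately minimal: no gap-closing, no
re-tracking.

### State identification

States are found on a **geometric sketch** of the data: the standardised
features are projected by PCA, the projection is covered by equal-volume
hypercubes, and points are sampled uniformly across *occupied* cubes. The
sketch (default 20,000 objects) therefore covers the occupied volume of
phenotype space evenly instead of proportionally to density, so rare
morphologies survive subsampling. The grid resolution is chosen by binary
search so the number of occupied cubes reaches the sketch size; cubes are
then visited in random order, one random unsampled point per cube per
round.

Sketched points are clustered with the shared-nearest-neighbour community
approach standard in cytometry phenotyping: a Euclidean k-nearest-neighbour
graph (k = 40) on the feature subset, edges reweighted by the Jaccard
overlap of the two endpoints' neighbour sets, then Louvain modularity
optimisation (Leiden available behind `community_method`). Communities are
renamed A, B, C, … by decreasing size so runs are comparable. Unsketched
records then take the majority state among their k nearest sketched
neighbours; the k-NN vote was chosen over nearest-centroid because
communities need not be convex. Ties resolve toward the alphabetically
smaller state.

A property of modularity optimisation worth knowing when interpreting
simulations: on *perfectly separated* dense islands much larger than k,
Louvain can split an island into several communities (modularity is a
global criterion and disconnected dense components are shreddable). With
moderate overlap between modes — the regime of real morphology data, and
of the package's default synthetic separation — planted modes are
recovered essentially exactly; the test suite exercises both regimes.

### Trajectory identification

Per corrected track, state labels are re-ordered by frame into a
categorical sequence; frames without a record are missing. Three filters
follow, in order:

1. sequences with no observation at t = 20 h are dropped (objects must
   exist from early in imaging);
2. all sequences are trimmed at the point at which tracking has ceased for
   half of the surviving objects — the retained length is the last frame
   at which *more than* 50% of sequences still have an observation at or
   after it (the strict inequality makes a 10-track fixture with
   last-observation frames 30…96 trim at exactly 70, the worked boundary
   case of the rule);
3. sequences with more than two consecutive missing entries inside the
   trimmed window are removed. Note that tracks ending well before the
   trim point fall to this rule through their trailing gap, which is the
   intended behaviour — they were not tracked long enough to compare.

Remaining gaps are imputed by **reverse LOCF** (next observation carried
backward); a trailing gap, impossible when trimming precedes imputation
but guarded anyway, is filled forward and logged.

The complete equal-length sequences are then embedded by **multiple
correspondence analysis**: each frame is one categorical variable, the
one-hot indicator matrix is built, and correspondence analysis (SVD of the
standardised residuals of the indicator table) yields principal row
coordinates; the first 50 axes are kept, zero-padded beyond the matrix
rank so the width is fixed. The indicator-matrix convention (rather than
the Burt matrix) matches the default of the standard MCA implementations.
Frames, not hours, are the variables, so non-hourly imaging is handled by
`imaging_interval_h`. Finally the same Jaccard-weighted k-NN community
detection (k = 40) on the MCA coordinates yields trajectory labels,
numbered 1, 2, … by decreasing size.

### Trajectory summaries

* **Motifs** — state frequencies per 12-h interval per trajectory
  (proper distributions per interval), plus the per-interval top state
  (lexicographic tie-break): the sequence-logo view of a trajectory.
* **Transitions** — ordered (state at t, state at t+1 frame) pairs,
  self-pairs included (state maintenance), counted in a 2-h sliding window
  stepping one frame, aggregated into 12-h intervals by window start,
  converted to per-interval proportions, and filtered at 2%. The window
  covers interior frame pairs twice and boundary pairs once; the
  per-interval normalisation makes the proportions invariant to this
  multiplicity except at interval boundaries, so the unstated step size
  only affects boundary weighting.
* **Representative object** — the consensus sequence (per-frame most
  frequent state, computed on imputed sequences) defines the archetype;
  each member's raw sequence with missing frames removed is compared to it
  by generalized Levenshtein distance (unit costs, `utils::adist`, the
  convention of the cited implementation); the minimal-distance member
  wins, ties to the lowest track key. Consensus on imputed but members on
  raw reflects that the consensus should be defined at every frame while a
  member should not be rewarded for imputed values.
* **Representative outline** — for a state or trajectory, the 30 members
  nearest the group's mean feature vector are resampled along their
  boundaries to 128 equidistant arc-length points, expressed as complex
  z = x + iy, Fourier-transformed, and reduced to power spectra scaled to
  maximum 1. The zero-frequency (centroid) term is dropped before scaling
  — otherwise translation dominates — making the descriptor invariant to
  position, size and starting vertex. PCA of the scaled spectra followed
  by a 2-D kernel density estimate (Scott's-rule bandwidths; 100×100 grid
  padded 10% beyond the data range) selects the member nearest the density
  mode: the group's most typical shape. All non-DC frequencies are used;
  128 points is a power of two chosen for the transform and is
  configurable.

### Replicate-aware statistics

Class membership (user-defined phenotype, data-driven state, or
trajectory) is counted per sample and replicate, and each class is tested
one-vs-rest against the reference sample on a 2×2×K table with one stratum
per replicate:

* **Cochran-Mantel-Haenszel** association chi-square, no continuity
  correction (flag available), zero-margin strata dropped as
  uninformative;
* odds-ratio **homogeneity** across replicates by the **Woolf** test
  (+0.5 Haldane-Anscombe correction, matching the cited implementation)
  for data-driven states and trajectories, or **Breslow-Day** (expected
  cells under the Mantel-Haenszel common OR, solved numerically by
  `uniroot` on the monotone conditional-odds function; Tarone correction
  behind a flag, default off) for user-defined phenotypes — both are
  implemented because the original analyses used one per context;
* **log2 fold changes** of pooled proportions from the reference (pooled
  across replicates because a heatmap shows one value per sample; a
  per-replicate variant is a one-line `quantify_classes` regrouping);
* **Bonferroni** adjustment over all (class × sample) tests within one
  table — the family definition is configurable in the sense that the
  caller controls which classes and samples enter one call;
* heatmap row/column orders from complete-linkage hierarchical clustering
  of Euclidean distances on the log2FC matrix.

Feature-level comparisons (e.g. mean area per 12-h interval) use pooled
two-sample two-tailed Student's t-tests with the same Bonferroni family
convention, and object counts are reported normalised to each
(sample, replicate)'s initial count.

## The synthetic-data generator

Real datasets of this kind run to ~10^5 objects over days of imaging and
are not shippable; every claim the test suite makes is therefore measured
on `simulate_tracked_data()`, which plants ground truth at the study's
own conditions: hourly imaging over 96 frames, morphological states as
Gaussian modes in feature space (default 8 states at pairwise centroid
separation 6 within-state standard deviations — clearly distinct modes,
comfortably inside the well-separated regime), recurring trajectory
archetypes as piecewise-constant state sequences (dwell 8–24 frames,
regenerated until every pair differs in ≥25% of frames; default 5), 5%
per-frame label noise, 5% missingness in runs of at most 2 frames,
optional split events whose children inherit the parent's raw label, and
an optional archetype planted at a chosen odds ratio (per replicate, so
both homogeneous and heterogeneous effects can be planted exactly).

Two motion models are provided. The default derives
`IntegratedDistance` (cumulative step length), `DistanceTraveled` (net
displacement) and `Linearity` (net/cumulative, in [0, 1]) from the
simulated centroid walk, so the internal relations of real tracker output
hold in the synthetic table; the `"gaussian"` model draws every subset
feature independently from the state's Gaussian and is the planted-
Gaussian-state benchmark the recovery tests quantify against.

What the generator does **not** emulate: heavy-tailed or skewed feature
distributions, state-dependent missingness, tracking drift, gradual
(rather than block-wise) state transitions, and object merging beyond the
label-sharing mechanics. Passing planted-recovery tests therefore
demonstrates the machinery is correct, not that real 3D-culture data will
separate as cleanly.

## Numerical choices and problem sizes

Deterministic tie-breaks throughout: equal kNN distances resolve to the
lower index; equal areas at a split keep the parent label on the earlier
row; state-frequency ties go to the lexicographically smaller label; tied
KDE maxima take the first grid cell in scan order. All stochastic steps
(sketching, community detection, t-SNE, simulation) consume an explicit
seed, and reruns under a fixed seed are bit-identical — this is itself
under test. The t-SNE used for visualisation computes exact input
affinities and gradients with PCA initialisation, appropriate at sketch
scale; its `theta` argument is accepted for interface parity and the
exact computation corresponds to the theta → 0 limit.

The validation suite runs planted-state recovery at 20,000 objects
(8 states, sketch 10,000 so the assignment step is genuinely exercised,
k = 40), trajectory recovery at 1,000 tracks × 96 frames (5 archetypes,
k ∈ {30, 40, 50} for the robustness probe), the type-I calibration at
2,000 null replicates of 3 strata × 200 objects, and the enrichment
end-to-end at 6,000 tracks per sample-replicate with a rare class
(reference probability 0.015) planted at odds ratio 4 — rare enough that
the log2 fold change approximates log2 of the odds ratio, and large
enough that its sampling error is small. These sizes are the package's
validation conditions and are stated here so results are reproducible at
face value.

## Known limitations

* Modularity community detection can over-partition perfectly isolated
  dense islands (see above) and, like the original method, gives no
  uncertainty on the number of states or trajectories; the k-robustness
  probe is the provided sanity check.
* Exact duplicate sequences (short sequences at low noise) make kNN ties
  index-structured; at realistic sequence lengths duplicates are rare.
* The label-correction rule resolves splits only; merges appear as new
  labels (fresh tracks) by construction of the upstream tracker, and
  short-lived merge products are removed by the sequence filters rather
  than modelled.
* Sequences are compared frame-by-frame; there is deliberately no
  time-warping alignment, and no pseudotime inference from snapshots.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(seed = 1)
sim <- simulate_tracked_data(spec)

rec <- merge_key(sim$measurements, sim$key)
rec <- correct_tracks(rec)
rec <- filter_records(rec, max_time_h = 96)
rec <- derive_features(rec)

cfg <- pipeline_config(sketch_size = 4000, rng_seed = 1)
rec <- zscore_features(rec, cfg$feature_subset)

states <- fit_states(rec, cfg)
seqs <- build_sequences(rec, states$state_labels)
traj <- fit_trajectories(seqs, cfg)

motifs <- motif(traj$sequences, traj$trajectory_labels)
trans <- transitions(traj$sequences, traj$trajectory_labels)
reps <- representative_spheroid(traj)

tracks <- sim$truth$tracks
tracks$trajectory <- NA
tracks$trajectory[match(rownames(traj$sequences$states),
                        paste(tracks$experiment_id, tracks$well,
                              tracks$position, tracks$raw_track_label,
                              sep = "\r"))] <- as.character(traj$trajectory_labels)
counts <- quantify_classes(tracks[!is.na(tracks$trajectory), ], "trajectory")
enrich <- fold_change_table(counts, reference = "control")
```
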