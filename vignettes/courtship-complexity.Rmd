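---
title: "Quantifying cross-modal courtship complexity and its correlated evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-modal courtship complexity and its correlated evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ornadiv)
```

`ornadiv` measures the complexity of courtship phenotypes in three signal
modalities — display behavior, plumage color, and courtship sound — on one
common scale, and tests whether those axes evolve together across a clade.
This vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic-data
machinery does and does not establish.

## A common currency: richness and Hill diversity

Each modality is reduced to a weighted categorical distribution: seconds per
behavior in a time window, pixel area per perceptually distinct color, note
count per note type. Two measures are computed on the positive-weight
categories:

* richness, the number of categories, and
* diversity, the numbers equivalent of Shannon entropy,
  \(D = e^{H}\), \(H=-\sum_i p_i\ln p_i\).

Diversity is the count of *equally weighted* categories with the same
entropy, so it is bounded by richness, reaches it exactly at evenness, and is
doubling-consistent: a repertoire at \(D=2x\) behaves like one with twice as
many equally used elements as one at \(D=x\). Entropy is computed in natural
log; the numbers equivalent is base-free. Zero total weight is treated as an
invalid (unscorable) distribution rather than silently scored 0.

## Behavioral sequences and the sliding window

Display recordings arrive as timed tokens: *states* with start and end
seconds and instantaneous *events*. Because recording effort varies wildly
across species, species are not compared on whole recordings but on each
individual's **window of maximal complexity**: a fixed-length window (default
50 s, the duration at which per-individual scores stabilize in this kind of
data) slides along every clip and the best window is kept, independently for
richness and for diversity. Averaging those per-individual maxima gives the
species score.

Choices a user can revisit:

* `event_weight_s` (default 1 s): instantaneous events enter the
  time-proportion distribution with a nominal duration so that counts and
  state durations are commensurate. The weighting is configurable because
  the field convention is not settled.
* `step_s` (default 1 s): window offsets are `0, step, 2·step, …` within a
  clip; windows never span clips. A finer step only matters when token
  boundaries are far off the 1 s grid.
* Clips shorter than the window contribute one whole-clip window rather than
  being dropped — discarding them would systematically penalize
  rarely-recorded species.
* `single_window_by`: by default the richness-maximal and diversity-maximal
  windows are located independently; setting this to one metric scores both
  measures from that metric's single best window (the coupled reading).
* Ties break deterministically: earliest clip in input order, then earliest
  offset.

The implementation is validated against an exhaustive window-enumeration
oracle on random sequences up to 200 tokens.

## Color: receptor-noise-limited distances and spatial clustering

Specimen images are per-pixel cone quantum catches \(q_i\) (2–4 chromatic
channels plus luminance) with a foreground mask. Perceptual distance uses
the receptor-noise-limited model on log catches (\(f_i=\ln q_i\)): the
chromatic distance for \(n\) channels is the standard noise-weighted
quadratic form in the pairwise contrast differences
\(\Delta f_i-\Delta f_j\) (so any uniform intensity scaling is invisible),
and the achromatic distance is \(|\Delta f_L|/\omega_L\). Channel noise
follows \(\omega_i=\nu\sqrt{n_{ref}/n_i}\) from relative cone densities.
The default `visual_model()` is a violet-sensitive tetrachromat with
densities 1:2:2:4, \(\nu=0.1\) on the most abundant (lws) channel, and
\(\omega_L=0.1\) — pigeon-like values appropriate for birds-of-paradise,
fully configurable.

A median blur (default radius 1, i.e. 3×3, restricted to the foreground)
removes aberrant pixels before clustering.

`cluster_image()` then partitions the foreground:

1. every pixel starts as a cluster;
2. clusters with any two pixels within a Chebyshev radius \(r\) (starting at
   1, growing by 1 per pass) are neighbors;
3. each cluster's nearest neighbor is chosen by the composite distance
   \(\sqrt{(\Delta S/T_c)^2+(\Delta L/T_l)^2}\) on cluster mean catches, and
   the merge is accepted only if *both* \(\Delta S<T_c\) and
   \(\Delta L<T_l\);
4. accepted merges chain transitively within a pass (union–find), cluster
   means are recomputed as area-weighted means, and the radius grows.

The algorithm stops when a pass merges nothing *and* the radius has reached
the image dimension — so identically colored patches on opposite ends of the
specimen end in one cluster, and clustering effectively operates over the
\(n+2\) dimensions of color and image space. Cluster areas then yield color
richness and diversity; view scores average into specimens and species.

Defaults and degenerate behavior:

* `T_c = T_l = 3` JND: the conventional supra-threshold cut for reliable
  discrimination under uncontrolled viewing; both thresholds are exposed.
* As \(T\to 0^+\) the result is the count of distinct perceptual pixel
  values; as \(T\to\infty\) any foreground collapses to one cluster. Both
  limits, partition conservation, and catch-mass conservation are asserted
  in the tests.
* Ties in nearest-neighbor choice go to the lowest cluster index; cluster
  identity is the smallest member pixel index, making the procedure fully
  deterministic.
* `min_area_frac` (default 0 = off) can drop speck clusters (dust) before
  scoring.
* An empty mask or nonpositive foreground catch is an error: the log model
  is undefined there.

## Sound: two-step note classification

Notes carry ~15 numeric features (duration, frequency extremes, bandwidth,
peak frequency, contour and entropy summaries). Features are z-scored
(correlation-matrix PCA; zero-variance features are dropped with a warning;
component signs are fixed by making each component's dominant loading
positive), notes are placed in the first three PC dimensions, and
agglomerative clustering (Euclidean distance, Ward linkage by default;
average and complete are available) assigns the acoustic part of note
identity. The tree is cut at a user-supplied `k` when the analyst knows the
type count, otherwise at the largest *relative* gap between successive merge
heights. Two guards make that heuristic usable: only merges above the median
height are eligible (near-zero early heights otherwise dominate the ratio),
and if the best ratio is below `min_gap_ratio = 2` the cloud is declared
unstructured and \(k=1\). The four manual yes/no qualities (frequency
modulation, nonharmonic, impulsive, stochastic) form a 4-bit code appended to
the cluster id; the full identity is the pair.

Identified notes are scored as instantaneous events through the same sliding
machinery as behavior, with a 10 s default window — note trains are dense
relative to the window, and each note counts once.

## Phylogenetic regression and imputation

Species scores (log transformed; nonpositive values raise an error rather
than being offset) enter one multiple PGLS per measure: the response is
regressed on the two like measures from the other modalities ("like" meaning
richness with richness, diversity with diversity) plus display height
(dummy coded, ground reference) and display proximity (solitary reference).
Residuals are correlated as \(C_{ij}=e^{-\alpha d_{ij}}\) on patristic
distances (the Martins–Hansen form; \(\alpha=0\) gives perfect correlation,
large \(\alpha\) independence). For fixed \(C\), estimates follow the closed
form \(\hat\beta=(X'C^{-1}X)^{-1}X'C^{-1}y\) via Cholesky whitening; the
scale uses the \(n-p\) denominator and p values come from \(t(n-p)\).

\(\alpha\) is profiled over a log-spaced grid on
\([10^{-4},\,50/\text{tree height}]\) and refined by golden-section search.
The profiling criterion is **REML by default** (ML available): on null
simulations the fixed-\(\alpha\) test is well calibrated while ML-profiled
\(\alpha\) noticeably inflates type-I error; REML profiling removes most of
that inflation and matches the default behavior of the standard GLS tooling
this analysis mirrors. The grid-plus-refinement search also avoids the local
optima that general-purpose optimizers can hit on this profile. Calibration
and power are quantified in the acceptance suite (1,000 null Brownian-motion
simulations and 200 effect simulations on 40-tip trees).

Missing species are imputed before fitting (a complete-case switch exists):
for each trait, candidate covariance models — Brownian motion, stationary OU,
early burst (\((e^{r t}-1)/r\) on shared paths, \(r<0\)), and Pagel's lambda
(off-diagonal scaling) — are fitted by ML with mean and scale profiled out,
compared by AIC (k = 2 for BM, 3 otherwise), and the winner supplies the
conditional multivariate-normal expectation of the missing tips. On a star
tree under BM this reduces to the observed mean, and a zero-distance
duplicate tip is recovered exactly — both are test assertions.

Scaled composite scores (`composite_diversity()`) min–max scale each
modality's diversity to \([0,1]\) across species and sum them; a constant
column scales to 0 with a warning.

## What the synthetic data emulate — and what they do not

The generators produce every input class with known ground truth:
pure-birth ultrametric trees; multi-clip event logs with species-specific
repertoires (alternating log-normal states, Poisson events); striped
cone-catch images whose patch means sit a chosen chromatic JND apart with
Gaussian log-catch pixel noise (noise in log space keeps the perceptual size
of pixel noise distribution-stable); and Gaussian-mixture note clouds whose
component means are separated by 10 within-component standard deviations,
spread across all features so the separation survives per-feature
standardization. Traits evolve on the tree as a matrix normal with a
controllable cross-trait correlation.

Default study conditions: 120 s clips, 3 individuals and 2 clips per
individual, repertoires of 2–8 elements, 1–6 color patches, 1–5 note types,
8 JND patch separation with 0.02 log-catch noise, and 40-tip trees for the
calibration suites (the worked-example pipeline runs at 6–12 species to
keep simulation sizes modest). These are realistic magnitudes for
museum-and-archive comparative datasets.

Passing tests on these data show that the algorithms recover known structure
under clean separations; they do not show that real specimens meet those
separations. Real data differ in ways the generators deliberately omit:
iridescence (color depends on view geometry beyond three fixed views),
spatially correlated pixel noise, behavioral syntax (the generator has no
transition structure beyond no-immediate-repeat), note-feature correlations
within types, and observer error in qualitative flags.

## Known limitations

* The color clustering is greedy and order-deterministic; it is not a global
  optimum of any objective, matching its field use as a perceptual
  segmentation rather than a statistical estimator.
* The gap-cut for note types assumes types are either well separated or
  absent; gradual continua will be cut arbitrarily (supply `k` instead).
* The OU correlation is stationary (tip correlation depends only on
  distance); non-ultrametric trees are accepted with a warning but the form
  is then only an approximation.
* mPGLS treats the profiled \(\alpha\) as known in the t tests; REML
  profiling reduces but does not eliminate the resulting anticonservatism at
  small \(n\).
* Multivariate (cross-trait) imputation is out of scope; traits are imputed
  one at a time.
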