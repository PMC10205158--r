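---
title: "Methods: lexical similarity models and searchlight RSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexical similarity models and searchlight RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexrsa)
```

## What the package computes

`lexrsa` implements a complete analysis path from word-level similarity
models to group-level brain maps. The scientific question it serves is
whether distinct ways of quantifying word similarity — affective judgements
(valence, dominance, arousal) versus co-occurrence-based word embeddings —
are reflected in the similarity structure of fMRI activity patterns, and
whether those reflections are *independent* of one another. The statistical
engine is representational similarity analysis (RSA): for a set of $n$ words,
every model and every local neighbourhood of brain activity yields an
$n \times n$ similarity matrix, and the rank correlation between their
off-diagonal vectors measures how well the model explains the local neural
geometry.

The pipeline has four analysis stages plus a synthetic-data generator:

1. **Lexical models** — similarity matrices from ratings, embeddings,
   phonology and taxonomies, with model-level statistics (correlogram,
   Pearson–Filon dependent-correlation test, summary-statistics ANOVA).
2. **Activation extraction** — per-trial activation volumes by the BOLD
   area-under-the-curve rule, motion quality control, tSNR, grey-matter
   masking, and pooling into per-word condition patterns.
3. **Searchlight RSA** — fixed-size (k = 200) neighbourhoods over the mask;
   cosine neural similarity with data centring; plain and partial Spearman
   correlation against model matrices; Fisher z and smoothing.
4. **Group inference** — voxelwise one-sample and paired t tests across
   subjects and cluster-extent familywise-error control by sign-flip
   permutation.

## Lexical similarity models

**Affective space.** Words sit in the 3-dimensional space of valence,
dominance and arousal (each on the 1–7 rating scale). Pairwise Euclidean
distances $d$ are divided by the maximum pairwise distance within the word
set and converted to similarities $s = 1 - d$. The normaliser is a genuine
design choice — range- or variance-based normalisation would be equally
defensible — and max-normalisation was fixed once because it maps
similarities onto $[0, 1]$ with the most distant pair at exactly 0 and is
invariant to common shifts and rescalings of the rating axes. A word set in
which all words share identical ratings has a zero normaliser and is rejected
as degenerate.

**Embeddings.** Cosine similarity between embedding vectors (e.g. 300-d).
Zero-norm rows are an error naming the offending word, since cosine is
undefined there.

**Phonology.** Transcription similarity is
$1 - \mathrm{lev}(a, b) / \max(|a|, |b|)$, where $\mathrm{lev}$ is the
Levenshtein edit distance with unit costs. The raw edit distance must be
normalised before the $1 - d$ conversion to keep values in $[0, 1]$; the
longer-string normaliser is the standard bounded choice. Neighbourhood
density yields $|{\rm dens}_i - {\rm dens}_j|$, kept on its native scale as a
*dissimilarity* with an orientation flag. Because the downstream correlations
are Spearman, only the sign convention matters, so dissimilarity vectors are
negated at correlation time rather than remapped onto $[0, 1]$.

**Taxonomy.** Wu–Palmer similarity
$\mathrm{WPsim}(a, b) = 2\,\mathrm{depth}(\mathrm{LCS}) /
(\mathrm{depth}(a) + \mathrm{depth}(b))$ with node-counting depths and
$\mathrm{depth}(\mathrm{root}) = 1$, which keeps every value strictly
positive. Words missing from a source (as happens with real lexical
databases) raise an error listing them; the correlogram then works on the
intersection of labels across models.

**Pair ordering.** Every matrix flattens to its upper triangle in row-major
order $(1,2), (1,3), \dots, (n-1,n)$. The ordering is fixed package-wide so
model and neural vectors always align element by element, and
`rdm_matrix()` inverts `rdm_vector()` exactly.

**Model comparison.** Two dependent overlapping correlations $r_{12}$ and
$r_{13}$ (sharing variable 1, overlap $r_{23}$, $n$ pairs) are compared with
the Pearson–Filon statistic

$$z = \frac{(r_{12} - r_{13})\sqrt{n}}
{\sqrt{(1 - r_{12}^2)^2 + (1 - r_{13}^2)^2 - 2k}},\quad
k = r_{23}(1 - r_{12}^2 - r_{13}^2) -
\tfrac12 r_{12} r_{13} (1 - r_{12}^2 - r_{13}^2 - r_{23}^2),$$

referred to the standard normal. The correlogram values consumed by this test
are treated as Pearson correlations, which is what the statistic is defined
for. The test's type-I error is verified by simulation under a trivariate
null in the test suite. Word pairs within one correlation are not mutually
independent observations; the same caveat applies to any RDM-level
correlation test and is inherited from the method being modelled.

**ANOVA from summaries.** When only per-group means, SDs and sizes are
printed (as in stimulus-matching tables), the one-way F is reconstructed from
the between- and within-group sums of squares those summaries determine
exactly. Rounded inputs propagate to roughly percent-level accuracy in F.

## Activation extraction

**Trial AUC.** The per-trial activation of a voxel is the trapezoidal
integral of its signal from 2 s to 8 s after trial onset, sampled on the
TR = 1 s acquisition grid with linear interpolation at window edges, after
subtracting the (interpolated) signal value at trial onset. The baseline
choice is ours: the source procedure does not state one, and onset
subtraction removes slow drifts and constant offsets without requiring a full
GLM. The operation is exactly linear in the input signal, which the tests
exploit.

**Motion QC.** Framewise displacement is the sum of absolute differentiated
realignment parameters, rotations converted to arc length on a 50 mm sphere
(the conversion radius is configurable; 50 mm is the common convention).
Runs — not volumes — are the exclusion unit: a run is dropped when its
maximum FD exceeds 1 mm (strict inequality).

**Pooling.** Word trials are averaged per word across runs, tasks and
modalities (control trials excluded), producing one pattern per word
(averaging rather than concatenating replications; the RSA consumes one
pattern per condition). Masks binarise grey-matter probability maps at a
strict 0.3 threshold.

## Searchlight RSA

**Neighbourhoods.** Every in-mask voxel is a center whose searchlight is its
k = 200 nearest in-mask voxels by Euclidean distance in mm. Fixed k (with
radius growing as needed) rather than fixed radius matches a design where the
voxel count is set a priori; distance ties are broken by ascending linear
voxel index so neighbourhoods are bit-reproducible across platforms. A mask
smaller than k uses all voxels.

**Neural similarity.** Within a searchlight, the mean pattern across
conditions is subtracted from every condition ("data centring" — the
conventional centring for cosine-based RDMs, without which cosine similarity
is dominated by the shared mean response), then pairwise cosine similarity is
computed. Conditions with zero centred norm flag the searchlight as missing.

**Correlation.** Spearman throughout (average ranks for ties). The partial
correlation rank-transforms all vectors, residualises neural and model ranks
on the covariate ranks (plus intercept) by least squares, and correlates the
residuals; with one covariate this equals the first-order closed form, which
the tests check. Order of post-processing is fixed as
$\rho \rightarrow \operatorname{atanh} \rightarrow$ smooth, taking the
quoted description of the modelled procedure literally. Smoothing is
Gaussian with a configurable FWHM (tests use 5 mm; the modelled procedure
does not state its kernel), with kernel weights renormalised inside the mask
so values never bleed across the mask border and a constant volume is
unchanged.

## Group inference

Voxelwise one-sample t tests ($t = \bar{x} / (s/\sqrt{N})$, $df = N - 1$)
on the per-subject z maps; paired comparisons are one-sample tests on
differences. A voxel enters group statistics only when finite for *all*
subjects; zero across-subject variance flags the voxel missing.

Cluster-extent familywise-error control uses a sign-flipping permutation
null instead of random-field theory (the RFT machinery of the original
software is not reproducible from its description; sign-flipping is
assumption-light and exact under symmetric nulls, and uses the same
voxel-forming threshold, $p < 0.001$ one-sided by default). Clusters are
formed by 18-connectivity (the convention of the modelled software). All
$2^N$ sign patterns are enumerated when $N \le 12$; otherwise a seeded random
sample (always containing the identity) is used, making corrected p-values
reproducible given the seed and, under enumeration, invariant to subject
order. The corrected p of a cluster is the proportion of null maximum cluster
sizes at least as large as it.

Peaks are reported in voxel indices and mm via the voxel size; anatomical
labelling is out of scope. On unsmoothed white noise the null distribution of
the maximum cluster size is extremely discrete and the realised FWE is
conservative (~0.01 at a nominal 0.05); after the pipeline's smoothing step
the realised FWE sits at the nominal level, which is what the calibration
test measures.

## The synthetic-data generator

The generator emulates the study design the pipeline targets: 66 words in
three valence classes of 22; eight runs per subject of 77 trials (66 word +
11 control) at an 8.25 s interstimulus interval, TR = 1 s, giving 8
replications per word; runs in two modalities and two tasks, pooled by the
pipeline; motion traces with FD violations placed exactly in configured
runs; and a grey-matter probability map thresholded at 0.3. Ratings are drawn
per class (positive high valence, negative low, neutral mid) with arousal
following a U-shaped function of valence so the neutral class is least
arousing, mirroring the matching pattern the design reports.

**Planted geometry.** Each signal region carries a target similarity matrix
$S = \sum_m w_m S_m$ (a weighted mixture of model RDMs). $S$ is factored by
eigendecomposition with negative eigenvalues truncated into condition scores
$U$ ($U U^\top = S$ up to the truncation), rotated onto the region's voxels
by a random orthonormal basis, and scaled to unit per-voxel RMS. At zero
noise the cosine similarity of the region patterns therefore *equals* the
planted matrix (up to truncation), and the end-to-end pipeline recovers it at
$\rho > 0.99$.

**Response kernel.** Trial responses follow a smooth gamma-shaped kernel
peaking near 4 s, tapered by a raised cosine to return exactly to baseline
within one interstimulus interval. The pipeline never models this kernel (it
integrates the raw signal), so any plausible shape works; compact support is
the deliberate choice because a long-tailed canonical response at this trial
pacing leaks into the next trial's AUC window after baseline correction,
which would make exact zero-noise recovery impossible. Real BOLD responses do
overlap at this pacing — that contamination, like physiological noise, scanner
drift and spatial autocorrelation, is a feature of real data that the
generator deliberately omits. Passing recovery tests therefore demonstrate
the correctness of the pipeline's computations, not its sensitivity on real
acquisitions.

**Model overlap.** The embedding table is a mixture
$(1-\lambda) Z + \lambda Y$ of unit-norm Gaussian vectors $Z$ and an
affective-aligned factor $Y$ (rotated scores of the affective matrix), with
$\lambda$ tuned by bisection until the embedding-cosine RDM correlates with
the affective RDM within $\pm 0.02$ of the configured target. The default
target, 0.065, emulates the low affective/co-occurrence overlap central to
the independence question; setting it to 0.458 reproduces the
association-level overlap.

**Noise scale.** White voxel noise with SD 1 against unit-RMS planted
patterns and unit response amplitude was chosen once: it yields
single-subject in-region searchlight correlations around 0.5–0.8 at desk
scale, strong enough that 4-subject groups over 10 seeds give decisive
recovery tests. Real single-subject searchlight effects are an order of
magnitude weaker (peak group means near 0.03); the generator is a
correctness harness, not a power simulation.

**Problem sizes.** The `"paper-like-small"` preset runs the full design for
4 subjects on a 20 × 20 × 22 grid of 2 mm voxels (~3,600 in-mask voxels),
which keeps a complete generate–extract–searchlight pass around 10 s per
subject; `"smoke-tiny"` (1 subject, 2 runs, 12³ grid) exercises the on-disk
bundle quickly. Calibration simulations use 12³ grids with 10 subjects and
500 replicates. These sizes are the package's desk-scale choices for
routine verification.

## Numerical conventions and degenerate inputs

* Similarity matrices are symmetrised representations; asymmetry beyond
  1e-12 (1e-8 for floating-point pipelines) is an error.
* Ranks use average ties; searchlight tie-breaks are lexicographic by linear
  voxel index; all randomness flows from explicit seeds.
* Degenerate searchlights (zero-norm centred pattern, zero rank variance)
  yield missing values and are excluded from group statistics; $|\rho| = 1$
  maps to missing under the z transform.
* A model constant after rank transform, or fully explained by its
  covariates, is an error at map time; a degenerate *neural* vector is
  missing, not an error.
* Eigenvalue truncation in pattern planting keeps only components with
  eigenvalue > 1e-10.

## Known limitations

* Partial Spearman by rank-then-residualise is the standard pragmatic
  definition; it is not the same as a fully nonparametric partial rank
  correlation, but it is closed-form checkable and matches common practice.
* Sign-flip cluster inference assumes symmetric per-voxel null
  distributions; Fisher-z maps satisfy this under the null.
* The generator's noise is white in space and time; spatially correlated
  noise would widen searchlight nulls relative to what the calibration tests
  show.
* Surface-based searchlights, cross-validated distance estimators and
  noise-normalised patterns are out of scope, as is anatomical labelling of
  clusters.
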