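# lexrsa

Searchlight representational similarity analysis (RSA) of lexical similarity
models, for researchers asking how different facets of word meaning —
affective judgements (valence, dominance, arousal), co-occurrence-based word
embeddings, word associations, phonology, taxonomy — are reflected in fMRI
activity patterns, and whether those reflections are independent of one
another.

## What it computes

For a set of *n* words, every model produces an *n × n* similarity matrix:

- **affective**: words embedded in (V, D, A) rating space; pairwise Euclidean
  distances *d* max-normalised and converted by *s = 1 − d*;
- **embedding / experiential**: cosine similarity between vectors;
- **phonological**: 1 − Levenshtein distance / max string length, plus
  |Δ neighbourhood density| as a separate dissimilarity model;
- **taxonomic**: Wu–Palmer similarity 2·depth(LCS) / (depth(a) + depth(b)).

At the brain side, per-trial activation maps are extracted by the BOLD
area-under-the-curve rule (trapezoidal integral, 2–8 s post onset, onset
baseline subtracted) from motion-QC'd runs (run excluded if framewise
displacement > 1 mm), pooled into per-word patterns, and analysed in a
whole-brain searchlight (k = 200 nearest in-mask voxels per center): cosine
neural similarity after data centring, then plain or partial Spearman
correlation ρ with each model's RDM vector. Subject maps are Fisher
z-transformed, smoothed, and submitted to one-sample or paired t tests with
cluster-extent familywise-error control by sign-flip permutation
(voxel-forming p < 0.001, cluster FWE p < 0.05, 18-connectivity).

Model-level statistics include the correlogram between model RDMs, the
Pearson–Filon z for comparing two dependent overlapping correlations

> z = (r12 − r13)·√n / √((1 − r12²)² + (1 − r13²)² − 2k),
> k = r23(1 − r12² − r13²) − ½ r12 r13 (1 − r12² − r13² − r23²),

and a one-way ANOVA reconstructed from per-group summary statistics.

A synthetic-data module generates every input the pipeline needs — word sets
with class-structured ratings, embeddings tuned to a target RDM overlap,
transcriptions, taxonomies, and per-subject 4D runs with representational
geometry planted in known regions — so the whole path is testable end to end
with full ground truth. See the methods vignette
(`vignettes/searchlight-rsa-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(lexrsa)

# Comparing two dependent correlations between model RDMs: does the affective
# model overlap more with the association-based model (r = 0.310) than with
# the co-occurrence model (r = 0.065), given their mutual overlap 0.458?
pearson_filon_z(r12 = 0.065, r13 = 0.310, r23 = 0.458, n = 2145)
#> Pearson-Filon z = -11.356, two-sided p = 6.92e-30 (r12 = 0.065, r13 = 0.310, r23 = 0.458, n = 2145)

# Arousal matching across valence classes from printed summaries
anova_from_summary(c(3.98, 4.23, 4.54), c(0.49, 0.79, 1.05), 22)
#> One-way ANOVA (from summaries): F(2, 63) = 2.641, p = 0.0792

# A fully synthetic study: 66 words in 3 valence classes, embeddings tuned to
# overlap the affective RDM at r = 0.065
ws <- generate_word_set(synth_config(n_subjects = 1), seed = 1)
models <- list(affective    = affective_similarity(ws$ratings),
               embedding    = embedding_similarity(ws$embeddings),
               phonological = phonological_similarity(ws$phonology),
               density      = density_dissimilarity(ws$phonology))
model_correlogram(models, method = "pearson")
#> <model correlogram> method = pearson, 66 shared words (2145 pairs)
#>              affective embedding phonological density
#> affective        1.000     0.065       -0.004   0.092
#> embedding        0.065     1.000       -0.006  -0.028
#> phonological    -0.004    -0.006        1.000  -0.034
#> density          0.092    -0.028       -0.034   1.000

# One synthetic subject through the full pipeline: 8 runs x 77 trials,
# motion QC, trial AUC extraction, pooling, then a 200-voxel searchlight
sub <- simulate_subject_patterns(ws, models["affective"], seed = 1, subject = 1)
glance(sub$qc)
#> # A tibble: 1 x 4
#>   n_runs n_excluded pct_excluded threshold_mm
#> 1      8          0            0            1

rho <- searchlight_rsa(sub$patterns, sub$mask, models$affective,
                       k = 200, voxel_size = c(2, 2, 2))
reg <- sub$ground_truth$region_masks$signal
mean(rho[reg], na.rm = TRUE)              # planted-region model fit
#> [1] 0.749
mean(rho[sub$mask & !reg], na.rm = TRUE)  # elsewhere (searchlight smearing)
#> [1] 0.118
```

The searchlight correlation is high exactly where the affective geometry was
planted; partial maps (`covariates =` in `searchlight_rsa()`) let you ask
whether one model's fit survives controlling another, and
`one_sample_ttest()` / `cluster_inference()` take lists of subject maps to
the group level.

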