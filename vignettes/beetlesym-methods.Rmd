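---
title: "Methods: cuticle redness scoring and symbiont rate tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cuticle redness scoring and symbiont rate tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetlesym)
```

## The biological setting

Several stored-product beetles carry bacteriome-associated endosymbionts —
intracellular bacteria housed in dedicated abdominal organs and transmitted
maternally. When such a symbiont is experimentally removed (e.g. by
tetracycline feeding), the host may show subtle phenotypes: a paler or, on a
red-green axis, a *redder*, less sclerotized cuticle, and a lower dry body
weight. On the symbiont side, long-term endosymbiosis leaves a molecular
signature: AT-biased nucleotide composition and an accelerated substitution
rate, both consequences of reductive genome evolution.

`beetlesym` implements the two quantitative arms of such a study:

1. **Cuticle colour scoring** — a redness index measured on ventral
   photographs of the metasternum, with rank-based masking of highlight and
   shadow pixels, compared between symbiotic and aposymbiotic cohorts by a
   two-sample *t* test.
2. **Molecular evolution of the symbiont 16S rRNA gene** — AT content,
   JC69/K2P-corrected distances, two-lineage relative rate tests with
   column-bootstrap variance, and neighbor-joining phylogeny with bootstrap
   supports.

A seeded synthetic-data module generates images, alignments, composition-
biased sequences and weight samples with known ground truth, so every
estimator is testable end to end without any external download.

## The redness index

A specimen photograph is scored in three steps (`score_image()`):

1. **Square extraction** (`extract_square()`). The user supplies a rectangle
   bounding the metasternum (automatic segmentation is out of scope); the
   maximal inscribed square is taken, centred along the rectangle's longer
   axis with ties broken toward the top-left (the centring offset is
   floored). Coordinates are 0-based, half-open.
2. **Brightness masking** (`mask_extremes()`). Pixels whose brightness falls
   in the darkest 10% or brightest 10% are excluded, to suppress specular
   highlights and shadows. Two choices here were genuinely open and are made
   explicit:
   * *Brightness definition.* We use the arithmetic mean of R, G, B. The
     index itself is expressed relative to mean(R,G,B), so this keeps the
     mask and the score on one scale; max-channel and Rec.601 luma are
     available via the `brightness` argument but are not defaults.
   * *What "top/bottom 10%" means.* We read it as pixel-count (rank)
     quantiles, not 10% of the intensity range: rank quantiles are invariant
     to exposure. The cut values are nearest-rank order statistics (the
     values at ranks `ceiling(0.10 N)` and `ceiling(0.90 N)`), and masking
     uses *strict* inequalities against them. Strictness matters in
     degenerate cases: a perfectly uniform region has all brightnesses equal
     to both cuts, so nothing is masked and the index is always defined; it
     also guarantees at least 80% of pixels are retained at the default
     fractions.
3. **Averaging** (`redness_index()`). The index is
   `sum(R - mean(R,G,B)) / n` over the `n` retained pixels, in 8-bit
   intensity units, computed in floating point directly on the raw 8-bit
   integers — no gamma correction or colour-space conversion, matching how
   such photographs are scored in practice. The index is 0 for any grayscale
   image, +170 for pure red, −170 for pure cyan, and is invariant to adding
   a constant to all channels (as long as nothing clips) and to pixel order.

```{r}
sim <- simulate_cuticle_image(200, 200, base_rgb = c(150, 100, 100),
                              noise_sd = 8, highlight_frac = 0.05,
                              shadow_frac = 0.05, seed = 1)
score_image(sim$image, rect = c(0, 0, 200, 200))
sim$truth$redness   # analytic redness of the base colour
```

### What the image simulator does and does not emulate

`simulate_cuticle_image()` draws each pixel independently: with probability
`highlight_frac` a near-white highlight, with probability `shadow_frac` a
near-black shadow, otherwise the base cuticle colour plus per-channel
Gaussian noise (default sd 8 intensity units, a realistic sensor/texture
level for macro photography), clipped and rounded to \[0, 255\]. Highlights
and shadows are *not* spatially clustered as they are in real photographs —
the mask is rank-based, so spatial structure is irrelevant to the statistic
— and no optics (vignetting, chromatic effects, exposure drift) are
modelled. Passing tests therefore demonstrate that the estimator recovers a
known base-colour redness under noise and extreme pixels, not that any
particular camera setup is unbiased.

## AT content

`at_content()` reports `100 * (A + T) / (A + C + G + T)` per sequence. U
counts as T (rRNA-style input behaves like DNA); gaps and IUPAC ambiguity
codes, including N, are excluded from numerator *and* denominator rather
than fractionally allocated — deposited 16S sequences carry almost no
ambiguity, and whole-base exclusion keeps the statistic deterministic. By
construction `at_content + gc_content = 100` exactly, and the value is
invariant under gap insertion and case changes.

## Distances and the relative rate test

Pairwise distances (`dist_matrix()`) use either the JC69 correction
`d = -(3/4) ln(1 - 4p/3)` or the K2P correction
`d = -(1/2) ln(1 - 2P - Q) - (1/4) ln(1 - 2Q)`, with `P`/`Q` the transition
and transversion fractions over shared unambiguous sites. K2P is the default:
16S data are strongly transition-biased, and K2P is the conventional choice
of the classic rate-test tooling for rRNA. Saturated inputs (log argument
≤ 0) raise an error rather than returning infinity. The default site filter
is complete deletion — every column containing a gap or ambiguity in any row
is dropped — so one common site count underlies all distances in a result,
the way a single aligned-site count is quoted for a whole table of tests;
pairwise deletion is available.

The relative rate test (`relative_rate_test()`) asks whether lineage 1 and
lineage 2 have evolved at the same rate since their last common ancestor,
located using an outgroup. For each triplet (a, b, o) the decomposition

```
K1 = (d_ab + d_ao - d_bo) / 2
K2 = (d_ab + d_bo - d_ao) / 2
```

gives the two lineage-to-ancestor distances, with `K1 + K2 = d_ab` exactly.
Multi-taxon lineages are summarised by the *unweighted* mean over all
triplets; topology-aware weighting schemes are deliberately not reproduced
(for single-taxon lineages, the headline use case, the two coincide
exactly). Negative per-triplet values — possible by sampling noise around
near-zero branches — are reported as-is and flagged, never clamped.

The variance of `K1 - K2` is estimated by a nonparametric bootstrap over
alignment columns (default 2,000 replicates, seeded): model-agnostic and
directly checkable against simulation, which is why it is preferred here
over analytic variance formulas. `z = (K1 - K2) / se` is referred to the
standard normal for a two-sided P value. Internally, columns are collapsed
to unique site patterns with counts, and each bootstrap replicate is drawn
as a multinomial over pattern frequencies — exactly the distribution of
resampling columns with replacement, which makes thousand-replicate
calibration studies cheap. Bootstrap replicates whose distances saturate
are skipped and counted, with a warning past 1%. If both lineages hold
identical sequences the difference and its bootstrap variance are both
zero; the test reports `z = 0`, `p = 1` by convention.

```{r}
aln <- simulate_alignment("((L1:0.10,L2:0.05):0,O:0.20);", model = "k2p",
                          kappa = 2, length = 50000, seed = 5)
relative_rate_test(aln, "L1", "L2", "O", n_bootstrap = 500, seed = 9)
```

### Calibration

Two properties are checked at full study scale by the test suite and the
acceptance script: under an equal-rate three-taxon simulation (10,000
sites, 500-replicate bootstrap, 1,000 datasets) the type-I error at
α = 0.05 must lie in \[0.03, 0.07\]; under a 2:1 rate asymmetry (branches
0.10 vs 0.05, outgroup 0.2, 50,000 sites, 50 seeds) the median recovered
`K1/K2` must lie in \[1.8, 2.2\]. These problem sizes are the package's
reference calibration conditions and are what the numbers in the README
refer to.

## Sequence simulation

`simulate_alignment()` evolves i.i.d. sites down a rooted tree whose branch
lengths are expected substitutions per site, starting from a uniform-
composition root (the JC69/K2P stationary distribution) and using the exact
closed-form transition-probability matrices — no Gillespie simulation, so
results are exact and fast. Compositional bias is deliberately *not*
modelled here: the simulator stays exactly matched to the distance
corrections it feeds (which assume stationarity), and AT-content testing is
served by the separate i.i.d. generator
`simulate_composition_sequences()`. No indels, no across-site rate
variation, no GTR-class models. Rate asymmetry between lineages is
expressed through unequal branch lengths, which is precisely the structure
the relative rate test estimates.

## Neighbor joining and bootstrap

`neighbor_joining()` implements Saitou–Nei agglomeration with the
Studier–Keppler criterion `Q[i,j] = (r-2) d[i,j] - R[i] - R[j]`. Ties in Q
are broken by the lowest (row, column) pair, making results identical
across platforms. On an additive matrix the generating topology is
recovered with exact branch lengths (verified in the tests against an
exhaustive least-squares enumeration of topologies). Negative branch
lengths, which NJ can produce on noisy matrices, are clamped to zero in the
returned tree — downstream Newick consumers expect nonnegative lengths —
with the clamp count attached as an attribute.

`bootstrap_nj()` resamples alignment columns (again via the site-pattern
multinomial), rebuilds the NJ tree per replicate, and annotates each
internal edge of the full-data tree with the percentage of successful
replicates containing the same bipartition — supports are matched by
bipartition identity, not node identity. Replicates with saturated
distances are skipped and counted. An alignment of identical sequences has
no signal to resample and raises an error. Maximum-likelihood and Bayesian
inference, substitution-model selection, and alignment construction are out
of scope: alignments are consumed, not computed.

## Phenotype comparison

`welch_t_test()` wraps the standard two-sample *t* test, defaulting to the
Welch unequal-variance form (the safer default when only "*t* test" is
specified; the pooled Student form is an option). Tests are two-sided, and
significance is coded `*` / `**` / `***` at 0.05 / 0.01 / 0.001. With two
planned comparisons (redness, weight) no multiple-testing correction is
applied; this is a documented choice, not an omission. Degenerate input —
both samples constant — yields `p = 1` for equal means and `p = 0`
otherwise, by convention.

## Pipeline and reproducibility

`run_pipeline()` executes stages (`simulate`, `redness`, `atcontent`,
`rrt`, `nj`, `phenotypes`) from a JSON/list config and writes one output
per stage plus `manifest.json` (package version, seed, parameters, MD5 per
output). One top-level seed is split into per-stage substreams by a fixed
affine scheme (`(seed %% 1000003) * 2011 + 7919 * stage_index`, mod
2147483629), so stages are independently re-runnable and a re-run of the
same config is bit-identical. All generators seed through
`withr::with_seed`, leaving the caller's RNG state untouched.

```{r, eval = FALSE}
cfg <- list(
  seed = 7, out_dir = "run1",
  stages = c("simulate", "redness", "rrt", "phenotypes"),
  simulate = list(
    alignment = list(tree = "((L1:0.10,L2:0.05):0,O:0.2);", length = 2000),
    images = list(n_per_group = 10, width = 80, height = 80,
                  base_rgb_sym = c(110, 85, 70), base_rgb_apo = c(120, 87, 72)),
    weights = list(n = 30, mean_sym = 0.9, mean_apo = 0.81, sd = 0.05)),
  rrt = list(lineage1 = "L1", lineage2 = "L2", outgroup = "O"))
run_pipeline(cfg)
```

## Default study conditions

The synthetic defaults encode the conditions the analyses are calibrated
under, chosen once as field-realistic values: cohort sizes of 25 (redness)
and 30 (weights); a +8-intensity-unit redness shift at a between-specimen
sd of 3 (the magnitude at which aposymbiotic cuticles are visibly redder
yet overlapping); dry weights near 0.9 mg with sd 0.05 mg and a −10% shift;
image noise sd 8 with 5% highlight and 5% shadow pixels; 16S-scale
alignments of 10^4–5×10^4 sites for rate-test calibration. They are
defaults, not dials: the test suite asserts behaviour *at* these
conditions.

## Known limitations

* The redness index depends on the user-supplied metasternum rectangle; no
  colour-card normalisation or camera calibration is attempted, so indices
  are comparable only within a constant-lighting imaging session.
* The brightness definition and the rank reading of the 10% cutoffs are
  explicit assumptions (see above); alternatives are exposed as options.
* Exact reproduction of published rate-test values from deposited
  accessions depends on the original tool's (unstated) distance correction
  and deletion policy; this package states its own (K2P, complete deletion)
  and exposes both knobs.
* The relative rate test assumes the outgroup is genuinely external and
  distances are unsaturated; it reports, but does not correct, negative
  triplet decompositions.
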