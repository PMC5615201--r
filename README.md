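# beetlesym

Quantitative analysis of bacteriome-associated endosymbiosis in
stored-product beetles: does the symbiont contribute to host cuticle
formation, and does its genome show the molecular signature of reductive
evolution?

`beetlesym` implements the two measurement arms such a study needs, plus a
seeded synthetic-data module so the whole pipeline is testable with known
ground truth:

* **Cuticle colour scoring.** From a ventral RGB photograph and a
  user-supplied rectangle around the metasternum, the maximal inscribed
  square is extracted; pixels in the darkest and brightest 10% (rank-based,
  strict cuts) are masked to suppress shadows and specular highlights; the
  **redness index** is then

  `index = Σ [R − mean(R, G, B)] / n`

  over the n retained pixels (0 for grayscale, +170 for pure red).
  Symbiotic vs. aposymbiotic cohorts are compared with a Welch *t* test.

* **Symbiont molecular evolution.** Per-sequence AT content
  (`100·(A+T)/(A+C+G+T)`, U→T, ambiguity excluded); JC69 and Kimura
  2-parameter distances,
  `d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)`; the two-lineage **relative rate
  test** — for lineages 1, 2 and outgroup O,
  `K1 = (d12 + d1O − d2O)/2`, `K2 = (d12 + d2O − d1O)/2`, with the variance
  of `K1 − K2` from a column bootstrap and `z = (K1 − K2)/se` referred to
  the standard normal; and neighbor joining (Studier–Keppler) with
  column-bootstrap bipartition supports, Newick in/out.

## Worked example

```r
library(beetlesym)

# --- cuticle redness on a simulated metasternum photograph -------------
sim <- simulate_cuticle_image(200, 200, base_rgb = c(150, 100, 100),
                              noise_sd = 8, highlight_frac = 0.05,
                              shadow_frac = 0.05, seed = 1)
score_image(sim$image, rect = c(0, 0, 200, 200))
#> redness index: 33.280  (n = 32129 of 40000 pixels retained)
```

The base colour (150, 100, 100) has analytic redness
150 − (150+100+100)/3 = 33.33; after masking the 5% highlight and 5%
shadow pixels (plus noise-extreme body pixels — 32,129 of 40,000 retained,
within the ≥ 80% mask guarantee), the index recovers it to 0.05 units.

```r
# --- relative rate test on a 2:1 rate-asymmetric simulation ------------
aln <- simulate_alignment("((L1:0.10,L2:0.05):0,O:0.20);", model = "k2p",
                          kappa = 2, length = 50000, seed = 5)
relative_rate_test(aln, "L1", "L2", "O", n_bootstrap = 500, seed = 9)
#> Relative rate test (k2p, 50000 sites, 1 triplet(s))
#>   K1 = 0.1020  K2 = 0.0489  K1-K2 = +0.0531  K1/K2 = 2.09
#>   z = 23.265, two-sided P = 1e-119  (bootstrap se 0.00228, 500 reps)
```

The generating branch lengths were 0.10 and 0.05 substitutions/site: K1 and
K2 land on them, the ratio recovers the designed 2:1 asymmetry, and the
rate difference is (correctly) overwhelmingly significant.

```r
# --- NJ tree with bootstrap supports -----------------------------------
aln5 <- simulate_alignment(
  "(((A:0.05,B:0.05):0.1,(C:0.05,D:0.05):0.1):0.0,E:0.15);",
  length = 2000, seed = 3)
write_newick(bootstrap_nj(aln5, n_reps = 1000, seed = 4))
#> (E:0.1511870186,(A:0.05270067343,B:0.04946374631)100:0.1022957321,
#>  (C:0.03992944852,D:0.06224032233)100:0.09375736388);

# --- AT content of a 16S PCR primer ------------------------------------
at_content("AGTTTGATCATGGCTCAGGAT")
#> 21 bp ungapped (A 5, C 3, G 6, T 7, ambiguous 0); AT 57.1%
```

Both true internal bipartitions get 100% support; branch lengths are close
to the generating 0.05/0.10/0.15.

`run_pipeline()` chains the stages (simulate → redness → atcontent → rrt →
nj → phenotypes) from a JSON config and writes per-stage TSV/Newick outputs
plus a manifest with an MD5 digest per file; same config + seed ⇒
bit-identical outputs. See the methods vignette
(`vignettes/beetlesym-methods.Rmd`) for the model details, parameter
defaults and design choices.

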