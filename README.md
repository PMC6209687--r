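# oakdemog

Multilocus demographic inference and landscape genetics for temperate oaks
(and other low-marker phylogeographic studies), in R.

The package re-implements, as tested and reusable functions, a complete
analysis pipeline for a species sampled as ~21 populations x 5 diploid
individuals at two phased nuclear loci and one concatenated plastid region:

* **Diversity and neutrality statistics** per locus and partition:
  haplotype diversity *Hd = n(1 − Σp²)/(n − 1)*, per-site nucleotide
  diversity π, Watterson's *θ_W = S/(a₍n−1₎·L)*, Tajima's *D*, the
  maximum-frequency-of-derived-mutations (MFDM) neutrality test
  *p = min(1, 2(n − e)/(n − 1))*, haplotype tables with private-haplotype
  flags, and the Hudson–Kaplan minimum number of recombination events
  (four-gamete intervals).
* **AMOVA** (Excoffier Φ-style, on squared pairwise sequence distances):
  one-level and hierarchical decompositions with Φ_ST, Φ_SC, Φ_CT,
  permutation p-values, and pairwise F_ST matrices.
* **Coalescent simulation** under seven demographic scenarios (constant
  size; exponential decline/growth; expansion-then-decline and
  decline-then-expansion with pre- or post-glacial timing), with
  piecewise-exponential N(t), HKY mutation, and the plastid's 0.5
  effective-size multiplier.  The reference-table path is compiled (Rcpp);
  an independent pure-R engine backs the tests and the structured
  (two-cluster) synthetic data.
* **Approximate Bayesian computation** in the DIY-ABC style: ten summary
  statistics (variance of pairwise differences, Tajima's D, singleton
  segregating sites, mean/variance of the rarest-nucleotide count, per
  plastid and nuclear group), reference tables, direct and
  multinomial-logistic scenario choice with 95% CIs, local-linear
  (Beaumont) parameter estimation, POD-based type I/II error and RMAE,
  and PCA goodness-of-fit.
* **Landscape association**: great-circle geographic distances (R = 6371
  km), scaled-Euclidean ecological distances, two-tailed Mantel and
  partial Mantel tests (999 permutations), and stepwise-AIC
  diversity~environment regressions (Gaussian GLM and Huber RLM).
* **Synthetic studies**: `generate_study()` emulates the full sampling
  design (optionally with a two-cluster split and tunable isolation by
  distance/ecology) so that every stage is testable without external data.

## Worked example

```r
library(oakdemog)

# a synthetic study with the default design: 21 populations x 5 diploids,
# nuclear loci of 336/434 bp, plastid 1814 bp with 5 indel columns
st <- generate_study(synth_config(seed = 8))
ds <- st$dataset

diversity_table(ds, groups = st$truth$cluster_of)[, c("locus", "partition",
  "n", "S", "Hd", "pi", "theta_w", "tajima_d")]
#> # A tibble: 9 x 8
#>   locus partition     n     S    Hd      pi theta_w tajima_d
#> 1 cpDNA species     105    42 0.907 0.00431 0.00443  -0.0846
#> 2 cpDNA cluster1     75    38 0.905 0.00453 0.00429   0.185
#> 3 cpDNA cluster2     30    37 0.920 0.00367 0.00515  -1.05
#> 4 nucA  species     210    53 0.927 0.0144  0.0266   -1.37
#> ...
```

`nucA` shows 53 segregating sites over 336 bp with π ≈ 0.014 per site and
a negative Tajima's D — the footprint of the default expansion-then-decline
history (deep growth inflates rare variants faster than pairwise
diversity).

```r
# ABC scenario choice against a reference table
rt  <- build_reference_table(2e4, seed = 99)       # 7 scenarios x ~2857 rows
obs <- summary_stats(ds)
choose_scenario(obs, rt, tolerance = 0.01)
#> <oak_scenario_choice> tolerance 0.01, 200 accepted
#>    method scenario       pp    ci_lo    ci_hi
#>    direct       S1 0.070000 0.034638 0.105362
#>    direct       S2 0.015000 0.000000 0.031846
#>    direct       S3 0.295000 0.231796 0.358204
#>    direct       S4 0.245000 0.185393 0.304607
#>    direct       S5 0.300000 0.236489 0.363511
#>    ...
```

The data were generated under the expansion-then-decline scenario S4, and
the posterior mass concentrates on S3/S4/S5 — the growth-dominated
histories that are nearly indistinguishable at this design (see the
methods vignette on scenario identifiability).

```r
# hierarchical AMOVA between the two clusters
tidy(amova_two_level(ds$loci$nucA, st$truth$cluster_of))
#>   source                          df sum_sq sigma2 percent  phi   p_value
#> 1 Among groups                     1   3.03 -0.237    0     -0.0140 0.906
#> 2 Among populations within groups 19 443.    0.685    3.99   0.0399 0.0809
#> 3 Within populations             189 3110.  16.5     96.0    0.0265 0.172

# isolation by ecology (null here: the default config has no cluster split
# and ibe_strength = 0)
E   <- ecological_distances(ds$populations, synth_config()$env_variables)
Fst <- pairwise_fst(ds$loci$nucA)
mantel_test(Fst, E)
#>         r p_value n_permutations
#>   -0.0295   0.841            999
```

Each fitted object has broom-style `tidy()`/`glance()` methods and an
`autoplot()` (scenario posterior bars, AMOVA decomposition, Mantel
permutation distribution, goodness-of-fit PCA).

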