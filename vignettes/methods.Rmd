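---
title: "Models and methods behind oakdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oakdemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

oakdemog analyses multilocus sequence data from a phylogeographic study
design — a modest number of populations, a handful of diploid individuals
each, two phased nuclear loci and a concatenated plastid region — and asks
three questions: how is diversity distributed (within/among populations and
clusters), what demographic history generated it (coalescent ABC over seven
scenarios), and whether genetic structure tracks geography or ecology
(Mantel-type tests and diversity~environment regressions).  This vignette
records the models, conventions and design choices; the README shows the
user-facing workflow.

## Sequence statistics

All statistics operate on a `hap_alignment`: equal-length phased sequences
over `A,C,G,T,-,N` with a sample-to-population map.  `N` is always missing
data and is excluded pairwise-complete from difference and
segregating-site counts.  Gaps are a *fifth character state* for the
human-facing statistics (haplotype identity, AMOVA distances) — indel
variation in plastid spacers is informative — but are *dropped by column*
ahead of any ABC statistic, where the simulator never produces gaps.  This
asymmetry is deliberate and mirrors how indels are usually handled by
population-genetic software on the two sides of such a pipeline.

Haplotype diversity uses the small-sample correction
$Hd = \tfrac{n}{n-1}(1-\sum_i p_i^2)$; nucleotide diversity is the mean
pairwise difference count divided by the alignment length; Watterson's
estimator is $S/(a_{n-1}L)$; Tajima's D uses the standard $e_1/e_2$
normalisation and is **undefined (NA)** when $S = 0$ for reporting
purposes.  The ABC stage instead maps every degenerate case to 0 so that
all simulated rows remain usable — a convention difference, not a bug.

Two counts of `L` are reported (`L`, and `L_complete` without any missing
data) because summary tables in the literature are ambiguous about how
software counted partially missing columns; similarly both gene-copy and
individual counts (`n`, `n_ind`) are reported for phased nuclear loci.

The MFDM neutrality test polarises segregating sites with a user-supplied
(or, for synthetic data, true) ancestral sequence, takes the maximum
derived-allele count $e$, and reports $p = \min(1,\,2(n-e)/(n-1))$ — the
neutral-coalescent tail probability of so unbalanced a basal split.  The
minimum recombination bound is Hudson–Kaplan's: biallelic site pairs
showing all four gametes define incompatibility intervals, reduced greedily
by right endpoint (provably the maximum number of disjoint intervals).
Note that recurrent mutation under a finite-sites model can also produce
four-gamete violations; the bound is a statement about the data, not a
proof of recombination.

## AMOVA

AMOVA is Φ-style (Excoffier): sums of squares of pairwise sequence
distances (difference counts, squared), decomposed among/within
populations, or among groups / among populations within groups / within
populations.  Negative variance components are reported as computed;
percentages are renormalised after flooring negatives at zero, with the raw
percentages kept alongside.  Permutation conventions: Φ_ST permutes
sequences among populations; Φ_SC permutes sequences among populations
within their group; Φ_CT permutes whole populations among groups.  All
p-values use $(1+x)/(1+B)$ so that $p > 0$ always.  With few populations
per group the Φ_CT permutation has coarse resolution (with 3+3 populations
only ~10 distinct relabellings exist), so a large Φ_CT can fail to reach
nominal significance — a property of the test, reproduced faithfully.

## Coalescent simulator

Seven demographic scenarios are parameterised as ordered anchors
$(t_i, N_i)$ in backward time (generations), with exponential
interpolation between anchors and constancy beyond the last: a constant
size; decline and growth (two anchors, ancestral size above/below the
current); and four three-anchor histories that place an intermediate bump
(`Ndb` above both endpoint sizes: expansion-then-decline) or dip (below
both: decline-then-expansion) at a time `Tdb` drawn from either a
last-interglacial-to-LGM window (250–1500 generations, i.e. 20–120 ka at
80 y/generation) or an LGM-to-Holocene window (75–275 generations).  The
second window is our own choice — the original supplementary material
pinning it is not available — and spans the mid-Holocene to the LGM.

Priors are uniform: sizes $10^3$–$10^5$ (diploid), ancestral age
$1.25$–$3.75\times10^4$ generations (1–3 Ma at 80 y/generation; we read
the published "(year)" label on that row as a typesetting slip, since the
published posterior ancestral age of ~1.9 Ma is only consistent with
generations), plastid rate $5$–$7\times10^{-8}$ and nuclear rate
$1$–$3\times10^{-7}$ per site per generation.  Ordering constraints are
enforced by rejection; the current size is never constrained against the
ancestral one.

The pair-coalescence rate at time $t$ is $1/(2N(t)m)$ with $m$ the locus
size multiplier: $m=1$ gives the diploid autosomal $2N$ gene copies,
$m=0.5$ the maternally inherited haploid plastid of a monoecious tree
(configurable).  Waiting times invert the integrated rate in closed form
within each exponential epoch.  Mutation is HKY with κ = 2 and equal base
frequencies by default (both configurable per locus group), applied
sparsely by uniformisation: candidate events are Poisson on total tree
length × dominating rate × length, and each hit site evolves down the tree
through the jump chain $P = I + Q/R$.  This is exact for HKY and costs
only O(events), which is what makes a $10^5$-row reference table a
minutes-scale computation.  No recombination and no migration are
simulated (the ABC stage deliberately ignores within-species structure);
per-group mutation rates are shared across loci within a simulation.

Two engines exist: a compiled batch path (Rcpp) used for reference tables
and PODs, and a pure-R path (`simulate_genealogy()` + `mutate_hky()`,
`ape`-compatible trees) used as an independent cross-check in the tests
and as the structured-coalescent engine for synthetic two-cluster data.
Their output distributions are compared by Kolmogorov–Smirnov tests in the
suite.

## ABC

The ten summary statistics are, per locus group (plastid first, then
nuclear), averaged over the group's loci: variance of pairwise difference
counts (unbiased, over all $\binom{n}{2}$ pairs), Tajima's D, the number
of segregating sites whose rarest nucleotide occurs exactly once (our
reading of "private segregating sites" for a single-population sample:
singletons), and the mean and variance of the rarest-nucleotide count over
segregating sites.  Reference tables standardise each statistic by its
table-wide mean and SD; distances are Euclidean on the standardised scale;
the accepted set is exactly $\lceil \text{tolerance}\cdot N\rceil$ rows.

Scenario choice: the *direct* estimate is the scenario frequency among
accepted rows with a normal-approximation binomial CI; the *logistic*
estimate fits a multinomial logit (`nnet::multinom`) of scenario on the
statistics centred at the observation, evaluated at the origin, with CIs
from the asymptotic covariance of the intercepts via the delta method.
Parameter estimation is Beaumont-style local-linear regression with
Epanechnikov weights; sizes and times are adjusted on the log scale and
back-transformed; the mode is the peak of a Gaussian-kernel density
(Silverman bandwidth) of the adjusted draws.  Posterior-predictive
goodness of fit simulates PODs from the (clamped-to-prior) adjusted draws,
reports two-sided empirical tail probabilities per statistic, and projects
everything onto the principal components of the standardised reference
statistics.

**Confidence in scenario choice.** PODs are drawn from each scenario's
prior, pushed through the chosen selection method, and summarised as:
type I error (fraction of focal-scenario PODs in which the focal scenario
is not the highest-probability one), its complement the *selection rate*,
and type II error (mean over competing scenarios of the fraction of their
PODs in which the focal scenario wins).  Under the priors above the focal
expansion-then-decline scenario is intrinsically hard to identify: its
distinguishing decline phase lasts at most 1500 generations while
coalescent time scales with $2N \le 2\times10^5$, so its prior-predictive
distribution largely coincides with those of its neighbours, and *all
three* quantities — selection rate when true, and selection rate when
false under either method — sit near 0.08–0.12 rather than near the
1/7 ≈ 0.14 of exchangeable scenarios.  Published "type I" figures for such
designs are therefore only interpretable as selection probabilities; the
package reports both so the distinction is explicit.

## Landscape stage

Geographic distances are great-circle (haversine) on a 6371-km sphere.
Ecological distances z-score each variable across populations (sample SD;
range scaling available) and take the Euclidean norm — one of several
"scaled Euclidean" conventions in legacy software; z-scoring is the one we
fix.  Mantel tests correlate strictly-upper-triangle entries, permute rows
and columns of one matrix simultaneously, and are two-tailed with
$(1+x)/(1+B)$; the partial Mantel uses the first-order partial correlation
and permutes the first matrix.  A control matrix perfectly collinear with
an input is rejected as degenerate (the partial correlation is 0/0 there);
near-collinear controls legitimately leave only noise, which is why the
tests probe cancellation with a shared-structure construction rather than
an exact-equality one.

Stepwise regression starts from the full candidate model and greedily adds
or drops single terms by AIC until no move improves, for a Gaussian GLM
(`stats::AIC`) or a Huber robust fit (`MASS::rlm`; AIC analogue
$n\log(\text{RSS}_w/n) + 2k$ on the converged weighted residual sum of
squares, since `rlm` has no likelihood).  Per-predictor univariate fits are
returned alongside the winner.  Note the statistical reality of AIC-driven
selection under a pure-noise design: each decoy survives with probability
$\approx P(\chi^2_1 > 2) \approx 0.16$, so an intercept-only outcome with
five decoys occurs in only ~40% of runs; the tests assert this calibrated
behaviour rather than an idealised always-null one.

## Synthetic studies

`generate_study()` reproduces the study design the pipeline targets: 21
populations × 5 diploid individuals, nuclear loci of 336 and 434 bp (210
phased copies), a 1814-bp plastid concatenation (105 copies) whose length
*includes* 5 indel columns (gap alleles assigned along a minor-allele
lineage so they behave like real indel characters), coordinates on a
jittered grid spanning ~10° × 8°, and eight environmental variables around
temperate baselines.  The default demographic history is the
expansion-then-decline scenario at its published point estimates (current
size 3.29 × 10⁴, bump 7.35 × 10⁴ at 878 generations, ancestral 1.66 × 10⁴
at 24 000 generations) — under these conditions nuclear per-site π lands
in the 0.001–0.02 envelope of the motivating data in most seeds.

Optional structure: the labelled cluster-2 populations evolve as a
separate deme with no migration since `cluster_split_time` (structured
pure-R engine, layered on the global scenario so the ABC engine itself
stays panmictic); `ibe_strength` shifts temperature seasonality up and
broadens precipitation seasonality for cluster 2 (at strength 1 the shift
is large — ~6 within-population SDs on BIO4 — so that an 8-variable
ecological distance matrix carries a reliably detectable signal at n = 21);
`ibd_strength` adds latitudinal/longitudinal trends; `fix_plastid` samples
a single maternal lineage per population, reproducing the
every-population-fixed plastid pattern (F_ST = 1).

What the generator does **not** emulate: real spatial coalescent
structure (isolation by distance arises only through the environmental
trends, not through migration), recombination, sequencing error, phasing
uncertainty, and real WorldClim covariance between bioclimatic variables.
A pipeline that passes on these data is therefore validated for its
*computational* behaviour, not certified against every idiosyncrasy of
field data.

## Numerical choices and test scales

Ties in scenario choice resolve to the first maximum; zero-variance
statistic columns are dropped from standardisation; Epanechnikov weights
at the boundary row are floored at a small positive value; singular
local-linear designs fall back to rejection-only with a warning; the
rejection sampler for constrained priors aborts after 10⁶ draws.  Times
are generations internally; multiply by the generation time (default 80 y)
for years.

The test suite runs its simulation-based checks at deliberately chosen
desk scales: a shared 10⁵-row reference table (full locus lengths) with
200 PODs per scenario for the confidence experiment; 5 × 10⁴-row and
nested 10³/10⁴/10⁵ subsets for recovery and RMAE monotonicity (subsets of
an iid-within-scenario table are themselves valid smaller tables; the
RMAE comparison runs at a 10% tolerance, the smallest power of ten whose
accepted set exceeds the regression covariate count at every size —
tighter tolerances leave the 10³-row table with a degenerate local-linear
design); 500–600
replicates for estimator-unbiasedness and permutation-calibration checks;
and 10–25 seeds for property-style generator checks.  The whole suite
completes in roughly a quarter of an hour on one CPU.

## Known limitations

* The ABC stage assumes panmixia within scenarios; hierarchical structure
  in the data (which the synthetic generator can induce) is a model
  violation the goodness-of-fit stage may or may not flag.
* Finite-sites homoplasy at high θ can mimic recombination in the
  four-gamete bound and perturb the MFDM polarisation.
* The logistic scenario-choice CIs are asymptotic; with few accepted rows
  per scenario they can be degenerate (probability pinned at 0 or 1).
* RLM's AIC analogue is a pragmatic device, not a likelihood; comparing
  GLM and RLM AICs across families is not meaningful, only within.
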