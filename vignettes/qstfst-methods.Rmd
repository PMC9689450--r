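---
title: "Methods: Q_ST-F_ST comparison for half-sib provenance trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Q_ST-F_ST comparison for half-sib provenance trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements, the assumptions behind them, the choices made where the design
was genuinely open, and what the simulation-based tests do and do not
demonstrate. Nothing here states an empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## 1. The study design

A provenance trial plants open-pollinated (half-sib) families collected
from many source populations together in one randomized-block garden, so
that phenotypic differences between provenances reflect genetics rather
than site. The same populations are genotyped at microsatellite (SSR)
loci, which are taken as selectively neutral. Comparing the
among-population share of trait variance (Q_ST) with the neutral marker
differentiation (F_ST) asks whether trait divergence exceeds what drift
alone would produce.

## 2. The trait model

Every observation is modelled as

$$Y_{ijkl} = \mu + B_i + P_j + F_{k(j)} + E_{ijkl}$$

with fixed block effects $B_i$, random provenance effects
$P_j \sim N(0, \sigma^2_P)$, random family-within-provenance effects
$F_{k(j)} \sim N(0, \sigma^2_F)$, and residuals
$E \sim N(0, \sigma^2_E)$. `fit_varcomp()` fits this by REML through
`lme4::lmer` with the family term coded as the provenance-by-family
interaction, so family labels only need to be unique within their
provenance. `lme4` enforces non-negative variance components by its
boundary parameterization; a component estimated at the boundary is
reported as exactly 0. Convergence is checked from the optimizer status
and `lme4`'s convergence messages and propagated as a flag; results with
`converged = FALSE` should not be reported.

Because half-sib family variance is one quarter of the additive genetic
variance, the quantitative differentiation is

$$Q_{ST} = \frac{\sigma^2_P}{\sigma^2_P + 8\,\sigma^2_F}.$$

`pairwise_qst()` refits the model on every pair of provenances (231 pairs
for 22 provenances) rather than reusing the global fit: whether the
original analysis refit per pair is not stated anywhere we could verify,
and the per-pair refit is the choice that lets each pair's own design
imbalance propagate into its estimate. Block factors are rebuilt from the
pair's observations; in a crossed randomized-block design every block is
present in every pair, so the coding is the same as the full model's.
Pairs where either member has a single family are flagged (`sigma2_F`
inestimable), as are pairs whose fit fails or lands on the double
boundary ($\sigma^2_P = \sigma^2_F = 0$, where the ratio is 0/0).

Survival (SR) is analyzed on its observed 0/1 scale with the same linear
mixed model, not through a link function, because one model is applied
uniformly to all traits; the simulator additionally offers a
threshold-liability generator for SR so both observation models can be
exercised. Trait codes are year-indexed (`HEIT` year 1..5 etc.) without
assuming any other numbering convention.

## 3. Marker statistics

All marker statistics start from per-population allele counts with
missing genotypes — encoded as the (0, 0) pair — excluded cell-wise.
Population-by-locus cells with no typed individuals are flagged
undefined, never silently zero.

* Diversity per cell: observed alleles $N_a$; effective alleles
  $N_e = 1/\sum p^2$; Nei gene diversity $h = 1 - \sum p^2$; unbiased
  expected heterozygosity $He = \frac{2n}{2n-1}\,h$; Shannon index
  $I = -\sum p \ln p$; Botstein's codominant PIC
  $1 - \sum p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$; and $F_{IS} = 1 - Ho/h$
  (per locus, then averaged). Assigning the sample-size-corrected
  quantity to `He` and the raw $1-\sum p^2$ to `h` is the only
  assignment under which `He >= h` for every population, which is how
  per-population summaries in this field print the two columns.
* G_ST uses the Nei–Chesser (1983) sample-size-corrected $H_S$ and
  $H_T$, including their observed-heterozygosity terms, with the
  multilocus value formed from the locus-averaged $H_S$ and $H_T$.
  Negative per-locus estimates are reported as computed; globally
  monomorphic loci are undefined and excluded from the average with a
  warning.
* Pairwise and multilocus F_ST is the Weir–Cockerham (1984) theta,
  summed over alleles and loci as the ratio of among-population
  components to total components. Estimates are kept untruncated in
  tables; truncation at zero is applied only on request, for use as a
  distance.
* Nei's (1972) standard distance averages the identity sums over loci;
  a pair with zero shared identity (fixed differences) is reported as
  infinite with a warning, and tree building refuses infinite input
  rather than capping silently — `bootstrap_support()` caps explicitly
  at twice the largest finite distance unless the caller supplies a cap.

Hardy–Weinberg testing defaults to a Monte-Carlo exact test: conditional
on the observed allele counts, alleles are re-paired at random and the
conditional probability of each table is compared with the observed
one. SSR loci here carry ~8 alleles per locus, which makes asymptotic
chi-square counts sparse; the chi-square test is retained as a fast
alternative. The Bonferroni threshold divides alpha by the full grid of
population-by-locus cells (31 x 15 = 465 cells at the study design, so
0.05/465 ≈ 0.00011); non-applicable (monomorphic) cells still count in
the denominator, which reproduces the published accounting of "465
tests".

## 4. Geography and climate

Sites are embedded on a sphere of radius $R$ plus elevation:
$x = (h+R)\cos(\mathrm{lat})\cos(\mathrm{lon})$,
$y = (h+R)\cos(\mathrm{lat})\sin(\mathrm{lon})$,
$z = (h+R)\sin(\mathrm{lat})$, and the geographic distance is the
straight-line (chord) norm between embeddings — deliberately not the
great-circle arc. $R$ defaults to 6,371,000 m, elevation shares the
meter unit, and coordinates are converted to radians before the
trigonometry; none of these are stated by the formula itself, so they are
package choices. Degree–minute text (`25°19′`) is parsed with hemisphere
letters and second marks supported. Climate distance per variable is the
absolute difference of population means. No ellipsoid (WGS84) geodesy
and no climate interpolation are attempted.

## 5. Matrix inference

`mantel()` correlates lower triangles and permutes rows and columns of
one matrix jointly; `p = (1 + \#\{r^* \ge r\})/(n_{perm}+1)`, one-sided
positive by default (two-sided available), 10,000 permutations by
default. Undefined cells are pairwise-deleted and the retained pair count
is always reported. The isolation-by-distance regression is OLS of
$x/(1-x)$ on $\ln(\text{distance})$ over pairs, with a Mantel p on the
transformed matrices; differentiation entries of 1 or more make the
linearization infinite and are an error, and zero-distance pairs are
excluded with a count. Correlation grids between per-trait Q_ST matrices
and predictor matrices are not adjusted for multiple testing — matching
the way such tables are conventionally printed — with Holm adjustment
behind a flag.

## 6. The neutrality test

`qst_fst_test()` forms the observed statistic $Q_{ST} - F_{ST}$ (REML
Q_ST; multilocus theta) and builds its neutral null by resampling, in the
spirit of the half-sib dam-design comparison tools:

1. $\theta^*$ — bootstrap loci with replacement and recombine their
   Weir–Cockerham components.
2. Neutral components — draw the design mean squares as scaled
   chi-squares: $MS_E^*$ on the residual df, $MS_F^*$ on
   $df_F = n_{fam} - n_{pop}$, $MS_P^*$ on $df_P = n_{pop} - 1$, with
   expectations set by the fitted $\sigma^2_E$, $\sigma^2_F$ and the
   neutral $\sigma^2_{P,neut} = 8\sigma^2_F\,\theta^*/(1-\theta^*)$
   (so that the neutral expectation of Q_ST equals $\theta^*$). Recover
   $\sigma^{2*}_F = (MS_F^* - MS_E^*)/k_F$ and
   $\sigma^{2*}_P = (MS_P^* - MS_F^*)/k_P$, where $k_F$ and $k_P$ are
   the balanced-design coefficients (observations per family and per
   provenance; group-size means when the design is unbalanced).
3. Form $Q^*_{ST} - \theta^*$, report the 2.5%/97.5% null quantiles as
   critical values, and a two-tailed p as twice the smaller add-one
   tail fraction, capped at 1.

Drawing the mean squares — not the components directly — matters: the
subtraction in the moment equations is what gives variance-component
estimates their heavy sampling noise, and a null that skips it is far too
narrow (we measured neutral rejection rates of ~25% that way). With the
mean-square construction the neutral rejection rate at $\alpha = 0.05$
is 0.04–0.05 in the calibration suite. The df conventions
($n_{pop}-1$; $n_{fam}-n_{pop}$) are package choices, documented here
because the upstream tools only cite them implicitly. By default the
resampled components are projected onto $[0, \infty)$
(`truncate_null = TRUE`), mirroring the REML boundary constraint on the
observed side; calibration is insensitive to this switch. $\theta^*$ is
clamped to $[10^{-6}, 1-10^{-6}]$ so the neutral $\sigma^2_{P,neut}$
stays finite when a bootstrap replicate lands on a degenerate locus set.

Two honest caveats. The null mean of $Q^* - \theta^*$ is not exactly
zero: $Q^*$ is a nonlinear ratio and carries a small Jensen bias (about
2% of the null SD at the trial scale), which no amount of resampling
removes. And the direction calls are asymmetric at small designs: REML
truncation compresses the observed statistic's left tail, so
uniform-selection calls are slightly conservative.

The test refuses fewer than 5 loci or 3 populations (the locus bootstrap
and the provenance df would make the null meaningless), and refuses
traits whose family variance is estimated at 0 (the neutral Q_ST is then
undefined).

## 7. The simulator

`simulate_markers()` draws per-population allele frequencies from the
Balding–Nichols island model: Dirichlet with parameters
$p_a (1-F)/F$ around ancestral frequencies, giving a closed-form F_ST
dial; genotypes are two independent draws per individual, i.e.
Hardy–Weinberg within populations. Defaults emulate the SSR panel of a
31-population chinaberry survey: 15 loci, 15 diploids per population,
8 alleles per locus drawn from a symmetric Dirichlet(2) (expected
heterozygosity ≈ 0.8), and `target_fst = 0.086`, the multilocus
differentiation level of that survey. The acceptance suite verifies the
dial: mean multilocus theta over 50 replicates within ±0.03 of targets
0.02, 0.086 and 0.2.

`simulate_common_garden()` draws effects exactly as the trait model
assumes, with fixed block offsets (default an evenly spaced ±0.5
gradient), unequal family counts per provenance supported as a vector
(1–26 in the emulated design), missing-at-random thinning standing in
for field mortality, and an optional threshold-liability binary survival
trait. Defaults are 22 provenances, 10 families each, 10 blocks, 5 trees
per family per block, $\sigma^2_P = 0.3$, $\sigma^2_F = 0.05$,
$\sigma^2_E = 1$ — a true Q_ST of 0.43, within the 0.3–0.8 band of
annual Q_ST means such trials report. All randomness derives from one
integer seed with deterministic stream splitting; identical seed and
config give bit-identical output.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: no coalescent ancestry, linkage, or
mutation model; no null alleles or genotyping error; no spatially
explicit dispersal; trait effects are exactly Gaussian with no
genotype-by-block interaction or spatial field trend; mortality is
missing-at-random, not selective. Calibration results transfer to real
trials only to the extent those assumptions hold.

`simulate_geography_climate()` places sites uniformly in a
latitude/longitude box (default 18–39° N, 100–120° E, elevations up to
1500 m, the emulated species range) and builds 23 climate variables as
linear-in-latitude plus Gaussian noise, so geography–climate coupling is
configurable per variable down to zero.

## 8. Trees and cluster-number selection

Neighbor joining is delegated to `ape::nj`; negative branch lengths (an
NJ artifact on non-additive input) are clamped to zero with the deficit
moved to the sister branch and the count recorded. `ape`'s deterministic
tie handling replaces the lexicographic tie-break we would otherwise
specify; for fixed input the output is reproducible either way. Support
values come from resampling loci with replacement, rebuilding the Nei
distance and tree per replicate, and counting bipartitions of the
original tree (`ape::prop.clades`), 1000 replicates by default. On
island-model data the true tree is a star, so mid-range supports
(0.3–0.5) are expected and two independent bootstrap streams agree on
average to ±0.05. The Newick writer quotes labels containing
metacharacters and round-trips through the package's reader.

`evanno_delta_k()` implements the standard second-order-difference
selection of the cluster number from a table of replicate-run
log-likelihoods: $L'(K)$, $L''(K)$, $\Delta K = L''(K)/SD(L(K))$, with
zero-SD groups flagged rather than divided by. The clustering inference
itself (the MCMC) is out of scope; only the selection from a supplied
likelihood table is provided.

## 9. Problem sizes in the test suite

The suites size their simulations to what the statistics need, not more:
estimator oracles run on toy tables; the F_ST dial check uses 50
replicates at 20–31 populations; variance-component recovery uses 50
seeds at the full trial design (22 provenances x 10 families x 10 blocks
x 5); the neutrality-test calibration uses 200 neutral and 50 inflated
replicates at 15 populations x 8 families x 5 blocks with 500 resamples,
a scale at which the method's nominal error rates are measurable with
usefully small Monte-Carlo noise.

## 10. Known limitations

* Single-trait analysis only: no multivariate REML, no heritability or
  genetic-gain estimation, no spatial field-trend correction.
* The neutrality null conditions on the fitted $\sigma^2_F$ and
  $\sigma^2_E$; traits with family variance at the boundary cannot be
  tested.
* Unbalanced designs enter the null through mean group sizes; severely
  unbalanced family sets (single-family provenances) are flagged rather
  than modelled exactly.
* No partial Mantel or MMRR-style decomposition of geography vs
  environment; correlations are reported predictor by predictor.
* AMOVA, null-allele inference, linkage-disequilibrium testing and
  stepwise-mutation distances are out of scope.
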