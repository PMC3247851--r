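---
title: "Planning DNA-pooling GWAS: variance components, effective sample size and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning DNA-pooling GWAS: variance components, effective sample size and power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolgwas)
```

## The problem

A genome-wide association study (GWAS) genotypes thousands of individuals on
SNP arrays. Pooling replaces individual genotyping in Phase I: equal amounts
of DNA from the cases are combined into one pool, likewise the controls, and
each pool is assayed on a handful of arrays. The array then reports, for each
SNP, an *estimated allele frequency* of the pool (allelotyping) rather than
individual genotypes, at a small fraction of the cost. The price is extra
error in the frequency estimates, and therefore a loss of power. This package
quantifies that error from replicate-array data, and translates it into the
quantities a study designer actually needs: effective sample size, planning
tables, and pool-adjusted power.

## Allele frequency from bead intensities

On a two-colour beadarray each SNP is interrogated by roughly 16–18 beads,
each reporting a green and a red fluorescence intensity corresponding to the
two alleles. The pooled frequency estimate for a SNP is the unweighted mean
of the per-bead intensity ratios,

$$\tilde p = \frac{1}{n}\sum_{i=1}^{n} \frac{G_i}{G_i + R_i},$$

computed by `snp_allele_frequency()` / `build_frequency_table()`. Before
estimation three quality rules apply (`filter_beads()`):

* beads with a negative intensity in either channel are removed (background
  subtraction during image processing can produce these; the negative rule is
  applied first, so a bead with one negative and one zero channel counts as
  negative);
* beads with zero in both channels are failed and removed;
* SNPs left with fewer than four beads are excluded entirely — they are
  *absent* from the frequency table rather than carried as `NA`, so paired
  comparisons downstream automatically use the intersection of SNP sets.

### Strip normalization

Arrays are manufactured in strips, and the red:green intensity balance can
differ markedly between strips and arrays. `normalize_array()` rescales the
red channel per strip by a factor $c$ so that the strip's mean allele
frequency is 0.5. Because every bead ratio $G/(G + cR)$ is non-increasing in
$c$, the strip mean is monotone and the root is unique; it is found by
bisection on $\log c$ over $c \in [10^{-6}, 10^{6}]$ to $|{\rm mean}-0.5|
\le 10^{-9}$ (cap 200 iterations). Strips where the mean cannot reach 0.5
(e.g. every bead red-only) raise a non-normalizable error naming the strip.

Two open choices were settled as follows. The targeted mean is the mean of
*per-SNP* frequency estimates (each SNP with ≥ 4 beads counts once), not of
raw per-bead ratios — the two differ when bead counts vary across SNPs; a
`level = "bead"` switch provides the alternative. And only multiplicative
scaling of the red channel is performed; no additive offset is implied by a
channel-balance correction.

## Variance decomposition from paired arrays

Model the estimate from array $x$ of pool $a$ as
$\tilde p_{ax} = \hat p_a + e_{\rm array}$, where $\hat p_a$ is the pool's
true frequency. Three kinds of paired-array contrasts isolate the variance
components; all use

$$\widehat{\rm var}(\tilde p_1 - \tilde p_2)
  = \frac{1}{n-2}\sum_{i=1}^{n}(\tilde p_{1,i} - \tilde p_{2,i})^2$$

over the $n$ SNPs shared by the two arrays (`paired_diff_variance()`; the
$n-2$ denominator is kept exactly as the field's estimator is defined — at
$n$ in the hundreds of thousands it is immaterial, and the package's tests
cover it explicitly at small $n$ where it is not).

* **Type A** — two arrays of the *same* pool: the only source of variation
  is the array, so ${\rm var}(e_{\rm array}) = {\rm var}(\tilde p_{a1} -
  \tilde p_{a2})/2$. With $k$ replicate arrays, all $\binom{k}{2}$ pairings
  are averaged (`array_variance_pool()`).
* **Type B** — arrays of two *independently constructed but identical*
  pools: array and construction error both contribute, giving the pooling
  variance ${\rm var}(e_{\rm pooling,1}) = {\rm var}(\tilde p_{a1} -
  \tilde p_{b2})/2$, averaged over all cross pairings.
* **Type C** — arrays of pools holding *different individuals*: genuine
  binomial sampling now also contributes, and is subtracted per SNP:
  $${\rm var}(e_{\rm pooling,2}) = \frac{1}{n-2}\sum_i
    \left[(\tilde p_{a1,i}-\tilde p_{b2,i})^2 - \tilde V_i\right] / 2,
    \qquad
    \tilde V_i = \frac{p_{a1,i}(1-p_{a1,i})}{2N_a} +
                 \frac{p_{b2,i}(1-p_{b2,i})}{2N_b}.$$
  $\tilde V_i$ is evaluated at the observed frequencies of that specific
  pairing. It is the variance of a difference of two independent estimates,
  hence a **sum** of the two pools' binomial variances with diploid $2N$
  denominators; a `denominator = "N"` switch is available for comparison
  with per-individual conventions.

Construction variance follows by subtraction,
${\rm var}(e_{\rm construction}) = \max(0,\ {\rm var}(e_{\rm pooling}) -
{\rm var}(e_{\rm array}))$; chance can drive the raw difference negative, and
the clamped-at-zero convention is used with the pre-clamp value retained.

`decompose_experiment()` orchestrates this over a whole experiment: Type A
over every within-pool pairing, Type B for pools with a construction
replicate (linked by `replicate_of`), Type C for the rest against all arrays
of all other pools (each estimate the unweighted mean over its cross
pairings), optional stratification by `batch_id`, and a diagnostic that
flags (never removes) any array whose mean pairwise variance exceeds five
times the experiment median — the signature of a faulty array.

## Planner theory

Drawing $N$ diploid individuals into a pool samples $2N$ chromosomes, so the
pool's true frequency varies around the population value with
$V_s = p(1-p)/2N$ — variation a pooled design shares with individual
genotyping of the same people. Measurement adds ${\rm var}(e_{\rm pooling})$,
which $k$ replicate arrays reduce by $1/k$. The **relative sample size**

$$ {\rm RSS} = \frac{V_s}{V_s + {\rm var}(e_{\rm pooling})/k} = \frac{N^*}{N} $$

is the fraction of the pool's nominal size retained, and $N^* = {\rm RSS}
\cdot N$ (rounded to the **nearest** integer — required so that, e.g.,
283.76 reports as 284) is the **effective sample size**: the number of
individually genotyped samples with equivalent precision.

Notes on conventions, each of which the tests pin down:

* The $1/k$ reduction applies to the *entire* pooling variance, construction
  component included. Physically only array error averages over replicate
  arrays, but this is how planning tables in the field are computed and how
  the worked numbers reproduce; `reduce = "array-only"` gives the
  conservative alternative.
* An "array:construction ratio" of `7:3` means construction is 30% of the
  *total* pooling variance, i.e. ${\rm var}(e_{\rm pooling}) =
  {\rm var}(e_{\rm array})/0.7$.
* Average minor allele frequency defaults are shipped per array class
  (`default_array_maf`): 0.21 for the 1M-class arrays, 0.29 for the
  660-class; any $p \in (0, 0.5]$ may be supplied.
* `arrays_for_target_rss()` uses the closed form
  $k = \lceil {\rm var}(e_{\rm pooling})\,t / (V_s (1-t)) \rceil$ for target
  $t$, guarded by a scan at the boundary against floating-point edge cases.
* `optimal_allocation()` scans every split of a fixed array budget between
  two pools, minimising ${\rm var}_A/k_A + {\rm var}_B/k_B$ (the estimation
  contribution to the case–control difference); ties break toward the more
  balanced split. With equal pooling variances the optimum is the equal
  split regardless of pool sizes — arrays should not be allocated
  proportionally to pool size.

## Power and minimum detectable odds ratio

Effective sample sizes plug into any case-control power calculator. For
convenience the package ships a standard normal approximation to the
two-sided allelic test on $2N^*$ chromosomes per group
(`power_case_control()`): control frequency $p_0$, case frequency
$p_1 = {\rm OR}\,p_0 / (1 + p_0({\rm OR}-1))$ under a log-additive
(per-allele) model, null SE from the pooled frequency, alternative SE from
the group frequencies. Under the rare-disease approximation control
frequencies equal population frequencies. `minimum_detectable_or()` inverts
the curve by bisection on $\log {\rm OR}$ (tolerance $10^{-4}$). This is an
approximation — different calculators' power internals differ in the percent
range — so comparisons against published MDOR values are made at ±0.05 and
as orderings, never digit-exact; the package's own tests cross-check the
approximation against Monte-Carlo simulation of the test itself.

## The synthetic-data generator

No public bead-level pooled dataset exists to validate against, so
`simulate_experiment()` generates one with known ground truth, following the
error model above literally:

1. true population frequency per SNP (default uniform MAF on [0.05, 0.5]);
   the green-labelled allele is the minor or major allele with probability
   1/2 each — this makes the mean green-allele frequency of a strip ≈ 0.5,
   the symmetry strip normalization relies on;
2. realized pool frequency: Binomial($2N$, $p$)/$2N$, *shared* by
   construction replicates (they are built from the same DNA samples);
3. + Gaussian construction error per constructed pool (SD
   `sd_construction`);
4. + Gaussian array error per array (SD `sd_array`);
5. + Gaussian bead noise per bead (SD `sd_bead`); green $= I f$, red
   $= I(1-f)\,b_s$ with $I$ a per-bead total intensity and $b_s$ the
   strip's red-channel inflation;
6. a configurable fraction of beads per array has one channel forced
   strictly negative (emulating background over-subtraction; forced values
   are $-(|x|+1)$ so the forced count is exact).

Every perturbed frequency is clipped to [0, 1]; clip events are counted and
a clip fraction above 1% is flagged, since heavy clipping breaks the
additive-error reading of the recovered variances. Defaults emulate a
660-class experiment: 17 beads per SNP, ${\rm var}(e_{\rm array}) =
3.3\times10^{-4}$, construction at 30% of pooling variance, 3% negative
beads. Gaussian error shapes are a modelling choice (the additive model
itself does not specify a distribution); kept small, they make clipping
negligible at default MAFs.

What the generator does *not* emulate: unequal allelic amplification (its
effects largely cancel in paired contrasts, and all estimators here are
paired), dye-bias and saturation physics, and LD between SNPs (SNPs are
independent). Passing recovery tests therefore validate the estimators under
the stated error model, not the full physics of a real array.

Because a per-array frequency estimate averages `beads_per_snp` noisy bead
ratios, any array-level estimator absorbs
$\sigma^2_{\rm bead}/\texttt{beads\_per\_snp}$ into the array component;
`recovery_report()` accounts for this in its "injected" column.

## Validation problem sizes

The package's test suite recovers injected parameters end-to-end (beads →
filter → normalize → decompose): array variance $3.3\times10^{-4}$ from one
pool of 2 arrays at $10^5$ SNPs (within 10%), and a 30% construction share
from a replicate-pool pair (2 + 2 arrays, Type B route) averaged over 20
seeded replicates of 5000 SNPs (within 5 percentage points). Bead noise is
set to zero in these runs so the injected array variance is exactly the
Type A estimand. Small-$n$ brute-force oracles (explicit loops over SNPs
and pairings) pin down every estimator, including the $1/(n-2)$ scaling and
all-pairings averaging, to machine precision.

## Known limitations

* Array variance is treated as constant across SNPs; in reality low-MAF
  SNPs are estimated with larger error, so a single mean understates their
  variance.
* The Type C binomial correction may under-correct real sampling variation;
  construction estimates from Type C tend to run higher than Type B, and
  clamping negatives at zero biases small construction estimates upward.
* The power module is a design-stage approximation, not an analysis tool:
  association testing between pools (with pooling-error-aware test
  statistics) is out of scope.
* Raw (unnormalized) mode is provided, but raw-data variance estimates are
  several-fold larger and dominated by channel-balance artifacts; normalized
  mode is the default for a reason.
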