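---
title: "Methods: position-density testing of rare variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: position-density testing of rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doestrare)
```

## The model and its assumptions

A tested region holds $P$ rare variants at positions $l_1,\dots,l_P$ (1-based
bp offsets in a region of length $L_g$), with rare-allele counts
$X_{ij}\in\{0,1,2\}$ for individual $i$ and binary phenotypes $Y_i$. The null
hypothesis is that cases and controls share both the *position distribution*
of rare mutations and the *average allele frequency*; the alternative is a
difference in either. The statistic is

$$\mathrm{STAT}=\int_1^{L_g}\left|\hat p^A \hat f^A(pos)-\hat p^U \hat
f^U(pos)\right|\,dpos,$$

where $\hat f$ are Gaussian kernel density estimates of mutation positions
weighted by each variant's share of the group's mutations, and $\hat p$ are
weighted mean allele frequencies. Without the $\hat p$ factors this is the
total-variation-style distance between the two position densities; the
factors add burden sensitivity, so a pure excess of mutations in cases is
detected even with identical position distributions.

The variant weights $w_j = P(M_j^A \le m_j^A)$ under
$M_j^A \sim \mathrm{Bin}(2N_A, \hat q_j^U)$, with
$\hat q_j^U = (m_j^U+1)/(2N_U+2)$, assume deleterious (not protective)
causal variants: a variant enriched in cases relative to its control
frequency gets weight near 1, a depleted one near 0. The shrinkage in
$\hat q_j^U$ keeps the binomial parameter strictly inside $(0,1)$ even for
variants unseen in controls.

Significance is by phenotype permutation with the ties-inclusive estimator
$p=(r+1)/(B+1)$, $r=\#\{b: \mathrm{STAT}^{(b)}\ge \mathrm{STAT}\}$. This is
valid (sub-uniform under the null) for any statistic, which is why the
burden-formula constant discussed below cannot affect error rates.

## Numerical and design choices

**Burden constant.** Printed renderings of the weighted-mean-frequency
formula sometimes carry an extra $1/P$ factor of ambiguous placement. We
define $\hat p = \sum_j w_j m_j/(2n) \,/\, \sum_j w_j$, the weighted mean
allele frequency. Any constant common to $\hat p^A$ and $\hat p^U$ rescales
every observed and permuted statistic by the same factor, leaving all
exceedance ranks — hence all permutation p-values — unchanged. The test
suite asserts this scale-cancellation property directly.

**Bandwidth.** No canonical bandwidth exists for count-weighted position
densities; we default to Silverman's rule of thumb on the pooled,
count-weighted position sample, $0.9\min(s,\mathrm{IQR}/1.34)\,n^{-1/5}$
with $n$ the total rare-allele count, floored at $L_g/100$ so that regions
with one or two distinct mutated positions still get a usable curve. The
pooled counts are invariant under label permutation, so the bandwidth is
computed once per region and shared by the observed and all permuted
statistics (this also makes the permutation loop cheap: the grid × variant
kernel matrix is precomputed and each permutation is a matrix product).
`bw` is exposed as a parameter for sensitivity analysis.

**Grid and quadrature.** $G=1000$ equally spaced points on $[1,L_g]$ and the
trapezoidal rule, both configurable. Tests compare against a 100× finer
Riemann sum; agreement is well within 1% relative error for
$bw \ge L_g/200$. No boundary correction is applied: kernel mass leaking
outside the region affects both groups symmetrically.

**Degenerate inputs.** Monomorphic variants are dropped (with a message)
before testing. If the *observed* data have no rare mutation in one group
the test is undefined and reported as such — this mirrors how missing
p-values arise in candidate-gene practice. A *permuted* labeling that
empties one group is still used: that group's scaled curve is identically
zero ($\hat p = 0$), so the permuted statistic is the integral of the other
group's scaled curve. This keeps every permutation usable without biasing
the exceedance count in either direction; with realistic mutation counts
the event is vanishingly rare anyway.

**Ties.** The exceedance comparison is `>=`, exactly as in the estimator's
definition.

**Adaptive permutation.** The schedule runs permutations in batches
(default 1000) and stops once the exceedance count reaches
$r_{stop}=\lceil 1/c^2\rceil$ — 25 for the default precision $c=0.2$ — so
the p-value estimate at stop has relative standard error about $c$. The
budget defaults to $\lceil r_{stop}/\alpha\rceil$, which resolves p-values
down to the target level $\alpha$. Checking at batch boundaries rather than
after every permutation keeps the stopped estimator's effective sample size
from collapsing for moderate p-values and adds negligible cost; the batch
size is a parameter. With a common seed, the standard and adaptive
procedures consume the same permutation stream, so a one-batch adaptive run
reproduces the standard result exactly — convenient for validation, and the
test suite exploits it.

**Comparators.** The carrier test dichotomizes individuals (any rare allele
vs none) and applies Fisher's exact test to the 2×2 table. The weighted-sum
test scores individuals by $S_i=\sum_j w_j X_{ij}$ with
$w_j = 1/\sqrt{N \hat q_j (1-\hat q_j)}$ from the shrunken control
frequency, takes the case rank sum as statistic, and permutes phenotypes
with weights recomputed from each permuted control group. These are the
simplest faithful forms of the two classic burden strategies and exist here
as benchmarking baselines, not as reference implementations.

## What the simulator emulates — and what it does not

`haplotype_pool()` stands in for coalescent-simulated population data: a
10 kb region carrying ~30 rare sites with pool MAF in $[0.001, 0.01]$ among
10,000 haplotypes. Site frequencies are drawn from a Beta(0.5, 50)
truncated to the MAF window (heavily skewed toward the rare end, as site
frequency spectra are); positions are distinct integers placed uniformly
(distinct, rather than literally i.i.d., so the KDE never sees duplicated
positions); haplotypes carry the minor allele independently per site, and
any site whose realized pool frequency escapes the window is redrawn so the
advertised MAF range holds exactly.

The main fidelity gap is **linkage**: pool sites are independent, with no
LD, recombination, demography or selection. Rare variants carry little
pairwise LD, but this remains the key difference from coalescent output —
calibration and power results on these pools demonstrate correctness of the
machinery under the stated generative model, not performance on any real
population. The variant-count distribution of a real coalescent model is
also not reproduced, only its rare-variant summary (~30 usable sites per
10 kb gene).

Disease status follows
$\mathrm{logit}\,P(Y=1\mid X)=\beta_0+\sum_{j\in\text{causal}}\log(\mathrm{OR})X_j$
with $\beta_0=\log(0.05/0.95)$ — a 5% baseline prevalence for individuals
carrying no causal allele — and a constant per-allele odds ratio (default
3) for every causal variant. Case/control datasets are rejection-sampled to
exact group sizes; excess individuals of a filled class are discarded, and
no sample-level MAF re-filtering is applied afterwards.

Causal-variant placement supports three scenarios: `uniform` (simple random
sample), `one_cluster` (grown outward from the variant nearest the median
position), and `two_clusters` (grown alternately from the variants nearest
the 1/3 and 2/3 position quantiles). Growth absorbs, at each step, the
flanking neighbor nearest the cluster seed, taking the left flank on exact
ties; clusters that meet merge and continue outward. The causal count is
`round(drv_proportion * P)` with half-up rounding and a floor of one.

## Evaluation conventions

`run_replicates()` draws a fresh pool per replicate (matching replicated
coalescent designs), derives per-replicate seeds deterministically from the
master seed (so a run's results are reproducible and a longer run's prefix
equals a shorter run), and records undefined results with their status
rather than dropping them. `estimate_rate()` excludes undefined p-values
from the denominator and reports them as a separate missingness fraction.
Confidence bands use the normal approximation to the binomial: centered on
the nominal level for type-I-error displays (the convention for null
calibration plots) and on the point estimate for power.

## Problem sizes used by the test suite

The suite favors sizes that demonstrate each property at adequate
Monte-Carlo resolution: null calibration uses 500 replicates of the default
10 kb / ~30-variant gene with 200 cases, 200 controls and $B=200$
(binomial 95% band $0.05\pm 1.96\sqrt{0.05\cdot 0.95/500}$); disease-model
calibration uses $10^5$ zero-carrier individuals (3-SE band); the power
ordering checks use 100 replicates per condition at 500/500 with OR 3,
comparing scenarios within 2-SE margins; adaptive-vs-standard agreement
uses 50 non-significant simulated genes with a 2000-permutation standard
reference. Exact/oracle equivalences (binomial weight sums, double-loop
KDE, fine-grid quadrature) are deterministic.

## Known limitations

* Deleterious-variant orientation only: the binomial-tail weights penalize
  protective variants; mixtures of effect directions need a different
  weighting.
* Binary phenotypes without covariates; no population-stratification
  adjustment.
* Density estimation is unreliable for regions with very few distinct
  mutated positions — the bandwidth floor keeps the statistic defined, but
  position information is then essentially absent.
* Clustering signals can be produced by technical artifacts (poorly
  sequenced short segments); significant hits warrant sequence-quality
  review.
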