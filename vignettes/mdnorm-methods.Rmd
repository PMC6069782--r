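---
title: "mdnorm: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mdnorm: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdnorm)
```

## The model

A chromosome's Hi-C data is a symmetric matrix of interaction frequencies
(IFs) over genomic bins of size $X$. `mdnorm` compares two such matrices by
reading them off-diagonal by off-diagonal: each bin pair $(i, j)$ has a
unit-length distance $D = j - i$, and for two datasets the pair contributes
a point $(D, M)$ with $M = \log_2(IF_2 / IF_1)$ — the MD plane. Two
systematic effects contaminate $M$: a global shift (one library is deeper)
and a distance-dependent drift (enzyme, batch and processing biases act
differently on short- and long-range contacts). Both are captured by one
smooth function $f(D)$, the trend of $M$ against $D$, estimated by locally
weighted regression, and removed symmetrically:

$$\log_2 IF_1' = \log_2 IF_1 + f(D)/2, \qquad
  \log_2 IF_2' = \log_2 IF_2 - f(D)/2.$$

The two half-corrections cancel within a pair, so
$\log_2 IF_1' + \log_2 IF_2' = \log_2 IF_1 + \log_2 IF_2$ exactly: the
geometric mean of each pair is invariant. (It is sometimes said loosely
that the *average* IF is unchanged; the identity the equations actually
force is on the log sum, i.e. the geometric rather than arithmetic mean,
and that is the invariant the package asserts.) Normalized IFs below 1 are
treated as unreliable and dropped from all further analysis; the drop is
applied to the whole pair if either side falls below 1, which keeps the
joint table well formed.

Differential detection assumes the normalized $M$ on a chromosome are
approximately normal: $Z = (M - \bar M)/\sigma_M$, two-sided normal
p-values, and FDR control. Low-support pairs — average expression
$A = (IF_1 + IF_2)/2$ below `A_min` — are removed *before* $\bar M$ and
$\sigma_M$ are computed, are assigned $Z = 0$, and are reported as
"untested" rather than given $p = 1$, so downstream counting is
unambiguous.

## Zero handling

Contact matrices are sparse and a zero IF cannot be told apart from missing
data. The default join keeps only pairs non-zero in both datasets. The
`keep_partial_zeros` policy carries one-sided pairs for bookkeeping with
the missing side recorded as 0 and $M$ undefined; such records never enter
trend fitting, normalization or testing.

## The local regression

`fit_trend()` implements the tricube-kernel local polynomial estimator
directly: at query distance $d$, the $\lceil \mathrm{span} \cdot n \rceil$
records nearest by $|D - d|$ are weighted by
$w = (1 - (|D - d|/h)^3)^3$ with $h$ the largest neighbour distance, and a
degree-1 (default) or degree-2 polynomial is fit by weighted least squares;
$f(d)$ is its value at $d$. Because $D$ is integer-valued and weights
depend only on $D$, the normal equations collapse onto per-distance
sufficient statistics (counts and $M$-sums), so the cost scales with the
number of distinct distances, not records, and the estimator is queried
only at observed distances — no interpolation is ever needed. Points at
exactly $|D - d| = h$ get weight zero; $h = 0$ degenerates to the local
mean; a weighted-support smaller than the polynomial order falls back to
the weighted mean. The test suite pins this implementation against an
independent brute-force per-record weighted-least-squares oracle at
$10^{-8}$, and cross-checks it qualitatively against `stats::loess`
(whose neighbourhood conventions differ slightly — `floor` rather than
`ceiling` windows and interpolation surfaces — which is why it is a
reference, not the implementation).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `span` | `"auto"` (CV), else 0.75 | fraction of points per local window |
| `degree` | 1 | local polynomial degree (2 available) |
| `A_min` | 15 | minimum average expression to test |
| `adjust_scope` | per distance | FDR family: per-D stratum or chromosome |
| `adjust_method` | BH | BH, Holm, Bonferroni or none |
| `alpha` | 0.05 | calling threshold on adjusted p |

The span is the one genuinely open smoothing choice: no single value suits
both a flat bias and a strongly curved one. The high-level pipeline
therefore defaults to seeded 5-fold cross-validation over
$\{0.1, 0.25, 0.5, 0.75, 1\}$ (`select_span()`), which is deterministic
given its seed; a fixed span of 0.75 is the conservative manual default.
Degree 1 is the default because degree-2 windows are unstable in the
sparse far-distance tail. `A_min = 15` suits deeply sequenced 1-Mb maps;
at higher resolutions or lower depth it should be lowered — it is a flag
everywhere it matters. The sample ($n-1$) standard deviation is used for
$\sigma_M$; at the $n$ involved (tens of thousands of pairs per
chromosome) the population/sample distinction is negligible, but the
choice is pinned here. Strict per-distance FDR families are the default
even though far-distance strata are small; merging degenerate strata is
deliberately *not* done silently.

## The synthetic study conditions

`simulate_replicate_pair()` generates the data every stochastic test runs
on. For each upper-triangular pair at distance $D$:
$\mu(D) = c (1 + D)^{-\alpha}$, $IF_1 \sim \mathrm{NB}(\mu, \theta)$,
$IF_2 \sim \mathrm{NB}(\mu \cdot r \cdot b(D), \theta)$, with optional
independent zeroing and an optional plaid compartment factor
$(1 + \gamma s_i s_j)$. The defaults — 500 bins at 1 Mb, $c = 10^5$,
$\alpha = 1$, $\theta = 50$, $r = 1$, flat $b$, no zero inflation — model
a deeply sequenced chromosome map: near-diagonal IFs around $10^5$,
roughly $2.6 \times 10^8$ intra-chromosomal contacts, and a replicate
log-ratio spread $\sigma_M \approx 0.30$, the regime in which published
replicate comparisons at 1 Mb operate. The negative binomial is the
standard overdispersed count model for sequencing data; the generator
exists to produce data with the qualitative structure the method assumes
(monotone decay, overdispersion, multiplicative distance-dependent bias),
not to model chromatin physics. It has no TADs or loops, no
restriction-fragment effects and no trans contacts, so passing tests show
the *method's* statistical behaviour under its own assumptions — they are
not evidence about artifact structure in real maps.

Bias presets (`default_bias_library()`): `flat` ($f \equiv 0$),
`global_shift(k)` ($f \equiv k$), `linear_in_logD(a, b)`
($f = a + b\log_2(1+D)$), `sinusoidal(A, T)`
($f = A \sin(2\pi D/T)$). The recovery checks use the sinusoidal preset
with amplitude 1 (a two-fold bias at its peak, comparable to what
replicate MD plots show) because its curvature is bounded everywhere,
making it a fair smoothness-matched target for a local-linear fit;
recovery and post-normalization flatness are evaluated on
$D \in [0, 125]$ (a quarter of the 500-bin range) — beyond that the
per-distance record count shrinks linearly toward 1 and any smoother's
edge behaviour, not the normalization, dominates.

## The controlled-difference benchmark

With no gold standard for differential interactions, ground truth is
manufactured: sample pairs positive in both replicates, set both IFs to
their average, multiply one side — chosen at random per entry, to avoid a
directional artifact — by a fold change, so the injected
$|M| = \log_2 FC$ exactly. Detection at FDR < 0.05 is scored by confusion
counts over *tested* pairs; injected entries that never reach testing are
reported separately rather than counted as misses. The Matthews
correlation coefficient summarizes the table, with the zero-denominator
convention MCC = 0. The same injection seed is reused across fold changes
so rows differ only in effect size. On the default synthetic conditions
the benchmark reaches MCC ≈ 0.9 at fold change 4 and is non-decreasing in
fold change for the large majority of seeds; the printed values on real
deeply-sequenced data would require those datasets and are not shipped.

## Compartment profiling

No single canonical A/B pipeline exists; `compartment_profile()` uses the
standard construction — densify, mask zero-marginal bins,
observed/expected by off-diagonal means, Pearson correlation matrix,
leading eigenvector, sign = compartment — and documents it as such.
Zero-variance bins after O/E are masked `NA`, never imputed. Eigenvector
sign is arbitrary, so `compare_profiles()` sign-aligns before computing
its metrics (absolute correlation, sign-match proportion, Jaccard A/B),
making all four invariant to global flips of either input.

## Numerical choices and degenerate inputs

- Duplicate bin-pair keys on input are an error, never summed.
- All-equal $M$ after filtering raises "no variability" rather than
  emitting infinite Z-scores.
- Fewer distinct distances than 2, or fewer points than `degree + 2`,
  refuse to fit.
- IFs are stored as doubles; sparse text round trips are exact for
  integers and better than $10^{-9}$ relative for normalized values
  (15 significant digits written).
- Injected IFs are kept as doubles (replicate averaging produces halves);
  integer consumers can round downstream.
- Per-chromosome runs derive their seeds from the chromosome *name*, so a
  chromosome's result is invariant to which other chromosomes are present
  and to the worker count.

## Problem sizes

Stochastic checks run at the generator defaults (500 bins, 125,250 pairs)
for calibration, recovery and the benchmark; structural and oracle checks
use 30–300-bin instances where exhaustive brute-force comparison is
feasible. These sizes give Monte-Carlo bounds tight enough to be
informative while keeping the full suite to a few minutes.

## Known limitations

Pairwise comparisons only (no multi-sample design); intra-chromosomal
contacts only; the normality of normalized $M$ is an assumption that
heavy-tailed real data can violate — the per-distance variance
heterogeneity left after pooling $\sigma_M$ over distances inflates the
false-positive rate slightly even on synthetic data (visible as ~50 calls
among 125k true-null pairs at FDR 0.05); and the CNV/blacklist step only
*consumes* a BED of regions, detection is upstream.
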