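---
title: "Methods: two-sample MR, sensitivity analysis, and mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, sensitivity analysis, and mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from GWAS summary statistics alone. For each
instrument SNP $j$ we observe an exposure association
$\hat\gamma_j \sim N(\gamma_j, \sigma_{xj}^2)$ from one cohort and an
outcome association $\hat\Gamma_j \sim N(\Gamma_j, \sigma_{yj}^2)$ from
another. Under the instrumental-variable assumptions (relevance, no
confounding of the instrument, and no effect on the outcome except through
the exposure), $\Gamma_j = b\,\gamma_j$, and each SNP supplies a Wald
ratio $\hat b_j = \hat\Gamma_j / \hat\gamma_j$.

A valid instrument set is assembled by:

1. genome-wide significance, $p < 5\times10^{-8}$ strictly
   (`select_significant()`; the boundary value is excluded, matching the
   strict inequality conventionally printed);
2. greedy LD clumping at $r^2 > 0.001$ within a 10,000 kb window
   (`clump()`): repeatedly keep the most significant remaining SNP (ties
   broken lexicographically by identifier so the result is independent of
   input order) and discard its correlated neighbours. The window is
   measured center-to-center between positions — the simplest convention
   that is exactly reproducible. SNPs absent from the supplied LD matrix
   are treated as unlinked; this is permissive, so drops are logged;
3. removal of SNPs annotated to confounder traits
   (`filter_confounders()`), driven by a user-supplied annotation table
   rather than a live phenotype-database query;
4. allele harmonization against the outcome (`harmonize()`), described
   below.

Instrument strength is summarized by
$F = R^2 (N - 1 - K) / ((1 - R^2) K)$ with $R^2$ the aggregate variance
explained, $N$ the exposure sample size and $K$ the instrument count.
Per-SNP variance explained uses the t-statistic form
$t^2/(t^2 + n - 2)$, which needs no allele frequency or trait variance; a
frequency-based alternative $2p(1-p)\beta^2$ is available for standardized
traits (`per_snp_r2_af()`).

## Harmonization

Outcome effects are re-expressed on the exposure's effect allele. The
matching rules, in order: identical alleles are kept as-is; swapped
effect/other alleles flip the outcome beta (and frequency); pairs that
match only after strand complementation are complemented first, on the
view that summary files mix strand conventions — these drops and rescues
are counted for audit. Palindromic (A/T, C/G) SNPs cannot be
strand-resolved from alleles; the default policy drops them. An optional
`infer_by_frequency` policy keeps palindromic SNPs whose effect-allele
frequency is decisive on both sides (outside [0.42, 0.58]) and aligns by
minor allele — standard practice, but off by default. Proxy-SNP
substitution is deliberately not implemented: a defensible implementation
needs an LD reference panel and an $r^2$ threshold, and guessing either
would silently change the instrument set. Missing outcome SNPs are simply
dropped and counted.

## Estimators

All estimators consume a `harmonized_set` and return the effect on the
log scale with a normal-theory 95% CI, the exponentiated (odds-ratio)
scale, and a two-sided p-value.

**IVW.** $\hat b = \sum w_j \hat b_j / \sum w_j$ with
$w_j = \hat\gamma_j^2/\sigma_{yj}^2$ — algebraically the zero-intercept
weighted least-squares slope of $\hat\Gamma$ on $\hat\gamma$ with weights
$1/\sigma_{yj}^2$. The default variance model is multiplicative random
effects, scaling the fixed-effect SE by $\sqrt{\max(1, Q/(J-1))}$; the
truncation at 1 keeps the random-effects SE from undercutting the
fixed-effect one. Fixed effects are available by flag, and both variants
are emitted by the pipeline since published IVW rows rarely state which
was used.

**MR-Egger.** The same regression with a free intercept, after orienting
all exposure effects non-negative (flipping the paired outcome signs) —
the orientation under which the estimator is identified. The intercept
estimates the average directional pleiotropy; its p-value is the
pleiotropy test. SEs carry the $\sqrt{\max(1, \mathrm{RSS}/(J-2))}$
overdispersion factor and p-values use the normal reference; with few
instruments this is slightly anti-conservative relative to a t reference,
one reason the intercept test's size runs a little above nominal in the
calibration checks.

**Weighted median.** The interpolated weighted median of the Wald ratios:
with ratios sorted and normalized weights $w_{(j)}$, the cumulative
weights $\sum_{i \le j} w_{(i)} - w_{(j)}/2$ are linearly interpolated and
inverted at one half. It is consistent when instruments carrying at least
half the weight are valid. Its SE comes from a parametric bootstrap
(default `n_boot = 1000`) that redraws both summary statistics from their
reported normals; the bootstrap is seeded and bit-reproducible.

**Maximum likelihood.** Each pair $(\hat\gamma_j, \hat\Gamma_j)$ is
modeled as independent normals with means $(\xi_j, b\,\xi_j)$. Profiling
the $\xi_j$ analytically leaves
$\ell(b) = -\tfrac12\sum_j (\hat\Gamma_j - b\hat\gamma_j)^2 /
(\sigma_{yj}^2 + b^2\sigma_{xj}^2)$, maximized by Brent search from the
IVW start in a bracket of $\pm\max(1, 100\,\mathrm{SE}_{IVW},
10|\hat b_{IVW}|)$; the SE is the inverse root of a central-difference
observed information. As $\sigma_{xj} \to 0$ this collapses to
fixed-effect IVW.

**MR-RAPS.** Balanced pleiotropy is absorbed into an overdispersion
variance $\tau^2 \ge 0$: standardized residuals
$t_j = (\hat\Gamma_j - b\hat\gamma_j)/\sqrt{\sigma_{yj}^2 +
b^2\sigma_{xj}^2 + \tau^2}$ enter the profile-score equation
$\sum_j \psi(t_j)\,\partial t_j/\partial b = 0$, with $\psi$ the identity
or (default) the Huber score at tuning constant 1.345. $\tau^2$ is
estimated jointly from $\sum_j t_j\psi(t_j) = J\,E[Z\psi(Z)]$, where
$E[Z\psi(Z)] = 2\Phi(c)-1$ for the Huber score; the alternating solver
brackets each root explicitly and errors (rather than returning a
boundary value) if no root lies in the expanding bracket. The SE is the
single-parameter M-estimation sandwich $\sqrt{B}/A$ with
$A=\sum\psi'(t_j)(\partial t_j/\partial b)^2$,
$B=\sum\psi(t_j)^2(\partial t_j/\partial b)^2$, treating $\tau^2$ as
known at its estimate — an approximation that slightly understates
uncertainty when $J$ is small.

## Sensitivity suite

Cochran's $Q = \sum w_j(\hat b_j - \hat b_{IVW})^2$ is referred to
$\chi^2_{J-1}$; it equals the weighted RSS of the zero-intercept
regression, an identity the tests exploit. The reference distribution is
exact under the statistic's own model (outcome noise only) and mildly
inflated — by a factor $\approx 1 + b^2\sigma_x^2/\sigma_y^2$ — when
exposure noise is appreciable. Leave-one-out refits IVW without each SNP;
funnel data pairs each ratio with its precision for symmetry inspection.

MR-PRESSO builds the null of the leave-one-out residual sum of squares by
simulation: for each SNP the expected outcome effect is
$\hat b_{(-j)}\hat\gamma_j$ from the fixed-effect IVW fit excluding it,
and `n_sim` (default 1000) replicate datasets redraw both summary
statistics from their reported normals. The global p is the Monte Carlo
tail probability of the observed RSS; per-SNP squared residuals are
tested against their own simulated distributions and flagged when the
Bonferroni-adjusted p falls below 0.05; the distortion test compares the
raw-versus-corrected IVW shift with shifts from removing random subsets
of the same size (1000 draws). All Monte Carlo p-values use the add-one
convention $(1+r)/(n+1)$, so they are never exactly zero and retain their
interpretation as empirical tail probabilities; note the Bonferroni
outlier flag can therefore still fire on clean data with probability
roughly $J/(n_{sim}+1)$ per dataset, which is a property of any empirical
test at this resolution. Per-SNP simulation streams are seeded from the
master seed and the SNP identifier, so results are bit-reproducible and
invariant to row order.

## Two-step mediation

For mediators $k = 1,\dots,K$ the indirect effect is the product-method
sum $\sum_k \beta_{1k}\beta_{2k}$, with $\beta_{1k}$ the
exposure-to-mediator and $\beta_{2k}$ the mediator-to-outcome MR
estimates (each leg an independent instrument set and, by default, IVW).
The mediated proportion is

$$E = \frac{\sum_k \beta_{1k}\beta_{2k}}{\beta_3 + \sum_k \beta_{1k}\beta_{2k}},$$

the indirect effect over the reconstituted total. Two decompositions of
the direct effect $\beta_3$ are offered because published analyses are
ambiguous about which denominator they use:

* `total_minus_indirect` (default): $\beta_3$ is the two-sample total
  effect minus the indirect effect, so direct + indirect = total holds
  exactly and $E$ reduces to indirect/total. This is the only
  self-contained choice when the multivariable-MR adjustment behind a
  published direct effect cannot be reproduced from summary data alone.
* `external`: a user-supplied $\beta_3$ (for example from multivariable
  MR run elsewhere), honouring the equation's literal structure.

Mediators are treated as independent when summing over $k$, which is what
an unadorned product-method sum implies. When the indirect and total
effects have opposite signs the ratio is not a proportion; the result is
flagged as inconsistent mediation rather than silently reported. The
delta-method SE propagates the three legs' SEs assuming independence and
is labelled approximate. Proportions are reported as percentages rounded
to one decimal in serialized output.

Fed with published odds ratios (log-transformed) as degenerate
single-instrument legs, the machinery reproduces published mediation
arithmetic; `scripts/acceptance.R` exercises exactly this path for the
thyroid-function-to-gallstone worked example.

## The synthetic generator

`simulate_pair()` emulates the structure the analysis assumes: shared
variants with per-SNP effect/SE pairs for two traits, a configurable true
causal effect, invalid-instrument fraction with balanced or directional
pleiotropy, palindromic allele fraction, and block LD. Choices, made once
as the package's study conditions:

* True instrument effects $\gamma_j \sim N(0.05, 0.02^2)$ — positive
  because effect alleles in practice are oriented trait-increasing after
  instrument selection; the magnitudes give strong instruments
  ($F \gg 10$) at biobank-scale $n$, matching the regime the method is
  meant for.
* Standard errors follow standardized-trait asymptotics
  $\sigma_j = 1/\sqrt{2np_j(1-p_j)}$, with MAF uniform on [0.05, 0.5];
  binary traits scale by $1/\sqrt{\phi(1-\phi)}$ with case fraction
  $\phi$.
* Pleiotropic effects are drawn independently of instrument strength
  (the InSIDE assumption holds by construction); an
  `inside_violation_cor` knob correlates them for stress tests.
* Defaults: 100 SNPs, causal effect 0.1, $n = 10^6$ per GWAS, no invalid
  instruments; every draw is governed by a single integer seed and
  identical configs reproduce bit-identical tables.

What the generator does *not* emulate: genome-wide LD beyond idealized
equal-$r^2$ blocks, winner's-curse bias from selecting instruments in the
same sample, sample overlap between cohorts, MAF-dependent effect-size
architecture, and non-normal effect distributions. Passing recovery and
calibration tests on this generator therefore demonstrates correctness of
the estimators under their stated assumptions, not robustness to the full
messiness of real GWAS data.

## Numerical and design notes

* All p-values are two-sided normal; significance thresholds are applied
  only in reporting, never inside estimation.
* Wald-ratio SE uses the first-order delta method by default
  (`second_order = TRUE` adds the exposure-noise term), the dominant
  convention.
* The weighted-median majority-weight property (a ratio carrying more
  than half the weight is returned exactly) holds at the interpolated
  definition when the heavy ratio occupies the median position; an
  extreme-positioned majority ratio is approached by interpolation.
* Degenerate inputs error early and specifically: zero exposure effect in
  a Wald ratio, fewer instruments than a method needs (2 for IVW/ML, 3
  for Egger/median/RAPS, 4 for MR-PRESSO), every SNP flagged as an
  outlier, zero mediation denominator.
* The test suite's simulation sizes — 200 replicates for recovery and
  mediation means, 500 for intercept-test size, 100 runs for MR-PRESSO
  power and size, 50 instances for the least-squares oracle equivalence —
  were chosen to hold Monte Carlo error comfortably inside each asserted
  band while keeping the default check quick on a laptop.

## Known limitations

Multivariable MR (and hence an internally estimated direct effect),
proxy-SNP lookup, LD estimation from genotypes, and web-service
annotation queries are out of scope by design. The RAPS sandwich ignores
$\tau^2$ uncertainty; the Egger intercept test uses a normal reference;
bootstrap and Monte Carlo p-values have resolution $1/(n+1)$. F-statistic
ranges published alongside real analyses depend on per-SNP $R^2$ sources
(often supplementary materials) that summary statistics alone cannot
always reproduce.
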