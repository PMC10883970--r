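---
title: "Models and methods in somnimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in somnimr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

somnimr implements the summary-statistics causal-inference toolkit used in
epidemiological studies of heritable exposures: two-sample Mendelian
randomization (MR) with a full sensitivity suite, multivariable MR,
two-step mediation, and a genetic-overlap layer. This vignette is the
package's own account of the models, the tunable parameters, the
synthetic-data generator that stands in for real GWAS downloads, and the
numerical choices made where the design was genuinely open.

## The instrumental-variable model

For instrument $j$, let $\gamma_j$ be its effect on the exposure and
$\Gamma_j$ its effect on the outcome, estimated in two non-overlapping
GWAS with standard errors $\sigma_{\gamma j}$, $\sigma_{\Gamma j}$. Under
the three IV assumptions (relevance, independence from confounders,
exclusion restriction), $\Gamma_j = \beta\,\gamma_j$ and each Wald ratio
$\hat\beta_j = \hat\Gamma_j/\hat\gamma_j$ estimates the causal effect
$\beta$. Violations enter as a direct (pleiotropic) effect $\alpha_j$:
$\Gamma_j = \beta\gamma_j + \alpha_j$.

The five estimators trade efficiency against robustness to $\alpha_j$:

- **IVW**: $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$ with first-order
  weights $w_j = \hat\gamma_j^2/\sigma_{\Gamma j}^2$ — algebraically the
  weighted least-squares slope of $\hat\Gamma$ on $\hat\gamma$ through the
  origin (an identity the tests assert to $10^{-10}$). Consistent only if
  pleiotropy is absent or balanced.
- **MR-Egger**: the same regression with a free intercept after orienting
  all instruments to positive $\hat\gamma_j$; the slope tolerates
  directional pleiotropy under the InSIDE assumption and the intercept
  estimates it.
- **Weighted median**: the ratio at standardized cumulative weight 1/2
  (piecewise-linear interpolation over $s_j = (\sum_{i\le j} w_i -
  w_j/2)/\sum w$); consistent while valid instruments hold $>$ 50% of the
  weight.
- **Weighted mode**: the argmax of a weighted normal-kernel density of the
  ratios; consistent when the largest cluster is valid.
- **MR-RAPS**: maximizes the adjusted profile log-likelihood
  $\sum_j[-\tfrac12\rho(t_j) - \tfrac12\log v_j]$ with
  $v_j = \sigma_{\Gamma j}^2 + \beta^2\sigma_{\gamma j}^2 + \tau^2$,
  $t_j = (\hat\Gamma_j - \beta\hat\gamma_j)/\sqrt{v_j}$, jointly in
  $(\beta, \tau^2 \ge 0)$; $\rho$ is squared loss by default or Huber
  ($k = 1.345$) via `loss = "huber"`. Note $v_j$ carries the
  $\beta^2\sigma_{\gamma j}^2$ term that first-order IVW ignores.

## Tunable parameters

All thresholds default to the values conventional in this literature:
genome-wide significance $5\times10^{-8}$; clumping $r^2 < 0.001$ within a
10 Mb window; proxy search $r^2 > 0.8$; palindromic ambiguity window
$(0.42, 0.58)$ in effect-allele frequency; MR-PRESSO with 1000 simulated
distributions and per-SNP outlier removal at $p < 0.05$; mode bandwidth
multiplier $\phi = 1$ on the modified Silverman rule
$0.9\min(\mathrm{SD}, \mathrm{IQR}/1.34)\,n^{-1/5}$ applied to the
inverse-variance-weighted spread of the ratios; bootstrap SEs for median
and mode from 1000 parametric resamples with an explicit seed.

Decisions where the convention had to be chosen:

- **Random-effects IVW is multiplicative**: the fixed-effect SE is scaled
  by $\sqrt{\max(1, Q/(n-1))}$ rather than adding an additive variance
  component. The pipeline switches to it when Cochran's Q has $p < 0.05$,
  mirroring the usual analysis rule. This matters beyond heterogeneity:
  at realistic sample-size ratios the ignored exposure-noise term
  $\beta^2\sigma_\gamma^2$ inflates Q above its nominal expectation, and
  the multiplicative correction absorbs it (without the switch,
  first-order IVW intervals under-cover when $\beta^2 n_{outcome} \sim
  n_{exposure}$).
- **Palindromic A/T and G/C variants** cannot be strand-resolved from
  allele labels. They are kept only when both datasets' frequencies are
  unambiguous (outside the 0.42–0.58 window) *and* fall on the same side
  of 0.5; opposite-side variants are dropped rather than frequency-flipped
  — conservative, at the cost of a few recoverable instruments. Missing
  frequency also drops the variant.
- **Egger p-values** use the t distribution on $n-2$ df; all other
  methods use two-sided normal p-values.
- **Proportion mediated** is indirect/total (not
  indirect/(direct+indirect)); odds ratios are log-transformed before the
  product so both coefficients live on the linear (log-odds) scale. The
  delta-method SE for the indirect effect,
  $\sqrt{\beta_{xm}^2 se_{my}^2 + \beta_{my}^2 se_{xm}^2}$, is an
  extension beyond the source procedure and is labelled as such in the
  result object.
- **MR-PRESSO** uses leave-one-out IVW slopes for the expected outcome
  effects, add-one smoothing on empirical p-values (so the global p lies
  in $[1/(n_{sim}+1), 1]$), and the raw per-SNP 0.05 removal rule without
  multiplicity correction. Under the null that rule flags roughly one of
  22 clean instruments per run — an accepted property of the rule, not a
  defect; the pipeline refuses a filter that would leave fewer than three
  instruments.
- **MVMR** drops SNPs absent from any exposure (no proxying inside the
  joint model), scales SEs by $\sqrt{\max(1, Q/\mathrm{df})}$ with
  $\mathrm{df} = n_{iv} - K$ (IVW) or $n_{iv} - K - 1$ (Egger), and
  reports IVW as primary unless the MVMR-Egger intercept test is
  significant.

## The synthetic-data generator

`simulateIvData()` draws, per instrument,
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma^2)$, observes
$\hat\gamma_j \sim N(\gamma_j, 1/n_{exp})$, assigns direct effects
$\alpha_j$ to a configurable fraction of instruments (balanced,
directional, or correlated with $\gamma_j$ at 0.5 to violate InSIDE),
sets $\Gamma_j = \beta\gamma_j + \alpha_j + N(0, \sigma_{het}^2)$ and
observes $\hat\Gamma_j \sim N(\Gamma_j, 1/n_{out})$. Defaults encode the
reference study design: 22 instruments, $\beta = -0.60$, exposure GWAS
$n = 446{,}118$, outcome GWAS $n = 1{,}012{,}240$, 15% palindromic allele
pairs, no pleiotropy. Ground truth is returned as a sidecar table the
pipeline never sees.

The default exposure-effect scale, $\gamma_j \sim N(0.05, 0.015^2)$
(per-SNP $|t| \approx 30$), puts instruments firmly in the
strong-instrument regime. This is deliberate: at the weaker, real-scale
per-instrument strength of $F \approx 40$, the noise in $\hat\gamma$
attenuates the IVW slope by $\sigma_{\gamma}^2$-to-spread ratios of a few
percent and dilutes MR-Egger much more strongly (its slope is identified
from the *spread* of $\hat\gamma$, so dilution is
$\mathrm{var}(\gamma)/(\mathrm{var}(\gamma) + \sigma_\gamma^2)$). The
recovery suites are meant to validate estimator correctness, not to
reproduce weak-instrument attenuation, so the generator defaults assume
it away; analysts of real F ≈ 40 data should expect that attenuation and
lean on MR-RAPS, whose likelihood models the exposure noise.

`simulateGenomeScan()` draws per-SNP z-score pairs from the bivariate
normal implied by the LD score regression expectation,
$E[z_1^2] = n_1 h_1^2 \ell_j/m + 1$,
$E[z_1 z_2] = \sqrt{n_1 n_2}\, r_g \sqrt{h_1^2 h_2^2}\, \ell_j/m$, with
LD scores $\ell_j = 1 + (\text{block size} - 1) r_b^2$ from a block LD
structure. Per-block correlations are drawn uniformly on
$(0, r_{max})$ — a constant LD score would leave the regression slope
unidentified, so LD-score variation across blocks is a structural
requirement, not a free choice. Cohorts are disjoint (no sample-overlap
intercept term); z-scores are drawn independently across SNPs, so the
panel reproduces the LDSC *expectation* per SNP but not the
correlated-noise structure real LD induces between neighbouring test
statistics.

What passing tests show — and what they do not: the generators emulate
the moment structure of GWAS summary statistics under the stated models.
They do not emulate realistic human LD maps, allele-frequency spectra,
liability-scale binary traits (binary labelling only renames units), nor
winner's-curse selection of instruments from the same GWAS that
estimates their effects. Recovery under the generator therefore validates
the estimators and the plumbing, not performance on any particular real
dataset.

## Numerical choices

- RAPS optimizes over $(\beta, \log\tau^2)$ with Nelder-Mead and reports
  the SE from a finite-difference observed information of the profile in
  $\beta$ (with $\tau^2$ re-profiled); $\hat\tau^2 < 10^{-10}$ is snapped
  to the boundary at zero.
- The weighted-mode density argmax is evaluated on a 512-point grid
  spanning the ratio range ± 3 bandwidths; identical ratios (zero
  bandwidth) return that common ratio directly.
- Clumping sorts candidates by (p, chromosome, position, snp id) so the
  output is invariant to input row order; ties at equal p resolve
  deterministically.
- Proxy search breaks r² ties by base-pair distance, then lexicographic
  id.
- Conditional FDRs are the raw empirical-CDF ratios
  $p_1 F_2(p_2)/F_{12}(p_1,p_2)$ capped at 1, computed in
  $O(n\log n)$ with a Fenwick tree over the joint ranks (equal to the
  naive double loop, which the tests assert); the monotone
  (cumulative-max smoothed) decile lookup grid is returned alongside for
  diagnostics, leaving the per-SNP values exactly reproducible by the
  brute-force definition.
- LDSC jackknife: 200 contiguous SNP blocks; per-block sufficient
  statistics are subtracted from the totals so each delete-one fit is
  $O(1)$. The MHC region (chr6: 26–34 Mb) is excluded before fitting.
  Regression weights are a single pass of $1/\ell_j$ rather than the
  iterative heteroskedasticity weights of the reference tool — a
  desk-scale simplification validated by recovery of known generative
  parameters rather than against the original implementation.
- All stochastic procedures (bootstraps, MR-PRESSO, simulators) take an
  explicit seed; the pipeline derives per-stage sub-seeds from one master
  seed so a config re-run is byte-identical.

## Validation problem sizes

The test suite validates estimator recovery and CI coverage over 500
simulated 22-instrument studies (bootstrap SEs from 300 resamples there;
the user-facing default is 1000), breakdown robustness over 20 studies
with 40% grossly pleiotropic instruments, MR-PRESSO calibration over 150
null studies, and LDSC recovery over 20 genomes of 20,000 SNPs. The
parametric bootstrap mandated for median and mode — resampling around the
*observed* summary statistics — is known to be conservative for
order-statistic and density-argmax estimators (the resampled ratios carry
roughly twice the cross-sectional dispersion), and the weighted mode's
intervals over-cover accordingly (~99% at these conditions); its SE
should be read as an upper bound.

## Known limitations

- No correlated-instrument MR; clumping is assumed to have removed LD.
- Steiger r² for binary traits is computed on the observed log-odds scale
  without a liability-scale conversion.
- No sample-overlap correction in LDSC (simulated cohorts are disjoint;
  the bivariate intercept is estimated and reported, not constrained).
- Mediation assumes the two-step linearity under which the product of
  coefficients is interpretable; direct + indirect need not equal the
  total effect and the package reports that as a diagnostic gap rather
  than asserting it.
- The MVMR module does not compute conditional F statistics, so weak
  conditional instruments are not flagged.
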