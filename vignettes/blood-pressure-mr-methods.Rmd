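---
title: "Methods: two-sample and multivariable MR for blood-pressure traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample and multivariable MR for blood-pressure traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gwasmr` implements the full two-sample Mendelian randomisation (MR)
workflow used in large blood-pressure epidemiology: instrument selection
from GWAS summary statistics, allele harmonisation, the univariable
estimator suite with pleiotropy-robust sensitivity analyses, multivariable
MR for the direct effects of correlated exposures (systolic and diastolic
pressure), and the instrument diagnostics that decide whether any of it can
be believed. This vignette explains the models, the conventions the package
adopts where the literature leaves a choice, and what the synthetic
generator does and does not emulate.

## The model

For SNP $j$, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its estimated
association with the exposure (per allele, exposure in SD units) and
$\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its association with the outcome
(log-odds for binary outcomes, z-score units for lifespan), estimated in
non-overlapping (or approximately non-overlapping) samples. Under the
instrumental-variable assumptions each SNP gives a Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order SE
$\sigma_{Yj}/|\hat\beta_{Xj}|$.

**IVW with multiplicative random effects.** The headline estimator is the
weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the
origin with weights $1/\sigma_{Yj}^2$. Cochran's $Q$ measures
heterogeneity; the multiplicative random-effects SE multiplies the
fixed-effects SE by $\max(1, \sqrt{Q/(k-1)})$, so the point estimate is
unchanged and the SE is never deflated. This assumes balanced pleiotropy.

**Sensitivity estimators.**

* *Weighted median* (`mr_weighted_median`): per-SNP ratios ordered, weighted
  by $\hat\beta_{Xj}^2/\sigma_{Yj}^2$, estimate interpolated at cumulative
  weight 0.5 with the $w_j/2$ percentile offset. Consistent while more than
  half of the weight comes from valid instruments. SEs are a parametric
  bootstrap (default 1000 replicates, seed recorded in the result).
* *MR-Egger* (`mr_egger`): the same regression with an intercept after
  orienting every SNP so $\hat\beta_{Xj} > 0$; the intercept estimates
  directional pleiotropy, the slope remains consistent under InSIDE. Its
  validity degrades with measurement error in $\hat\beta_{Xj}$, monitored
  by $I^2_{GX}$ (values below 0.9 are a warning).
* *MR-PRESSO* (`mr_presso`): the observed inverse-variance-weighted
  leave-one-out residual sum of squares is compared with parametric
  simulations under the fitted model (global test); per-SNP outlier
  p-values are Bonferroni-corrected across SNPs; the corrected estimate is
  IVW on the non-outliers; the distortion test compares the raw-to-corrected
  change against a null built by dropping random non-outlier subsets of the
  same size. The per-SNP outlier test can only resolve
  $p < \alpha/k$ when `n_sim` exceeds $k/\alpha$; the default 1000
  simulations suit sets of up to ~50 SNPs, larger sets need more.

**Multivariable MR.** With exposure-effect matrix
$B = (\hat\beta_{Xje})$, `mv_ivw` fits the no-intercept weighted multiple
regression of $\hat\beta_{Yj}$ on all exposure columns; the coefficient on
exposure $e$ is its *direct* effect holding the other exposures fixed. The
univariable ("total") and multivariable ("direct") estimates together
resolve mediation: a trait whose univariable effect is positive but whose
direct effect is null acts through its correlated partner. `mv_egger`,
`mv_presso` extend the corresponding univariable constructions with
multivariable leave-one-out residuals.

**Multivariable weighted median.** The literature names the method but its
exact construction varies. A bootstrap-median-of-component-fits is *not*
robust: every resampled fit carries roughly the same contaminated fraction,
so the median of fits inherits the bias. The package instead solves the
inverse-variance-weighted $L_1$ (median) regression through the origin by
iteratively reweighted least squares, which is the natural multivariable
generalisation of the weighted median and empirically withstands 30% gross
contamination in the test suite; SEs come from a parametric bootstrap.

**Conditional instrument strength and the modified Q.** For exposure $e$,
the Sanderson–Windmeijer conditional F regresses its SNP effects on the
other exposures' SNP effects by minimising
$Q_e(\delta) = \sum_j (\hat\beta_{Xje} - \delta'\hat\beta_{Xj,-e})^2/v_j(\delta)$,
where $v_j$ propagates the covariance of estimated SNP effects,
$\mathrm{cov}(\hat\beta_{Xje}, \hat\beta_{Xjf}) = \rho_{ef}\sigma_{Xje}\sigma_{Xjf}$,
with $\rho$ the phenotypic correlation between the exposure traits measured
in their shared GWAS sample (0.69 for systolic/diastolic pressure). The
statistic is $Q_e(\hat\delta)/(k - d + 1)$ for $k$ SNPs and $d$ exposures,
so a single exposure reduces exactly to the mean univariable F. Two notes:

* With two exposures the identity $Q_2(1/\delta) = Q_1(\delta)$ holds term
  by term, so the Q-minimising construction yields *equal* conditional F
  for both exposures — a property of this variant, not a bug.
* When the estimation errors are correlated ($\rho \ne 0$), conditioning
  can transiently *raise* the statistic at moderate genetic correlation
  (the correlated noise partially cancels); the collapse towards zero as
  the genetic correlation approaches one always holds, and with
  uncorrelated errors the decline is monotone throughout.

The modified Cochran's Q uses per-SNP variances
$s_j^2 = \sigma_{Yj}^2 + \sum_{e,f}\theta_e\theta_f\,\rho_{ef}\sigma_{Xje}\sigma_{Xjf}$,
with $\theta$ re-estimated under those weights by IRLS; df $= k - d$.
Ignoring the covariance term inflates Q on correlated-exposure data, which
the test suite demonstrates by paired simulation.

**Diagnostics.** Per-SNP $F_j = (\hat\beta_{Xj}/\sigma_{Xj})^2$ with the
mean-below-10 weak-instrument flag; variance explained
$r^2 = \sum_j 2p_j(1-p_j)\hat\beta_{Xj}^2$ on SD-scaled betas under
Hardy–Weinberg (an F-based approximation $\sum F_j/(F_j + n - 2)$ is
available — the two differ only through the frequency weighting);
$I^2_{GX} = \max(0, (Q_{GX} - (k-1))/Q_{GX})$; the Steiger directionality
test compares scale-free per-SNP pseudo-$r^2 = z^2/(z^2+n)$ sums on the two
sides through Fisher's z — for binary outcomes this is on the observed
log-odds scale, a documented convention, not a liability-scale conversion.
Power uses the noncentrality approximation: detectable
$|\beta| = (z_{1-\alpha/2}+z_{\mathrm{pow}})/\sqrt{n r^2}$, divided further
by $\sqrt{cf(1-cf)}$ for a binary outcome with case fraction $cf$; defaults
$\alpha = 0.05$, power 0.80.

## Harmonisation conventions

Alignment matches allele pairs directly, after swapping, or after strand
complementing, flipping the outcome beta sign and frequency on swaps;
irreconcilable pairs are excluded as `allele-mismatch`. Palindromic SNPs
(A/T, C/G) cannot be strand-resolved from letters: when the effect-allele
frequency on either side lies strictly inside (0.42, 0.58) the variant is
ambiguous and is proxy-substituted where the proxy table offers an
$r^2 \ge 0.8$ proxy present in all tables (highest $r^2$ wins, ties by
variant id), else excluded; outside the window the minor allele is matched
across datasets. The endpoints are exclusive — a frequency of exactly 0.42
or 0.58 is alignable. Palindromes with a missing frequency on either side
are excluded (conservative). Proxies are attempted only for
outcome-missing variants and ambiguous palindromes. Variant pairs absent
from the LD reference are treated as unlinked with a warning. Clumping is
the deterministic greedy p-ranked rule (ties broken lexicographically by
variant id), so its output is independent of input order. Every exclusion
carries exactly one reason in the exclusion log, and the workflow manifest
aggregates the logs across analyses.

## The synthetic generator

`synthetic_truth()`/`generate_study()` emulate the statistical structure of
the real inputs so every stage can be exercised offline. Defaults, chosen
once as the study conditions: 400 candidate SNPs with allele frequencies
Uniform(0.05, 0.95); true per-SNP effects bivariate normal across the two
exposures with genetic correlation 0.7, rescaled so the candidate set
explains exactly 2.59%/2.96% of variance; exposure GWAS of n = 757,601, so
per-SNP SEs $1/\sqrt{2p(1-p)n}$ and roughly 170–190 genome-wide-significant
instruments per trait with mean F in the tens (the selection threshold
$p < 5\times10^{-8}$ implies a minimum F of about 29.7 among directly
selected SNPs); estimation errors correlated at 0.69 across exposures
(shared sample); binary outcomes on the log-odds scale with SEs
$1/\sqrt{2p(1-p)\,n\,cf(1-cf)}$ at UK-Biobank-scale case fractions, plus a
z-scored lifespan outcome; default direct effects taken from the
direct-effect scale of the blood-pressure literature (CVD log 1.83 and
log 1.18; lifespan −0.13 and −0.07 per SD). Optional features: LD blocks
(tag SNPs for clumping to remove), palindromic variants, outcome-missing
variants with $r^2 = 0.9$ proxies, a BMI annotation table for the
pleiotropy screen, sample overlap as shared estimation noise with
correlation `overlap_fraction * sqrt(phenotypic correlation)`, and
pleiotropy modes: `balanced` (zero-mean), `directional`, and
`inside-violating` (correlated with instrument strength). Directional
pleiotropy is defined relative to the exposure-raising allele of the first
exposure: allele labels are arbitrary, so a mean shift in the unoriented
frame would cancel under MR-Egger's orientation and be indistinguishable
from balanced pleiotropy.

What the generator does *not* emulate: realistic genome-wide LD, winner's
curse relief from external replication (selection and estimation use the
same simulated GWAS, as in the source study), liability-scale binary
traits, sex-specific standardisation of parental lifespan (the outcome is
generated directly as a z-score), and population structure. Passing tests
therefore demonstrate estimator correctness and calibration under the
stated sampling model, not robustness to those additional features of real
data.

## Numerical choices and degenerate inputs

p-values are always recomputed two-sided from $\hat\beta/\mathrm{SE}$ under
the normal approximation; the file's p-value is kept as `pvalue_reported`.
CIs are normal-theory throughout. Wald-ratio SEs are first-order by default
to match the IVW weighting; the second-order option adds the exposure-side
term. A single SNP degrades IVW to the Wald ratio; $I^2_{GX}$ with one SNP
is NA with a warning; Egger needs 3 SNPs, PRESSO 4 (univariable) or
$d + 3$ (multivariable), the multivariable median $d + 2$; rank-deficient
exposure matrices raise a collinearity error naming the offending columns.
The conditional-F minimisation starts from the unweighted least-squares
delta (one-dimensional problems use golden-section search on a wide
bracket, higher dimensions BFGS); the modified-Q IRLS iterates to
$10^{-10}$ with a variance floor of $10^{-30}$; the $L_1$ IRLS floors
residuals at $10^{-8}$. Evidence labels: `strong` for $p < 0.0125$
(0.05 / [2 exposures × 2 outcome groups]), `suggestive` for
$0.0125 \le p < 0.05$ — the boundary value itself is labelled suggestive,
a documented choice where the verbal rule is ambiguous.

## Known limitations

* Summary-data multivariable IVW carries a regression-dilution bias of
  order $1/F_{\mathrm{cond}}$ from measurement error in the SNP-exposure
  effects. At the default study conditions (mean F ≈ 70–110, conditional
  F ≈ 65) this is a ~1.5% relative attenuation of a strong direct effect —
  about 0.6 SE — so nominally 95% CIs on the causal exposure cover at
  roughly 90% in the package's own replicate experiments. This is the same
  weak-instrument caveat that motivates the conditional-F > 10 rule; the
  package reports the statistic rather than attempting a bias-corrected
  estimator.
* MR-Egger SEs are not SIMEX-corrected; with $I^2_{GX}$ near 1 (as here)
  the uncorrected estimate is adequate.
* The Steiger pseudo-$r^2$ is an observed-scale convention for binary
  traits; liability-scale conversion is out of scope.
* Problem sizes in the test suite (replicate counts of 100–500, candidate
  sets of 60–400 SNPs, bootstrap/simulation counts of 60–1500) were chosen
  to give stable Monte-Carlo verdicts on a single CPU; all are arguments,
  not constants.
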