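---
title: "Two-sample Mendelian randomization of glycemic traits on breast cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization of glycemic traits on breast cancer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtmr)
```

## The question and the design

Observational associations between circulating glycemic traits — fasting
glucose (FG, mmol/L) and fasting insulin (FI, natural-log pmol/L) — and
breast cancer risk are vulnerable to confounding, reverse causation and
measurement error. Two-sample Mendelian randomization (MR) sidesteps these
by using genetic variants as instrumental variables: alleles are assigned at
meiosis, before any phenotype, so a variant that raises fasting glucose by a
known amount provides a natural experiment on downstream cancer risk.
"Two-sample" means the variant–exposure associations (here, MAGIC glycemic
GWAS in non-diabetic European women) and the variant–outcome associations
(breast-cancer GWAS: BCAC OncoArray; ATLAS CGEMS, GEE age-adjusted, and GEE
age+BMI-adjusted) come from different samples, and only published summary
statistics are needed.

For variant $k = 1,\dots,K$ let $X_k$ be the change in the exposure per
effect allele with standard error $\sigma_{Xk}$, and $Y_k$ the change in
log-odds of breast cancer per that same allele with standard error
$\sigma_{Yk}$. Each variant's Wald ratio $\theta_k = Y_k / X_k$ estimates
the causal log-odds per exposure unit; the fixed-effect inverse-variance
weighted (IVW) estimator combines them:

$$
\hat\beta_{IVW} = \frac{\sum_k X_k Y_k \sigma_{Yk}^{-2}}
                       {\sum_k X_k^2 \sigma_{Yk}^{-2}},
\qquad
se(\hat\beta_{IVW}) = \frac{1}{\sqrt{\sum_k X_k^2 \sigma_{Yk}^{-2}}} .
$$

This is the weighted mean of the $\theta_k$ with weights
$w_k = X_k^2 \sigma_{Yk}^{-2}$ — a fact the test suite uses as an exact
oracle. The weights ignore $\sigma_{Xk}$ (the "no measurement error",
NOME, assumption); `gtmr` carries exposure SEs in its data model but, by
design, never feeds them to the estimators.

Two diagnostics probe the exclusion restriction. Cochran's
$Q = \sum_k w_k (\theta_k - \hat\beta_{IVW})^2$, referred to
$\chi^2_{K-1}$, flags heterogeneous per-variant effects. MR-Egger regresses
$Y_k$ on $X_k$ by weighted least squares with an *unconstrained* intercept:
under the InSIDE assumption the intercept estimates the average directional
pleiotropic effect per allele, and the slope is a pleiotropy-robust causal
estimate. Constraining the intercept to zero collapses the Egger slope back
to $\hat\beta_{IVW}$ exactly — another identity the tests assert.

## Harmonization

Exposure and outcome panels are joined on rsid (positions in the source
tables differ by one between outcome datasets, so coordinates are not a
usable key) and every outcome record is re-expressed on the exposure's
effect allele: label swaps negate $Y_k$ and complement the allele
frequency; opposite-strand records are reconciled by complementing alleles.
Palindromic variants (A/T, C/G) are ambiguous from labels alone and follow
a policy: `drop`, `infer_by_freq` (orient by allele-frequency agreement,
dropping variants whose minor-allele frequency exceeds 0.42 — the 0.08
tolerance is the package default since frequencies that close to 0.5 cannot
arbitrate), or `keep` (same-strand assumption). Every decision lands in a
line-oriented audit log attached to the instrument table. The packaged
fixture is reproduced with `keep`: its source is a single curated table
whose instrument set includes palindromic variants (e.g. rs7944584 T/A), so
both panels are known to share a strand.

LD pruning (`greedy_ld_prune()`) implements the standard greedy rule — keep
the most significant variant, discard everything with $r^2 \ge 0.1$ to a
kept variant, ties broken by (p-value, rsid) — against a user-supplied LD
matrix. The packaged instrument tables are already the post-pruning set, so
the fixture pipeline does not prune; the mechanism is exercised on
constructed matrices in the tests.

## The packaged fixture and what it reproduces

`load_fixture()` ships six instrument blocks — FG against OncoArray (19
SNPs), ATLAS-CGEMS (19), ATLAS-GEEA (9), ATLAS-GEEAB (9); FI against
OncoArray (4) and ATLAS-CGEMS (3); 38 and 6 unique rsids — with exposure
effects in trait units and outcome odds ratios with 95% CIs. Outcome ORs
convert to log-odds on load with $\beta = \ln OR$,
$se = (\ln hi - \ln lo)/(2 z_{0.975})$; the symmetric-midpoint formula
absorbs the slight asymmetry of 3-decimal printed intervals. Since printed
inputs are rounded to 3 decimals, reproduced ORs carry that rounding
through the weights; agreement to about $\pm 0.01$–$0.05$ on the OR scale
is the attainable precision, and the test suite asserts $\pm 0.05$.

```{r fixture}
row <- run_dataset_analysis("FG", "OncoArray")
row[c("analysis", "n_snps", "or", "or_ci_low", "or_ci_high", "egger_intercept_or")]
```

Pooling (`run_pooled()`, policy `per_dataset_rows`) concatenates all
dataset-specific instrument rows into one IVW — an rsid instrumented in
several outcome datasets contributes one row per dataset — while reporting
the unique-rsid count (38 FG rows over 56 instrument rows; 6 FI over 7).
This is the only pooling rule consistent with the study's printed SNP
counts; alternatives (`first_dataset`, `none`) are available but change the
question being asked.

Two numerical choices deserve note:

* **Egger orientation.** Conventionally, exposure effects are oriented
  positive before the Egger fit (`orient = TRUE`, the `mr_egger()`
  default), which fixes the sign convention of "directional" pleiotropy.
  The study's published intercepts, however, are reproduced exactly —
  point estimates *and* CIs, e.g. FI/OncoArray 1.014 (0.995–1.034) — only
  by the unoriented regression, so the reproduction pipeline
  (`run_dataset_analysis()`, `run_pooled()`) defaults to
  `egger_orient = FALSE`. With oriented fits the FI/OncoArray intercept
  would be 1.056. Unoriented intercepts are harder to interpret when
  exposure effects have mixed signs; both options are exposed.
* **Intercept inference** uses the $t$ distribution with $K-2$ degrees of
  freedom (configurable to normal): at $K = 3$–19 the difference is
  material.

Sensitivity exclusions (diabetes- and visceral-obesity-associated loci) are
configuration inputs: the definitive locus lists are not recoverable from
the published tables, so `default_exclusions()` ships documented
placeholders (MTNR1B, CDKN2B-AS1, ADCY5; PPP1R3B-region) that exercise the
machinery, and no exclusion-row output is treated as a reproduction target.
Likewise out of scope: the upstream 430-to-44 instrument selection from raw
consortium downloads, and the starred OncoArray subset rows whose defining
footnote is absent from the source.

A reproducibility note the pipeline surfaces but does not resolve: the
per-dataset heterogeneity p-values computed here match the source's
footnoted column closely (e.g. 0.993 for FG/ATLAS-CGEMS), but the pooled
ones do not (0.017 vs 0.0007 for pooled FG), and the pooled-FI Egger p
(0.009–0.015 depending on the reference distribution) sits at odds with the
study's overall "no significant directional pleiotropy" reading. The
package reports its own computed values alongside and leaves the
interpretation to the analyst.

## The synthetic generator and what calibration shows

`simulate_two_sample()` draws, per variant, a true exposure effect $x_k$
uniform on `exposure_effect_range` with random sign, a pleiotropic effect
$\alpha_k \sim N(\mu_\alpha, \sigma_\alpha^2)$, an outcome SE uniform on
`se_Y_range`, and observed effects

$$X_k = x_k + \varepsilon_{Xk}, \qquad
  Y_k = \beta x_k + \mathrm{sign}(x_k)\,\alpha_k + \varepsilon_{Yk},$$

with Gaussian noise at the reported SEs. Two deliberate choices: effects
are generated directly on the summary-statistic scales (no individual-level
logistic model — that is the regime the estimators assume, and the thing
being tested is the estimators); and pleiotropy enters per
*exposure-increasing* allele, via $\mathrm{sign}(x_k)$, so that
"directional" survives the joint $(X_k, Y_k)$ reorientation the Egger fit
applies — pleiotropy attached to an arbitrary allele labeling would average
out under orientation and $\mu_\alpha$ would be unestimable by
construction. Random signs on $x_k$ exist precisely to exercise that
orientation step.

Defaults mirror the fixture's magnitudes — $|x_k| \in [0.015, 0.075]$
trait units per allele (the glycemic GWAS range),
$\sigma_{Yk} \in [0.005, 0.015]$ (large outcome GWAS), $\sigma_{Xk} = 0$
(the NOME regime), no pleiotropy — so calibration probes the estimators
under the study's own conditions. What the generator does *not* emulate:
LD between instruments, realistic allele-frequency spectra, winner's curse
in instrument selection, and exposure measurement error unless switched
on. Passing calibration therefore validates the estimators under their
stated assumptions; it does not certify robustness to those real-data
violations.

`calibration_experiment()` runs the full simulate–harmonize–estimate path
per replicate (per-replicate seeds are drawn once from the master seed, so
any replicate is independently reproducible). The shipped acceptance
checks use $K = 50$ and 1000 replicates per scenario — large enough that
the Monte-Carlo envelope on coverage is about $\pm 0.014$, small enough to
run in seconds:

```{r calibration}
calibration_experiment(sim_config(K = 50, beta_causal = 0.3, seed = 7),
                       n_reps = 200)
```

Under the no-pleiotropy null with $\sigma_{Xk} = 0$, the IVW estimate is
exactly normal around the truth and $Q$ exactly $\chi^2_{K-1}$, so bias
stays within Monte-Carlo noise of zero, coverage sits at the nominal 95%,
and both the $Q$ and Egger-intercept tests hold their 5% level. With
directional pleiotropy ($\mu_\alpha = 0.05$ log-odds per allele) the naive
IVW is badly biased while the Egger intercept detects the violation with
essentially full power — the scenario the diagnostics exist for.

## Limitations

The fixture reproduces published summary tables, not the underlying
consortium data: its precision is bounded by 3-decimal rounding, and
analyses that need unpublished inputs (menopausal stratification, the
starred subsets, the true exclusion lists) are unreachable from it. The
estimators are the study's own — fixed-effect IVW, Q, Egger — not the wider
modern MR toolbox (weighted median/mode, MR-PRESSO, multivariable MR), and
the harmonizer handles biallelic SNVs only.
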