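---
title: "Lifecourse Mendelian randomization with family-history-proxied outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifecourse Mendelian randomization with family-history-proxied outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinmr)
```

## The problem

Large biobanks ask participants about illnesses of their parents. Those
reports can stand in for disease outcomes the participants themselves have
not (yet) experienced, which makes outcomes like parental heart disease,
diabetes or lung cancer available at very large sample sizes — at a price:
the genotype in the association is the *participant's*, not the case's. A
participant shares on average half their DNA with each parent, so every
genetic association with a parental outcome — and every Mendelian
randomization (MR) estimate built on such associations — is attenuated by
the genotypic sharing coefficient $s$ ($s = 0.5$ for first-degree
relatives).

`kinmr` implements a complete two-sample MR workflow for this
"GWAS-by-proxy" setting, with a particular focus on *lifecourse* questions:
does early-life body size affect disease directly, or only by persisting
into adulthood?

## The estimators

All estimators consume per-SNP summary statistics: exposure effects
$\hat\beta_{Gx}$ and outcome effects $\hat\beta_{Gy}$ for a harmonized set
of instruments.

**IVW.** The inverse-variance-weighted estimate is the weighted regression
of $\hat\beta_{Gy}$ on $\hat\beta_{Gx}$ through the origin with weights
$w_j = 1/\mathrm{se}(\hat\beta_{Gy,j})^2$:
$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\beta_{Gx,j}\hat\beta_{Gy,j}}
{\sum_j w_j \hat\beta_{Gx,j}^2}.$$
The default model is multiplicative random effects: the fixed-effect
standard error is inflated by $\sqrt{\max(1, Q/(n-1))}$, where $Q$ is
Cochran's heterogeneity statistic, and never deflated below the
fixed-effect value. $Q$ is reported but never used to drop SNPs — no
outlier-removal stage exists in this workflow.

**MR-Egger** adds a free intercept (after orienting all exposure effects to
be non-negative); the intercept estimates directional pleiotropy and the
slope remains a causal estimate under weaker assumptions. **Weighted
median** takes the weighted 50th percentile of the per-SNP ratio estimates
(midpoint convention with linear interpolation), with a parametric
bootstrap SE (default 1000 draws, caller-supplied seed recorded in the
fit). P-values throughout use the standard normal reference, the summary
data convention.

**Multivariable MR.** With $K$ exposures the same weighted regression is run
on the $n \times K$ matrix of exposure effects (no intercept), giving each
exposure's *direct* effect conditional on the others; the SE scale factor
uses $Q/(n-K)$. Instruments are the union of the exposures' clumped
instrument sets, re-harmonized jointly. A conditional instrument-strength
statistic is reported per exposure: the mean squared standardized residual
of that exposure's effects after projecting out the other exposures'
columns — an intentionally simple approximation to the conditional
F-statistic (the auxiliary projection ignores the exposure-side SEs).

**Decomposition.** For an early-life exposure, the univariable estimate is
the *total* effect and the multivariable estimate is the *direct* effect.
The *indirect* effect (the part transmitted through the later-life
exposure) is reported two ways: the difference $\text{total} -
\text{direct}$, with the conservative SE
$\sqrt{se_{total}^2 + se_{direct}^2}$ (the covariance of the two estimates
is not identifiable from summary output and is ignored, which is flagged in
the output), and the product of the early-on-late effect with the late
exposure's direct effect, with a first-order delta-method SE. The two
coincide in expectation under a linear structural model; divergence is a
diagnostic, which is why both are always shown.

**Sharing de-attenuation.** "Halved by proxy" is a statement about the
linear/log-odds scale, not the OR scale: an OR of 1.97 observed on a
parental proxy corresponds to $\exp(2\ln 1.97) = 3.88$ on the case scale,
not $2 \times 1.97$. `deattenuate_proxy()` therefore divides the estimate,
SE and CI bounds by $s$ on the log-odds scale and ORs are exponentials of
the adjusted values. Both raw and adjusted estimates are always reported,
since published proxy results do not always state which convention they
use.

**FDR gate.** Multivariable analyses are run only for exposure–outcome
pairs passing a Benjamini–Hochberg gate at $q = 0.05$ on the univariable
IVW p-values. Whether the family of tests pools outcomes within each
exposure or globally across all pairs is genuinely ambiguous in practice;
the default is per-exposure pooling with a `fdr_pooling = "global"` switch,
and neither mode is asserted to be what any particular study did.

## Harmonization choices

Effect alleles are oriented to the first exposure's effect allele.
Swapped and strand-complement allele pairs are aligned by sign-flip /
frequency complement; incompatible pairs are dropped with a logged reason.
Palindromic variants (A/T, C/G) cannot be resolved from alleles alone:
the default policy drops them; `infer-by-eaf` aligns them by allele
frequency when both frequencies lie outside $0.5 \pm 0.08$ (the tolerance
is a flag). Duplicate variant ids keep the smallest p-value. These are
deliberate, conventional defaults — nothing here claims to reproduce any
specific study's (unpublished) harmonization settings.

Clumping is greedy: candidates below the p-value threshold (default
$5 \times 10^{-8}$) are ranked by ascending p (ties broken by genomic
position, for determinism), the best remaining candidate is accepted, and
everything correlated at $r^2 \ge$ the threshold (default $0.001$) with it
is discarded. The LD matrix is user-supplied: the package does not compute
LD from a reference panel, and sub-threshold variants absent from the
matrix are excluded rather than assumed independent.

## What the trio simulator emulates — and what it does not

`simulate_cohort()` draws independent mother–father–offspring trios:

* **Genotypes.** Unlinked SNPs; parents are Hardy–Weinberg with per-SNP
  allele frequency uniform in `maf_range` (default $[0.1, 0.5]$); each
  offspring inherits one uniformly chosen allele from each parent, so the
  offspring–parent dosage correlation is 0.5 per SNP. SNPs are simulated
  unlinked (identity LD) to keep the halving-law algebra exact; clumping is
  exercised on separately constructed correlated fixtures in the tests.
* **Exposures.** Childhood exposure is $G\beta_c$ plus noise scaled to a
  target heritability (default 0.3, a realistic value for body size);
  adult exposure is $\kappa \times$ childhood (default persistence
  $\kappa = 0.5$) plus adult-specific genetic effects plus noise scaled so
  the adult genetic fraction hits its target. If the childhood noise
  carried over by $\kappa$ already exceeds the adult environmental budget
  the generator refuses and reports the achievable bound rather than
  silently missing its target. Per-SNP effects default to
  $N(0, 0.15^2)$ draws — dozens of small effects, the polygenic regime the
  workflow assumes.
* **Disease.** Parental liability is a linear combination of the parent's
  own exposures plus *standard logistic* noise; disease is liability above
  the realized $(1-\text{prevalence})$ quantile pooled over parents
  (default prevalence 0.3, in the range of common parental endpoints like
  hypertension or heart disease). The realized quantile fixes prevalence
  exactly per replicate, reducing Monte-Carlo variance. Logistic rather
  than normal noise is a deliberate choice: it makes the $\theta$
  parameters genuine log-odds effects, so a logistic per-SNP scan is
  correctly specified and parameter recovery on the log-odds scale is
  meaningful. With normal (probit-style) noise every logistic scan would
  recover $\theta$ only up to a non-collapsibility factor and the
  recovery tests would be testing an approximation instead of the method.
* **Mediator.** The mediator (a lifetime-smoking analogue) is
  $\gamma \times$ adult exposure plus mediator-specific genetic effects
  plus unit noise. The mediator-specific effects matter: without its own
  instruments the mediator's effect column is collinear with the adult
  column in expectation and the three-exposure model is unidentifiable —
  exactly as real mediation MR requires the mediator to have instruments
  of its own.
* **Outcome coding.** Family history is mother + father disease
  ($\{0,1,2\}$, the biobank parental-illness coding) with single-parent
  binaries for sex-specific endpoints. One disease per run: multi-endpoint
  studies are multiple configs, matching how such endpoints are analysed
  marginally.

Not modelled, by design: LD structure, assortative mating, parental age /
survival, participation ascertainment, and recall error in parental
illness reports (a missingness flag exists but defaults to off). A green
test on this generator therefore establishes the *statistical machinery* —
transmission algebra, estimator consistency, gate calibration — not
robustness to those real-data complications.

## Numerical and design notes

* The package's estimators are closed-form weighted least squares written
  directly in linear algebra; the test suite checks them to $10^{-10}$
  against independently coded `lm()` oracles, and the clumping against an
  independent recursive implementation on random block-LD instances.
* The halving-law check (offspring-genotype vs parent-genotype IVW
  estimates) has a Monte-Carlo SD of ~4.5 percentage points per
  20,000-trio replicate; the acceptance report averages the ratio over 12
  independent replicates (MC SE ≈ 1.3 points). The ratio is exactly
  scale-free, so it is computed from linear scans.
* The FDR calibration uses 500 replicates of 8 small all-null cohorts
  (400 trios, 20 SNPs): under the global null the BH false-discovery
  proportion equals the probability of any discovery, which is $q$ for
  independent p-values, and this is independent of cohort size.
* Degenerate inputs have defined behaviour: all-zero exposure columns in
  multivariable fits are dropped and reported as explicit NA fits (the
  remaining columns reproduce the nested model exactly); monomorphic SNPs
  scan to missing records with a logged skip; estimators refuse
  insufficient instruments rather than returning unstable numbers.
* Report tables are byte-reproducible from config + inputs + seed;
  timestamps appear only in log messages, never in output files.

## Worked example

```{r example, eval = FALSE}
co <- simulate_cohort(sim_config(n_trios = 6000, n_snps = 40,
                                 theta_adult = 0.5, kappa = 0.5, seed = 314))
files <- emit_study(co, "study/")
cfg <- run_config(
  exposure_early = files[["exposure_childhood"]],
  exposure_late = files[["exposure_adult"]],
  outcomes = data.frame(name = "father_binary",
                        path = files[["outcome_father_binary"]],
                        sharing = 0.5),
  ld = files[["ld"]], out_dir = "report/")
report <- run_pipeline(cfg)
report$lifecourse[["father_binary"]]
```

The childhood total effect is positive (it persists into adulthood, which
affects disease), while the sharing-adjusted direct effects recover
approximately (0, 0.5) — the generating $(\theta_{child},
\theta_{adult})$.

## Known limitations

Conditional instrument strength is an approximation, not the full
conditional F; the difference-method indirect SE is conservative by
construction; mediation proportions carry delta-method uncertainty only;
and nothing here corrects for the selection, recall and survival biases
that affect real family-history reports.
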