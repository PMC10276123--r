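# kinmr — lifecourse Mendelian randomization with family-history-proxied outcomes

Biobank participants report their parents' illnesses; those reports can be
used as disease outcomes for participants' own genotypes ("GWAS-by-proxy").
Because a participant shares on average 50% of their DNA with each parent,
every genetic association with a parental outcome — and every Mendelian
randomization (MR) estimate built on one — is attenuated by the genotypic
sharing coefficient *s* (0.5 for first-degree relatives). `kinmr` is an R
package for two-sample MR in exactly this setting, aimed at
genetic-epidemiology analysts who want to separate early-life from
adult-life exposure effects using such proxy outcomes.

What it provides:

* **Summary-statistics plumbing** — tab-separated GWAS summary statistics
  (`SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N`) with validation,
  lossless round-tripping, and effect-allele harmonization (swapped and
  strand-complement alleles aligned; palindromic variants dropped or
  resolved by allele frequency).
* **Instrument selection** — greedy LD clumping at `P < 5e-8`,
  `r² < 0.001` against a user-supplied LD matrix, plus F-statistic
  diagnostics.
* **Univariable estimators** — IVW (multiplicative random effects by
  default),

  `b_IVW = Σ w·bx·by / Σ w·bx²`, `w = 1/se(by)²`,

  MR-Egger (free intercept = directional pleiotropy), weighted median
  (bootstrap SE), Wald ratio, odds-ratio conversion, and a
  Benjamini–Hochberg FDR gate.
* **Lifecourse multivariable MR** — direct (conditional) effects of K
  exposures, total/direct/indirect decomposition (difference *and*
  product formulations), three-exposure mediation, and de-attenuation of
  proxy estimates by *s* on the log-odds scale (a proxy OR of 1.97
  adjusts to `exp(2·ln 1.97) = 3.88`, not 2 × 1.97).
* **A trio simulator** — mother/father/offspring genotypes with Mendelian
  transmission, heritability-targeted childhood → adult exposures, a
  liability-threshold parental disease model, and the 0/1/2
  family-history outcome coding; it emits complete simulated studies in
  the summary-statistics schema and is the test bed for everything above.

## Worked example

Simulate a study in which childhood body size affects parental-proxied
disease *only* by persisting into adulthood (θ_child = 0, θ_adult = 0.5,
persistence κ = 0.5), then run the full pipeline:

```r
library(kinmr)

co <- simulate_cohort(sim_config(n_trios = 6000, n_snps = 40,
                                 theta_adult = 0.5, kappa = 0.5, seed = 314))
files <- emit_study(co, "study/")
cfg <- run_config(
  exposure_early = files[["exposure_childhood"]],
  exposure_late  = files[["exposure_adult"]],
  outcomes = data.frame(name = "father_binary",
                        path = files[["outcome_father_binary"]],
                        sharing = 0.5),
  ld = files[["ld"]], seed = 77, out_dir = "report/")
report <- run_pipeline(cfg)
report$lifecourse[["father_binary"]]$unadjusted
#> Lifecourse decomposition: exposure_childhood -> father_binary (via exposure_adult)
#>   total    +0.1528 (SE 0.0633)
#>   direct   +0.0393 (SE 0.0572)
#>   indirect +0.1135 (SE 0.0853, difference) / +0.1258 (SE 0.0507, product)

deattenuate_proxy(report$mvmr[["father_binary"]], s = 0.5)
#> Multivariable MR fit: 2 exposures, 22 SNPs (Q = 15.99 on 20 df)
#>   exposure_childhood       b = +0.0786 (SE 0.1144), p = 0.492, cond. F = 48.6
#>   exposure_adult           b = +0.4034 (SE 0.1016), p = 7.21e-05, cond. F = 53.4
```

Reading the numbers: the childhood *total* effect (0.15, p < 0.05) is
real but entirely indirect — conditioning on adult size collapses the
direct effect to null (0.04 ± 0.06), while the sharing-adjusted adult
direct effect (0.40 ± 0.10) recovers the generating log-odds effect 0.5
within Monte-Carlo error. This is the simulated analogue of the
observation that childhood adiposity's apparent effects on adult disease
largely reflect persistence of adiposity into adulthood.

Tables (`results.tsv`, `lifecourse.tsv`, `provenance.json`) are written
under `out_dir` and are byte-reproducible from config + inputs + seed. A
command-line launcher lives at `inst/cli/kinmr.R`
(`kinmr simulate|clump|run`).

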