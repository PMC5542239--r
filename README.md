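# nbpanel

Tumor-only targeted-panel analysis for pediatric neuroblastoma cohorts.

Deep sequencing of a capture panel (83 cancer genes) on tumor tissue
without a matched normal poses three linked problems that this package
solves as a tested, reusable pipeline:

1. **Somatic variant filtering.** Calls from several SNV/indel callers
   are merged (union; median allele fraction; deepest caller's strand
   counts), stripped of sequencing artifacts (exact binomial strand-bias
   test at p < 10⁻³ with ≥ 95% one-strand reads; ≥ 3 calls in a 10-bp
   window), and cleaned of germline variation by a two-rule filter:
   allele fraction ≥ 97% (hotspot-exempt), population-database frequency
   ≥ 1%, or panel-of-normals occurrence ≥ 3% of 480 normals.
2. **Copy number with tumor purity.** Exon depths are self-normalized,
   divided by a normal reference profile and log2-transformed. Purity
   *p* is estimated by a grid search under the mixture model
   r = (p·CN + 2(1−p))/2 for coverage and
   BAF = (p·nB + (1−p))/(p·CN + 2(1−p)) for heterozygous sites, with an
   integer-copy-number prior. Gene-level calls use the strict published
   thresholds: loss iff CN < 1, gain iff CN > 4.
3. **Cohort statistics.** MYCN amplification from FISH counts over 50
   nuclei (amplified iff ΣMYCN/ΣCEP2 ≥ 10); a patient×gene alteration
   matrix and prevalence table; actionability matching (ALK inhibitors,
   PARP for BRCA1-truncating / ATM-loss, and the other published rules);
   Kaplan–Meier estimates with Greenwood standard errors, G-group
   log-rank tests, and an ARID1-family × MYCN mutual-exclusivity check.

Because the study's patient-level data are not public, the package ships
a first-class synthetic cohort generator (`cohort_config()`,
`simulate_cohort()`) whose defaults encode the published cohort:
72 patients, the printed per-gene alteration prevalences (ALK 16.7%,
BRCA1 13.9%, ATM 12.5%, PTCH1 11.1%, ARID1B 6.9%, …), purity uniform on
0.3–1.0, negative-binomial exon depths, caller sensitivity/false-positive
models, Poisson FISH counts, and exponential stratum survival matching
the printed 3-year fractions. Every pipeline stage is tested end-to-end
against this generator; in its noise-free mode recovery is exact.

## Worked example

```r
library(nbpanel)
cc  <- cohort_config()                       # the published-world defaults
sim <- simulate_cohort(cc, seed = 1)         # one synthetic 72-patient cohort
res <- run_cohort_pipeline(sim, pipeline_config(seed = 1))

res$prevalence[gene %in% c("ALK", "BRCA1", "ATM", "PTCH1", "ARID1B")]
#>      gene n_altered   fraction
#> 1:    ALK        15 0.20833333
#> 2: ARID1B        10 0.13888889
#> 3:  PTCH1         8 0.11111111
#> 4:    ATM         4 0.05555556
#> 5:  BRCA1         4 0.05555556

length(attr(res$actionable, "candidates"))   # therapy candidates
#> 13

res$survival$os_high_risk$strata             # 3-year OS, high-risk strata
#>    stratum     n      surv         se
#> 1:  ARID1B     8 0.3750000 0.17116330
#> 2:    MYCN     4 0.2500000 0.21650635
#> 3: neither    27 0.9259259 0.05040102

res$survival$os_high_risk$logrank_global$p
#> 1.420822e-05
```

One seed's cohort scatters around the configured rates (here ALK drew
15/72 against a configured 12/72); averaging replicate cohorts recovers
the configured values — that recovery is what the acceptance report
measures. `res$survival` reads as: ARID1B-altered and MYCN-amplified
high-risk patients have far worse 3-year overall survival than high-risk
patients with neither lesion, the study's central clinical claim.
`write_report(res, "report")` writes the alteration matrix, prevalence,
actionability and survival summaries to disk.

A command-line front end covers the same flow
(`exec/nbpanel simulate|filter-variants|call-cnv|score-fish|report`).

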