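---
title: "Methods: targeted-panel somatic analysis for neuroblastoma cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted-panel somatic analysis for neuroblastoma cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbpanel)
library(data.table)
```

## Scope and model

nbpanel reimplements the downstream analysis of a tumor-only deep
targeted sequencing study of pediatric neuroblastoma: 72 tumors, an
83-gene capture panel, three SNV callers plus an indel caller upstream,
an in-house exon-coverage/B-allele-frequency copy-number method, MYCN
FISH, actionability matching, and Kaplan-Meier/log-rank cohort
statistics. The package consumes caller output tables, per-exon
coverage, BAF observations, FISH counts and a clinical table; alignment,
deduplication, recalibration and the callers themselves are out of
scope.

Because no patient-level data are public, the package carries a
first-class synthetic cohort generator whose defaults encode the
published cohort-level facts. Every pipeline stage is tested against
that generator, in two regimes: a *noise-free* world in which recovery
must be exact, and a *noisy* world with negative-binomial depths and
binomial allele counts in which recovery is statistical.

## Somatic variant filtering

Per-caller calls merge by `(sample, chrom, pos, ref, alt)`: caller set
union, median allele fraction, strand counts from the deepest caller.
The merge is a union (one caller suffices) because the study detected
variants down to 2.6% allele fraction; a consensus requirement is a
config switch (`min_callers`).

Two artifact rules operationalize the original "in-house scripts":

* **strand bias** — exact two-sided binomial test of alt forward/reverse
  counts against 0.5, removed when `p < 1e-3` *and* at least 95% of alt
  reads sit on one strand;
* **clusters** — at least 3 distinct positions within any 10-bp window
  in one sample; all members removed.

These thresholds are our defaults, not published values, and are
configurable. The germline filter then removes a call iff

1. allele fraction ≥ 0.97 and the call is not a whitelisted hotspot
   (the exemption applies to this rule only), or
2. population-database allele frequency ≥ 1%, or
3. panel-of-normals occurrence ≥ 3% of 480 normals.

Sites absent from a resource count as frequency zero. The packaged
hotspot whitelist contains the activating changes the study names (ALK
R1275Q, F1174I, R1192G; HRAS Q61R) and is extensible. Filters mark
records rather than dropping them, so `|input| = |pass| + |removed|`
always holds and each removed record carries exactly one primary reason.

## Copy number and tumor purity

Per-exon mean depths are self-normalized by the sample median, divided
by a reference profile (median self-normalized coverage of normal
samples), and log2-transformed. Gene-level values are means over exons
(no segmentation: a capture panel has too few exons per gene, and the
study reports gene-level calls).

The purity model is the standard two-component mixture. With purity $p$
and integer tumor copy number $CN$,

$$ r = \frac{p\,CN + 2(1-p)}{2}, \qquad
   \mathrm{BAF} = \frac{p\,n_B + (1-p)}{p\,CN + 2(1-p)}, $$

for $n_B$ minor-allele copies. The copy-neutral log2 level is the
median of gene-level means (exact when most genes are diploid). Purity
is a grid search over $p \in \{0.05, \dots, 1.00\}$; per candidate $p$
each gene is assigned the integer $CN \in [0, 10]$ minimizing its summed
squared coverage-ratio and folded-BAF deviations. Numerical choices that
matter, and why:

* **ratio-space residuals.** Fitting $(r - r_{pred})^2$ instead of
  deviations of inverted CN from integers is the same integer prior with
  homoscedastic weighting; CN-space residuals scale as $1/p$ and bias
  the search toward high purity.
* **complexity penalty.** Every non-diploid assignment is charged
  $c = 3 \cdot \mathrm{median}((r-1)^2)$. Without it the fit collapses
  toward small $p$: as $p \to 0$ the lattice of attainable ratios
  becomes dense and absorbs diploid noise. The penalty is calibrated
  from the sample's own diploid scatter and is exactly 0 on noise-free
  data, so exact-recovery properties are untouched.
* **BAF weight 20.** At panel depths a het-site allele fraction is far
  more precise than a gene's mean coverage ratio; the weight is
  configurable.
* **ties** resolve to the largest purity — the least aberrant genome
  consistent with the data.
* **identifiability.** A flat profile with all BAFs near 0.5 carries no
  purity signal; the solution is flagged `identifiable = FALSE` with
  $p = 1$, under which $CN = 2r$ and all calls are neutral.

Copy number is inverted per gene as $CN = (2r - 2(1-p))/p$ and classed
with the study's strict thresholds: loss iff $CN < 1$, gain iff
$CN > 4$ ($CN = 4$ is neutral). One addition: a gene leaves the neutral
class only when its mean log2 ratio exceeds 3.5 standard errors of the
within-gene exon scatter (floored by the pooled median scatter). The
strict thresholds alone would convert coverage noise into hundreds of
CNV calls per cohort at realistic depths; the gate is zero for exact
data. This is our design choice, not a published rule.

## MYCN FISH

MYCN is absent from the panel; amplification is scored from FISH counts
over fifty non-overlapping nuclei as the ratio of summed MYCN to summed
CEP2 signals (summing avoids division by CEP2-null nuclei). "10-fold
increase" is read inclusively: amplified iff ratio ≥ 10. Both the
boundary and threshold are configurable.

## Actionability

The rule set encodes the study's drug-matching list exactly: ALK
whitelisted point mutations or copy-number gain → ALK inhibitor; BRCA1
truncating (nonsense/frameshift/splice) → PARP; ATM copy-number loss →
PARP; HRAS Q61R; MET exon-14 skip (represented as a flagged splice
variant — the pipeline has no RNA evidence); ERBB2 gain; STK11 loss.
Any ALK gain triggers the rule (amplitude is not conditioned on — the
study does not state one). ALK translocations are out of scope (none
were detected and there is no fusion caller). A patient is a candidate
iff at least one rule fires; matches deduplicate per (patient, therapy
class), so candidacy is monotone in alterations.

## Survival statistics

Kaplan-Meier product-limit with the events-before-censoring tie
convention and Greenwood variance
$S(t)^2 \sum d_j / (n_j(n_j - d_j))$; the G-group log-rank uses the
full hypergeometric covariance with $df = G - 1$. Both are implemented
in-package and verified against brute-force oracles and the survival
package on exhaustive small instances. The "± values" of the published
survival figures are treated as Greenwood SEs — an interpretation, as
the study does not define them. The ARID1B/MYCN exclusivity summary
reports a two-sided Fisher exact p as descriptive only. Strata follow
the published figure: ARID1B-altered; MYCN-amplified and not ARID1B
(ARID1B takes precedence for a hypothetical double positive — none can
exist when the exclusivity flag is on); neither. The 3-year horizon is
fixed at 36 months.

## The synthetic cohort: what it emulates, and what it does not

Defaults are the published cohort facts: n = 72; ALK 12/72, BRCA1
10/72, ATM 9/72, PTCH1 8/72, ARID1B 5/72, ARID1A and ATRX 3/72 each,
HRAS/MET/ERBB2/STK11 1/72; the remaining 72 panel genes share a
background prevalence solved so the configured any-alteration
probability equals the printed 63/72 = 87.5%. Kind mixtures per gene
follow the printed breakdowns (e.g. of 12 ALK-altered patients: 6
hotspot SNVs, 5 other missense, 1 gain). Gene draws are independent —
the study reports marginal prevalences only — except the exclusivity
constraint: ARID1A/ARID1B-altered patients are never MYCN-amplified.
Purity is uniform on 0.3–1.0 (only specimens above 30% tumor content
were sequenced). Survival is exponential per stratum with rate
$-\log(s)/36$ for printed 3-year fraction $s$ (37.5%/90.5% RFS;
33.3%/30.0%/90.5% high-risk OS), with 20% uniform censoring — the
simplest model matching one printed fraction per stratum. FISH counts
are Poisson (mean 40 vs 2 against a CEP2 mean of 2). Sequencing depth
is negative-binomial (mean 500, dispersion 0.1) around the purity-mixed
expected ratio, with deterministic per-exon capture efficiencies shared
with the reference.

Choices the study does not determine, made once:

* **truth allele fractions** uniform on 0.05–0.5 (the study gives only
  anecdotal ranges);
* **CNV truth patterns**: loss = CN 0, gain = CN 8 with minor allele 0.
  The published call definitions (CN < 1, CN > 4) imply biallelic loss
  and high-level gain; a gain with minor allele 1 is *unidentifiable*
  from coverage + BAF (the family $p' n_B' + (1-p') = p n_B + (1-p)$,
  $p' CN' + 2(1-p') = p\,CN + 2(1-p)$ has integer solutions at many
  purities), which would make exact recovery impossible in principle;
* **MYCN prevalence 5/72** (the cohort FISH rate is unpublished; five
  amplified high-risk patients reproduce the stratum-size arithmetic of
  the published high-risk survival figure, whose n = 31 splits as 4
  ARID1B + 27 others);
* **high-risk assignment**: baseline 31/72, ARID1B-altered patients
  high-risk with probability 0.8 (four of five), amplified patients
  always high-risk;
* **caller models**: sensitivities 0.97/0.95/0.92, per-site FP rates
  0.02/0.03/0.03 over 20 decoy sites, FPs stamped with a strand-bias or
  cluster signature so the artifact filter has real work; residual
  germline variants (one high-VAF, one popDB-site, one PoN-site per
  sample at rate 1) exercise the germline filter.

A green test on this world establishes that the *pipeline implements
its stated rules* and that parameter recovery behaves as configured. It
does not establish performance on real capture data: FFPE chemistry,
GC-dependent coverage waves, subclonality, arm-level events spanning
many genes, caller-specific error profiles and inter-sample reference
mismatch are all absent from the generator.

The packaged 83-gene panel BED is an illustrative reconstruction (real
gene names, key genes on their true chromosomes, representative exon
sizes); the original panel's exon composition and 366.2-kb footprint
are not public.

## Degenerate inputs and edge rules

Empty BED → empty panel with a warning; malformed BED line → error
naming the line; records without allele fraction → skipped and counted;
missing strand counts → retained with a warning (the test cannot run);
zero sample median coverage → sample-level error; masked reference
exons propagate, and fully-masked genes are omitted from CN calls with
a warning; zero total CEP2 signal → scoring error; empty survival
strata are reported as n = 0 rather than raising; absent resource
lookups are frequency 0.

## Reproducibility and scale

All randomness descends from one integer seed through deterministic
child seeds per module and replicate; identical (config, seed) gives
byte-identical outputs. Heavy Monte-Carlo checks are scaled to their
runtime budgets (the acceptance script runs 500 replicate cohorts
rather than 2,000; at that scale the Monte-Carlo 3-SE band is about
half a percentage point, far below the comparison slack) — tolerance
bands are computed from the replicate count actually used, never
widened.

## Worked example

```{r example, eval = FALSE}
library(nbpanel)
cc  <- cohort_config()              # the published-world defaults
sim <- simulate_cohort(cc, seed = 1)
res <- run_cohort_pipeline(sim, pipeline_config(seed = 1))
res$prevalence[gene %in% c("ALK", "BRCA1", "ATM", "PTCH1", "ARID1B")]
res$survival$os_high_risk$strata
write_report(res, "report", seed = 1)
```

## Known limitations

Gene-level aggregation only (no segmentation, no subclonal CN, no
allele-specific output); global copy-neutral level (per-chromosome
estimation is unimplemented, noted as a future config switch); no Cox
regression or multivariable adjustment (the study performs none); the
purity grid search is bounded below at 0.05 and gains are capped at
CN 10 for hypothesis generation; FISH heterogeneous/focal amplification
subcategories are not modeled (one binary call).
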