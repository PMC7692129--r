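# eqascore

Scoring and simulation toolkit for external quality assessment (EQA, also
known as proficiency testing) of targeted next-generation sequencing in
(hemato-)oncology.

In these schemes, laboratories receive blinded DNA samples derived from
engineered cell-line mixes carrying clinically relevant somatic variants at
certified allele frequencies, process them in triplicate through their
routine NGS workflows, and report the variants they detect. The scheme
organizer must then turn a pile of heterogeneous per-laboratory variant
reports — written in half a dozen protein-HGVS dialects, filtered by
different limits of detection, and amplified by incompatible gene panels —
into defensible per-laboratory scores and an anonymized global report.
`eqascore` implements that evaluation pipeline end to end, plus a synthetic
laboratory-cohort simulator for validating every stage against a planted
ground truth.

## The scoring model

For each benchmark, the set of **evaluative variants** (the scoring ground
truth) consists of the variants that are simultaneously:

* reported by at least two-thirds of enrolled participants
  (`k = ⌈2N/3⌉`),
* validated by ddPCR and/or whole-exome sequencing (per-benchmark policy),
* located inside the regions of interest of the national reimbursement
  convention.

Validated or reported variants failing that bar are **informative**
(reported back, never scored); variants reported by nobody or outside the
regions of interest are not assessed. A participant correctly identifies an
evaluative variant when it appears in **at least one** of its valid
replicates; an evaluative variant absent from all replicates is a **false
negative**, classified by a cause cascade (operator error, below the
laboratory's LOD, near the LOD, withheld as a VUS, panel/cassette
incompatibility, undetermined). Observations where an amplicon panel's
primers flank the 2 kb insertion cassette used to engineer a variant are
**masked**: excluded from every denominator, because the unamplifiable
variant is an artifact of the benchmark material.

Reported allele frequencies are scored informatively through Z-scores. Per
variant and participant:

```
MRAF = median allele frequency over the participant's (≤3) replicates
MAF  = median of participant MRAFs, after iterative two-sided Grubbs
       outlier removal (α = 0.05)
SD   = sample standard deviation of the retained MRAFs
Z    = (MRAF − MAF) / SD
```

A **Z-score citation** is issued when |Z| > 3.0. In peer-group mode
(panel-stratified benchmarks), MAF/SD and Z are computed within groups of
participants sharing a gene panel, and no Z is allocated in groups with
fewer than 6 reporters. Shapiro–Wilk p-values flag non-normal MRAF
distributions for reporting; they never gate scoring.

## Worked example

Three historical benchmarks are packaged as fixtures reconstructed from
their published per-variant results (solid tumors, hematological
malignancies, BRCA1/2). Scoring one of them:

```r
library(eqascore)

res <- fixture_results("2017/1")
res
#> <eqa_results> benchmark 2017/1
#>   success: 247 / 253 (97.63%)
#>   Z citations: 19 / 247 (7.69%)
#>   false negatives (incl. masked): 9
```

97.63% is the global success rate: 16 participants × 16 evaluative
variants, minus 3 observations masked for cassette incompatibility, gives
253 assessable observations of which 247 were detected in at least one
replicate. 19 of the 247 allocated Z-scores exceeded |3| (7.69%). Of the 9
missed observations, 3 are masked and 6 are true false negatives.

```r
head(res$variant_table, 4)
#> # A tibble: 4 × 8
#>   sample_id    gene  variant         maf    sd z_cited z_allocated success_n
#> 1 NGS-2017-001 BRAF  p.(Val600Glu)  13.2  0.6        1          16        16
#> 2 NGS-2017-001 KRAS  p.(Gly13Asp)   32.9  0.64       1          16        16
#> 3 NGS-2017-001 NRAS  p.(Gln61Lys)   21.6  1.17       1          16        16
#> 4 NGS-2017-002 BRAF  p.(Val600Arg)  11.3  1.13       1          16        16
```

The same pipeline runs on fresh data: `read_design()` +
`read_submissions()` → `evaluate_benchmark()` → `render_global()` /
`render_individual()`. A fully synthetic round looks like:

```r
design   <- generate_design(n_labs = 16, n_samples = 4,
                            variants_per_sample = 4, seed = 1)
profiles <- lab_profiles(design, seed = 1)
sub      <- generate_submissions(design, profiles, seed = 1)
res      <- evaluate_benchmark(design, sub$reports, sub$statuses,
                               policies = profiles)
render_global(res, "reports/")
```

`sub$ledger` carries the planted outcome of every (laboratory, sample,
variant) observation, so the pipeline's detections and false-negative
causes can be checked exactly.

## Scope

The package evaluates variant *detection* and allele-frequency concordance.
Wet-lab material production, ddPCR confirmation assays, read-level (BAM)
review, and the scoring of biological/clinical interpretation text are out
of scope; curated boolean flags (operator error, VUS policy) stand in for
manual review where the cause cascade needs them. False positives are not
scored: non-truth reported variants are listed descriptively only.
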