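---
title: "Scoring NGS proficiency-testing benchmarks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring NGS proficiency-testing benchmarks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqascore)
```

## The evaluation problem

An external quality assessment (EQA) round for somatic NGS testing ships
blinded DNA samples — cell-line mixes engineered to carry clinically
relevant variants at certified allele frequencies — to a national cohort of
laboratories, each of which processes them in triplicate through its own
routine workflow (its own panel, enrichment chemistry, sequencer,
bioinformatics, and reporting thresholds) and returns a table of detected
variants. The organizer's job, implemented by this package, is to

1. collapse heterogeneous variant descriptions onto common identities,
2. decide which variants constitute the scoring ground truth,
3. decide which observations are *assessable* at all,
4. score detection and allele-frequency concordance, and
5. explain every miss.

This vignette documents the model, its tunable parameters, and the design
choices made where the procedure was genuinely open.

## Variant identity: tolerant HGVS canonicalization

Laboratories render the same protein change in many dialects — for a
single Val→Arg substitution at residue 600 one observes `p.(Val600Arg)`,
`p(Val600Arg)`, `p.Val600Arg`, `p.V600R`, `p.Val600delinsArg` and
`p.V600delinsR`. `parse_protein_hgvs()` accepts an optional `p.`/`p`
prefix, optional parentheses, one- or three-letter residue codes, `*`/`Ter`
for the stop codon, and the `del`/`dup`/`ins`/`delins`/frameshift forms;
`canonicalize_protein()` then renders one deterministic string
(three-letter codes, parentheses, `_` range separator, `*` for stop), with
single-residue delins events rewritten as substitutions since they name
the same molecular outcome.

Decisions worth recording:

* **Hyphen ranges.** `p.(Glu746-Ala750del)` (hyphen for the prescribed
  underscore) occurs in real reports; the parser accepts both separators
  and canonicalizes to `_`.
* **Frameshift offsets.** Two frameshifts at the same start with different
  `fs*N` termination offsets are kept distinct. Collapsing them would
  silently merge variants whose downstream consequence differs; an
  organizer can still reconcile them manually. Frameshifts lacking an
  offset only match other offset-free renderings.
* **Matching precedence.** Protein-level identity is primary. When either
  side of a comparison fails to parse, matching falls back to the genomic
  tuple (chromosome, 1-based position, plus ref/obs nucleotides when both
  sides carry them); the two levels are never mixed, so a parseable
  protein report is never rescued by a coincidentally equal coordinate.
  Characterized design variants carry no ref/obs nucleotides, so the
  fallback against them compares chromosome and position.
* **No DNA-level normalization.** `c.` syntax, intronic positions, and
  3'-rule shifting require a reference sequence the package does not
  bundle; they are out of scope.

## Truth-set classification

Per benchmark, each candidate variant (the union of vendor-characterized
variants and everything reported) is classified per sample:

* **evaluative** — validated under the benchmark's policy (ddPCR and/or
  WES; hematological rounds may accept ddPCR only), inside the regions of
  interest, and reported by at least `consensus_threshold(N, 2/3)`
  participants. The threshold is the smallest integer `k` with
  `k/N ≥ 2/3` — 8/12, 11/16, 10/15 — computed as
  `ceiling(2N/3 − 1e−9)` so exact rationals are stable under floating
  point.
* **informative** — inside the regions of interest and reported by at
  least one participant, but unvalidated or below consensus. Note the
  asymmetry: an *unvalidated* extra reported by nearly everyone is still
  only informative, because post hoc validation of every extra call is
  economically impractical, while a validated variant below consensus is
  informative because the cohort could not corroborate it.
* **not assessed** — outside the regions of interest, lacking a genomic
  position (a protein-only report cannot be checked against interval
  regions; the package warns), or reported by nobody.

The consensus denominator is always the full enrolled cohort, not the
subset whose panel covers the region — consistent with the uniform
denominators of the published result tables.

## Assessability: cassette incompatibility masking

Variants engineered into cell lines via a ~2 kb insertion cassette break
amplicon enrichment whenever a panel's primers flank the cassette: the
amplicon becomes ~2 kb longer than designed and fails. An observation is
masked iff the participant's panel is amplicon-based and some panel
interval **contains the variant position and strictly spans both cassette
boundaries**; partial overlap leaves the observation assessable (a primer
inside the cassette footprint yields a normal-length product on the
insert-free allele context), and probe-based enrichment is never masked.
Masked observations leave every denominator and are reported as
`cassette_incompatibility`, never as laboratory failures.

## Detection scoring

A participant correctly identifies an evaluative variant when it appears
in **at least one valid replicate**. Replicates explicitly invalidated by
a quality-control status are removed from denominators — a laboratory that
reported a variant in 2 of its 2 valid replicates has no repeatability
issue, while 2 of 3 valid replicates does. Absence of any row for a
replicate is *not* the same thing: nothing reported counts against
repeatability.

False negatives (zero replicates) are classified by a cascade:
masked → curated operator-error flag → expected AF below the laboratory's
LOD → expected AF within `near_factor` (default 1.5) times the LOD →
curated VUS flag → undetermined. The near-LOD factor is a package
parameter: the underlying judgment ("close to the LOD") was qualitative,
and 1.5 reproduces the published assignments (5.12% against a 5% LOD is
near; 11.1% is not). Curated flags stand in for manual read-level (BAM)
review, which is outside the package's scope.

## Allele-frequency statistics

Per evaluative variant: each reporting participant's **MRAF** is the
median over its valid replicates; the consensus **MAF** is the median of
participant MRAFs after outlier trimming; **SD** is the sample standard
deviation (n−1) of the retained MRAFs; each reporter's
**Z = (MRAF − MAF)/SD**, cited when |Z| > 3.0.

* **Grubbs trimming.** Iterative two-sided Grubbs at α = 0.05: while the
  most extreme value's `G = max|x−x̄|/s` exceeds the t-based critical
  value and at least 3 values remain, remove it and repeat. The test names
  only the procedure's family; the two-sided variant, the one-at-a-time
  iteration, α = 0.05 and the n ≥ 3 floor are package defaults, chosen as
  the textbook configuration.
* **SD after trimming.** The spread is computed on the retained values
  (computing it before trimming would let a single outlier inflate the
  very scale used to judge everyone else).
* **Removed participants still get a Z** against the trimmed MAF/SD —
  they are exactly the laboratories the citation mechanism exists to
  flag — and they remain in the allocation denominator.
* **MAF is a median of medians** (per-participant MRAFs), not a pooled
  median of all replicate values, so each laboratory contributes equally
  regardless of replicate count.
* **Degenerate spread.** When SD = 0, a reporter equal to the consensus
  receives Z = 0; any other reporter cannot be scored and is left
  unallocated. A single reporter never receives a Z (no distribution to
  compare against).
* **Peer groups.** In panel-stratified mode, MAF/SD and Z are computed
  within groups of participants sharing a panel, and groups with fewer
  than 6 reporters receive no Z at all — small-group Z-scores are
  dominated by the reporter's own contribution to the consensus.
* Percent values stay on the 0–100 scale throughout.

Shapiro–Wilk p-values are attached per variant for reporting only;
constant or n < 3 inputs yield `NA` rather than a spurious verdict.

## Packaged fixtures

Three historical benchmarks are packaged as fixtures
(`table3_fixture()`, `fixture_results()`) reconstructed from their
published marginals: per-variant success counts, Z-citation numerators and
allocation denominators, consensus MAF/SD values, the stratified
participant table, the masking narrative and the false-negative cause
tally. Laboratory identities are anonymous in the source, so the fixtures
fix one deterministic assignment of misses, masked observations and
repeatability gaps to labeled laboratories that preserves every published
marginal simultaneously; aggregate results are invariant to that choice.
The fixtures carry the published consensus statistics rather than
recomputing them — the underlying per-replicate frequencies were never
published.

## The synthetic cohort generator

`generate_design()` / `lab_profiles()` / `generate_submissions()` emulate
the study conditions: 16 laboratories, 4 samples, 3 replicates, expected
allele frequencies uniform on 5–50%, reporting LODs drawn from 1–10% AF
and 100–1000 reads, per-laboratory AF noise SD drawn from 0.4–3 percentage
points (the spread observed across evaluative variants), the six HGVS
dialects, and optional cassette-bearing variants (2 kb footprint centered
on the variant). Mechanisms, applied per replicate: panel incompatibility
(deterministic), LOD censoring of the noisy AF, Bernoulli misses,
whole-replicate QC dropout (emitted as invalid statuses), Gaussian AF
noise truncated to [0, 100], and a per-laboratory systematic AF bias for
planting Z-score outliers.

The planted ledger labels every miss with its intended cause using the
same cascade as the evaluator (cassette, then deterministic LOD censoring,
then near-LOD/undetermined for realized random misses, with VUS policy in
cascade position), which makes "parameter recovery" well defined: with
noise, misses and dropout disabled the pipeline must recover the ledger
exactly, and the test suite verifies that it does.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: FFPE artifacts, tumor heterogeneity, coverage
non-uniformity, alignment- or caller-specific error modes, clerical
transcription errors, and reporting-format chaos beyond the six HGVS
dialects. The generator validates the *scoring pipeline*, not NGS assays.

## Numerical and reproducibility choices

* Display percentages are rounded half-up to 2 decimals (`round_half_up`),
  so 97.625 prints as 97.63; published tables that printed a coarser
  "17%" for 1/6 are rendered as 16.67%.
* All randomness flows through explicit integer seeds via
  `withr::with_seed`; identical inputs and seeds give byte-identical
  designs, submissions and rendered reports (report files contain no
  timestamps).
* Anonymization codes are keyed 32-bit FNV-1a hashes truncated to 6
  base-36 characters, re-salted on collision, stable per seed.
* Genomic positions are 1-based in designs and submissions (VCF
  convention); all interval tables are 0-based half-open (BED convention);
  conversion is localized in the interval-membership check.

The test suite and the acceptance script keep simulation sizes modest by
design: statistics oracles run on 1,000 random samples of n ≤ 10,
nomenclature fuzzing on 10,000 generated variants, and the Z-outlier power
check on 200 simulated rounds of a 16-laboratory, 2-variant cohort — the
16-laboratory size matching the solid-tumor cohort. Power to cite a
planted outlier depends on cohort size through both the SD estimate and
the Grubbs removal step; at 16 laboratories a 5-SD mean shift is cited in
well over 95% of rounds, which the acceptance suite asserts.

## Known limitations

* Protein-only reports (no genomic coordinates) cannot be checked against
  regions of interest; the package warns and treats them as outside.
* The false-negative cascade depends on curated flags for operator errors
  and VUS policies; absent curation those cases fall through to
  `undetermined`.
* Informative-variant statistics are untrimmed (median/SD of reporter
  MRAFs): these variants are unscored, so outlier handling is not applied.
* No DNA-level (`c.`) normalization and no wild-type/negative-target
  scoring; false positives are listed descriptively, never scored.
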