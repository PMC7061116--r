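---
title: "Methods: five-tier variant classification for familial bradycardia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: five-tier variant classification for familial bradycardia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bradyvar)
```

## The classification procedure

A variant's evidence is a subset of the 28 ACMG/AMP criteria
(`evidence_codes()`), each asserted at most once. Because every criterion
belongs to one strength category determined by its prefix (PVS, PS, PM,
PP, BA, BS, BP), classification factors through the per-category count
vector; the admissible space is the product of category ranges, 2 × 5 × 7
× 6 × 2 × 5 × 8 = 33,600 vectors (`enumerate_count_vectors()`).

The combination table is encoded as per-line conjunctions of minimum
counts. We read every printed operand as a minimum ("at least"): for
example the likely-pathogenic line "1 PS + 1–2 PM" is encoded PS ≥ 1 and
PM ≥ 1, because the case PM ≥ 3 is already captured by the pathogenic line
"1 PS + ≥3 PM" which is evaluated first. This is the standard reading used
by automated implementations of the framework, and it is the reading under
which more pathogenic evidence can never demote a classification — a
property the test suite asserts over the whole benign-free space. Under an
"exactly" reading, adding a moderate criterion to a likely-pathogenic
profile could drop it out of every line, which no user of the framework
intends.

The engine evaluates the pathogenic side (any pathogenic line, else any
likely-pathogenic line) and the benign side (any benign line, else any
likely-benign line) independently. Three outcomes follow:

* exactly one side matches: that side's tier is returned;
* both sides match: the evidence is contradictory and the result is
  uncertain significance with `via_contradiction = TRUE`;
* neither matches: uncertain significance without the contradiction flag.

We define "contradictory" at the level of matched combination lines, not
the mere presence of codes on both sides: a single strong pathogenic
criterion alongside BA1 classifies benign, because one strong criterion
alone matches no pathogenic-side line. This is the minimal operational
reading of the contradiction clause; a code-presence reading would send
every profile containing, say, PM2 and BP4 to uncertain significance and
would make the likely-benign line `1 BS + 1 BP` unreachable whenever any
pathogenic code is present. The choice matters only for profiles whose
pathogenic codes fall short of every combination line.

Within a tier, lines are disjunctive, so their order is irrelevant to the
tier; `explain_profile()` reports every line with a matched flag so that
rule-by-rule provenance does not depend on evaluation order either.

## Rule dialects

Two dialects are built in and selectable everywhere a classification is
made (`rule_dialect()`):

* **`paper_verbatim`** (default) — the combination table exactly as
  printed in the bradycardia reclassification study. It contains a
  likely-pathogenic line satisfied by three supporting criteria alone
  (≥3 PP) and lacks the pathogenic line "1 PVS1 + 1 PM + 1 PP".
* **`acmg2015`** — the 2015 guideline combinations: ≥3 PM instead of the
  supporting-only line, plus the "PVS1 + 1 PM + 1 PP" pathogenic line.

The package reproduces the study, hence the default; no intent is guessed
about whether the printed deviation was deliberate. Enumeration shows the
dialects disagree on 963 of the 33,600 vectors, exactly those reachable by
the differing lines; the test suite pins this.

## Evidence assignment and its thresholds

`assign_codes()` maps an annotation bundle to codes. The two numeric
tunables are allele-frequency thresholds, both strict inequalities:

| threshold | default | rule |
|---|---|---|
| `pm2_max_af` | 0.001 | PM2 fires for AF strictly below (or AF absent) |
| `ba1_min_af` | 0.005 | BA1 fires for AF strictly above ("> 0.5 %") |

A variant at exactly 0.001 or 0.005 triggers neither code; boundary tests
assert this. An absent allele frequency is treated as "absent from large
population studies" and yields PM2 — the curated frameshift/splice records
show a dash in the population-frequency column yet were evaluated, which
forces this reading.

Gene-level knowledge is configuration, not annotation: PVS1 requires
`lof_mechanism = TRUE` for the gene and PP2 requires
`missense_constrained = TRUE`; both default to off, so the engine
withholds these codes for unconfigured genes rather than guess mechanism.
Criteria requiring external evidence the bundle cannot carry (PS1, PS4,
PM3, PM5, PP4, PP5, BS1, BP1–BP3, BP5–BP7) enter only through
`manual_codes`, which are additive, never revoked, and never
double-counted against automatic assignments. BS1 in particular is
manual-only because no disorder-specific frequency expectation is stated
anywhere in the curated material; inventing one would be a silent modeling
decision.

Splice records carried only as HGVS strings are classed
`canonical_splice` when the intronic offset is ±1/±2 and
`other_splice_region` otherwise (`splice_consequence()`); legacy IVS
notation without a parseable offset conservatively maps to the non-null
class, so PVS1 is never granted on an unparsed description.

## The curated dataset

The fixture transcribes the study's four variant tables row for row: 73
SNVs with five-tier verdicts, 16 frameshift records, 1 large deletion and
9 splicing records — 99 records. Each printed row is one record, so a
variant reported by two studies is two records; this row-as-record
convention is the only one under which the published total of 99 is
reproduced. Gene symbols are normalized (`NKX2.5` → `NKX2-5`, `TGF beta 1`
→ `TGFB1`, printed forms retained), which is what yields the published
count of 34 distinct genes. Irregular source rows (a frameshift record
with a malformed HGVS, rows lacking loci or verdicts) are transcribed
verbatim with absent fields and no correction. The file is plain TSV with
a SHA-256 sidecar verified at load; positions are 1-based GRCh38, and the
VCF 4.2 exporter keeps them 1-based per the standard.

The SNV-table verdicts were produced by an external automated
implementation of the framework whose per-variant evidence profiles were
never published; they are therefore carried as data and are **not**
recomputed. Engine correctness is instead established by exhaustive
enumeration against an independent oracle. Per-gene prioritization
consumes printed verdicts for the fixture and computed verdicts for user
cohorts (`verdict_source`).

Three genes named in the study's phenotype prose (GJA5, GNB5, DSP) appear
in none of its variant tables and are absent from the fixture. The prose
also lists 15 genes as reevaluated to uncertain significance while the
SNV table prints two of them (DSG2, LDB3) on the benign side;
`reclassified_to_vus()` follows the table, so those two are excluded.

## Prioritization conventions

Per-gene summaries take the strongest tier among a gene's records on the
order benign < likely benign < uncertain < likely pathogenic < pathogenic.
Slashed verdicts rank by their stronger side — "Pathogenic/likely
pathogenic" counts as at-least-likely-pathogenic, which is forced by the
published 13-gene list (it contains three genes whose only strong verdicts
are slashed); "Benign/likely benign" ranks benign. "Conflicting
interpretations of pathogenicity" and records published without a verdict
rank as uncertain significance — the conservative choice, consistent with
the absence of those genes from the published panel. A gene is
high-priority iff its best tier is at least likely pathogenic. The 13-gene
list is unchanged when the non-SNV tables are excluded (their
pathogenic-side genes already appear in the SNV table); a test runs both
ways.

Phenotype tokens aggregate per gene into five categories (conduction
disease; other arrhythmia; cardiomyopathy/myopathy; nervous system;
other). Tokens the study's groupings do not place — heart failure, ASD,
congenital cardiovascular disease, atrial dilatation, FSGS — map to
`other`; Timothy syndrome is grouped with the arrhythmias. Unknown tokens
map to `other` with a message rather than an error, so a new cohort never
fails on vocabulary.

## The synthetic cohort generator

`gen_cohort()` emulates the evidence structure the pipeline assumes, not
population genetics: no linkage, no sequence, no coalescent. Planted genes
are loss-of-function-mechanism genes whose variants are null variants
absent from population databases — PVS1 + PM2 by construction, which
already reaches likely pathogenic — with functional support (probability
0.5), confirmed de novo status (0.3), segregation (0.7) and deleterious
predictions (0.8) layered on top. Non-planted variants are common
(benign via BA1, probability 0.5) or rare with no further evidence (PM2
only, hence uncertain); with probability `noise_rate` a non-planted
variant instead draws confirmed de novo plus supporting functional
evidence — two strong criteria, a guaranteed false pathogenic call at the
gene level. Rare allele frequencies are log-uniform on [10⁻⁶, 5 × 10⁻⁴]
and common ones uniform on [0.01, 0.5], so both classification thresholds
are straddled with margin and boundary behaviour is left to the explicit
boundary tests. At zero noise, recovery of planted genes by
`high_priority_genes()` is exact by construction; the suite asserts
sensitivity and specificity 1.0 over twenty seeds, and a non-strict
decline of specificity as noise rises.

Every draw is scoped to the spec's single seed via a local RNG state, so
cohorts are reproducible and generation never perturbs the caller's
random state. The ground-truth `true_tier` is recorded at generation time
as the tier implied by the drawn annotations.

What passing these tests shows — and does not show: the pipeline
correctly recovers genes whose variants carry textbook-clean evidence
profiles, and degrades as contradictory noise is injected. Real cohorts
have correlated annotations, uncertain parentage, incomplete segregation
data and frequency estimates with sampling error, none of which the
generator models; recovery rates on synthetic cohorts are a correctness
check, not a performance claim.

## Problem sizes and numerical choices

The engine's exhaustive checks run over all 33,600 count vectors in both
dialects; recovery checks use cohorts of 40 variants over 5 genes (2
planted) across 20 seeds, and the noise trend uses 60 variants over 10
genes across 8 seeds per noise level — sizes at which every property is
checked exactly, in seconds, with no sampling compromise. All
classification logic is integer comparison, so there are no tolerances
anywhere in the engine; the only numeric boundaries in the package are
the two allele-frequency thresholds, both strict. Ties cannot occur:
combination lines within a tier are disjunctive and the tier order is
total.

## Known limitations

* Per-variant verdicts of the curated SNV table cannot be independently
  recomputed (evidence profiles unpublished); they are data.
* No Bayesian or points-based refinement of the framework, no
  strength-modulated criteria (e.g. PS toward PM), and no gene-specific
  rule specifications.
* No transcript-aware HGVS validation and no coordinate liftover; HGVS
  strings are carried as printed.
* The annotation vocabulary is deliberately small; consequence classes
  outside it must be mapped by the user (`other` withholds all
  consequence-driven codes).
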