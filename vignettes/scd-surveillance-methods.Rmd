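---
title: "Methods: multi-source SCD surveillance linkage and case classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-source SCD surveillance linkage and case classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdlink)
```

## The surveillance problem

Sickle cell disease (SCD) is a genetic disorder diagnosed by newborn
screening in the United States, but screening programs only reach in-state
births since each program started, clinical registries only see patients who
reach a participating clinic, and administrative claims only see persons with
billed encounters. State surveillance programs therefore link five systems —
newborn screening (NBS), clinic case reports, Medicaid/CHIP claims,
hospital/emergency-department discharges, and death certificates — into one
deduplicated person index, and classify each indexed person against a
three-tier case definition. `scdlink` implements that pipeline; because the
real inputs are protected health records, it ships a seeded synthetic-data
generator so that every stage can be validated against known ground truth.

## Diagnosis-code classification

The code module classifies normalized ICD-9-CM/ICD-10-CM codes into `SCD`,
`TRAIT`, or `OTHER`. The ICD-9-CM SCD set is the nine literal codes
282.41, 282.42, 282.6, 282.61–282.64, 282.68, 282.69, with 282.5 as trait.
The ICD-10-CM set is the D57 family: the bare `D57` plus the wildcard
families `D57.0`, `D57.1`, `D57.2`, `D57.4`, `D57.8` (a family matches any
suffix, including none — standard ICD-10-CM family notation), with the
`D57.3` family as trait. Two deliberate choices:

* **Trait precedence.** `D57.3x` is checked after (and overrides) the bare
  `D57` prefix, so `D57.31` is trait even though it extends `D57`. This also
  covers trait subcodes introduced after the code lists were first compiled —
  the prefix rule is forward-compatible by construction.
* **Fail loudly.** Unknown code systems and syntactically invalid codes raise
  classed errors naming the offending value rather than silently mapping to
  `OTHER`; schema drift in an upstream extract should stop a run, not bias
  it.

Claims extracts often omit the decimal point; `normalize_icd()` inserts it
after three digits (ICD-9-CM) or three characters (ICD-10-CM). The code sets
ship as a plain-text table (`inst/extdata/icd_scd_codes.tsv`) so a program
can extend them through configuration.

## The synthetic-data generator

`generator_config()` parameterizes a ground-truth population and the five
derived source extracts. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `n_population` | 5,000 | large enough for stable rates, small enough for fast simulation |
| `scd_prevalence` | 0.02 | gives ~100 cases per run at the default size |
| `genotype_props` | 0.63 / 0.08 / 0.27 / 0.02 | the published genotype mix among confirmed cases (sickle cell anemia / HbS-β⁺ / HbSC / other) |
| `period` | 2004–2018 | the 15-year retrospective window the surveillance programs report |
| `source_coverage` | NBS .95, clinic .50, Medicaid .65, hospital .70, death 1.0 | per-source capture in the published tables spans roughly 16–87%; these sit in that range with clinic reporting deliberately partial |
| `encounter_rate` | 2.0 /person-year | several billed encounters per year per captured case, so the three-encounter rule is reachable but not automatic |
| `miscode_rate` | 0.004 | a small stream of non-cases with stray trait (and, at `miscode_scd_share = 0.25`, true SCD) codes, populating the possible tier with mostly non-cases — the situation that motivates excluding possible cases from reports |
| `migration_rates` | in .01 / out .015 per year | annual, memoryless; a person out of state in a year emits nothing dated that year |
| `corruption_rates` | see `default_corruption_rates()` | SSN missing 15% (claims systems often cannot share it), name typos 3–5%, date-of-birth day/month transposition 2%, surname substitution 2% |

Birth dates are uniform over the 68 years ending at the period close, giving
roughly a quarter of the population aged 0–18 — the order of the published
pediatric shares. Sex is drawn 50/50 in truth; the published female excess
among probable cases is a health-care-use artifact the generator does not
model. Deaths use a flat annual hazard (1.2% cases, 0.4% non-cases) within
the period only; everyone is alive at the period start. Duplicate billing
(`dup_billing_rate = 0.1`) emits the same Medicaid encounter into the
hospital file on the same date, exercising the distinct-date rule.

What the generator does **not** emulate: realistic geography, race/ethnicity,
correlated identifier errors (e.g. a twin sharing a surname and birth date),
household structure, out-of-state care, or coding-practice drift over time.
Passing tests therefore show the pipeline is correct *under this noise
model*, not that real-world linkage would achieve the same quality.

`noiseless_config()` is the analytic limit — no corruption, full coverage, no
miscoding, no migration, all confirmations on file — in which the pipeline
must recover the truth exactly; the test suite asserts this at 5,000 persons.

## Record linkage

Candidate pairs come from blocking: the union of pairs sharing
(Soundex(surname), birth year) or the full SSN. Blocking is mandatory above
trivial sizes (an `all_pairs` escape hatch exists for oracle tests, guarded
at 10,000 pairs). Fields are then compared: names agree when their
Jaro–Winkler similarity reaches `name_similarity_cutoff` (default 0.85 —
`"SMITH"`/`"SMYTH"` at 0.893 survives the generator's typo model; raising the
cutoff to 0.95 splits them); date of birth, SSN, sex and ZIP require exact
equality after normalization; a field is `MISSING` when either record lacks
it. Jaro–Winkler and Soundex are implemented in-package and tested against an
independent reference implementation plus standard published values.

Pair scoring follows the Fellegi–Sunter model: weight
`Σ log2(m/u)` over agreements plus `Σ log2((1−m)/(1−u))` over disagreements,
0 for missing. The default m/u values are chosen from the generator's error
rates and field cardinalities (e.g. SSN agreement is worth ~13 bits, sex
agreement ~1) rather than estimated: EM estimation is deliberately out of
scope to keep the engine deterministic and auditable. Decisions:

1. **Deterministic cascade first** — exact SSN + date of birth, or exact
   first + last + date of birth + sex, is a match regardless of weight.
2. Otherwise match at `weight ≥ upper_threshold` (default 12, boundary
   inclusive), non-match below `lower_threshold` (default 6), review in
   between.
3. Reviews resolve by policy; the default `AS_NONMATCH` replaces clerical
   review conservatively (surveillance practice favors precision in
   auto-linking). `SECOND_RULE` offers a softer resolution (date of birth
   plus one name).

Clusters are connected components of the match graph (via igraph), so
linkage is transitive; singletons are allowed. Every compared pair is logged
(pattern, weight, rule, status) for audit.

## The master index

The pipeline order is fixed: (1) each source file is cleaned — records with
missing/duplicate ids, missing or out-of-period dates, or no usable
identifiers are quarantined with a reason, never dropped — and deduplicated
with the linkage engine; (2) NBS and clinic entities (the sources that can
carry laboratory confirmation) are cross-linked into a provisional confirmed
index; (3) Medicaid and hospital entities with at least one sickle-coded
(SCD *or* trait) encounter are cross-linked into an administrative index —
trait-coded persons must enter so the possible tier can exist; (4) the two
indices merge on cross-stratum matches only, leaving unmatched administrative
persons for classification and retaining unmatched confirmed persons; (5)
death records attach last: a matched death sets the person's death date, an
unmatched death is logged — a person found only in death records never enters
the index, since death certificates are supplementary, not case-finding.
Demographics resolve per field from the highest-priority source holding a
value (NBS > clinic > Medicaid > hospital/ED > death), with the modal value
within a source, lexicographic tie-break for determinism, and a logged
discrepancy when screening and clinic genotypes conflict.

Person identifiers are deterministic (ordered by each cluster's smallest
member record id), so a rerun on the same inputs is byte-identical, and
adding a later tranche of records can merge but never split an indexed
person — the suite tests this with two-stage runs.

## Case classification

Evidence per person: confirmation flags from NBS/clinic records, and the
distinct encounter dates across the pooled claims sources carrying SCD
(non-trait) codes versus trait-only codes. A date in both claims systems
counts once; a date with both trait and SCD codes is an SCD date. Tiers, in
strict precedence:

* **CONFIRMED** — screening result with confirmatory testing, or clinical
  diagnosis with documented confirmatory laboratory testing.
* **PROBABLE** — unconfirmed screening result, clinical diagnosis without
  documented confirmation, or ≥3 SCD-coded encounter dates with some triple
  spanning ≤1,826 days.
* **POSSIBLE** — one or two sickle-coded (SCD or trait) encounter dates.
* **NONE** otherwise.

Boundary decisions made here, where the definition text is open:

* The "5-year period" is a **rolling window of 1,826 days** (5 × 365.25,
  rounded down), inclusive at the boundary — the stricter, order-free
  reading; a calendar-anchored window would let the same dates pass or fail
  depending on alignment.
* "Separate encounters" means **distinct service dates after cross-source
  pooling**; duplicate billing of one event must not count twice.
* Persons with ≥3 SCD dates but **no qualifying triple** fall to POSSIBLE:
  they literally exceed "one or two encounters", but the probable tier
  explicitly requires the window, and possible is the natural holding tier.
* **Trait-only persons with ≥3 trait dates are POSSIBLE**, not NONE. A
  literal reading of the tier text leaves them unclassified, but that would
  make classification non-monotone (a person with two trait dates would be
  *downgraded* by a third); the trait ceiling — trait-only evidence can never
  exceed POSSIBLE — is the invariant that matters, and monotone upgrade
  (NONE → POSSIBLE → PROBABLE → CONFIRMED as evidence accrues) is
  property-tested.
* ICD system is taken from each record's declared system with no hard 2015
  cutover date imposed by the classifier.

## Prevalence reports

A person counts in a source row iff at least one linked record of that source
is dated in-period; only confirmed and probable persons are reported, each
once in the deduplicated row. Percentages are `100 × total / deduplicated
total`, **rounded half-up to one decimal** (the convention of the published
tables; IEEE round-half-even would disagree on exact halves). Person-years
count calendar years with source evidence (Medicaid: positive enrollment
months also qualify). The annual cohort for year *Y* applies the migration
adjustment: in-year evidence, or evidence strictly before *and* after *Y*;
persons known dead before January 1 of *Y* are excluded regardless of stray
later claims (the definition text does not state death handling; exclusion is
the conservative, testable choice). The adjustment can be switched off per
report. Strata use genotype among confirmed cases with a known result, an
unknown-genotype column counting probable cases plus confirmed cases without
a result, and a pediatric stratum of ages 0–18 **inclusive** at mid-year
(July 1), since no reference date is stated.

Truth-based evaluation computes the standard 2×2 metrics of
confirmed∪probable against true status among true persons with at least one
source record, and pairwise linkage precision/recall/F1 from the index-person
× true-person contingency (no pair enumeration).

## Numerical and degenerate-input conventions

Weights are exact floating-point sums of log2 terms and are tested against a
term-by-term oracle at 1e-12. Threshold comparison is `≥` at the upper bound.
An all-missing comparison has weight 0. Empty sources, zero populations, and
zero-case populations flow through every stage and produce empty outputs
with headers. Rounding uses a 1e-9 nudge before the floor to guard against
representation error just below a half. All randomness passes through R's
seeded generator; identical config + seed reproduces every output file
byte-for-byte.

## Problem sizes

The test suite and the acceptance script use populations of 150–5,000
persons (about 6,000–8,000 source records at the default settings), five
seeded replicates for stability checks, and 15-year surveillance periods —
sizes chosen so a full validation run completes in about a minute while
keeping binomial/Poisson oracle tolerances tight (3σ bands at these sizes
are a few percent).

## Limitations

The linkage parameters are configured, not learned; real deployments
typically calibrate m/u (or use EM) against clerical review, which this
package deliberately omits. The generator's independence assumptions
(per-field corruption, memoryless migration, flat hazards) make linkage
easier than hard real-world cases such as twins and shared addresses.
Reported metrics are therefore upper bounds on what the same engine would
achieve on real records, and nothing here validates the case definition
itself against clinical truth — only the pipeline's faithfulness to it.
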