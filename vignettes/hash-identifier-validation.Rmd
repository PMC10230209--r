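---
title: "Anonymous hash identifiers for roster deduplication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymous hash identifiers for roster deduplication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uidlink)
```

## The procedure

Service rosters record one row per contact between a person and an
organisation. Deduplication asks how many distinct people a roster
contains; linkage asks how many people two rosters share. Both are
usually answered with a single personal key — here the military service
number — which both under-identifies (distinct people can share a
number) and over-identifies (the number itself is personal data and
cannot travel between organisations).

`uidlink` replaces the raw key with the SHA-256 digest of a canonical
string built from a configured field set, by default gender and service
number joined by `"|"` with an optional secret salt prefix. The digest is
deterministic, fixed-length (64 hex characters) and, for practical
purposes on these input sizes, collision-free, so it deduplicates exactly
as the underlying field combination would while exposing neither field.

Validation treats the gold-standard key as the reference classifier.
Under a chosen convention, the first (or last) record holding each key
value is the *primary* case and the rest are *duplicates*; records are
cross-tabulated by their status under the gold key and under the hash
identifier. With the gold key among the hash inputs, the hash partition
refines the gold partition, so the (gold-primary, hash-duplicate) cell is
structurally zero and sensitivity `a/(a+c)` is structurally 1. The
informative quantity is specificity `d/(b+d)`: each count in cell `b` is
a record whose service number is a gold duplicate but whose
(gender, number) pair is new — a second individual behind a shared
number. The package reports exact Clopper–Pearson intervals for both
proportions, the uncorrected Pearson chi-square on the 2×2 table, and the
single-threshold ROC AUC, which for one operating point is identically
`(sensitivity + specificity)/2` and is always labelled with that formula.

Linkage collapses each roster to one record per uid, then counts the
intersection of the two uid sets. Collapsing first makes the operation
total — duplicated contacts can never inflate the match count — while
`strict = TRUE` restores the hard one-to-one semantics that errors on
duplicate keys.

## Assumptions

* The key fields, after normalization, are stable attributes of a person.
  A person recorded as `M` in one roster and `F` in another, or a
  transcribed digit in the service number, yields two different uids;
  the method has no fuzzy matching by design.
* Two genuinely different people with the same gender *and* the same
  service number are indistinguishable to this identifier. The two-field
  uid resolves only cross-gender collisions; same-gender collisions are a
  documented blind spot (the generator has a knob to plant them when one
  wants to demonstrate it), and the remedy is widening the field set.
* An unsalted digest of a small identifier space can be reversed by
  enumerating inputs. The salt default is empty so examples are
  reproducible; deployments that publish uids must set a secret salt.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fields` | `gender`, `service_number` | ordered field set hashed into the uid |
| `delimiter` | `"|"` | separator making the concatenation unambiguous; forbidden inside field values (hard error naming the record) |
| `salt` | `""` | secret prefix; changes every uid |
| `pattern` | `^[A-Z0-9]+$` | anchored format check applied after canonicalization; stricter presets in `sn_patterns` |
| `strict` | `FALSE` | whether invalid (not missing) key values exclude a record or only warn |
| `convention` | `"first"` | which holder of a key value is primary; counts are provably invariant to it |
| `conf_level` | 0.95 | binomial interval level |
| `ci_method` | Clopper–Pearson | `"wilson"` available for comparison |

Records missing either key field are always deleted (listwise), each with
a single audit reason — the first failing rule, gender checked before
service number — so the exclusion log partitions the input exactly.

## Numerical and reporting choices

* **Exact interval.** The Clopper–Pearson bounds are computed through the
  beta-quantile closed form, with the boundary cases `x = n` and `x = 0`
  as closed forms. The exact method is the default because it reproduces
  the reference bounds that the Wilson score interval does not (at
  316/326 Wilson's upper bound is 98.3% against the exact 98.5%); Wilson
  remains available behind `ci_method`.
* **Chi-square.** The 2×2 statistic uses the closed form
  `n(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` with no continuity correction and a
  1-df reference distribution; the tests verify it against the
  expected-count formulation `Σ(O−E)²/E` to a relative 1e-9.
* **Degenerate tables.** An empty margin (for instance, a roster with no
  duplicates, or an empty roster after cleaning) leaves the affected
  statistics `NA` and flagged as undefined — never silently 0 — and the
  CLI exits with a status distinct from success.
* **Rounding.** Point estimates are formatted as percentages at one
  decimal, chi-square at three decimals, both with round-half-up (base
  `round()` ties to even, which would mis-render boundary values);
  rounding happens only at formatting, never in computation.
* **Ties.** Primary-case selection cannot tie: row order is a total
  order, and both conventions produce identical cross-tab counts because
  each cell is a function of the record count and the two group counts
  alone.
* **Encoding.** Hash inputs are encoded as UTF-8 bytes before digesting
  and digests are rendered lowercase, so uids are byte-identical across
  platforms and runs.

## The synthetic generator

Real rosters of this kind are confidential, so the package ships a
generator that emulates their statistical structure: latent persons with
unique service numbers (two letters + six digits by default,
format-compatible with the preprocessing presets); a configurable number
of planted person pairs sharing one number with discordant gender;
contacts per person with a geometric-tailed distribution (every person
appears at least once; the remaining contacts are allocated
multinomially with exponential person weights, a Poisson–exponential
mixture whose marginal is geometric — a few heavy service users, many
single contacts); reversible formatting noise (case folding, padding,
spelled-out gender, internal whitespace) that normalization undoes
exactly; and missingness applied after noise. Defaults describe a
mid-sized charity year — 2,306 persons, 2,622 contacts, 10 collision
pairs, 90% male, 2% missingness per key field, 5% noise — chosen once as
a realistic operating point for this population.

Every simulated roster carries per-record truth (person identity,
canonical field values, planted missing/noise flags), and
`oracle_statistics()` recomputes the expected cross-tabulation by brute
force on the truth fields, independently of the pipeline's normalization
and hashing code paths. `margins_config()` inverts the three published
cross-tabulations: given a table's record count and its two group counts,
it plants exactly the collisions that reproduce all four cells, so every
derived statistic follows to full precision.

What the generator does **not** emulate: irrecoverable data-entry errors
(typos that change the canonical value), same-gender collisions (off by
default), longitudinal drift in a person's attributes, and any
distributional realism in the auxiliary columns (which no computation
reads). Passing tests therefore demonstrate correctness of the pipeline's
logic and statistics under the stated structure, not robustness of the
identifier to dirty real-world keys — the method itself offers none
beyond format normalization, and says so.

## Problem sizes in the test suite

The suite validates the three published table shapes at their real sizes
(2,622, 2,513 and 26,684 records), property checks on 200 random rosters
of 20–100 records, oracle-equivalence sweeps over 50 seeds, exhaustive
digest-uniqueness over a 20,000-point input space, and parameter-recovery
runs with 0–50 planted collisions; the whole suite completes in well
under a minute on one core.

## Known limitations

* Exact-equality matching only: no probabilistic (Fellegi–Sunter)
  linkage, phonetic encodings, or imputation of missing key fields.
* The identifier's discriminating power is bounded by its field set; with
  two fields, specificity improvements come only from cross-gender
  collisions.
* The AUC is the one-point trapezoid, reported with its formula; it is
  not comparable to AUCs computed from a continuous score.
* Uid uniqueness is cryptographic, not logical: two distinct field
  combinations colliding under SHA-256 is possible in principle and
  ignored as negligible at roster scale.
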