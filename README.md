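# uidlink

Privacy-preserving deduplication and linkage of health and welfare service
rosters via hash-based anonymous unique identifiers.

## The problem

Organisations that support the same population — here, UK military
charities supporting veterans — each keep their own roster of service
contacts, typically keyed by a single personal identifier (the military
service number). That key has two failure modes: distinct individuals can
share a number, so single-key deduplication under-counts unique people;
and the number itself is identifying, so it cannot be carried between
organisations to link their records.

`uidlink` derives an anonymous unique identifier as the SHA-256 digest of
a small canonical field set — by default gender `g` and service number
`s`, optionally salted with a secret `k`:

```
uid = SHA256( k | g | s )
```

Equal inputs give equal digests, so the uid deduplicates exactly like the
underlying fields while revealing neither. Because the uid is a function
of a field set that *contains* the gold-standard key, the uid grouping
refines (splits, never merges) the gold-key grouping: a record that is
the first holder of its service number is necessarily the first holder of
its (gender, number) pair. Validation against the gold standard is a 2×2
cross-tabulation of primary/duplicate status under each key:

|                | gold primary | gold duplicate |
|----------------|--------------|----------------|
| uid primary    | a            | b              |
| uid duplicate  | c = 0        | d              |

with sensitivity `a/(a+c)` (structurally 100%), specificity `d/(b+d)`,
exact Clopper–Pearson binomial confidence intervals, the uncorrected
Pearson chi-square `n(ad−bc)² / [(a+b)(c+d)(a+c)(b+d)]`, and the
single-threshold ROC AUC `(sensitivity + specificity)/2`. Cell `b`
counts exactly the cross-gender service-number collisions — distinct
individuals the single key conflates and the two-field uid resolves.

Step 2 links two rosters one-to-one: each side is collapsed to one record
per uid and the match count is the size of the uid-set intersection.

A synthetic roster generator (`simulate_roster()`) produces rosters with
latent persons, geometric-tailed repeated contacts, planted cross-gender
collisions, missing key fields and reversible formatting noise, together
with per-record ground truth so every downstream statistic can be checked
against an independent oracle (`oracle_statistics()`).

## Worked example

Validate a roster whose margins match a 2,622-record charity year
(2,296 distinct service numbers, 2,306 distinct gender/number pairs,
i.e. ten planted cross-gender collisions):

```r
library(uidlink)
sim <- simulate_roster(margins_config(n_records = 2622, n_gold = 2296,
                                      n_hash = 2306, seed = 1))
fit <- validate_roster(sim$roster)
fit
#> Hash-identifier validation against gold-standard key
#>   records: 2622 in, 2622 clean (0 excluded)
#>   primaries: 2296 gold, 2306 hash (first-occurrence convention)
#>   sensitivity 100% (95% CI 99.8%-100%)
#>   specificity 96.9% (95% CI 94.4%-98.5%)
#>   chi-square 2530.549, p < 0.001
#>   AUC [(sens + spec)/2] 98.5%
```

Reading the numbers: all 2,296 gold-primary records are uid-primary
(sensitivity 100%, the refinement guarantee); 316 of the 326 gold
duplicates are also uid duplicates (specificity 96.9%), and the 10
uid-primary gold-duplicates are the planted collisions — ten individuals
a service-number key alone would have merged away. `summary(fit)` prints
the cross-tabulation, `coef(fit)` the two proportions, `confint(fit)`
their exact intervals, `plot(fit)` the ROC polyline.

Linkage across two years sharing 1,771 individuals recovers exactly
1,771 matches (`run_linkage()`), and rosters over disjoint populations
match zero records regardless of size.

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "uidlink.R", package = "uidlink"))') \
  validate --input roster.csv --out outdir --gender-col sex --service-col svc
```

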