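---
title: "Processing two-station raptor migration counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing two-station raptor migration counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raptorcount)
```

## The problem

Autumn raptor migration through a coastal bottleneck is monitored from two
hilltop stations that together cover a roughly 12 km transect. Counters log
*records*: a group of one or more birds of identical classification passing
one station, with date, time, a lateral distance zone (W3 … O … E3/E4
relative to the station), and — where the protocol asks for it — age, sex
and morph. Because a record can be a solitary bird, an entire stream, or a
subset of a flock split by age class, record counts carry no flock-size
meaning.

Raw streams of such records are not usable for trend analysis as they are.
Three systematic distortions must be corrected first:

1. **Under-specified identifications.** Some field identifications are only
   trustworthy together with supporting detail. Ringtail-plumaged Montagu's
   and Pallid Harriers are only accepted at species level when aged;
   several large eagles cannot be identified at all without ageing.
2. **Double counts.** The two stations watch overlapping airspace; birds
   passing between them can be recorded twice.
3. **Unidentified birds.** Birds that cannot be identified to species are
   logged under nested morphological groups ("MonPalHen", "Buzzard_SPEC",
   "MediumRaptor", "Raptor_SPEC", …) and must be reallocated to species
   before totals are comparable across days and years.

`raptorcount` implements the full post-processing chain — validation,
double-count removal, proportional reallocation, and standardized
aggregation — plus a synthetic two-station simulator with per-flock ground
truth, so that every stage can be verified end to end without access to any
particular deposited dataset.

## Validation and degradation

`integrity_pass()` runs a registry of documented rules over each record.
Rules are either *warnings* (reported, data untouched) or *degradations*:
the record keeps its individuals but its species code is replaced by a
designated ancestor group (Mon/Pal without age → MonPalHen; Greater
Spotted / Steppe / Imperial Eagle without age → LargeEAGLE). Degradation is
monotone on the identification hierarchy, conserves individuals, and is
idempotent.

Two deliberately open choices:

* Lesser Spotted Eagle records without age are *not* degraded by default.
  For this abundant species, on-station identification is trusted even when
  age did not make it into the record on busy days; the rule is
  configurable.
* Hen Harrier is a MonPalHen pool member but is not subject to the
  age-degradation rule, which names Montagu's and Pallid only.

## Double-count removal

Potential double counts are record pairs from different stations on the
same date that are *taxon-compatible* (equal codes, or one an ancestor
group of the other), lie within a per-size-class time window (±10 min for
small active fliers such as harriers and falcons, ±15 min for large soaring
birds), and whose zone pair falls in the configured overlap set. Overlap
sets are configuration, not geometry: the default treats station 1's
eastern zones and station 2's western zones as shared airspace, with a
narrower band for small species, which are detectable over shorter
distances.

Matching is greedy and chronological: candidates are ordered by time gap,
then time of day, then record id; observer-flagged "double count" records
get priority, and "single count" records are excluded altogether. Each
individual participates in at most one adjustment, a record can absorb
several partners until its number is exhausted, and the matched quantity is
the minimum of the unmatched numbers on the two sides. The *less* detailed
record of a pair is reduced (species level beats group level; then more of
age/sex/morph; then the earlier-entered record wins). Both records receive
a `dcremark` audit entry (`<partner>:+q` on the kept record, `<partner>:-q`
on the reduced one), which simultaneously makes the procedure idempotent:
adjusted records are never re-matched.

The procedure is deliberately conservative — it will occasionally match
records that were in fact distinct birds — so the output estimates the
*minimum* number of individuals passing. The test suite quantifies this on
small instances against an independent maximum-flow oracle (greedy removal
equals the maximum-matching optimum in ≥95 % of random instances and never
exceeds it) and on simulated streams against planted ground truth.

Age-protocol sampling records (`HB_JUV`, `SB_NONJUV`, …; see below) are
never matched: they are samples, not counts, and pairing them with regular
records would subtract real birds.

## Allocating unidentified birds

For every date, `estimate_daily_species_totals()` first sums identified
species records and group records separately (`daily_raw_totals()`), then
processes groups from most specific to most general. A group with $N_g$
birds hands each pool species $s$ the share

$$\hat n_s \mathrel{+}= N_g \cdot \frac{T_s}{\sum_{s' \in \mathrm{pool}(g)} T_{s'}},$$

where $T$ are the *running* totals — already augmented by the more specific
groups processed before. For European Honey-buzzard this means: split
Buzzard_SPEC over the buzzards, then MediumRaptor over buzzards *and*
kites using the updated totals, then Raptor_SPEC over all raptors.
Fractions are never rounded inside the pipeline; rounding happens only in
reports.

The estimator's identifying assumption is exchangeability: within a pool,
the probability that a bird ends up recorded as the group rather than the
species must not depend on the species. Heterogeneous visibility between
pool members (say, one species passing systematically farther out) biases
the split; no uncertainty is propagated onto the allocated fractions.

When a group has birds on a day with a zero identified pool, the default
fallback is the season-wide pool proportion (keeping conservation); `skip`
(report as unallocated) and `equal_split` are selectable. Conservation
holds whenever pools resolve: date-wise, allocated totals sum to identified
plus group individuals. Allocation is monotone for the group's own pool
members; note that a species *outside* a group's pool can legitimately lose
part of a higher group's count when the pool species come to dominate the
higher-level running totals.

Non-raptor groups (Stork_SPEC) are allocated by the same rule; a toggle
excludes them.

## Standardized aggregation

* `select_standardized()` filters on the `filter` column (0 =
  non-standardized, 1 = standardized, 2 = standardized early-morning
  harrier count). Most analyses should use `{1}`; harrier analyses that
  include the early-morning extension use `{1, 2}`.
* `passage_quantile()` is the earliest date whose cumulative season total
  reaches $q$ of the full total — day resolution, no interpolation, which
  matches count data and keeps the statistic monotone in $q$.
* `season_window()` anchors the count season on priority-species
  phenology: by default 3 days before the 1 % quantile of Montagu's Harrier
  to 3 days after the 99 % quantile of Lesser Spotted Eagle.
* `age_proportions()` estimates daily age structure. For the three
  mass-migration species with a dedicated age protocol (European
  Honey-buzzard, Black Kite, Steppe Buzzard) only the protocol codes
  (`HB_JUV`/`HB_NONJUV`, …) are used — regular records of these species are
  not an age sample, and juvenile/non-juvenile is the only distinction the
  protocol supports (second-calendar-year birds are effectively absent or
  indistinguishable, and subadult large eagles are recorded as adult).
  Other species use aged regular records. `age_class_totals()` multiplies
  allocated daily totals by these fractions, falling back to
  individual-weighted season-pooled proportions on days without a sample
  (flagged as such), so class totals always sum to the species total.
* `world_population_percentage()` and `early_morning_addition()` implement
  the report-time arithmetic for population-importance and early-morning
  contribution percentages. All report-time rounding is half-up, so results
  do not depend on floating-point parity at .5 ties.
* The `north` column (reverse movement) is carried through unchanged;
  totals use `number` as stored.

## The simulator

`simulate_season()` generates a full season of records plus a per-flock
truth log. Mechanisms, each switchable:

* **Passage laws.** Per species: a Gaussian passage-date law (peak,
  spread), a unimodal diurnal law within the standardized count day (07:00
  to 17:00 in count-day minutes), an optional early-morning component for
  harriers (06:00–07:00 inside the fixed early-morning date window), and a
  Gaussian lateral-position law across the 12 km corridor (stations at
  km 2.4 and 6.4). Flock sizes are geometric with configurable mean.
* **Detection.** The nearer station records a flock with probability
  `detect_prob` within a per-size-class range; the distance zone follows
  from fixed lateral breakpoints (0.25, 1, 2, 4 km) per station.
* **Duplication.** Flocks whose zone pair lies in the overlap set for
  their size class are recorded by the second station with probability
  `p_dup`.
* **Identification failure.** A bird is recorded as ancestor group $g$
  with probability `uid_rates[g]` scaled by viewing distance — by
  construction independent of the species given the pool, i.e. the
  simulator *meets* the allocation estimator's exchangeability assumption.
  Passing recovery tests therefore validates the implementation, not the
  assumption; real data can violate it.
* **Entry latency.** Recorded times get a uniform jitter bounded by the
  protocol's entry latency (5 min for harriers/falcons/rollers/doves,
  10 min otherwise), which keeps genuine duplicates inside the matching
  windows.
* **Age.** Protocol species are sampled per individual in the inner zones
  (W1–E1) into `*_JUV`/`*_NONJUV` records; other species carry
  record-level age with a per-species ageing probability.

What the simulator does *not* emulate: weather-driven accumulation and
release, geographic flight-path structure, observer-effort variation within
a day, misidentification *between* species (only species-to-group), and
non-exchangeable visibility differences within pools. Recovery results
should be read with those limits in mind.

Three packaged scenarios define the study conditions:

* `default_scenario()` — five species spanning the mechanism space (a
  mass soarer with age protocol, a late soarer, a scarce ringtail, an
  early-morning flier, a large eagle), all noise mechanisms on; used for
  regression-style checks.
* `recovery_scenario()` — identification failure only: one shared tight
  coastal lateral law (so the second station sees nothing and dedup runs
  vacuously), certain detection, 10,000 birds per species. The acceptance
  suite runs 50 seeds and requires every species' mean relative error of
  allocated totals to stay below 2 %.
* `duplication_scenario()` — duplication only: one solitary-flying small
  species, 1,000 flocks of one bird crossing inside the overlap band,
  `p_dup = 0.2`. Planted duplicates are Binomial(N, 0.2); the suite
  requires the removed planted excess (per-flock reductions capped at
  flock size) to sit within 3σ of the expectation. False positives are
  reported as over-removal (the procedure is conservative by design), not
  bounded by this check.

These problem sizes (50 × 10,000 birds per species; 1,000 flocks) are the
package's chosen verification conditions: large enough that binomial noise
sits well below the tolerance being asserted, small enough to run
routinely.

## Numerical and degenerate-input choices

* Quantiles and season windows error on zero-passage species, naming the
  species.
* Allocation with an unresolvable pool (even season-wide) leaves the group
  count unallocated and reports it rather than inventing a split.
* Matching excludes records without time or zone (warned), and reduces
  `north` along with `number` so the reverse-movement count never exceeds
  the record count.
* Ties in matching are broken deterministically (gap, time, id), so runs
  are reproducible; group processing order within one hierarchy depth is
  alphabetical, which only matters for reporting order since same-depth
  pools are disjoint chains.
* Record ids are the audit currency: dcremark entries reference partner
  ids, and a record that reaches zero is dropped from the stream while its
  partner keeps the trail.

## Limitations

* The overlap-zone geometry is configuration with documented defaults, not
  a measured viewshed; site-specific calibration belongs in the YAML
  config.
* The rare-flock screen needs a species list and threshold from the
  protocol owner; the default list is a plausible stand-in.
* Allocated fractions carry no uncertainty; downstream trend models see
  them as data.
* Trend fitting itself is out of scope: the pipeline produces trend-ready
  daily and annual tables only.
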