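---
title: "Assessing EHR data quality for ICHOM heart-failure records"
author: "ichomdq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing EHR data quality for ICHOM heart-failure records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichomdq)
```

## The problem

Hospitals increasingly need to demonstrate the health outcomes they achieve,
and the only scalable source of outcomes evidence is the routine electronic
health record (EHR). The ICHOM heart-failure standard set defines the
outcome variables to collect; whether routinely collected hospital data can
populate them *reliably* is an empirical data-quality question. `ichomdq`
implements a five-dimension assessment — uniqueness, consistency,
completeness, temporal stability and correctness — for a flat,
visit-centered table of 22 ICHOM heart-failure variables (21 selected
standard-set items plus a visit identifier), together with a synthetic
relational-EHR generator and a relational-to-flat mapper, so every check can
be exercised, and its error-recovery behaviour proven, without access to any
private hospital database.

The central scientific point the package encodes is that many apparent data
errors are *manufactured by extraction*, not by clinicians: a warehouse that
links measurements to visits by calendar date will duplicate clinical data
across same-day visits; a target format that only accepts numbers forces
missing heights and weights to be written as `0`; and coded diagnosis data
cannot distinguish "the patient does not have the condition" from "nobody
recorded it", so condition-history flags regress impossibly from *yes* to
*no*. The checks are designed to surface exactly these signatures.

## The data model

A `visit_table` holds one row per hospital visit. Raw values are kept
verbatim (missing = empty string) so CSV round trips are lossless; typed
values and per-field parse statuses (`ok` / `missing` / `type_failure`) are
computed once at construction. The `data_dictionary` describes each
variable: its area, value kind, response codes (`0=No, 1=Yes, 999=Unknown`;
sex `1/2`), plausibility ranges, and date formats (`DD/MM/YYYY`, with ISO
8601 also accepted on input).

Three parsing conventions matter downstream and are fixed deliberately:

* `999` is a *legal response option*, never missingness. Completeness counts
  only empty fields; the fraction of 999s is reported separately as an
  unknown rate and does not lower any score.
* A height or weight of `0` parses fine. Zero-coding is an extraction
  artifact, and it is the range check's job — not the parser's — to flag it.
* Parsing is total: malformed text becomes a `type_failure` status, never an
  exception, because type failures are themselves a quality measurement.

## The checks

**Uniqueness.** Result 1 counts records whose visit identifier is shared
with at least one other record that differs in some field (the signature of
two discordant same-day measurements fanned out by the merge); exact
full-row duplicates are reported separately and deliberately excluded.
Result 2 counts records that have a same-patient, same-arrival-date twin
with identical clinical data under a *different* visit identifier (the
signature of date-matched linkage across same-day department visits). Both
use all records as the denominator, and *every* member of a colliding group
counts, because the published convention expresses both results as a share
of all visit records.

**Consistency** has three parts: by type (share of non-missing fields that
fail to parse as the declared kind), by range (numeric plausibility ranges,
date windows, categorical domains), and by declarative multivariate rules
(defaults: arrival ≤ discharge; discharge ≤ death). Type and range score
each variable separately and aggregate by *unweighted mean over variables* —
this is the convention under which two ~15%-valid measurement columns in a
22-variable dictionary produce an overall range score near 91%, matching the
published arithmetic. Rules use records as units, with a record entering the
denominator only when a rule is evaluable on it.

**Completeness** is the share of non-empty fields per variable, averaged
over variables. The date of death carries a *valid-incompleteness* rule: it
only exists when the patient died during the visit, so it is scored on the
subset of records where it is expected, while its raw unconditional rate is
reported alongside. From the flat table alone, "died during the visit" is
observable only through the field itself (a recorded death date within
[arrival, discharge]), so the default conditional score cannot fall below
100 on records where the date is absent; pass an explicit expected-present
mask (for synthetic data, `died_in_visit_mask()` against the generator's
ground truth) to make the rule falsifiable.

**Temporal stability** is assessed qualitatively, as monthly relative
frequencies: per calendar month of arrival, the share of records with
indicator value 1 among all records that month (0 and 999 count in the
denominator only). Months with fewer than 10 records (configurable) are
flagged low-support rather than suppressed. There is deliberately no scalar
stability score. `detect_shift()` is an explicit convenience extension — a
two-window mean-gap scan (12-month windows, 50% relative-change threshold,
low-support months excluded, earliest-month tie-break) — and is off by
default in reports.

**Correctness** combines BMI plausibility (records with computable BMI
strictly below 10 or strictly above 70 kg/m², as a share of *all* records,
with non-computable records tallied separately), height/weight inversion
candidates (weight in kg exceeding height in cm; candidates whose swapped
values give a plausible BMI are labelled swap-plausible), and the
temporal-order rule: once a record states a history of atrial fibrillation,
hypertension, diabetes or myocardial infarction, every later record of that
patient should state it too, so a later 0 after an earlier 1 is a violating
*record* (violations are counted per record, not per patient; 999 neither
violates nor resets the state; ties in arrival date break by visit
identifier).

No convention reconstructs every published aggregate exactly: the unweighted
mean over the five correctness components is the package default, and is
documented as a choice rather than a derivation, because the corresponding
published aggregate is not reproducible from its printed components.
Reported scores are rounded half-up to two decimals; raw fractions stay in
the result objects. Vacuous denominators (no assessable fields) score 100
and raise a `vacuous_denominator` flag instead of silently dividing zero by
zero.

## The synthetic generator

`generate_visit_table()` emulates the *mapped extract* of a hospital EHR
for a heart-failure cohort over 2006-01-01 to 2017-11-07. Its defaults are
the study conditions the checks are meant to confront:

* 85% of height/weight fields zero-coded; 54 out-of-range heights, 20
  out-of-range weights; 16 arrival dates before the window start;
* 16 implausibly low and 180 implausibly high BMI records;
* partial-duplicate rates of 1.2% (shared visit identifiers) and 2.8%
  (same-day clones);
* an abrupt regime shift in the recording of past medical conditions at
  2011-01-01 (frequency multiplier 0.3) and a gradual linear increase in
  medication recording;
* visit volume thinned in the first half of 2016 so those months fall below
  10 records at the default desk-scale size.

Cohort size (1,000 patients, geometric visit counts with mean 4),
demographics (ages 40-95 at first visit, ~55% male), condition prevalences
and medication base rates are not constrained by any published figure and
are documented, fixed defaults chosen for realism at desk scale. Heights
and weights are drawn from truncated normals (145-200 cm, 45-130 kg) so a
*clean* table can produce no BMI outside (10, 70) — every implausible BMI in
a planted table is planted. Patients die, with probability 0.3, during
their final visit; the death date equals that visit's discharge date and
appears on that record only.

`plant_errors()` applies the error plan with a ground-truth ledger. Each
class can be an exact count (bit-exact recovery tests) or a per-row rate
(stochastic realism); classes draw from disjoint row pools, each from its
own seeded substream, so disabling one class never perturbs another.
In-place classes modify rows; the two duplicate classes *append* rows as
self-contained pairs — a pair sharing a fresh visit identifier but differing
in weight, or a same-day pair with identical clinical data under two fresh
identifiers — so that planting `n` rows yields a numerator of exactly `n`
and row counts change by exactly `n`.

Condition onset is drawn uniformly over a patient's visits by default
(earlier visits are honest zeros); `condition_onset = "first_visit"` models
chronic conditions predating cohort entry, which makes the per-visit flag
frequency exactly prevalence × recording probability — the configuration
under which the regime-shift multiplier is recovered exactly from the
monthly series.

`generate_source()` instead emits the five *relational* tables (patients,
visits, diagnoses, drugs, measures) with the warehouse join topology:
diagnoses attach to visits by identifier, drugs and measures attach to
patients by calendar date only. `inject_temporal_patterns()` thins
history-of-condition rows after the shift date and shapes drug rows to the
monthly trend.

## The mapper

`map_to_ichom()` reproduces the successive left-outer-join extraction:
patient and visit identifiers are the spine; drugs and measures join on
(patient, arrival date), so the duplication artifacts above arise *in the
mapper*, not in the generator; unmeasured visits get height and weight `0`;
and condition flags are 1 when any matching diagnosis up to and including
the visit exists, else 0 — never 999. This deliberately models the flawed
real-world extraction in which absence of a code is indistinguishable from
missingness (`strict_history = TRUE` emits 999 instead, for contrast
experiments). Two consequences are worth stating plainly: because these
flags are cumulative over a patient's diagnosis history, a *mapped* table
cannot contain temporal-order violations, and a recording-practice shift
attenuates only slowly in mapped flag frequencies. The flat generator,
which models per-visit mention directly, is therefore the instrument for
studying order violations and abrupt shifts, mirroring how those phenomena
present in a real mapped extract whose upstream per-visit coding changed.
Hospital admissions/appointments in the last 12 months are computed as the
patient's overnight and same-day visit counts in the 365 days before
arrival — a documented assumption, since no computation is published.
Cohort selection keeps patients with at least one diagnosis from the
built-in 19-code ICD-9 428-family list within the window.

The comorbidity, procedure, lifestyle and medication code lists used by the
original assessment are not published; the package ships documented
synthetic default stubs (e.g. ICD-9 427.31 for atrial fibrillation, ATC
prefix C07 for beta blockers) and accepts site-specific lists via
`read_code_list()`.

## Numerical and design choices

* **Plausibility ranges** are not published (only violation counts), so the
  defaults — height 100-230 cm, weight 20-300 kg, birth dates from 1900,
  event dates inside the extraction window — are explicit assumptions,
  overridable per variable from a YAML dictionary configuration.
* **Rounding** is half-up to 2 decimals at the reporting boundary only.
* **Determinism**: every stochastic stage reseeds from (master seed, stage
  index); identical configuration and seed give byte-identical tables,
  ledgers and JSON reports.
* **Row order is meaningless**: all checks are row-order invariant; the
  mapper emits a documented stable sort (patient, arrival, visit
  identifier).
* **Degenerate inputs**: empty code lists are invariant violations; a
  missing column is a schema error naming the column; extra columns error
  in strict mode and drop with a warning otherwise; unwritable paths are
  I/O errors; check scores on empty denominators are flagged, not invented.

## What the tests do and do not show

The test suite proves the *arithmetic and recovery behaviour* of the
checks: published aggregation identities hold exactly; planted error counts
are recovered bit-exactly at study scale (e.g. 1,200 duplicate-identifier
rows and 2,800 same-day clones in a 100,000-row table yield 98.8% and
97.2%); numerators equal independent brute-force recounts (full pairwise
comparison for uniqueness, per-patient scans for temporal order) on 200
randomised small tables; and a planted 2011-01 regime shift is localised to
within one month across 20 seeded replicates. Problem sizes in the default
suite (tables of 10² to 10⁵ rows, 20 stability replicates of ~28,000
records) were chosen as the smallest scales at which these properties are
sharp.

The generator emulates the *mechanisms* of real extraction errors, not the
full messiness of real hospital data: free-text fields, coding-system
migrations mid-stream, inter-hospital variation and linkage to external
mortality registries are all out of scope. A perfect score on synthetic
data therefore certifies the instrument, not any hospital.
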