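---
title: "Assessing the research reusability of livestock-sector datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the research reusability of livestock-sector datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairlivestock)
```

## The assessment problem

Livestock value chains generate large operational datasets — laboratory
results, biosecurity records, production performance, animal movements —
that researchers in veterinary epidemiology would like to reuse. Whether
reuse is feasible depends on data stewardship properties that are rarely
visible from the data themselves: can the dataset be identified over time,
is there metadata, is the vocabulary intelligible to an outsider, who is
accountable for personal data. `fairlivestock` operationalises that audit.
Its unit of observation is a *dataset description*: one survey answer about
one dataset by one respondent in one survey round, validated against a
closed column dictionary (`survey_dictionary()`).

## The FAIR compliance rubric

Twelve criteria map the four FAIR principles onto properties a
non-scholarly dataset can realistically have. Two adjustments, both
deliberate, shape the rubric:

* identifiers need only be *locally* unique and persistent — there is no
  DataCite-like registry for agri-food operational data, so requiring
  globally persistent identifiers would floor every score;
* machine-actionability is relaxed to *human*-actionability: a dataset is
  interoperable when a person with no prior knowledge could understand its
  structure and vocabulary from the documentation.

Scoring, per criterion:

| Criterion | 1 | 0.5 | 0 |
|---|---|---|---|
| F1 data identifiable | unique identifier, or all identifying elements | exactly one element missing | otherwise |
| F2 metadata identifiable | as F1, on the metadata | as F1 | otherwise |
| F3 data–metadata link | metadata updated automatically | updated manually | no link / no metadata |
| A1 data access | documented protocol or URL | — | otherwise |
| A2 metadata access | documented protocol or URL | — | otherwise |
| I1 data structure | documented | — | otherwise |
| I2 data vocabulary | standard, retrievable glossary, or collaborative | — | otherwise |
| I3 metadata structure | standard schema or documented | — | otherwise |
| I4 metadata vocabulary | as I2 | — | otherwise |
| R1 rich-metadata elements | all available | one missing | otherwise |
| R2 process documentation | collection and quality processes | some | none |
| R3 licence | data and metadata | data only | none |

The *identifying elements* behind F1/F2 are fixed as the minimal catalogue
triple {name, version or release date, responsible organisation}. The triple
lives in the same column dictionary that drives reading, validation and
generation; keeping it a single constant guarantees that "one element
missing" means the same thing everywhere. A survey with a different element
list would change that one constant.

Two reporting conventions matter downstream. A criterion is *fulfilled*
only at score 1; 0.5 is reported separately as *partial* (the fulfilment
counts in `summarize_cohort()` would otherwise be ambiguous). And "at least
half of the criteria" counts criteria fulfilled (≥ 6 of 12), not points
(≥ 6 of 12 points), because partial credit should not accumulate into
nominal compliance.

Missing answers and explicit "unknown" answers never satisfy a condition.
This is the conservative reading — an undocumented property is treated as
absent — and it makes every scorer monotone: upgrading any single field
(adding an identifier, moving a licence from none to data-only to
data-and-metadata, switching metadata updates from manual to automatic)
can never decrease any criterion or the total. The test suite checks this
on 10,000 randomly perturbed record pairs, and checks every scorer against
an exhaustive enumeration of its input state space.

## The GDPR accountability rubric

Only datasets containing personal data are assessed (`gdpr_applicable()`);
a dataset whose personal-data status is unknown is treated as not
assessable, with a logged caveat, rather than guessed either way. The
minimum accountability requirement is that the two governance roles the
regulation names — data subject and data controller — are (i) identified
and (ii) formally documented; each criterion scores 1 only when *both*
roles satisfy it, so the total is 0–2. Documentation presupposes
identification, which the record validator enforces (a role documented but
unidentified is a data error, not a scoring case). The six process-oriented
GDPR principles are out of scope: they are the data controller's
responsibility and cannot be audited from a description survey.

## Answer quality

Open answers are scored on completeness (answer present) and coherence
(answer consistent with the question scope and other available
information); coherence judgment itself is human, entered as 0/1. An absent
answer cannot be coherent, so completeness 0 forces coherence 0 — the
constructor rejects the inconsistent combination. Per question,

$$\text{grade} = \frac{\sum_r (\text{completeness}_r + \text{coherence}_r)}{2\,n_\text{respondents}}$$

and a grade is *low* when strictly below 0.75 — exactly 75% is acceptable.
The threshold marks questions whose aggregated answers need review before
being trusted in the characterisation.

## Harmonisation and anonymisation

Two survey rounds cover overlapping datasets; the second round both adds
newly available datasets and validates first-round answers. The merge rule
is: single-round datasets pass through; for a dataset answered in both
rounds, the answer of the respondent with the higher summed coherence wins
field by field, missing values are filled from the other answer, and ties
go to the round-2 answer (the validation round — this also makes a
same-respondent re-answer supersede its round-1 version). Every overwrite
is logged in the provenance log, so the merged table is auditable.
Contradictory rows for one dataset *within* a round are refused outright.

Anonymisation is two-step: (1) dataset and respondent keys are replaced by
random integer IDs drawn as a seeded permutation of 1..N per entity class —
random but collision-free, and reproducible from the seed; (2) identifying
free text is reduced at read time to its analytical content (language →
`english`/`not_english`/`translated`; a data-owner name → "there is an
identified data owner"), and any column outside the dictionary is dropped.
The result is verified by a deny-list scan: no original identifier string
may appear anywhere in the output, including the provenance log (raw
pre-reclassification values are redacted there).

Percentages are produced by a single function, `percent()`: nearest
integer, halves away from zero. That convention reproduces every printed
ratio in the reported summaries (30/38 → 79, 6/19 → 32, 20/30 → 67,
4/30 → 13).

## What the synthetic generator emulates

`generate_cohort()` draws dataset descriptions field by field, either from
probability weights or from exact count quotas. `paper_like_config()` is
the study-sized configuration: 30 datasets, 19 respondents, species quotas
of 10 swine / 9 salmonids / 9 cattle / 4 poultry including 2 swine-and-
cattle datasets, and exact quotas of 11 personal-data, 16
metadata-available and 20 not-English datasets. Remaining fields use the
observed cohort proportions as weights; where a published tally is a bound
("6 or fewer"), the defaults take 6/5/4 for movements/economic/behaviour
content, and the vocabulary-practice counts are scaled so the quotas sum to
30 while preserving the 14 datasets with a comprehensible vocabulary.
Structural invariants hold by construction: metadata-dependent fields are
only drawn where metadata exist, and a role is only documented if
identified. Round structure is emulated by moving a fraction (default 0.2)
of datasets to round 2 and re-answering a fraction (default 0.2) of round-1
datasets by a different respondent with a per-field conflict rate of 0.1,
confined to fields without quota constraints.

The generator emulates *marginal* structure only. Fields are independent
given the invariants, whereas real stewardship practices are strongly
correlated (a dataset with a standard metadata schema likely also has a
licence and an access protocol); respondents have no individual bias; and
coherence scores are independent of the answers themselves. Passing tests
therefore demonstrate that the pipeline computes the intended quantities on
data with the right shape and margins — not that it would reach the same
per-dataset conclusions as a real audit, which requires the real survey.

## Numerical and degenerate-input choices

* Categorical tokens are matched case-insensitively after trimming; unknown
  tokens map to `unknown` (or `NA` where no such level exists) with a
  warning, never silently.
* `NA` (no answer) and the empty set (multi-select answered "none") are
  distinct and survive CSV round-trips (`NA` vs empty string).
* An empty cohort summarises to zero counts and writes a valid report;
  group means over empty groups are `NA`, not 0.
* Criterion scores outside {0, 0.5, 1} and percentages with zero
  denominator are domain errors, not clamped values.
* Every source of randomness (generation, ID permutation) is driven by an
  explicit seed through an RNG-state-preserving wrapper, so a pipeline run
  is byte-reproducible and never perturbs the caller's RNG.

## Problem sizes used in the checks

The exhaustive rubric enumerations cover the full criterion state spaces
(at most 3^4 = 81 governance states; 36 identification states). The
monotonicity suite uses 10,000 record pairs; generator-recovery checks use
the 30-dataset quota cohort plus 10,000-dataset weight-mode cohorts, where
empirical prevalences must land within 3 standard errors of their targets.
These sizes make the full suite run in well under a minute while leaving
the binomial checks sharp enough to catch a mis-wired probability.

## Known limitations

* The coherence judgment is exogenous: the package aggregates human 0/1
  scores, it does not judge answers.
* Conflict resolution uses a respondent's *global* coherence sum, not
  per-question coherence, mirroring the "most coherent response" rule; a
  respondent careful on governance but sloppy on metadata is still one
  number.
* GDPR assessment covers accountability only; lawfulness, minimisation,
  storage limitation etc. are not inferable from a description survey.
* The rubric is ordinal and bespoke: totals are comparable within a cohort
  assessed with this instrument, not against other FAIR maturity models.
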