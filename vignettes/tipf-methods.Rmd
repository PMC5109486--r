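---
title: "Interaction-profile fingerprints: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction-profile fingerprints: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipf)
```

## The model

`tipf` implements ligand-based target prediction from interaction data
alone. The premise is pharmacological: compounds with near-identical
target repertoires tend to share their remaining targets, so the known
interaction profile of a compound is itself a fingerprint that can be
searched, exactly as structural fingerprints are searched in conventional
virtual screening.

Given a curated set of positive compound–target pairs, each compound $c$
is encoded as a binary vector over the target universe (its TIPF), stored
sparsely as the set of on positions $A_c$. Similarity between compounds is
the Tanimoto coefficient of those sets,

$$TC(a, b) = \frac{|A_a \cap A_b|}{|A_a \cup A_b|} \in [0, 1],$$

and every compound–target combination $(c, t)$ is scored by its maximum
similarity to the known binders of $t$:

$$s(c, t) = \max_{b \ne c,\; (b, t) \in P} TC(c, b),$$

with the argmax reported as the reference compound. Because the
maximisation excludes $c$ itself, known pairs are scored by the same rule
as novel ones — they act as internal positive controls rather than
trivially recovering themselves. Scored combinations are classified
against the standard as known-positive, known-inactive (explicit "not
active" evidence) or novel; the three classes always partition the total.

All combinations are scored, not only the non-intersecting targets of
each compound pair: recovery of the known pairs is precisely what the
threshold curves measure, and classification afterwards separates the
novel predictions. This reading reconciles the candidate-generation view
(novel pairs) with the positive-control view (known pairs recovered).

## Curation rules and their parameters

Raw assay records are collapsed to one case per compound–target pair and
activity class before filtering; active and explicit-inactive evidence
for the same pair are kept as separate collapsed cases so they can be
arbitrated deliberately. The filters, all configurable via
`curation_config()`:

* **Target class** — only `"SINGLE PROTEIN"` targets by default; protein
  complexes and unspecified targets are rejected (`TARGET_TYPE`).
* **Comment vocabulary** — case-insensitive substring matching against
  "not active", "not determined", "not soluble", "potential missing
  data". "Not active" is special: the pair is retained as a known
  inactive rather than discarded; the others reject the record
  (`COMMENT_EXCLUDED`). Substring matching is used because real-world
  comments vary in casing and phrasing.
* **Potency ceiling** — 50,000 nM. A record whose relation is `>` or `>=`
  at or above the ceiling is rejected (`POTENCY_CEILING`); by default a
  *measured* value above the ceiling is rejected too, which keeps the
  standard internally consistent (a measured 60,001 nM is no more a
  high-affinity interaction than "> 50,000"), and this extension can be
  switched off (`reject_measured_above_ceiling = FALSE`). Only nM values
  are compared to the ceiling; other units are rejected
  (`UNIT_UNSUPPORTED`) rather than silently converted.
* **Minimum targets per compound** — 15 distinct positive targets after
  curation. Below that, a profile is too sparse for its Tanimoto
  similarity to be informative. The filter counts distinct curated
  targets, never raw records.

Every rejected record carries exactly one machine-readable reason, so the
rejection log partitions the discarded evidence. A pair with both active
and inactive evidence is arbitrated in favour of the positive and the
conflict is logged: explicit inactivity annotations are assay-scoped,
whereas a single credible potency measurement is direct evidence of
binding.

Compound and target universes are sorted lexicographically and every
writer emits sorted, LF-terminated output, so re-runs are byte-identical.

## Numerical choices

* Intersection and union cardinalities are integers; the TC is their
  ratio in double precision. Equal set pairs give exactly 1 and disjoint
  pairs exactly 0 (no rounding is involved in either case), and the
  all-pairs output carries `n_intersect` and `n_union` alongside `tc` so
  any threshold decision can be re-derived exactly. Scores are rendered
  to 6 decimals in the TSV writers; that rounding is presentation-only.
* The all-pairs search prunes through a sparse compound × target
  cross-product — only pairs sharing at least one target produce a
  nonzero intersection — which is lossless by construction; tests assert
  exact equality with the naive double loop on randomized instances.
* Reference-compound ties are broken by the lexicographically smallest
  compound id, making ranked outputs deterministic.
* Candidates below the materialisation floor (`min_tc`, default 0.5) are
  never stored. The evaluator treats everything unmaterialised as
  predicted-negative, and refuses thresholds below the floor, where
  false-positive and true-negative counts would be silently wrong.
* The two-sided Fisher exact test follows the minimum-likelihood
  convention: the p-value sums the hypergeometric probabilities of every
  table with the observed margins that is no more probable than the
  observed one. Probabilities come from log binomial coefficients, and a
  relative tolerance of 1e-7 guards the "no more probable" comparison
  against floating-point ties. A one-sided variant is available.

## Evaluation design

**Confusion universe.** The evaluation universe is all compound × target
combinations of the standard, *excluding* known-inactive pairs by
default: they are a distinct evidence class, and counting them as
ordinary negatives (or as false positives when predicted) would conflate
"known not to bind" with "never tested". A flag restores the inclusive
accounting for comparison.

**Enrichment factor.** EF at a threshold is precision divided by the
positive base rate of the evaluation universe — the standard
virtual-screening convention — so EF is exactly 1 at a threshold that
admits every combination, and tests assert that identity on fully
materialised scoring runs.

**Hold-out validation.** Positive pairs are split at the pair level
(record level), uniformly at random under a user seed, into training and
test sets; 0.8 and 0.6 are the study settings. The reference standard is
rebuilt from training pairs only, including re-application of the
min-target filter, so fingerprints never see test evidence. Candidates
not already positive in the training standard are ranked by descending
score and recovery of test pairs is measured at top-N rank cutoffs
(a geometric grid scaled to the candidate count by default, since
absolute rank grids only make sense at a fixed database size). Test pairs
whose compound or target dropped out of the training universe cannot be
scored at all; both accountings are reported — sensitivity over scoreable
test pairs and over all test pairs — rather than silently counting the
unscoreable as misses. Pair-level splitting is the default because the
procedure divides "the data", i.e. interactions, not compounds;
compound-level splitting would remove whole profiles and measure a
different (cold-start) problem.

## The synthetic generator

`synth_generate()` emulates the structure the method exploits:
`n_families` pharmacological families, each with a disjoint base set of
`targets_per_family` targets; every compound carries a random
`within_family_share` fraction of its family set plus out-of-family
interactions at rate `cross_family_noise`. Defaults (4 families × 10
compounds × 20 targets, share 0.9, noise 0.02, seed-driven) give curated
worlds of ~40 compounds × 80 targets with ~19 targets per compound —
comfortably above the 15-target filter and small enough that brute-force
oracles can label every combination. Decorated records (a "not active"
pair, a "> 60,000 nM" potency, a protein-complex target, a duplicate
assay, a "not determined" comment) wrap the clean pairs so each curation
rule fires exactly once, and masked pairs are removed from the emitted
records but listed in the truth with their closed-form expected recovery
score: in a noiseless family of identical $m$-target profiles, a masked
pair scores exactly $(m-1)/m$ against any family member (intersection
$m-1$, union $m$).

What the generator does **not** emulate: realistic potency distributions,
promiscuity heavy tails, overlapping family target sets (available as a
non-default option), assay-level correlation structure, or any chemistry.
Passing tests therefore demonstrate algorithmic correctness and the
qualitative behaviour of the metrics on family-structured data — not
predictive performance on a real bioactivity snapshot, whose absolute
candidate counts and curve positions depend on the database release and
compound whitelist used.

## Problem sizes used in tests

Unit and property tests run on worlds of up to 150 compounds × 100
targets, where exhaustive double- and triple-loop oracles stay exact and
fast; the hold-out property uses 20 seeded splits of a 40-compound ×
120-target clustered world (30 targets per family, so training matrices
survive the min-target filter at a 0.6 train fraction). The 80 %-training
mean test-set sensitivity is asserted to be at least the 60 % mean minus
a Monte-Carlo tolerance of 0.02, fixed in advance of any run: the
direction of the effect is the property; the tolerance only absorbs
seed noise in two 20-seed means.

## Known limitations

* Identifier-level clustering only: assays are merged per exact
  `target_id`; no ortholog mapping or cross-organism merging.
* No unit conversion: potencies not reported in nM are rejected, not
  converted.
* The score is similarity, not potency: a high-TC candidate is a
  hypothesis about binding, with no affinity estimate attached.
* Dense compound × compound similarity is materialised during candidate
  scoring, which is fine for the tens of thousands of compounds a curated
  standard contains but would need blocking for millions.
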