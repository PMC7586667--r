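---
title: "Scoring drugs for replacement and herbs for substitutability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drugs for replacement and herbs for substitutability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbsub)
library(dplyr)
```

`herbsub` implements a cross-lingual literature-based-discovery pipeline:
western drugs are ranked by how conspicuous their side-effect literature is
relative to their indication literature, and traditional Chinese medicine
herbs are ranked as candidate alternatives for a flagged drug. This
vignette explains the statistical model, the parameters that matter, the
design choices made where the method left room, what the synthetic
generator does and does not emulate, and the package's known limitations.

## Link weights and the replaceable score

The atomic observation is a *link weight*: the number of abstracts in which
a drug (or herb) co-occurs with a disease concept. Co-occurrence is at
abstract granularity — a pair counts once per abstract no matter how often
either entity is mentioned — and entities arrive pre-normalized to concept
ids; named-entity recognition and synonym resolution are out of scope.
Title and abstract are treated as one text unit. Drug–disease links are
split into side-effect and indication relations by dictionary membership; a
disease listed in both dictionaries for the same drug stays in both
relation tables, since dropping either would silently bias the scores.

For drug $d$ and side effect $s$ with link weight $f_s$:

$$\mathrm{score}(d, s) = \frac{f_s}{\overline{f}_s}, \qquad
  \overline{f}_s = \text{mean link weight of } s \text{ across all drugs linked to } s$$

**Denominator scope.** "Average side-effect link weight" could be read per
drug (average over the drug's own side effects) or per side effect (average
across drugs). The package uses the cross-drug reading: only under it does
a side effect common to many drugs — headache is the canonical case — get a
large denominator and hence contribute little to every drug's profile,
which is the stated purpose of the normalization; under the per-drug
reading every drug's mean score would be identically 1 and the ranking
degenerate. A direct consequence, asserted by the test suite, is the
normalization identity: each concept's scores average to exactly 1 across
its linked drugs, and rescaling one concept's weights by any constant
leaves its scores unchanged.

$\mathrm{Rate}_{se}(d)$ is the arithmetic mean of the drug's side-effect
scores over its $\alpha$ *observed* side effects — those with nonzero link
weight in the corpus, not the dictionary's full list, since the selection
algorithm iterates over observed relations. The replaceable score is
$\mathrm{Rate}_{se} / \mathrm{score}(d, i)$ for the target indication $i$;
drugs with no observed link to the indication are excluded from the ranking
(with a message) rather than given an infinite score. Flagging uses a
strict threshold (`replaceable > 1`), ranking is descending with ties broken
by drug id in code-point order, and scores are carried at full floating
precision (display rounding is the caller's business).

## Prescriptions, doses, and term intersections

Classical doses are normalized exactly to the smallest unit, fen
(1 两 = 10 钱 = 100 分); fractional quantities are accepted because
classical half-doses exist. Duplicate entries of one herb within a
prescription are summed before proportions are computed, so proportions sum
to 1 per prescription (a tested invariant). Component strings parse as
`<herb><number><unit>` with the herb name the maximal prefix before the
numeric token.

Chinese matching is deliberately primitive: NFC normalization followed by
raw substring containment over the whole indication field, with no word
segmentation — the reference worked example requires a two-character
dizziness term to match inside a longer compound, which segmentation could
break. A side-effect concept counts once per prescription regardless of how
many of its synonyms match. The bilingual lexicon is an explicit input, not
hard-coded: published synonym sets are visibly richer than any printed
table, so callers can widen the lexicon without touching code.

## Direct and indirect substitutability

A herb is *direct* for the target indication when herb and indication
co-occur in at least one prescription (component list and indication text
of the same record). Then

$$\mathrm{substitutability}(d, h) = D \times N$$

with $D$ the unweighted mean of the herb's per-prescription dosage
proportions over qualifying prescriptions (not dose-weighted), and $N$ the
mean per-prescription intersection count plus one — the +1 records that the
qualifying prescriptions treat the target indication itself, so a direct
herb always has $N \ge 1$.

For *indirect* herbs the dosage proportion is propagated: for each direct
herb $h$, with $F_c$ prescriptions containing both herbs and $F_h$
containing the indirect herb, the contribution is $(F_c/F_h) \cdot D[h]$,
and the contributions are **summed** over direct herbs. The algorithmic
listing accumulates; surrounding prose could be read per-herb, and the
listing was followed. The propagated $D$ is therefore a score, not a
fraction, and may exceed 1. $N_{indirect}$ is averaged over *all*
prescriptions containing the indirect herb (the listing does not restrict
the set to prescriptions co-containing a direct herb) and carries no +1.
Presence counts are prescription-level: a herb listed twice in one
prescription counts once in $F_c$ and $F_h$. A herb qualifying as direct is
never also scored indirectly. If a database has no direct herb at all,
propagation has no source and indirect herbs receive $D = 0$ rather than an
error, so ranking an arbitrary database always succeeds.

Ranking keeps the top `k = 10` herbs by score, ties broken by herb name in
code-point order — deterministic by construction.

## Evaluating the selection

Flagged and unflagged drugs are compared on oral LD50 (rat, mg/kg) and
elimination half-life parsed from free-text profile fields. Parsing rules:
ranges (`2–4 h`, with hyphen, en/em dash, minus or "to" as separators) take
the median $(a+b)/2$; `x +/− y` forms take the central value; day units are
converted to hours (×24); toxicity requires an explicit `mg/kg` so that
case-report prose with bare milligram doses is excluded, mirroring the rule
that drugs without a recorded oral LD50 in rat do not enter the toxicity
mean. The median-of-range rule is applied uniformly to both metrics for
symmetry. Group means use parseable values only and are invariant to row
order and to inserting non-parseable profiles (tested).

The structural check builds herb–ingredient–target–disease graphs with
strict admission filters: oral bioavailability > 30 % and drug-likeness
> 0.18 — equality is excluded, and the suite plants exact-threshold values
to pin this down. Disease nodes are restricted to the focal drug's own
side-effect and indication concepts; targets survive only via retained
ingredients and diseases only via retained targets, so no edge ever
references a dropped node.

## What the synthetic generator emulates

`synth_config()` fixes the study conditions: 10 drugs, 8 side effects, 4
indications, 600 abstracts, 20 herbs, 40 prescriptions, base link rate 10,
planted-drug multipliers 3.0 (side effects) and 0.5 (indication),
planted-herb dose boost 2 with synonym-seeding rate 0.6 against a 0.1
background, and a 0.6 indication rate. These sizes keep the full test suite
around a minute on one CPU while leaving the planted signals comfortably
above sampling noise: expected link weights are ~10 for ordinary pairs, ~30
for the planted drug's side effects and ~5 for its indication. A corpus
much sparser than this lets ordinary drugs draw near-zero indication counts
whose reciprocal explodes their replaceable score — a real phenomenon the
cross-drug normalization does not protect against — which is why the base
rate is set an order of magnitude above 1, as in any corpus of realistic
size. The acceptance suite asserts planted-drug recovery in at least 19 of
20 fixed seeds and planted-herb top-rank recovery likewise.

The planted herb's dose is written as `dose_boost ×` the mean component
dose of its own prescription (expressed in qian, one decimal), so its
dosage proportion is the boost multiple of an average component *by
construction* rather than on average only. Synthetic Chinese synonyms and
herb names are distinct two-character strings drawn from the CJK unified
range, exercising the Unicode path end to end; indication texts are
comma-joined synonym strings plus neutral filler.

What the generator does **not** emulate: realistic MeSH-like vocabulary
structure, citation dynamics or topical correlation between abstracts,
polysemous or overlapping Chinese terms (synonyms are globally unique by
construction), dose-form differences, and prescriptions whose indication
field uses non-synonym paraphrases. Passing the planted-recovery tests
therefore shows the scoring machinery is correct and well-powered under
clean conditions — not that the pipeline is robust to noisy entity
recognition or lexicon gaps in real corpora.

## Numerical choices and degenerate inputs

* All ratios are computed and compared at full double precision; tests on
  published values use the tolerances those values are printed at.
* Zero-indication drugs, empty relation sets, empty prescription databases
  and lexicons with blank synonyms raise typed errors (or return empty
  results where the operation is a ranking) rather than NaN.
* Proportion sums, score normalization and ranking permutation are asserted
  to 1e-12.
* Ties anywhere resolve by code-point order of the id, never by input
  order.
* All randomness flows through a single integer seed; identical seed and
  configuration reproduce every generated file byte for byte.

## Limitations

The two normalizations are the only guard against literature bias; no
multiple-testing correction or confidence intervals are attached to the
rankings, and substitutability is a heuristic composite, not a calibrated
probability. Chemical-similarity weighting of herb ingredients is out of
scope, as are protein–protein interaction networks and GO/KEGG enrichment,
which depend on external annotation services. Only the three classical mass
units are handled; count-based units (枚, 片) and dynasty-specific unit
systems are not.
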