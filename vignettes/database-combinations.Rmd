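---
title: "Evaluating database combinations for systematic review searches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating database combinations for systematic review searches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchrecall)
```

## The problem

Systematic reviews are expected to find *every* study that meets their
inclusion criteria, so searchers query several bibliographic databases
(Embase, MEDLINE, Web of Science, Google Scholar, Cochrane CENTRAL,
subject databases such as CINAHL or PsycINFO). Each extra database costs
search-translation effort and, above all, screening time, because most of
what a search returns is irrelevant. The question this package addresses
is empirical: **given per-review documentation of which database
retrieved which reference, which combinations of databases would have
been enough?**

The unit of observation is one systematic review with

* a set of searched databases and, per database, the number of records
  retrieved (recorded at search time, before deduplication),
* optionally the full record-level library (every retrieval event),
* the published review's included references, each carrying its
  *provenance* — the set of databases whose searches retrieved it.

Includes that no database search retrieved are attributed to other search
methods (hand searching, reference checking, expert contact) and are
excluded from retrieved-basis recall denominators; a `published` basis
that keeps them in the denominator is available where the complete-search
perspective is wanted.

## Measures

For a database combination $C$ evaluated on a review (or pooled over a
corpus),

$$\mathrm{recall}(C) = \frac{|\,\text{includes retrieved by } C\,|}
 {|\,\text{includes retrieved by any searched database}\,|},\qquad
\mathrm{precision}(C) = \frac{|\,\text{includes retrieved by } C\,|}
 {|\,\text{records retrieved by } C\,|},$$

and the number needed to read $\mathrm{NNR}(C) = 1/\mathrm{precision}(C)$,
the screening burden per relevant reference. All three are kept as
full-precision fractions internally; percent formatting (one decimal for
performance tables, whole percents for practice tables, ties rounding up)
happens only in the reporting layer, so pooled totals never accumulate
rounding error.

Corpus-level evaluation of a combination (`evaluate_combination()`,
`evaluate_all_subsets()`) restricts to reviews that searched every member
of the combination — scoring an unsearched database as zero retrieval
would bias recall downward — and reports pooled overall recall, the
median and minimum of per-review recalls, the share of reviews at 100%
recall, precision and NNR. When record-level libraries are present,
result counts are exact deduplicated union sizes (records are clustered
into works by normalized author + year + title); otherwise the
per-database counts recorded at search time are summed and the row is
flagged `dedup = "counts"`, reproducing the arithmetic that is possible
when only search-time counts survive.

`attainment()` asks the question a review team actually has — *with what
probability would this combination have reached e.g. 95% recall in a
review like mine?* — as the share of reviews at or above each threshold.
The comparator defaults to `>=` (so the threshold-1.0 column equals the
percentage-100%-recall column exactly) and can be switched to strict `>`,
since prose descriptions of such thresholds are genuinely ambiguous.

Two per-review ratios summarize the efficiency side:
`results_reduction_ratio()` (combination results over full-search
results) and `precision_improvement_ratio()`. For the latter the package
fixes a convention: values **above 1 mean the combination is more
precise than searching everything**. Descriptions of this ratio often
invert numerator and denominator between text and figure; a single
documented direction avoids that trap.

`greedy_cover()` extends candidate selection into an explicit optimizer:
it adds databases by marginal gain in attainment share per unit cost
until a target share of reviews reaches a target recall. Greedy set cover
is not guaranteed optimal; the test suite compares it against exhaustive
enumeration on small candidate sets.

## Matching includes to their provenance

When provenance is not recorded directly, it is reconstructed by locating
each included reference in the review's combined, non-deduplicated
library (`match_review()`):

1. **Author-year key.** Candidate records share the normalized
   `surname|year` key (case-folded, diacritics stripped via ICU
   transliteration, punctuation dropped) — the probe a searcher types
   into a reference manager.
2. **Second author (2b).** If the key hits more than one distinct work
   and second-author surnames are available, exact second-surname
   equality is tried first: it is cheaper and stricter than title
   comparison.
3. **Title similarity.** Remaining ambiguity is resolved by token-set
   Jaccard similarity between normalized titles, with threshold 0.6. The
   manual procedure this emulates ("limit by a distinct part of the
   title") has no printed numeric equivalent; 0.6 was fixed a priori as
   the value at which two titles share a clear majority of their
   vocabulary, and is exposed as `title_threshold`.

All records of the surviving work — one per retrieving database —
contribute provenance. Zero survivors mean the include came from other
search methods. If more than one work survives the threshold, the include
is flagged `ambiguous-unresolved` and excluded with a warning: a
conservative, auditable choice in preference to silently picking the most
similar work, which would be invisible in downstream recall numbers.

## The synthetic generator

No public corpus carries per-review, per-database retrieval provenance,
so the package ships a generator (`generate_corpus()`) whose defaults are
calibrated to the one prospective benchmark available: 58 reviews, about
31 includes per review, single-database pooled recalls of 0.859 (Embase),
0.788 (MEDLINE), 0.681 (Web of Science), 0.344 (Google Scholar), 4.6% of
includes found by no database, about 17% of retrieved includes unique to
one database, and corpus NNR between 17 and 73.

The membership model for an include has two latent classes:

* **mainstream** (probability `overlap_strength`, default 0.78): every
  searched database retrieves it independently with an elevated
  probability;
* **niche** (the rest): the include has an *affinity database* — drawn
  with weights proportional to the benchmark's unique-reference profile
  — where retrieval is near-certain (`niche_hit` = 0.97), and it leaks
  only weakly into the other databases (`niche_leak` = 0.05).

The mainstream probabilities are solved at configuration time so the
pooled marginal equals `retrieval_marginals` exactly; infeasible
combinations are rejected with a configuration error. The niche class is
load-bearing: with these high marginals, *independent* retrieval already
leaves only ~6–7% of includes unique to one database, and adding positive
overlap pushes the share further down. A realistic 17% unique share
requires negative cross-database dependence — records findable in
essentially one source, which is exactly what indexing gaps produce — and
the affinity mechanism supplies it while preserving the marginals.

A note on semantics: because the mainstream probabilities are *solved*
from `overlap_strength` to preserve the marginals, raw pairwise Jaccard
overlap between databases is not monotone in `overlap_strength` (the
compensating mainstream class can overlap more as the niche share grows).
What `overlap_strength` controls monotonically — and what the calibration
targets — is the single-provenance share: more mainstream means fewer
unique references. The property suite asserts exactly that.

Two further layers reproduce the dispersion visible in real per-review
recall tables: a review-by-database search-effectiveness random effect
(logit-normal, sd `search_effect_sd` = 0.8, offset-corrected by numerical
integration so every marginal is preserved in expectation), and
negative-binomial irrelevant-record pools (mean 2500 candidate works per
review, retrieved independently per database at rates matched to the
benchmark's per-database result volumes), which give realistic
deduplicated union sizes and NNR. The Google-Scholar-like database is
relevance-ranked and truncated to its first `gs_rank_cap` = 200 records —
100 when the other databases' yield falls into the lowest
`gs_low_quantile` = 10% of the corpus, emulating the low-yield rule
searchers apply by judgment; the qualitative rule has no printed cutoff,
so the quantile is a package choice. Relevance ranking places relevant
candidates above irrelevant ones, so truncation sheds noise only.

Includes retrieved by no database become other-methods includes; an
analytic per-review top-up (computed from the review's exact zero-
retrieval probability) brings their expected share to
`other_methods_rate` = 4.6%.

Every corpus is a pure function of its configuration (the seed is
mandatory), and the generator returns a ground-truth ledger sufficient to
recompute every analysis output by brute force (`truth_recount()`, plain
loops sharing no code with the pipeline). `perturb_titles()` injects
case, truncation and diacritic noise into library titles to measure
matcher degradation against the ledger.

**What passing tests do and do not show.** The generator emulates the
*structure* of multi-database retrieval: marginals, overlap and
uniqueness, other-methods share, screening volume, truncation. It does
not model search-strategy quality, database indexing lag, topic-dependent
coverage beyond an optional planted domain effect, or duplicate works
with genuinely different metadata across databases (export formats are
clean). Oracle-equivalence tests therefore certify the bookkeeping — that
the pipeline counts exactly what the ledger says — and parameter-recovery
tests certify the calibration, but neither certifies performance on messy
real exports; the perturbation tests probe that direction, and matching
accuracy on real data has no external target to compare against.

## The practice-assessment model

Given a frequency table of which key-database combinations a sample of
published reviews searched (`practice_sample()`), and per-combination
probabilities of reaching a recall threshold
(`derive_probability_table()` from a corpus, or a table of printed
values), the probability that a randomly drawn published review reached
acceptable recall is the frequency-weighted average

$$P = \sum_{\text{combinations } c} \frac{f_c}{N}\; P(\text{recall}_c \ge t),$$

with reviews searching none of the key databases contributing zero. The
denominator defaults to the matched total (reviews that searched at least
one key database), matching how such tables print their "Total" row; the
full sample size is available as an alternative convention. On the
built-in benchmark inputs this reproduces totals of 40% at the 95%
threshold and 23% at 100%.

One column-labelling quirk of the benchmark's printed table is worth
recording: its final column is headed as a product involving the
95%-threshold column but its values are the frequency share times the
100%-recall probability; the package computes the latter.

## Numerical and design choices

* **Medians** over even review counts use the midpoint convention
  (`stats::median`).
* **Rounding** for display is round-half-up at the printed precision;
  `round_half_up` adds a `1e-9` guard against binary representation of
  exact halves.
* **Empty denominators** (no retrieved includes, zero results) raise
  typed errors rather than returning `NaN`; degenerate reviews are
  excluded from corpus statistics explicitly.
* **Tie-breaking** in candidate selection is by unique references, then
  reviews-with-unique, then canonical name — fully deterministic.
* **Database aliasing**: merges such as folding a publisher-supplied
  PubMed subset into MEDLINE are expressed in the registry's alias table,
  never in analysis code.
* **EndNote libraries are not parsed.** RIS (the standard reference-
  manager export) and CSV are the interchange formats; a minimal RIS
  reader/writer is included because the installed stack offers none.

## Problem sizes used in the shipped tests

Oracle-equivalence runs use 58 reviews × ~31 includes × 6 databases
across 20 seeds with the irrelevant-record pool scaled to 150 candidate
works per review: recount equality is exact at any screening volume, so
the smaller pool is purely a problem-size choice. Parameter recovery and
the invariant sweep run on one corpus under the full default calibration
(2500-work pools). Matching and IO tests use 2–8 review corpora.

## Limitations

* Recall is measured against includes retrieved by *some* searched
  database; truly unfindable studies are invisible to the design.
* The probability model treats the corpus-derived attainment shares as
  transferable to other reviews' searches — a strong assumption when
  searcher skill differs.
* Whether missed references would change a review's conclusions is out
  of scope.
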