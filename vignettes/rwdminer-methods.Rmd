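---
title: "Methods: mining structured and free-text EHR events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining structured and free-text EHR events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwdminer)
```

## The problem

A hospitalization (an *event*) leaves two records: structured tables —
one diagnosis row with up to 24 ICD-10-coded disease columns, plus zero
or more medication orders with a product name and a route (oral or
injection) — and a free-text discharge summary. The two are written for
different purposes (billing versus clinical narrative) and are known to
carry different slices of the patient's story: tables are exhaustive for
administered medications, text is far richer in symptoms. `rwdminer`
quantifies that difference per event, identifies disease cohorts from
each source separately, and screens drug-pair exposures against
text-reported symptoms for adverse-drug-effect (ADE) candidates.

The unit of analysis throughout is the event; sources are aligned by
intersecting event IDs (`align_corpus()`), keeping only events with both
a diagnosis record and a document. One diagnosis row is one event;
duplicate event IDs on the diagnosis side are treated as data errors
rather than merged. When several documents share an event ID they are
concatenated in document-ID order and flagged — event-level granularity
is preserved, at the cost of treating the concatenation as one note.
On patient-ID disagreement between a document and the diagnosis record,
the diagnosis side wins (it is the administrative source of record) and
the conflict is counted in the alignment report.

## Text processing

Extraction is a three-stage pipeline.

**Tagging.** The reference tagger (`tag_entities()`) performs a
longest-match-first, left-to-right scan of each document against the
union of dictionary surfaces, after NFKC normalization and Latin case
folding (full-width/half-width variants of clinical vocabulary unify
under NFKC; spans refer to the normalized text). Ties on length break by
leftmost start, then disease before drug. In production the tagger's
place is taken by a pretrained clinical NER model; its output enters
through `import_annotations()`, which validates spans against the
documents. Re-implementing such a model is out of scope by design — the
dictionary tagger exists so that the pipeline is runnable and *exactly*
testable without model weights.

**Factuality.** A mention is negated iff a cue string starts within
`window` characters after the mention's end, or ends at most one
character before its start. The default window of 12 characters covers a
separator plus a short clause tail while staying well inside typical
sentence length; the cue list is fully configurable. Clinical negation
in the wild is scoped by a parser or an ML model; this crisp rule is the
deterministic stand-in that makes ground-truth evaluation exact.
Cancelled drug orders mentioned in text ("the docetaxel has been
canceled") are not a separate factuality class — anything cued is folded
into `negated`, since both mean "not applicable to this patient".
`filter_negated()` then keeps exactly the positive mentions and reports
the removed counts per type.

**Normalization.** Surfaces link to concepts by the normalized
Levenshtein score `100 × (1 − lev(a, b) / max(|a|, |b|))`. Among several
conventions for normalizing an edit distance, division by the longer
string's length is used: it is the most common, keeps the score
scale-free, and bounds the score change of a single edit by `100/|a|`,
which makes cutoff behaviour analytically predictable. The acceptance
cutoff is 70 *inclusive*. If the top score is shared by surfaces of two
or more distinct concepts the mention is `ambiguous` and excluded from
all downstream counting — context-dependent disambiguation is left out
deliberately; a top-score tie within one concept's surface set is
harmless. The same contract links medication product names to
pharmaceutical ingredients (`link_mo_products()`). Levenshtein distances
are computed by `utils::adist()`; the test suite checks the whole linker
against an independently written textbook dynamic program on a thousand
random instances.

## Frequency analytics

Three frequency notions are distinguished per source and entity type:
*entity* frequency counts every mention occurrence; *normalized-entity*
frequency counts only mentions linked to a concept; *concept* frequency
counts distinct concepts. Diagnosis-table codes are concept-level by
construction, so their normalized rate is 1 by definition and they are
not re-normalized. Events with no entity of a type are excluded from
that type's per-event statistics (they are invisible to that source).
Per-event standard deviations use the population denominator `n`: the
events analysed are a census of the corpus, not a sample from it.
Vocabulary intersections (`common_counts()`) are taken on
NFKC-normalized surfaces, so trivially variant spellings do not inflate
the "unique to one source" counts.

The text-versus-table frequency comparison for medications fits
`y = βx` through the origin by least squares on raw counts
(`origin_regression()`), per route of administration; log scaling
belongs to the display only. For a no-intercept model the coefficient of
determination is convention-dependent, and the centered convention can
leave `[0, 1]` entirely; both `1 − SS_res/Σy²` (uncentered) and
`1 − SS_res/Σ(y − ȳ)²` (centered) are therefore reported, and users
should quote the uncentered one for through-origin fits.

## Cohort identification

A `disease_spec()` names a disease by ICD-10 prefixes (range notation
`E10-14` expands at load time) and optionally by a curated list of
ingredients used only or mainly for that disease. Prefix matching
implements subcategory semantics: `C50` covers `C509`. The three source
rules are: any prefix match in any of the 24 coded columns of any of the
patient's events (diagnosis route); any linked order for a listed
ingredient (medication route); any positive, linked disease mention
whose concept matches a prefix (text route). The package bundles a
reference configuration of eight diseases for cross-source
benchmarking; ingredient lists are site-specific and ship empty.
`venn_counts()` returns the seven exclusive regions, which always sum to
the union. The counting unit defaults to the patient — the natural unit
for "who can be found from which source" — with `unit = "event"`
available, since event-level overlap is equally well-defined and the
choice is a genuine modelling decision.

## ADE co-frequency screening

Within a drug category (e.g. anticancer agents), `build_M()` counts for
every unordered ingredient pair the events in which both were ordered —
exposure is deduplicated per hospitalization because combination therapy
makes repeated orders of the same pair routine. The diagonal holds
single-drug event counts: the square heatmap then reads naturally, with
monotherapy on the diagonal. `build_D()` counts the subset of those
events whose text carries the target symptom; symptoms are detected from
positive, linked text mentions only (either a dictionary ADE-relevance
flag or an ICD prefix), never from billing codes — symptoms
characteristically live in the narrative. The co-frequency ratio is the
elementwise quotient `D/M`; cells with `M` below `max(1, min_events)`
are masked (`NA`), not reported as 0, because an unobserved pair has no
ratio. No temporal ordering between the orders and the symptom mention
is required within a hospitalization; with discharge-summary
granularity there is no defensible way to impose one. The ratio is a
screening statistic, not a causal estimate — `pair_odds_ratio()` is
provided as an optional refinement but is off by default.

## The synthetic corpus

`simulate_ehr()` generates dictionaries, tables, documents and ground
truth with the statistical structure the analysis assumes:

* Events per patient are zero-truncated Poisson (every patient has at
  least one discharge) with mean 3.12, the events-per-patient ratio of a
  large real hospital cohort; filled diagnosis columns per event are
  zero-truncated Poisson with mean 4, capped at the 24 available
  columns.
* Disease concepts carry synthetic ICD-10-shaped codes (a letter, 2–3
  digits, half with a subcategory digit, so prefix semantics are
  exercised); each dictionary entry carries 7 binary ADE-relevance
  flags (dictionary samples in the field sometimes describe 8 relevance
  labels; the count is configurable via `n_ade_flags`, with 7 as the
  default matching the "seven popular adverse effects" convention).
* Documents interleave planted mention surfaces with filler tokens.
  Planted mentions are negated with probability `p_negated` (a cue
  token directly after the surface), perturbed with exactly one random
  character edit with probability `p_surface_perturb` (one edit keeps
  the normalized score of an 8-character surface at or above 87.5, so
  perturbed plants remain linkable at cutoff 70 by construction), or
  drawn out-of-dictionary with probability `p_out_of_dictionary`.
  With probability `p_echo` (default 0.5) a mention echoes a concept
  from the event's own structured record, which gives the three sources
  realistic overlap for the cohort and common-count analyses.
* Alphabets are disjoint by design: surfaces are lowercase-letter
  strings (8–12 characters), fillers are 12-digit strings, cues are
  uppercase. This guarantees the substring tagger can never match
  across token boundaries, and a 12-character filler between
  consecutive mentions keeps one mention's cue outside the next
  mention's negation window — ground truth is therefore exact, not
  approximate.

Identical configuration and seed reproduce byte-identical corpora; each
generator stage derives its own sub-seed so stages can be re-run
individually. Default sizes (100 patients, 50 disease and 30 drug
concepts, 3 surfaces per concept, ~20 mentions per document, ~8 orders
per event) give corpora of a few hundred events and tens of entities
per event — the right order of magnitude per event for discharge
summaries, though not a calibrated claim.

What the generator deliberately does **not** emulate: natural clinical
language (documents are token sequences, so passing tests demonstrate
correctness of the computation, not NER quality on real Japanese or
English notes), morphological variation beyond single character edits,
document-length and mention-burstiness heavy tails, coding practice
biases in the diagnosis columns, and temporal structure within an
admission. Results on real data therefore depend on the external NER
model's quality in a way these tests cannot show.

## Numerical conventions and degenerate inputs

* Empty strings have no defined similarity score and raise errors;
  empty dictionaries cannot be linked against.
* An empty mention set yields `NA` normalized rates, not 0.
* Zero-order events simply produce no medication rows; a corpus with
  disjoint table/text event IDs aligns to an empty corpus with a
  warning rather than an error.
* Ranking ties in top-k tables break by concept ID; the best-matching
  dictionary surface reported for a link breaks ties lexicographically.
  All tie-breaks are deterministic so that reruns are byte-identical.
* Through-origin regression requires at least two points per group and
  strictly positive frequencies (the display is logarithmic).

## Problem sizes

The test suite and the acceptance script run on synthetic corpora of
roughly 30–500 events: clean-recovery checks use ~500 events (160
patients), the frequency-recount property uses 50 corpora of ~10–40
events, linker–oracle equivalence uses 1,000 random queries against
dictionaries of up to 200 surfaces, and the planted ADE signal uses 250
pair-exposed events, sized so that the binomial standard error of the
recovered ratio is ~3%. These sizes were chosen to make the checks
sharp (multiset-exact where exactness is claimed, a 3-standard-error
band where the quantity is stochastic) while keeping a full run in the
minutes range on one CPU.

## Known limitations

* The dictionary tagger finds only exact (post-NFKC) surface matches;
  recall on perturbed or paraphrased mentions is the external NER
  model's job. Normalized-rate experiments that involve perturbed or
  out-of-dictionary surfaces therefore use the annotation-import route.
* Ambiguous surfaces are excluded rather than disambiguated; corpora
  with heavily ambiguous vocabularies will undercount.
* The co-frequency ratio conflates indication and adverse effect; it
  ranks hypotheses for expert review, nothing more.
* ICD prefix matching cannot express exclusions ("E11 but not E110").
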