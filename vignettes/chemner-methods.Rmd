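---
title: "Methods: grammar- and dictionary-driven chemical entity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grammar- and dictionary-driven chemical entity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemner)
```

## The recognition model

`chemner` recognizes chemical mentions by *expectation*: every entity is
the longest span at its position accepted by one of a set of named
resources. A resource is either a regular grammar compiled to a
deterministic finite-state machine, or a dictionary (lexicon) compiled
to a trie-shaped machine of the same form. The two assumptions this
rests on are (i) that systematic nomenclature is, for matching purposes,
a regular language — which we enforce syntactically by rejecting any
grammar whose rule-reference graph contains a cycle — and (ii) that
trivial names are a closed vocabulary that can be curated offline.
Neither assumption is fully true of chemistry at large (nesting depth in
IUPAC names is unbounded in principle, and novel trivial names appear
constantly); the post-processing stages below exist precisely to soften
the second assumption, and bracket tracking to soften the first.

Because bracket nesting cannot be captured by a finite-state machine, a
separate stack-based tracker runs alongside matching: a candidate span
is only accepted when the brackets `( ) [ ] { }` seen inside it end
balanced and well nested. A mismatched closer invalidates every longer
prefix, so matching stops there.

### The two-level automaton

For context-dependent nomenclature a flat machine either over-accepts or
explodes in size. The layered automaton keeps a *master* machine whose
transition labels are whole sub-machines; the master holds global
context (what may follow a substituent here) while sub-machines consume
actual characters. Matching is a small dynamic program over (master
state, text position) pairs in which each sub-machine reports *all* of
its accept lengths at a position, not just the longest — taking only the
longest would miss segmentations such as a substituent that is a prefix
of another. The shipped semi-systematic grammar
(`substituent substituent* parent`) demonstrates this; a test pins the
layered machine's language to that of the fully inlined flat
compilation.

### Matching policy

All positions are candidate starts for chemical resources, because
post-hoc boundary extension presupposes sub-word matches. Resources
whose terms are ordinary words (blocking lists, include lists) instead
require token boundaries. Overlaps are resolved longest-span-first, with
equal spans going to the resource earlier in the manifest; this
tie-break is not specified by the method itself, and manifest order was
chosen because it is visible and auditable in configuration. Spans lying
inside a blocking resource's match are suppressed and blocking matches
are never emitted.

The sum-formula machine carries a digit requirement (more than two digit
characters) applied when candidates are collected. Treating the
restriction as part of the resource rather than a late filter matters in
practice: a bare element-symbol match (`S` in `(S)-...`) would otherwise
survive long enough to be extended and merged into neighboring spans
before a late filter could discard it. The standalone
`filter_sum_formula()` operation is also applied at the end of the
pipeline, where it is a no-op for the built-in setup but covers
externally supplied entity tables.

## Spelling correction

Correction searches for the minimum-cost edit sequence turning a token
into a string the target machine accepts, by best-first (Dijkstra)
search over (automaton state, token position, generic-edit budget
spent). Generic insertions, deletions, substitutions and transpositions
cost 1 each and are limited by `max_unparameterized_edits`;
parameterized error classes — OCR confusions (`rn`↔`m`, `l`↔`1`,
`O`↔`0`), the `floro`→`fluoro` typo, erroneous space at digit–letter
boundaries, comma-for-period between digits, and hyphen insertion —
cost 0.3 and are not counted against that budget. The numeric costs are
conventions, not measurements: what the tests pin is *optimality*
(agreement with an exhaustive dynamic-programming minimization over the
lexicon) and the contract that a zero budget admits parameterized
corrections only. Equal-cost corrections tie-break by fewest edits, then
earliest first edit, then lexicographically smallest corrected string —
a total order chosen so results are reproducible; the method itself only
requires cost-based preference. Defaults
(`max_unparameterized_edits = 0`, `min_entity_length = 6`) reflect that
curated abstracts contain few real errors: by default only the known
error classes fire, and only on tokens long enough that a correction is
unlikely to be coincidence. Correction of a layered resource runs
against a flattened machine compiled from the same grammar (same
language, simpler search space).

## Boundary refinement

The five modification steps run in fixed order: extension, trimming,
merging, stop-term removal (which re-applies trimming), and the
S-transferase special case.

Extension grows an entity until whitespace, a mismatched bracket, or a
non-chemical English/noise word; hyphen-joined segments are crossed
unless the segment beyond the hyphen is such a word (`leucine-to-proline`
therefore stays two entities, stopped by `to`). Three boundary details
are this package's own resolutions of points the method statement leaves
open:

* Sentence punctuation (`, . ; : ! ?`) is treated as
  whitespace-equivalent. Without this, every sentence-final entity would
  absorb its period.
* An entity entirely enclosed in a balanced bracket pair retries
  extension from outside the brackets and keeps those boundaries only if
  they reach *beyond* the pair — `poly(ethylene glycol)` grows to the
  full name, while a merely parenthesized mention keeps its own span.
* Two entities joined by a single hyphen where both denote specific
  compounds (concrete structures, a per-resource flag) are not extended
  across that hyphen and not merged: `Resorcinol-Formaldehyde` usually
  names a mixture.

Merging combines overlapping entities unconditionally and
space-separated adjacent entities unless the instance-of table relates
them in either direction (`genistein isoflavonoid` stays split). The
merged record keeps a composite class and resource (constituents joined
by `+`) with the `merged` flag set, so provenance survives; whether a
merged mention should instead take its head word's class is genuinely
unclear, and the composite preserves the information needed to decide
later. The instance-of table ships as a small two-column fixture in the
format a real ontology export would use.

The hyphenated spelling `glutathione-S-transferase` is handled by
ordinary extension (which crosses `-S` and stops at the English word
`transferase`); the spaced spelling needs the special case, which adds a
separate `S` entity carrying the glutathione entity's class and
resource.

## Abbreviations

Detection considers each entity as a long form and checks six surface
patterns; a candidate short form must be at least 3 characters, have
balanced brackets, not be a Roman numeral or a compound-identifier shape
(`1a`), and pass the character-correspondence test: every alphanumeric
of the short form appears in order in the long form, the first at a
word-initial position. The equivalence map rewrites long-form substrings
(longest first) before the test, admitting token-level abbreviations
such as `MeHg` for `methylmercury`. Accepted short forms are annotated
at the defining occurrence and at every further exact-string occurrence
in the section (case-sensitive, at non-alphanumeric boundaries — the
propagation string is taken literally).

The reverse direction removes false positives: an entity sitting in
defining parenthetical position is postulated to be a short form, the
classic window of `min(|SF| + 5, 2|SF|)` preceding words is searched for
the shortest satisfying long form, and if that long form neither is nor
overlaps an entity, the entity and all same-text instances are removed.
One additional condition proved necessary: the candidate must contain an
uppercase letter or digit. The in-order character test is weak enough
that an ordinary lowercase word in brackets (`(solder, ...)`) will
almost always find a spurious "long form" in preceding prose; genuine
chemistry abbreviations (`cGMP`, `THF`) all have abbreviation-like
shape.

## Curation

Filters run in the order they are conventionally stated, and the first
failure becomes the record's reason code — the order matters (a
3-character term starting with a hyphen reports `too_short`, because the
length test precedes the hyphen test) and is fixed for auditability.
Qualifier stripping happens early so downstream filters judge the
cleaned term. The shipped English word list (~680 words), qualifier
vocabularies, dubious-word list and catalogue-number patterns are
deliberately minimal supersets of well-known examples; each is a
config-replaceable file, and a production deployment would substitute
full lists. Structure-derived limits (tetrasaccharide, hexadecapeptide)
consume pre-computed lengths in the input records — structure perception
is out of scope for this package.

## Evaluation

Scoring is mention-level and micro-averaged: a prediction is correct iff
a gold annotation has the identical document, section and half-open
span; class labels are carried but not compared. Degenerate denominators
follow the usual conventions (precision and recall are 1 when their
denominator is 0; F1 is 0 when P + R = 0). Include-list derivation is
greedy-sequential over candidates ordered by descending false-negative
frequency (ties lexicographic), keeping a term only when corpus F1
strictly increases; a batch variant would be order-free but
irreproducible when candidates interact.

## The synthetic corpus generator

`generate_corpus()` emulates title/abstract documents: lower-case filler
prose with injected mentions drawn from the resources' own languages
(lexicon terms sampled directly, grammar strings by random accepting
walks, sum formulae resampled until they satisfy the digit rule), at a
default density of 12 mentions per 100 tokens — roughly the mention
density of chemistry abstracts. Gold spans are recorded at injection
time. Optional perturbations: a proportion of eligible mentions receives
one random character edit (recorded, and vetted so that a one-edit
budget recovers exactly the original surface), and a proportion receives
a parenthetical abbreviation definition in one of the six patterns, with
one further standalone short-form instance placed later in the document.

The generator enforces, by construction, that the gold standard is
exactly recoverable: filler words are vetted against every resource (no
exact match anywhere inside them, no word of a multi-word term, and —
when typos are enabled — no reachability within one generic edit of any
correction-enabled resource), entities are never injected adjacent to
one another (they would legitimately merge), and short forms are vetted
against the resources and the short-form validity rules. A noise-free
corpus therefore scores P = R = F1 = 1 through the *full* pipeline, and
that is what the end-to-end tests assert.

What this does and does not show: passing on generated corpora
demonstrates that the pipeline's stages compose without destroying
correct annotations and that correction restores recall under the noise
model it was designed for. It says nothing about coverage of real
chemical language — the shipped grammars are a demonstrative subset (a
handful of rules against the hundreds in a production nomenclature
grammar), the dictionaries are toy-sized, and real abstracts contain
case variation, tokenization quirks and ambiguity the generator does not
emulate. Headline scores on a real benchmark corpus are therefore out of
scope here.

## Numerical and degenerate-input choices

* Offsets are 0-based, half-open, in Unicode code points of the original
  text; one-to-many normalizations (œ → oe) give every output character
  the full source range of its source character, and a span mapped back
  to source is the minimal range covering all contributing characters.
* Automata are determinized but not minimized; the language-equivalence
  tests are the contract, and toy-scale machines gain nothing from
  minimization.
* Empty matches are never returned; a match must consume at least one
  character.
* Correction search caps its expansion count (200k nodes) as a safety
  valve; toy resources stay orders of magnitude below it. Cost
  comparisons use an absolute tolerance of 1e-9.
* `curate_synonym` on an empty-after-trimming entity, evaluation with
  empty prediction/gold sets, documents with empty sections, and
  zero-row entity tables all take defined paths exercised by tests.

## Problem sizes used by the checks

The automaton-versus-oracle comparison enumerates all strings up to
length 8 over adversarially chosen 3–4 symbol sub-alphabets that include
accepting strings (about 137k strings across the four grammars),
together with full language enumerations and single-edit boundary
perturbations; full terminal alphabets up to length 8 would be ~10^9
strings, which buys no additional boundary coverage. Bracket validity is
checked on 10,000 random bracketed strings; correction optimality on 200
random lexicon/candidate pairs against the exhaustive dynamic program;
end-to-end recovery on a 100-document noise-free corpus and a
40-document corpus with a 20% typo rate.

## Known limitations

* The grammars and dictionaries shipped are demonstrative; recall on
  real text requires real resources (the manifest format accepts them).
* Case handling of propagated abbreviations is exact-string; plural
  short forms are not matched.
* The English word list is small; extension and curation quality on real
  text improves directly with a fuller list.
* Confidence scores in the prediction output are constant; the engine
  ranks nothing.
* Documents are processed independently; no cross-document abbreviation
  memory.
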