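# chemner

Grammar- and dictionary-driven chemical named-entity recognition for R.

Most chemical NER systems are statistical taggers: when they mislabel a
mention there is no artifact to fix. `chemner` takes the opposite,
knowledge-driven approach. Systematic nomenclature is described by
**regular grammars** compiled to deterministic finite-state machines;
trivial (unsystematic) names live in **curated dictionaries** compiled to
the same scannable form. Every emitted entity names the grammar or
dictionary that produced it, so a false positive can be pin-pointed to a
specific resource and corrected there, and a false negative fixed by
adding a rule or a term. Because recognition is driven by what is
*expected*, near-miss spellings can be corrected against the expected
vocabulary — which also helps downstream name-to-structure resolution.

The package is aimed at text-mining and cheminformatics developers who
need auditable chemical mention extraction from abstracts, patents or
full text, and at anyone studying dictionary-based NER methodology.

## What is inside

* **Normalization** — typographic Unicode variants (curly quotes, primes,
  dashes, ligatures) are folded to canonical characters, and light XML
  markup is stripped (`<p>H<sub>2</sub>O</p>` → `H2O`), while a
  per-character index map lets every entity be reported in original
  source coordinates.
* **Grammar engine** — a rule dialect (`alkane : alkaneStem 'ane'`) is
  parsed, checked for regularity (a rule may not reference itself),
  compiled via Thompson construction and subset determinization. For
  nomenclature whose context matters, a **two-level automaton** labels the
  transitions of a master machine with whole sub-machines, so the same
  `ethyl` matcher serves both `ethylbenzene` and `acetic acid ethyl
  ester` contexts. During matching a bracket tracker admits only spans
  whose `( ) [ ] { }` end balanced and well nested.
* **Lexicons** — named term lists with per-lexicon policy: entity class,
  case handling (including first-letter-insensitive for sentence-initial
  capitals), *matching* vs *blocking* role (blocking matches only
  suppress other entities), and token-boundary enforcement.
* **Lexicon curation** — the filter-and-expand pipeline that turns a raw
  synonym dump into a precise dictionary: bracket balance, qualifier
  stripping (`"(INN)"`), biopolymer limits (tetrasaccharide /
  hexadecapeptide and longer), English-word and dubious-word tests,
  catalogue-number/PDB/InChI-key recognizers, and variant expansion
  (`KF 17837` → `KF-17837`, `KF17837`; `alpha-` → `α-`). Each rejection
  carries a machine-readable reason code.
* **Spelling correction** — lowest-cost edit sequences
  (insertion/deletion/substitution/transposition) transforming a token
  into a string the automaton accepts, with cheap *parameterized* error
  classes (OCR confusions like `rn`↔`m`, the `floro`→`fluoro` typo,
  erroneous space, comma-for-period, missing hyphen) that do not consume
  the generic-edit budget.
* **Entity modification** — five post-processing steps: boundary
  extension (`nornicotine` → `(S)-nornicotine`), trimming of
  non-essential modifiers (`colloidal silver` → `silver`), merging
  (`monoterpene pyridine alkaloids`) guarded by an instance-of table
  (`genistein isoflavonoid` stays two mentions because genistein *is* an
  isoflavonoid), stop-term removal (`gold`), and the
  glutathione-S-transferase special case.
* **Abbreviations** — a Schwartz–Hearst-style procedure over six surface
  patterns (`Tetrahydrofuran (THF)` … `THF = tetrahydrofuran`) with an
  equivalence map (`mercury`→`Hg`, so `MeHg` abbreviates
  `methylmercury`); detected short forms propagate document-wide, and
  entities that turn out to abbreviate *non*-entities (`cGMP` after
  "current good manufacturing practice (cGMP)") are removed.
* **Evaluation** — micro-averaged mention-level precision/recall/F1 on
  exact spans, pooled over documents:
  P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R), with TSV dialects for
  gold and predictions, and a greedy include-list derivation that keeps a
  candidate term only if it strictly increases corpus F1.
* **Fixtures** — demonstrative grammars (CID, CAS number, registry
  number, sum formula with its more-than-two-digits restriction, alkanes,
  a layered semi-systematic grammar) and toy dictionaries, plus a seeded
  synthetic-corpus generator with controlled typo and abbreviation rates,
  so the whole pipeline is testable offline.

## Worked example

```r
library(chemner)
res <- builtin_resources()
doc <- source_document("doc1",
  title = "nornicotine exposure in smokers",
  abstract = paste("the (S)-nornicotine level rose after tetrahydrofuran (THF)",
                   "exposure. THF and 2634-33-5 with C20H25NO6 were detected,",
                   "but CDK2 and gold nanoparticles were not annotated."))
out <- run_pipeline(doc, res, pipeline_config())
out$entities[, c("section","start","end","text","class","resource")]
```

```
 section start end            text      class    resource
       A     4  19 (S)-nornicotine   chemical        drug
       A    37  52 tetrahydrofuran   chemical        drug
       A    54  57             THF   chemical        drug
       A    69  72             THF   chemical        drug
       A    77  86       2634-33-5 identifier         cas
       A    92 101       C20H25NO6    formula sum_formula
       T     0  11     nornicotine   chemical        drug
```

Reading the output: `nornicotine` was found by the `drug` dictionary and
extended over its stereo-prefix to `(S)-nornicotine`; the parenthetical
defined `THF`, whose second occurrence was annotated by propagation (the
`abbreviation`/`propagated` flags in the full table record this); the
CAS number and sum formula each name the grammar that matched them;
`CDK2` is *not* a sum formula under the more-than-two-digits rule, and
`gold nanoparticles` reduces to the stop term `gold` and is excluded.
Offsets are 0-based half-open code-point positions within each section
(`T` title, `A` abstract).

Scoring a generated corpus against its own gold standard:

```r
corp <- generate_corpus(fixture_spec(seed = 1, n_docs = 20), res)
evaluate(run_pipeline(corp$docs, res)$entities, corp$gold)
#> tp=136 fp=0 fn=0  P=1.0000 R=1.0000 F1=1.0000
```

## Command line

A thin wrapper is installed at `inst/scripts/chemner`:

```sh
chemner gen-fixtures --seed 1 --out fx/         # corpus + resource files
chemner annotate --manifest fx/manifest.yaml --in fx/docs.tsv --out pred.tsv
chemner evaluate --gold fx/gold.tsv --pred pred.tsv
chemner curate-dict --in raw.tsv --out lexicon.txt --audit audit.tsv
```

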