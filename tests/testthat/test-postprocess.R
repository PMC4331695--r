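res <- builtin_resources()
wl <- word_lists()

annotate_text <- function(txt) {
  annotate(source_document("x", abstract = txt), res)
}

test_that("extension grows entities to bracket- and hyphen-joined context", {
  txt <- "the (S)-nornicotine was pure"
  e <- extend_entities(annotate_text(txt), txt, wl)
  expect_true("(S)-nornicotine" %in% e$text)

  # already whitespace-bounded entities are fixed points
  txt2 <- "gave aspirin now"
  e2 <- extend_entities(annotate_text(txt2), txt2, wl)
  expect_identical(e2$text, "aspirin")
  expect_false(any(e2$extended))
})

test_that("specific-compound pairs joined by a hyphen stay separate", {
  txt <- "cured Resorcinol-Formaldehyde resins"
  e <- extend_entities(annotate_text(txt), txt, wl,
                       specific_resources = "drug")
  expect_setequal(e$text, c("Resorcinol", "Formaldehyde"))

  # without the specific-compound status on both sides, fusion proceeds
  e2 <- extend_entities(annotate_text(txt), txt, wl,
                        specific_resources = character(0))
  expect_true("Resorcinol-Formaldehyde" %in% e2$text)
})

test_that("extension stops at noise words inside hyphen chains", {
  txt <- "a leucine-to-proline substitution"
  e <- extend_entities(annotate_text(txt), txt, wl)
  expect_setequal(e$text, c("leucine", "proline"))
})

test_that("enclosed-bracket retry reaches beyond the brackets when longer", {
  lex <- build_lexicon("ethylene glycol", "t")
  rs <- resource_set(resource("t", lex), word_lists = wl)
  txt <- "in poly(ethylene glycol) solution"
  e <- annotate(source_document("x", abstract = txt), rs)
  expect_identical(e$text, "ethylene glycol")
  e2 <- extend_entities(e, txt, wl)
  expect_identical(e2$text, "poly(ethylene glycol)")

  # merely parenthesized mentions keep their own boundaries
  txt2 <- "solvent (ethylene glycol) was used"
  e3 <- annotate(source_document("y", abstract = txt2), rs)
  e4 <- extend_entities(e3, txt2, wl)
  expect_identical(e4$text, "ethylene glycol")
})

test_that("trimming removes non-essential boundary modifiers", {
  txt <- "added colloidal silver today"
  e <- entity_rows("x", "A", 6L, 22L, "colloidal silver", "element",
                   "element")
  out <- trim_entities(e, txt, wl)
  expect_identical(out$text, "silver")
  expect_true(out$trimmed)

  txt2 <- "the methyl group reacted"
  e2 <- entity_rows("x", "A", 4L, 16L, "methyl group", "chemical", "semi")
  expect_identical(trim_entities(e2, txt2, wl)$text, "methyl")

  txt3 <- "pure aspirin here"
  e3 <- entity_rows("x", "A", 5L, 12L, "aspirin", "chemical", "drug")
  out3 <- trim_entities(e3, txt3, wl)
  expect_identical(out3$text, "aspirin")
  expect_false(out3$trimmed)

  # an entity that trims away entirely is removed
  txt4 <- "the colloidal dye faded"
  e4 <- entity_rows("x", "A", 4L, 17L, "colloidal dye", "chemical", "drug")
  expect_identical(nrow(trim_entities(e4, txt4, wl)), 0L)
})

test_that("adjacent entities merge unless instance-of forbids it", {
  txt <- "novel monoterpene pyridine alkaloids were isolated"
  e <- merge_entities(annotate_text(txt), txt, wl)
  expect_true("monoterpene pyridine alkaloids" %in% e$text)
  merged <- e[e$text == "monoterpene pyridine alkaloids", ]
  expect_true(merged$merged)
  expect_match(merged$resource, "\\+")

  txt2 <- "the genistein isoflavonoid content"
  e2 <- merge_entities(annotate_text(txt2), txt2, wl)
  expect_setequal(e2$text, c("genistein", "isoflavonoid"))

  # single entities pass through unchanged
  txt3 <- "only aspirin here"
  e3 <- annotate_text(txt3)
  expect_identical(merge_entities(e3, txt3, wl)$text, "aspirin")
})

test_that("merged output never contains overlapping spans", {
  set.seed(9)
  corp <- generate_corpus(fixture_spec(seed = 9, n_docs = 5), res)
  for (doc in corp$docs) {
    for (si in seq_len(nrow(doc$sections))) {
      txt <- doc$sections$text[si]
      e <- annotate(doc, res)
      e <- e[e$section == doc$sections$label[si], ]
      m <- merge_entities(extend_entities(e, txt, wl), txt, wl)
      if (nrow(m) > 1) {
        m <- m[order(m$start), ]
        expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
      }
    }
  }
})

test_that("stop-term entities are removed after re-trimming", {
  txt <- "coated gold nanoparticles imaged"
  e <- entity_rows("x", "A", 7L, 25L, "gold nanoparticles", "element",
                   "element")
  expect_identical(nrow(remove_stop_entities(e, txt, wl)), 0L)

  # stop rule applies only to the full remaining text
  txt2 <- "added gold chloride salt"
  lex <- build_lexicon("gold chloride", "t")
  rs <- resource_set(resource("t", lex), word_lists = wl)
  e2 <- annotate(source_document("x", abstract = txt2), rs)
  expect_identical(remove_stop_entities(e2, txt2, wl)$text, "gold chloride")

  expect_identical(nrow(remove_stop_entities(empty_entities(), "", wl)), 0L)
})

test_that("the S of glutathione S-transferase is annotated by proximity", {
  txt <- "purified glutathione S-transferase activity"
  e <- modify_entities(annotate_text(txt), txt, wl)
  expect_true("S" %in% e$text)
  s_row <- e[e$text == "S", ]
  expect_identical(s_row$resource, "drug") # inherited from glutathione

  txt2 <- "purified glutathione-S-transferase activity"
  e2 <- modify_entities(annotate_text(txt2), txt2, wl)
  expect_true("glutathione-S" %in% e2$text)

  txt3 <- "plain glutathione level"
  e3 <- modify_entities(annotate_text(txt3), txt3, wl)
  expect_identical(e3$text, "glutathione")
})

test_that("the five-step pipeline is idempotent", {
  texts <- c(
    "the (S)-nornicotine was pure",
    "cured Resorcinol-Formaldehyde resins",
    "a leucine-to-proline substitution",
    "novel monoterpene pyridine alkaloids were isolated",
    "coated gold nanoparticles imaged",
    "purified glutathione-S-transferase activity",
    "gave vancomycin with red phosphorus"
  )
  for (txt in texts) {
    once <- modify_entities(annotate_text(txt), txt, wl,
                            specific_resources = "drug")
    twice <- modify_entities(once, txt, wl, specific_resources = "drug")
    expect_identical(twice[order(twice$start), c("start", "end", "text")],
                     once[order(once$start), c("start", "end", "text")],
                     label = txt)
  }
})

test_that("extension never crosses whitespace or unmatched brackets", {
  set.seed(31)
  corp <- generate_corpus(fixture_spec(seed = 31, n_docs = 5), res)
  for (doc in corp$docs) {
    for (si in seq_len(nrow(doc$sections))) {
      txt <- doc$sections$text[si]
      e <- annotate(doc, res)
      e <- e[e$section == doc$sections$label[si], ]
      ext <- extend_entities(e, txt, wl)
      for (i in seq_len(nrow(ext))) {
        span <- ext$text[i]
        expect_false(grepl("[ \t\n]", substr(span, 1, 1)))
        expect_true(oracle_brackets_balanced(span), label = span)
      }
    }
  }
})
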