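res <- builtin_resources()

test_that("grammar and lexicon entities carry resource attribution", {
  doc <- source_document(
    "d1", abstract = "the 2634-33-5 sample held vancomycin and C20H25NO6"
  )
  e <- annotate(doc, res)
  expect_setequal(e$text, c("2634-33-5", "vancomycin", "C20H25NO6"))
  expect_identical(e$resource[e$text == "2634-33-5"], "cas")
  expect_identical(e$resource[e$text == "vancomycin"], "drug")
  expect_identical(e$resource[e$text == "C20H25NO6"], "sum_formula")
  expect_identical(e$class[e$text == "C20H25NO6"], "formula")
  # the entity text always equals the source slice
  ab <- doc$sections$text[doc$sections$label == "A"]
  for (i in seq_len(nrow(e))) {
    expect_identical(substr(ab, e$start[i] + 1, e$end[i]), e$text[i])
  }
})

test_that("removing a resource removes exactly its attributed entities", {
  doc <- source_document("d2", abstract = "vancomycin beside CID:99 here")
  e_all <- annotate(doc, res)
  expect_setequal(e_all$resource, c("drug", "cid"))
  slim <- resource_set(
    Filter(function(r) r$name != "cid", res$resources),
    word_lists = res$word_lists, equivalence = res$equivalence
  )
  e_slim <- annotate(doc, slim)
  expect_false(any(e_slim$resource == "cid"))
  expect_setequal(e_slim$text, "vancomycin")
})

test_that("blocking lexicon matches suppress entities without emitting any", {
  doc <- source_document("d3", abstract = "insulin was administered")
  e <- annotate(doc, res)
  expect_identical(nrow(e), 0L)
  # blocking never contributes entities across a full run
  corp <- generate_corpus(fixture_spec(seed = 2, n_docs = 3), res)
  out <- run_pipeline(corp$docs, res)
  expect_false(any(out$entities$resource == "biopolymer_block"))
})

test_that("empty documents yield no entities", {
  expect_identical(nrow(annotate(source_document("d4", abstract = " "), res)),
                   0L)
})

test_that("final annotation output has no overlapping spans", {
  doc <- source_document(
    "d5",
    abstract = "cyclic guanosine monophosphate with guanosine and ethylbenzene"
  )
  e <- annotate(doc, res)
  expect_true("cyclic guanosine monophosphate" %in% e$text)
  e <- e[order(e$start), ]
  if (nrow(e) > 1) {
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("sum-formula digit restriction drops short formula-like strings", {
  doc <- source_document("d6", abstract = "CDK2 and CaCo and H2O and MgSO4")
  e <- annotate(doc, res)
  expect_identical(nrow(e), 0L)
  doc2 <- source_document("d7", abstract = "C20H25NO6 measured")
  expect_identical(annotate(doc2, res)$text, "C20H25NO6")

  # the standalone filter on already-built entities
  ents <- entity_rows("x", "A", c(0L, 10L, 20L), c(4L, 13L, 29L),
                      c("CDK2", "H2O", "C20H25NO6"), "formula",
                      "sum_formula")
  kept <- filter_sum_formula(ents)
  expect_identical(kept$text, "C20H25NO6")
})

test_that("include list adds entities and stop list removes them", {
  inc <- build_lexicon("chikusetsusaponin L10", "include_list",
                       entity_class = "chemical", token_boundary = TRUE)
  doc <- source_document("d8",
                         abstract = "isolated chikusetsusaponin L10 sample")
  e0 <- annotate(doc, res)
  e1 <- apply_include_stop_lists(e0, inc, NULL, doc)
  expect_true("chikusetsusaponin L10" %in% e1$text)
  expect_identical(e1$resource[e1$text == "chikusetsusaponin L10"],
                   "include_list")

  # empty lists leave entities unchanged
  e2 <- apply_include_stop_lists(e0, NULL, NULL, doc)
  expect_identical(nrow(e2), nrow(e0))

  stop_lex <- build_lexicon("vancomycin", "stop_list")
  doc2 <- source_document("d9", abstract = "gave vancomycin dose")
  e3 <- annotate(doc2, res)
  expect_true("vancomycin" %in% e3$text)
  e4 <- apply_include_stop_lists(e3, NULL, stop_lex, doc2)
  expect_false("vancomycin" %in% e4$text)
})

test_that("spelling correction annotates near-miss tokens with provenance", {
  doc <- source_document("d10", abstract = "dosed with vancomicin today")
  e0 <- annotate(doc, res, correction = FALSE)
  expect_identical(nrow(e0), 0L)
  budget <- correction_config(TRUE, 1, 5)
  e1 <- annotate(doc, res, correction = TRUE, correction_override = budget)
  expect_identical(e1$text, "vancomicin")
  expect_identical(e1$resource, "drug")
  expect_match(e1$corrections, "vancomicin -> vancomycin")
})

test_that("annotation is deterministic across repeated runs", {
  doc <- source_document(
    "d11", abstract = "CID:7732 with pig iron and TMEDA plus ethylbenzene"
  )
  expect_identical(annotate(doc, res), annotate(doc, res))
})
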