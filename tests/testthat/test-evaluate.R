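test_that("micro-averaged counts follow the closed-form definitions", {
  gold <- data.frame(
    doc_id = c("a", "a", "b", "c"), section = "A",
    start = c(0L, 10L, 5L, 7L), end = c(4L, 14L, 9L, 12L),
    text = "x", class = "chemical", stringsAsFactors = FALSE
  )
  pred <- data.frame(
    doc_id = c("a", "a", "b", "c"), section = "A",
    start = c(0L, 10L, 5L, 8L), end = c(4L, 14L, 9L, 13L),
    stringsAsFactors = FALSE
  )
  ev <- evaluate(pred, gold)
  expect_identical(c(ev$tp, ev$fp, ev$fn), c(3L, 1L, 1L))
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$f1, 0.75)

  # perfect self-evaluation
  ev2 <- evaluate(gold, gold)
  expect_equal(c(ev2$precision, ev2$recall, ev2$f1), c(1, 1, 1))

  # off-by-one spans count as FP + FN (exact-span rule)
  p3 <- gold[1, ]
  p3$start <- p3$start + 1L
  ev3 <- evaluate(p3, gold[1, ])
  expect_identical(c(ev3$tp, ev3$fp, ev3$fn), c(0L, 1L, 1L))

  # degenerate denominators
  ev4 <- evaluate(pred[0, ], gold[0, ])
  expect_equal(c(ev4$precision, ev4$recall), c(1, 1))
  ev5 <- evaluate(pred[0, ], gold)
  expect_equal(ev5$precision, 1)
  expect_equal(ev5$recall, 0)
  expect_equal(ev5$f1, 0)
})

test_that("duplicate identical predictions are counted once with a warning", {
  gold <- data.frame(doc_id = "a", section = "A", start = 0L, end = 4L,
                     text = "x", class = "c", stringsAsFactors = FALSE)
  pred <- rbind(gold[, 1:4], gold[, 1:4])
  expect_warning(ev <- evaluate(pred, gold), "duplicate")
  expect_identical(c(ev$tp, ev$fp), c(1L, 0L))
})

test_that("pooled micro counts equal the sum of per-document counts", {
  set.seed(4)
  corp <- generate_corpus(fixture_spec(seed = 4, n_docs = 6))
  res <- builtin_resources()
  out <- run_pipeline(corp$docs, res)
  total <- evaluate(out$entities, corp$gold)
  per_doc <- lapply(unique(corp$gold$doc_id), function(id) {
    evaluate(out$entities[out$entities$doc_id == id, ],
             corp$gold[corp$gold$doc_id == id, ])
  })
  expect_identical(total$tp, sum(vapply(per_doc, `[[`, integer(1), "tp")))
  expect_identical(total$fn, sum(vapply(per_doc, `[[`, integer(1), "fn")))
})

test_that("annotation TSV dialects round-trip", {
  ents <- entity_rows("doc1", "A", c(0L, 12L), c(4L, 20L),
                      c("abcd", "efghijkl"), "chemical", "drug")
  pf <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(ents, pf)
  back <- read_predictions(pf)
  expect_identical(back$doc_id, c("doc1", "doc1"))
  expect_identical(back$start, c(0L, 12L))
  expect_identical(back$end, c(4L, 20L))

  gf <- withr::local_tempfile(fileext = ".tsv")
  write_gold(entities_as_gold(ents), gf)
  gold <- read_gold(gf)
  expect_identical(gold$start, c(0L, 12L))
  expect_identical(gold$text, c("abcd", "efghijkl"))
  ev <- evaluate(back, gold)
  expect_equal(ev$f1, 1)
})

test_that("include-list derivation keeps helpful terms and drops ambiguous ones", {
  res <- builtin_resources()
  # "xenobioticol" is a gold entity unknown to every resource;
  # "between" appears as gold once but also in many non-entity contexts
  docs <- list(
    tiny_doc("i1", "we found xenobioticol in the sample between runs"),
    tiny_doc("i2", "more xenobioticol appeared between visits and between"),
    tiny_doc("i3", "nothing between here but vancomycin")
  )
  span_of <- function(doc, term, occurrence = 1L) {
    txt <- doc$sections$text[doc$sections$label == "A"]
    s <- as.integer(gregexpr(term, txt, fixed = TRUE)[[1]][occurrence]) - 1L
    c(s, s + nchar(term))
  }
  sp <- rbind(span_of(docs[[1]], "xenobioticol"),
              span_of(docs[[2]], "xenobioticol"),
              span_of(docs[[2]], "between", 2L),
              span_of(docs[[3]], "vancomycin"))
  gold <- data.frame(
    doc_id = c("i1", "i2", "i2", "i3"),
    section = "A",
    start = sp[, 1], end = sp[, 2],
    text = c("xenobioticol", "xenobioticol", "between", "vancomycin"),
    class = "chemical", stringsAsFactors = FALSE
  )
  eval_fn <- function(include_terms) {
    rs <- resource_set(
      res$resources,
      include_list = if (length(include_terms)) {
        build_lexicon(include_terms, "include_list",
                      entity_class = "chemical", token_boundary = TRUE)
      } else NULL,
      word_lists = res$word_lists, equivalence = res$equivalence
    )
    out <- run_pipeline(docs, rs)
    evaluate(out$entities, gold)
  }
  base_f1 <- eval_fn(character(0))$f1
  accepted <- derive_include_list(
    data.frame(term = c("xenobioticol", "between"), count = c(2L, 1L)),
    eval_fn
  )
  expect_identical(accepted, "xenobioticol")
  expect_gt(eval_fn(accepted)$f1, base_f1)
  # empty candidate set: empty include list
  expect_identical(derive_include_list(character(0), eval_fn), character(0))
})
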