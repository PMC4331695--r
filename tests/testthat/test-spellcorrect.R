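toy_terms <- c("ethanol", "ethanal", "methanol", "butanol", "propanol",
               "fluorobenzene", "chlorobenzene", "vancomycin", "morphine",
               "caffeine", "aspirin", "naproxen", "ibuprofen", "limonene")
toy_lex <- build_lexicon(toy_terms, "toy", case_policy = "sensitive")

test_that("known-typo and OCR classes correct at reduced cost", {
  cfg0 <- correction_config(TRUE, max_unparameterized_edits = 0,
                            min_entity_length = 4)
  r <- correct_against(toy_lex, "florobenzene", cfg = cfg0)
  expect_identical(r$corrected, "fluorobenzene")
  expect_equal(r$cost, 0.3)
  expect_identical(r$edits$type, "parameterized")
  expect_identical(r$n_unparameterized, 0L)

  r2 <- correct_against(toy_lex, "vancornycin", cfg = cfg0)
  expect_identical(r2$corrected, "vancomycin")
  expect_equal(r2$cost, 0.3)

  # with the generic budget at zero, a plain substitution is unreachable
  expect_null(correct_against(toy_lex, "ethanil", cfg = cfg0))
})

test_that("already-accepted candidates return zero-cost identity", {
  cfg <- correction_config(TRUE, 1, 4)
  r <- correct_against(toy_lex, "ethanol", cfg = cfg)
  expect_identical(r$corrected, "ethanol")
  expect_identical(nrow(r$edits), 0L)
  expect_identical(r$cost, 0)
})

test_that("disabled or too-short candidates are skipped, not failed", {
  expect_true(is_correction_skipped(
    correct_against(toy_lex, "ethanil", cfg = correction_config(FALSE))
  ))
  expect_true(is_correction_skipped(
    correct_against(toy_lex, "eth",
                    cfg = correction_config(TRUE, 1, min_entity_length = 6))
  ))
  expect_false(is_correction_skipped(NULL))
})

test_that("equal-cost ties break to the documented order", {
  lex <- build_lexicon(c("ethanol", "ethanal"), case_policy = "sensitive")
  r <- correct_against(lex, "ethanil",
                       cfg = correction_config(TRUE, 1, 4))
  # both targets are one substitution away; lexicographically smallest wins
  expect_identical(r$corrected, "ethanal")
  expect_equal(r$cost, 1)
})

test_that("corrected strings are always accepted and within budget", {
  set.seed(101)
  cfg <- correction_config(TRUE, 2, 4)
  for (i in 1:60) {
    base <- sample(toy_terms, 1)
    cand <- base
    for (k in seq_len(sample(1:2, 1))) {
      chars <- strsplit(cand, "")[[1]]
      p <- sample(length(chars), 1)
      chars[p] <- sample(letters, 1)
      cand <- paste(chars, collapse = "")
    }
    r <- correct_against(toy_lex, cand, cfg = cfg)
    if (!is.null(r)) {
      expect_true(accepts(toy_lex, r$corrected))
      expect_lte(r$n_unparameterized, 2L)
    }
  }
})

test_that("search cost equals exhaustive weighted-edit-distance minimization", {
  set.seed(77)
  model <- edit_cost_model()
  for (i in 1:40) {
    base <- sample(toy_terms, 1)
    op <- sample(c("sub", "del", "ins", "swap", "ocr", "none"), 1)
    chars <- strsplit(base, "")[[1]]
    cand <- switch(op,
      sub = {
        p <- sample(length(chars), 1)
        chars[p] <- sample(letters, 1)
        paste(chars, collapse = "")
      },
      del = paste(chars[-sample(length(chars), 1)], collapse = ""),
      ins = {
        p <- sample(length(chars) + 1, 1)
        paste(append(chars, sample(letters, 1), after = p - 1),
              collapse = "")
      },
      swap = {
        p <- sample(length(chars) - 1, 1)
        tmp <- chars[p]
        chars[p] <- chars[p + 1]
        chars[p + 1] <- tmp
        paste(chars, collapse = "")
      },
      ocr = sub("m", "rn", base),
      none = base
    )
    for (budget in 0:2) {
      cfg <- correction_config(TRUE, budget, 4)
      r <- correct_against(toy_lex, cand, model, cfg)
      oracle <- oracle_lexicon_cost(cand, toy_terms, model, budget)
      if (is.finite(oracle)) {
        expect_false(is.null(r), label = sprintf("%s budget %d", cand,
                                                 budget))
        expect_equal(r$cost, oracle,
                     label = sprintf("%s budget %d", cand, budget))
      } else {
        expect_null(r, label = sprintf("%s budget %d", cand, budget))
      }
    }
  }
})

test_that("enlarging the budget never increases the returned cost", {
  set.seed(55)
  for (i in 1:20) {
    base <- sample(toy_terms, 1)
    chars <- strsplit(base, "")[[1]]
    p <- sample(length(chars), 1)
    chars[p] <- sample(letters, 1)
    cand <- paste(chars, collapse = "")
    prev <- Inf
    for (budget in 0:3) {
      r <- correct_against(toy_lex, cand,
                           cfg = correction_config(TRUE, budget, 4))
      cost <- if (is.null(r)) Inf else r$cost
      expect_lte(cost, prev)
      prev <- cost
    }
  }
})

test_that("edits recorded in the result reproduce the corrected string", {
  cfg <- correction_config(TRUE, 1, 4)
  r <- correct_against(toy_lex, "vancomycim", cfg = cfg)
  expect_identical(r$corrected, "vancomycin")
  expect_identical(nrow(r$edits), 1L)
  expect_identical(r$edits$type, "substitution")
  expect_identical(r$edits$from, "m")
  expect_identical(r$edits$to, "n")
})
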