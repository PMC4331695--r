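res <- builtin_resources()

lf_entities <- function(txt) {
  e <- annotate(source_document("x", abstract = txt), res)
  e[e$resource == "drug", , drop = FALSE]
}

test_that("short-form validation rejects identifiers and Roman numerals", {
  expect_true(is_valid_short_form("THF"))
  expect_true(is_valid_short_form("MeHg"))
  expect_false(is_valid_short_form("II"))
  expect_false(is_valid_short_form("1a"))
  expect_false(is_valid_short_form("12b"))
  expect_false(is_valid_short_form("AB"))      # below min length
  expect_false(is_valid_short_form("AB)"))     # unbalanced
  expect_true(is_valid_short_form("A(B)"))
  expect_false(is_valid_short_form("XIV"))
  # configuration is honored
  lax <- abbrev_config(min_length = 2, roman_numeral_check = FALSE)
  expect_true(is_valid_short_form("II", lax))
})

test_that("all six defining surface patterns are recognized", {
  cases <- list(
    c("pure tetrahydrofuran (THF) was used",        "LF (SF)"),
    c("pure THF (tetrahydrofuran) was used",        "SF (LF)"),
    c("pure tetrahydrofuran (THF; anhydrous) here", "LF (SF;"),
    c("pure tetrahydrofuran (THF, anhydrous) here", "LF (SF,"),
    c("we took (tetrahydrofuran, THF) as solvent",  "(LF, SF)"),
    c("here THF = tetrahydrofuran was used",        "SF = LF")
  )
  for (cs in cases) {
    d <- detect_abbreviations(lf_entities(cs[1]), cs[1])
    expect_identical(nrow(d$pairs), 1L, label = cs[1])
    expect_identical(d$pairs$pattern, cs[2], label = cs[1])
    expect_identical(d$pairs$short, "THF")
    # the defining SF occurrence becomes an entity with inherited class
    sf_ents <- d$entities[d$entities$abbreviation, ]
    expect_gte(nrow(sf_ents), 1)
    expect_true(all(sf_ents$class == "chemical"))
  }
})

test_that("detected abbreviations propagate to all further instances", {
  txt <- "tetrahydrofuran (THF) was dried. THF was used. more THF here"
  d <- detect_abbreviations(lf_entities(txt), txt)
  sf <- d$entities[d$entities$text == "THF", ]
  expect_identical(nrow(sf), 3L)
  expect_identical(sum(sf$propagated), 2L)
  # every occurrence of the short form is covered by an entity
  occ <- gregexpr("THF", txt, fixed = TRUE)[[1]]
  expect_identical(sort(sf$start), sort(as.integer(occ) - 1L))
})

test_that("the equivalence map admits token-level abbreviations", {
  txt <- "exposure to methylmercury (MeHg) and later MeHg again"
  d <- detect_abbreviations(lf_entities(txt), txt)
  expect_identical(d$pairs$short, "MeHg")
  expect_identical(sum(d$entities$text == "MeHg"), 2L)

  # without the map entry the correspondence test fails
  d2 <- detect_abbreviations(lf_entities(txt), txt,
                             eq = data.frame(long = character(0),
                                             short = character(0)))
  expect_identical(nrow(d2$pairs), 0L)
})

test_that("character correspondence rejects unrelated parentheticals", {
  txt <- "as aspirin (WHO) reported"
  d <- detect_abbreviations(lf_entities(txt), txt)
  expect_identical(nrow(d$pairs), 0L)
})

test_that("abbreviations of non-entities are removed document-wide", {
  txt <- paste0("current good manufacturing practice (cGMP) rules apply ",
                "and cGMP is enforced")
  s1 <- regexpr("cGMP", txt, fixed = TRUE)
  ents <- entity_rows("d", "A", c(s1 - 1L, 59L), c(s1 + 3L, 63L),
                      c("cGMP", "cGMP"), "chemical", "drug")
  expect_identical(substr(txt, 60, 63), "cGMP")
  expect_identical(nrow(remove_nonentity_abbreviations(ents, txt)), 0L)
})

test_that("abbreviations whose long form is an entity are retained", {
  txt <- "cyclic guanosine monophosphate (cGMP) rules apply"
  ents <- rbind(
    entity_rows("e", "A", 0L, 30L, "cyclic guanosine monophosphate",
                "chemical", "drug"),
    entity_rows("e", "A", 32L, 36L, "cGMP", "chemical", "drug")
  )
  out <- remove_nonentity_abbreviations(ents, txt)
  expect_true("cGMP" %in% out$text)

  # no parenthetical defining pattern: nothing changes
  txt2 <- "plain cGMP mention only"
  ents2 <- entity_rows("f", "A", 6L, 10L, "cGMP", "chemical", "drug")
  expect_identical(nrow(remove_nonentity_abbreviations(ents2, txt2)), 1L)
})
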