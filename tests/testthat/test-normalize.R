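test_that("quote-like and ligature characters normalize with an index map", {
  nt <- normalize_text("‘name’")
  expect_identical(nt$text, "'name'")
  expect_identical(nt$src_start, 0:5)
  expect_identical(nt$src_end, 1:6)

  nt <- normalize_text("œstradiol")
  expect_identical(nt$text, "oestradiol")
  # both normalized chars produced by the ligature map to its source range
  expect_identical(nt$src_start[1:2], c(0L, 0L))
  expect_identical(nt$src_end[1:2], c(1L, 1L))
  expect_identical(map_span(nt, 0, 2), c(0L, 1L))

  expect_identical(normalize_text("water")$text, "water")
  expect_identical(normalize_text("3–7")$text, "3-7")
})

test_that("xml mode strips stylistic tags and maps offsets to source", {
  nt <- normalize_text("<p>H<sub>2</sub>O</p>", xml_mode = TRUE)
  expect_identical(nt$text, "H2O")
  # span over the whole normalized text covers H<sub>2</sub>O
  sp <- map_span(nt, 0, 3)
  expect_identical(substr("<p>H<sub>2</sub>O</p>", sp[1] + 1, sp[2]),
                   "H<sub>2</sub>O")

  # non-stylistic tags delimit paragraphs
  nt2 <- normalize_text("<p>one</p><p>two</p>", xml_mode = TRUE)
  expect_identical(nt2$text, "one\ntwo")
  expect_identical(nt2$para_breaks, 3L)
  # the break char maps to an empty source range
  expect_identical(nt2$src_start[4], nt2$src_end[4])

  # character entities decode, then normalize
  nt3 <- normalize_text("a &amp; b", xml_mode = TRUE)
  expect_identical(nt3$text, "a & b")
  expect_identical(map_span(nt3, 2, 3), c(2L, 7L))
})

test_that("malformed markup raises a structured parse error with offset", {
  err <- tryCatch(normalize_text("a <p b", xml_mode = TRUE),
                  error = function(e) e)
  expect_s3_class(err, "chemner_parse_error")
  expect_identical(err$offset, 2L)
  expect_error(normalize_text("x</b>", xml_mode = TRUE),
               class = "chemner_parse_error")
  expect_error(normalize_text("<i>x", xml_mode = TRUE),
               class = "chemner_parse_error")
})

test_that("map_span handles empty spans and rejects out-of-bounds", {
  nt <- normalize_text("abc")
  expect_identical(map_span(nt, 1, 1), c(1L, 1L))
  expect_identical(map_span(nt, 3, 3), c(3L, 3L))
  expect_error(map_span(nt, 2, 5), "out of bounds")
})

test_that("normalization is idempotent and accounts for every character", {
  fixtures <- c("‘name’", "œstradiol café – x",
                "plain ascii", "a b")
  for (x in fixtures) {
    once <- normalize_text(x)
    twice <- normalize_text(once$text)
    expect_identical(twice$text, once$text)
  }
  # length accounting in xml mode: source ranges plus removed markup cover
  # the raw input
  raw <- "<p>H<sub>2</sub>O and N<i>2</i></p>"
  nt <- normalize_text(raw, xml_mode = TRUE)
  covered <- sum(nt$src_end - nt$src_start)
  markup <- sum(nchar(unlist(
    regmatches(raw, gregexpr("<[^>]*>", raw))
  )))
  expect_identical(covered + markup, nchar(raw))
})

test_that("round trip: normalized spans map to source slices that renormalize", {
  raw <- "the ‘œstrogen’ level – shown"
  nt <- normalize_text(raw)
  set.seed(42)
  n <- nchar(nt$text)
  for (rep in 1:25) {
    s <- sample(0:(n - 1), 1)
    e <- sample((s + 1):n, 1)
    sp <- map_span(nt, s, e)
    slice <- substr(raw, sp[1] + 1, sp[2])
    renorm <- normalize_text(slice)$text
    # the renormalized source slice contains the normalized span
    expect_true(grepl(substr(nt$text, s + 1, e), renorm, fixed = TRUE))
  }
})

test_that("normalization tables load from config files", {
  tf <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# test table", "\\u2019='", "X=Y"), tf)
  tab <- read_normalization_table(tf)
  expect_identical(unname(tab["’"]), "'")
  expect_identical(normalize_text("X’s", table = tab)$text, "Y's")
})
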