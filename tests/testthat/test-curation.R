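test_that("single-synonym curation matches the documented filter behavior", {
  cfg <- curation_config()
  r <- curate_synonym("command", cfg)
  expect_identical(r$status, "rejected")
  expect_identical(r$reason, "english_word")

  expect_identical(curate_synonym("abc", cfg)$reason, "too_short")
  expect_identical(curate_synonym("chloride)", cfg)$reason,
                   "unbalanced_brackets")
  expect_identical(curate_synonym("AstraZeneca", cfg)$reason,
                   "dubious_synonym")
  expect_identical(curate_synonym("what?ever", cfg)$reason,
                   "forbidden_character")
  expect_identical(curate_synonym("-phenyl", cfg)$reason, "hyphen_boundary")
  expect_identical(curate_synonym("2,4-D, sodium salt", cfg)$reason,
                   "comma_space")

  pep <- raw_synonym("somatostatin-28", peptide_length = 16L)
  expect_identical(curate_synonym(pep, cfg)$reason, "biopolymer")
  sac <- raw_synonym("stachyose", saccharide_length = 4L)
  expect_identical(curate_synonym(sac, cfg)$reason, "biopolymer")
  # shorter biopolymers pass the structure filters
  tri <- raw_synonym("raffinose", saccharide_length = 3L)
  expect_identical(curate_synonym(tri, cfg)$status, "accepted")

  acc <- curate_synonym("paracetamol (INN)", cfg)
  expect_identical(acc$status, "accepted")
  expect_identical(acc$cleaned_term, "paracetamol")

  # the 'acid' exception to the English first-word filter
  expect_identical(curate_synonym("strong acid", cfg)$status, "accepted")
  expect_identical(curate_synonym("strong base", cfg)$reason, "english_word")

  # a term matched in full by another dictionary is rejected
  cfg2 <- curation_config(blocking_lexicons = list(
    build_lexicon("aspirin", case_policy = "sensitive")
  ))
  expect_identical(curate_synonym("aspirin", cfg2)$reason,
                   "blocked_by_dictionary")
  expect_identical(curate_synonym("naproxen", cfg2)$status, "accepted")
})

test_that("variant expansion follows the three documented rules", {
  expect_setequal(expand_variants("KF 17837"),
                  c("KF 17837", "KF17837", "KF-17837"))
  expect_setequal(expand_variants("Bisphenol A"),
                  c("Bisphenol A", "Bisphenol-A"))
  expect_true("α-tocopherol" %in% expand_variants("alpha-tocopherol"))
  expect_true("β-carotene" %in% expand_variants("beta-carotene"))
  expect_identical(expand_variants("vancomycin"), "vancomycin")
  # letter+digit last word gets the hyphen variant only
  expect_setequal(expand_variants("compound B1"),
                  c("compound B1", "compound-B1"))
})

test_that("the 25-term fixture reproduces the hand-derived curation table", {
  raw_path <- system.file("extdata", "raw_synonyms.tsv", package = "chemner")
  exp_path <- system.file("extdata", "raw_synonyms_expected.tsv",
                          package = "chemner")
  if (!nzchar(raw_path)) {
    raw_path <- "../../inst/extdata/raw_synonyms.tsv"
    exp_path <- "../../inst/extdata/raw_synonyms_expected.tsv"
  }
  raw <- utils::read.delim(raw_path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  expected <- utils::read.delim(exp_path, sep = "\t", quote = "",
                                comment.char = "#",
                                stringsAsFactors = FALSE,
                                na.strings = "NA")
  expected$variants[is.na(expected$variants)] <- ""
  got <- curate_synonyms(raw)
  expect_identical(nrow(got), 25L)
  expect_identical(got$term, expected$term)
  expect_identical(got$status, expected$status)
  expect_identical(got$reason, expected$reason)
  expect_identical(got$cleaned_term, expected$cleaned_term)
  expect_identical(got$variants, expected$variants)
})

test_that("curation is idempotent on accepted terms", {
  raw <- c("paracetamol (INN)", "KF 17837", "alpha-tocopherol",
           "Bisphenol A", "vancomycin")
  for (t in raw) {
    r1 <- curate_synonym(t)
    expect_identical(r1$status, "accepted")
    r2 <- curate_synonym(r1$cleaned_term)
    expect_identical(r2$status, "accepted")
    expect_identical(r2$cleaned_term, r1$cleaned_term)
  }
})

test_that("no expanded variant violates any reject filter", {
  accepted <- c("paracetamol (INN)", "KF 17837", "Bisphenol A",
                "alpha-tocopherol", "gamma-linolenic", "compound B1")
  for (t in accepted) {
    r <- curate_synonym(t)
    expect_identical(r$status, "accepted")
    for (v in r$variants) {
      expect_identical(curate_synonym(v)$status, "accepted", label = v)
    }
  }
})

test_that("dictionary file curation writes lexicon and audit", {
  raw_path <- system.file("extdata", "raw_synonyms.tsv", package = "chemner")
  if (!nzchar(raw_path)) raw_path <- "../../inst/extdata/raw_synonyms.tsv"
  out <- withr::local_tempfile(fileext = ".txt")
  audit <- withr::local_tempfile(fileext = ".tsv")
  res <- curate_dictionary_file(raw_path, out, audit)
  terms <- readLines(out)
  expect_true(all(c("paracetamol", "KF-17837", "Bisphenol-A",
                    "α-tocopherol") %in% terms))
  aud <- utils::read.delim(audit, sep = "\t", stringsAsFactors = FALSE)
  expect_identical(nrow(aud), 25L)
})
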