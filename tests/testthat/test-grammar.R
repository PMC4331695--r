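cid_grammar <- function() {
  parse_grammar(c(
    "digit1to9 : '1'|'2'|'3'|'4'|'5'|'6'|'7'|'8'|'9'",
    "digit : digit1to9 | '0'",
    "cid : 'CID:' digit1to9 digit*"
  ))
}

test_that("the rule dialect parses into named rules with an inferred root", {
  g <- cid_grammar()
  expect_s3_class(g, "chem_grammar")
  expect_length(g$rules, 3)
  expect_identical(g$root, "cid")

  g2 <- parse_grammar(c(
    "alkaneStem : 'meth' | 'eth' | 'prop'",
    "alkane : alkaneStem 'ane'"
  ))
  expect_length(g2$rules, 2)
  expect_identical(g2$root, "alkane")

  expect_error(parse_grammar("x : 'a' |"), "empty production")
  expect_error(parse_grammar(c("x : 'a'", "x : 'b'")), "duplicate rule")
  expect_error(parse_grammar("x : y"), "unresolved reference")
})

test_that("self- and mutually-recursive grammars are rejected as non-regular", {
  expect_error(parse_grammar("X : 'a' X"), "may not reference itself")
  expect_error(parse_grammar(c("a : b 'x'", "b : a | 'y'")),
               "may not reference itself")
})

test_that("compiled CID automaton matches the independent regex oracle", {
  a <- compile_grammar(cid_grammar())
  rx <- oracle_regexes()$cid
  expect_true(accepts(a, "CID:42"))
  expect_false(accepts(a, "CID:0"))
  expect_false(accepts(a, "CID:"))
  expect_identical(match_longest(a, "CID:1234x", 0), c(0L, 8L))
  expect_null(match_longest(a, "CID:1234", 8))

  strings <- c(
    enumerate_strings(c("C", "I", "D", ":", "1"), 6),
    paste0("CID:", c(1, 7, 10, 90210, 123456789)),
    perturb_strings("CID:1234", c("C", "I", "D", ":", "0", "1", "9"))
  )
  expect_identical(accepts_all(a, strings), grepl(rx, strings))
})

test_that("compiled alkane automaton equals the enumeration oracle", {
  g <- parse_grammar(builtin_grammar_sources()$alkane)
  a <- compile_grammar(g)
  lang <- oracle_alkane_terms()
  expect_true(all(accepts_all(a, lang)))
  expect_true(accepts(a, "ethane"))
  expect_false(accepts(a, "ethan"))
  expect_false(accepts(a, "ethanee"))

  strings <- c(enumerate_strings(c("e", "t", "h", "a", "n"), 6),
               perturb_strings("cyclohexane", letters[1:8]))
  expect_identical(accepts_all(a, strings), strings %in% lang)
})

test_that("grammar case folding admits either case", {
  g <- parse_grammar("w : 'Abc'", case_sensitive = FALSE)
  a <- compile_grammar(g)
  expect_true(accepts(a, "abc"))
  expect_true(accepts(a, "ABC"))
  g2 <- parse_grammar("w : 'Abc'")
  expect_false(accepts(compile_grammar(g2), "abc"))
})

test_that("match_longest enforces balanced well-nested brackets", {
  lex <- build_lexicon(c("2(3H)-furanone"), case_policy = "sensitive")
  expect_identical(match_lexicon(lex, "2(3H)-furanone", 0), c(0L, 14L))
  expect_null(match_lexicon(lex, "2(3H-furanone", 0))

  # a prefix automaton: accepting states inside and after the brackets
  g <- parse_grammar("p : 'a(b' 'c)'?")
  a <- compile_grammar(g)
  m <- match_longest(a, "a(bx", 0)
  expect_null(m) # "a(b" accepted by the machine but bracket-unbalanced
  expect_identical(match_longest(a, "a(bc)", 0), c(0L, 5L))
})

test_that("scanning is deterministic and longest-match", {
  a <- compile_grammar(cid_grammar())
  text <- "x CID:12 yy CID:345 CID:0"
  m1 <- scan_matches(a, text)
  m2 <- scan_matches(a, text)
  expect_identical(m1, m2)
  for (i in seq_len(nrow(m1))) {
    s <- m1$start[i]
    e <- m1$end[i]
    # no longer accepted prefix exists at this start
    for (e2 in seq(e + 1, min(nchar(text), e + 3))) {
      if (e2 > nchar(text)) break
      expect_false(accepts(a, substr(text, s + 1, e2)))
    }
  }
})

test_that("layered automaton separates context from sub-machine matching", {
  sub_m <- compile_terms(c("methyl", "ethyl"))
  par_m <- compile_terms(c("benzene", "phenol"))
  master <- parse_grammar("name : substituent* parent",
                          lexicons = c("substituent", "parent"))
  la <- compile_layered(master, list(substituent = sub_m, parent = par_m))
  expect_true(accepts(la, "ethylbenzene"))
  expect_true(accepts(la, "methylethylphenol"))
  expect_true(accepts(la, "benzene"))
  expect_false(accepts(la, "ethyl"))
  expect_false(accepts(la, "benzeneethyl"))

  # the same substituent sub-machine reused in a different context
  ester_master <- parse_grammar(
    "ester : parent ' ' substituent ' ester'",
    lexicons = c("substituent", "parent")
  )
  acid <- compile_terms("acetic acid")
  ea <- compile_layered(ester_master,
                        list(substituent = sub_m, parent = acid))
  expect_true(accepts(ea, "acetic acid ethyl ester"))
  expect_false(accepts(ea, "acetic acid ester"))

  # degenerate layering: master = single sub-machine reference
  one <- parse_grammar("top : parent", lexicons = "parent")
  la1 <- compile_layered(one, list(parent = par_m))
  for (s in c("benzene", "phenol", "benzen", "phenolx")) {
    expect_identical(accepts(la1, s), accepts(par_m, s))
  }
})

test_that("layered language equals the fully inlined flat compilation", {
  subs <- c("methyl", "ethyl")
  pars <- c("benzene", "phenol")
  master <- parse_grammar("name : substituent* parent",
                          lexicons = c("substituent", "parent"))
  la <- compile_layered(master, list(substituent = compile_terms(subs),
                                     parent = compile_terms(pars)))
  flat <- compile_grammar(master,
                          lexicons = list(substituent = subs, parent = pars))
  # enumerate substituent^{0..2} x parent, plus near-misses
  lang <- as.character(outer(
    c("", subs, as.vector(outer(subs, subs, paste0))),
    pars, paste0
  ))
  negatives <- c("methyl", "benzenephenol", "ethylbenzen", "xbenzene",
                 "methylmethyl", "", "benzene ")
  for (s in c(lang, negatives)) {
    expect_identical(accepts(la, s), accepts(flat, s), label = s)
  }
})

test_that("automaton language sampling produces accepted strings", {
  a <- compile_grammar(cid_grammar())
  set.seed(1)
  for (i in 1:25) {
    s <- sample_automaton(a)
    expect_true(accepts(a, s), label = s)
    expect_lte(nchar(s), 21)
  }
})

test_that("compiled automata round-trip through the portable text format", {
  a <- compile_grammar(cid_grammar())
  tf <- withr::local_tempfile(fileext = ".fsm")
  write_automaton(a, tf)
  b <- read_automaton(tf)
  strings <- c("CID:42", "CID:0", "CID:1234", "cid:12", "CID:", "CID:907x")
  for (s in strings) expect_identical(accepts(b, s), accepts(a, s))
  expect_identical(match_longest(b, "CID:1234x", 0), c(0L, 8L))

  # unicode symbols survive the escape round-trip
  g <- parse_grammar("w : 'α-ol'")
  a2 <- compile_grammar(g)
  write_automaton(a2, tf)
  expect_true(accepts(read_automaton(tf), "α-ol"))
  expect_error(read_automaton(system.file("DESCRIPTION", package = "chemner")),
               "not a chemner automaton")
})
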