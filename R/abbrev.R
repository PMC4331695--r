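# Abbreviation handling: an adapted Schwartz-Hearst procedure. Because the
# long form is supplied (it is an entity the system already found), the
# classic weakness of the algorithm — guessing where the long form starts —
# does not arise for detection; the character-correspondence test and the
# six surface patterns remain. A reverse application removes entities that
# turn out to be abbreviations of non-entities.

#' Abbreviation detection settings
#'
#' @param min_length Minimum short-form length (default 3, per
#'   CHEMDNER-style annotation guidelines).
#' @param roman_numeral_check Reject short forms that are Roman numerals
#'   ("II").
#' @param identifier_check Reject short forms shaped like common chemical
#'   identifiers ("1a").
#' @return An `abbrev_config`.
#' @export
abbrev_config <- function(min_length = 3L, roman_numeral_check = TRUE,
                          identifier_check = TRUE) {
  stopifnot(min_length >= 1)
  structure(
    list(min_length = as.integer(min_length),
         roman_numeral_check = roman_numeral_check,
         identifier_check = identifier_check),
    class = "abbrev_config"
  )
}

is_roman_numeral <- function(s) {
  grepl("^[IVXLCDMivxlcdm]+$", s)
}

is_chem_identifier <- function(s) {
  # compound identifiers like '1a', '12b', 'a1' (3 chars or fewer)
  nchar(s) <= 3 &&
    (grepl("^[0-9]+[A-Za-z]+$", s) || grepl("^[A-Za-z][0-9]+$", s))
}

#' Validate a candidate short form
#'
#' A valid short form is at least `min_length` characters, has balanced
#' well-nested brackets, and is neither a Roman numeral ("II") nor a
#' common chemical identifier pattern ("1a").
#'
#' @param candidate Candidate short-form text.
#' @param cfg An [abbrev_config()].
#' @return Logical scalar.
#' @export
is_valid_short_form <- function(candidate, cfg = abbrev_config()) {
  if (nchar(candidate) < cfg$min_length) return(FALSE)
  if (!brackets_balanced(candidate)) return(FALSE)
  if (cfg$roman_numeral_check && is_roman_numeral(candidate)) return(FALSE)
  if (cfg$identifier_check && is_chem_identifier(candidate)) return(FALSE)
  TRUE
}

# rewrite long-form text using the equivalence map (longest token first),
# so "methylmercury" can be compared against "MeHg" as "MeHg"
apply_equivalence <- function(long, eq) {
  if (!nrow(eq)) return(long)
  for (i in order(-nchar(eq$long))) {
    long <- gsub(eq$long[i], eq$short[i], long, fixed = TRUE)
  }
  long
}

# Schwartz-Hearst-style character correspondence: every alphanumeric of
# the short form appears in order in the long form, and the first
# short-form character matches a word-initial character of the long form.
chars_correspond <- function(short, long) {
  sc <- strsplit(tolower(short), "")[[1]]
  sc <- sc[grepl("[[:alnum:]]", sc)]
  if (!length(sc)) return(FALSE)
  lc <- strsplit(tolower(long), "")[[1]]
  n <- length(lc)
  word_initial <- c(TRUE, !grepl("[[:alnum:]]", lc[-n]))[seq_len(n)]
  # first short char must sit at a word-initial position
  starts <- which(lc == sc[1] & word_initial)
  for (st in starts) {
    j <- st
    ok <- TRUE
    for (k in seq_along(sc)[-1]) {
      j <- j + 1L
      while (j <= n && lc[j] != sc[k]) j <- j + 1L
      if (j > n) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# correspondence with the equivalence map: the rewritten long form is
# compared case-sensitively on the map's short tokens (Me, Hg), and the
# raw long form case-insensitively
short_matches_long <- function(short, long, eq) {
  if (chars_correspond(short, long)) return(TRUE)
  if (nrow(eq)) {
    rewritten <- apply_equivalence(long, eq)
    if (rewritten != long && chars_correspond(short, rewritten)) return(TRUE)
  }
  FALSE
}

# all occurrences of a string in text at token-ish boundaries; returns
# 0-based starts
find_occurrences <- function(text, s) {
  if (!nchar(s)) return(integer(0))
  starts <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(s, substring(text, from), fixed = TRUE)
    if (p < 0) break
    abs0 <- from + as.integer(p) - 2L # 0-based
    before <- if (abs0 > 0) substring(text, abs0, abs0) else ""
    after_i <- abs0 + nchar(s) + 1L
    after <- if (after_i <= nchar(text)) substring(text, after_i, after_i)
    else ""
    if (!grepl("[[:alnum:]]", before) && !grepl("[[:alnum:]]", after))
      starts <- c(starts, abs0)
    from <- abs0 + nchar(s) + 1L
  }
  starts
}

# scan a short-form candidate inside "(" ... terminated by ')', ';' or ','
# allowing balanced inner brackets; i0 = 0-based position just after "(".
# Returns c(start, end) of the candidate (0-based half-open) or NULL.
sf_candidate_in_parens <- function(text, i0) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  depth <- 0L
  i <- i0 + 1L # 1-based
  while (i <= n) {
    ch <- chars[i]
    if (depth == 0L && ch %in% c(")", ";", ",")) {
      if (i - 1L == i0) return(NULL)
      return(c(i0, i - 1L))
    }
    if (ch %in% .open_brackets) depth <- depth + 1L
    if (ch %in% .close_brackets) depth <- depth - 1L
    if (depth < 0L) return(NULL)
    if (ch == "\n") return(NULL)
    i <- i + 1L
  }
  NULL
}

# token immediately before a 0-based position (skipping one space run);
# returns c(start, end) 0-based half-open, or NULL
token_before <- function(text, pos) {
  pre <- substr_cp(text, 0, pos)
  m <- regexpr("[^ \t\n]+[ \t]*$", pre)
  if (m < 0) return(NULL)
  tok <- sub("[ \t]*$", "", regmatches(pre, m))
  s <- as.integer(m) - 1L
  c(s, s + nchar(tok))
}

#' Detect abbreviations of found entities
#'
#' Recognizes six surface patterns around each entity taken as the long
#' form (LF), with SF the short form: `LF (SF)`, `SF (LF)`, `LF (SF;`,
#' `LF (SF,`, `(LF, SF)`, and `SF = LF`. A candidate short form must pass
#' [is_valid_short_form()] and the character-correspondence test (every
#' alphanumeric of the SF appears in order in the LF, the first at a
#' word-initial position), optionally after rewriting LF tokens with the
#' equivalence map (so "MeHg" is a plausible abbreviation of
#' "methylmercury"). On success the defining SF occurrence and all
#' further instances of that exact string in the document section are
#' annotated with the long form's class and resource.
#'
#' @param entities Entity data frame for one section.
#' @param text The section's source text.
#' @param eq Equivalence map data frame (`long`, `short`).
#' @param cfg An [abbrev_config()].
#' @return List with `pairs` (data frame: `short`, `long`, `pattern`,
#'   `sf_start`, `sf_end`) and `entities` (the input plus new short-form
#'   entities, `abbreviation`/`propagated` flags set).
#' @export
detect_abbreviations <- function(entities, text, eq = default_equivalence_map(),
                                 cfg = abbrev_config()) {
  pairs <- data.frame(short = character(0), long = character(0),
                      pattern = character(0), sf_start = integer(0),
                      sf_end = integer(0), stringsAsFactors = FALSE)
  if (!nrow(entities)) return(list(pairs = pairs, entities = entities))
  n <- nchar(text)
  new_rows <- empty_entities()

  add_sf_entities <- function(ent, sf_s, sf_e, sf_txt) {
    # defining occurrence
    rows <- entity_rows(ent$doc_id, ent$section, sf_s, sf_e, sf_txt,
                        ent$class, ent$resource)
    rows$abbreviation <- TRUE
    # all further instances of that exact string (case-sensitive)
    occ <- find_occurrences(text, sf_txt)
    occ <- occ[occ != sf_s]
    for (o in occ) {
      r <- entity_rows(ent$doc_id, ent$section, o, o + nchar(sf_txt),
                       sf_txt, ent$class, ent$resource)
      r$abbreviation <- TRUE
      r$propagated <- TRUE
      rows <- rbind(rows, r)
    }
    rows
  }

  for (i in seq_len(nrow(entities))) {
    ent <- entities[i, , drop = FALSE]
    lf <- ent$text
    found <- NULL

    # patterns LF (SF) / LF (SF; / LF (SF,  — "(" right after the entity
    after <- substr_cp(text, ent$end, n)
    if (startsWith(after, " (")) {
      cand <- sf_candidate_in_parens(text, ent$end + 2L)
      if (!is.null(cand)) {
        sf_txt <- substr_cp(text, cand[1], cand[2])
        closer <- substr_cp(text, cand[2], cand[2] + 1L)
        patt <- switch(closer, ")" = "LF (SF)", ";" = "LF (SF;",
                       "," = "LF (SF,", NA_character_)
        if (!is.na(patt) && is_valid_short_form(sf_txt, cfg) &&
            short_matches_long(sf_txt, lf, eq)) {
          found <- list(sf_s = cand[1], sf_e = cand[2], sf = sf_txt,
                        pattern = patt)
        }
      }
    }

    # pattern SF (LF): entity enclosed in parens, SF is the token before
    if (is.null(found) && ent$start >= 1L && ent$end < n &&
        substr_cp(text, ent$start - 1L, ent$start) == "(" &&
        substr_cp(text, ent$end, ent$end + 1L) == ")") {
      tb <- token_before(text, ent$start - 1L)
      if (!is.null(tb)) {
        sf_txt <- substr_cp(text, tb[1], tb[2])
        if (is_valid_short_form(sf_txt, cfg) &&
            short_matches_long(sf_txt, lf, eq)) {
          found <- list(sf_s = tb[1], sf_e = tb[2], sf = sf_txt,
                        pattern = "SF (LF)")
        }
      }
    }

    # pattern (LF, SF): entity after "(", followed by ", SF)"
    if (is.null(found) && ent$start >= 1L &&
        substr_cp(text, ent$start - 1L, ent$start) == "(") {
      after_e <- substr_cp(text, ent$end, n)
      m <- regexec("^, ([^()\n]+)\\)", after_e)[[1]]
      if (m[1] == 1L) {
        sf_s <- ent$end + m[2] - 1L
        sf_e <- sf_s + attr(m, "match.length")[2]
        sf_txt <- substr_cp(text, sf_s, sf_e)
        if (is_valid_short_form(sf_txt, cfg) &&
            short_matches_long(sf_txt, lf, eq)) {
          found <- list(sf_s = sf_s, sf_e = sf_e, sf = sf_txt,
                        pattern = "(LF, SF)")
        }
      }
    }

    # pattern SF = LF: entity preceded by "= ", SF the token before that
    if (is.null(found) && ent$start >= 2L) {
      before <- substr_cp(text, 0, ent$start)
      if (grepl("[=] $|[=]$", before)) {
        eq_pos <- ent$start - (if (endsWith(before, " ")) 2L else 1L)
        tb <- token_before(text, eq_pos)
        if (!is.null(tb)) {
          sf_txt <- sub(" ?=$", "", substr_cp(text, tb[1], tb[2]))
          sf_e <- tb[1] + nchar(sf_txt)
          if (nzchar(sf_txt) && is_valid_short_form(sf_txt, cfg) &&
              short_matches_long(sf_txt, lf, eq)) {
            found <- list(sf_s = tb[1], sf_e = sf_e, sf = sf_txt,
                          pattern = "SF = LF")
          }
        }
      }
    }

    if (!is.null(found)) {
      pairs <- rbind(pairs, data.frame(
        short = found$sf, long = lf, pattern = found$pattern,
        sf_start = found$sf_s, sf_end = found$sf_e,
        stringsAsFactors = FALSE
      ))
      new_rows <- rbind(new_rows, add_sf_entities(ent, found$sf_s,
                                                  found$sf_e, found$sf))
    }
  }

  if (nrow(new_rows)) {
    # don't duplicate spans already covered by entities
    keep <- vapply(seq_len(nrow(new_rows)), function(i) {
      !any(entities$start < new_rows$end[i] &
             new_rows$start[i] < entities$end)
    }, logical(1))
    new_rows <- new_rows[keep, , drop = FALSE]
    new_rows <- new_rows[!duplicated(new_rows[c("start", "end")]), ,
                         drop = FALSE]
    entities <- rbind(entities, new_rows)
    entities <- entities[order(entities$start), , drop = FALSE]
    rownames(entities) <- NULL
  }
  list(pairs = pairs, entities = entities)
}

#' Remove entities that are abbreviations of non-entities
#'
#' Each entity is postulated to be a short form; its local context
#' (bounded by paragraph breaks) is searched for a defining long form
#' using the same surface patterns, taking at most `min(|SF| + 5, 2|SF|)`
#' words before the parenthesis (the classic Schwartz-Hearst window) and
#' keeping the shortest word suffix that satisfies the character
#' correspondence. If a long form is found and it neither is an entity
#' nor overlaps one, the entity is judged a false positive and removed
#' together with every other entity of the same text in the section —
#' when "current good manufacturing practice (cGMP)" is seen, cGMP does
#' not mean cyclic guanosine monophosphate.
#'
#' @param entities Entity data frame for one section.
#' @param text The section's source text.
#' @param cfg An [abbrev_config()].
#' @param eq Equivalence map.
#' @return Filtered entity data frame.
#' @export
remove_nonentity_abbreviations <- function(entities, text,
                                           cfg = abbrev_config(),
                                           eq = default_equivalence_map()) {
  if (!nrow(entities)) return(entities)
  drop_text <- character(0)
  for (i in seq_len(nrow(entities))) {
    ent <- entities[i, , drop = FALSE]
    sf <- ent$text
    if (!is_valid_short_form(sf, cfg)) next
    # only abbreviation-shaped entities (an upper-case letter or digit)
    # are postulated as short forms: an all-lower-case word in brackets is
    # almost never an acronym, and the in-order character test alone would
    # find spurious "long forms" in ordinary prose
    if (!grepl("[A-Z0-9]", sf)) next
    # defining position: "(SF)" / "(SF;" / "(SF,"
    if (ent$start < 1L ||
        substr_cp(text, ent$start - 1L, ent$start) != "(") next
    closer <- substr_cp(text, ent$end, ent$end + 1L)
    if (!closer %in% c(")", ";", ",")) next

    # candidate long form: up to max_words before "(", within the segment
    seg_start <- 0L
    brk <- gregexpr("\n", substr_cp(text, 0, ent$start), fixed = TRUE)[[1]]
    if (brk[1] != -1) seg_start <- max(brk)
    pre <- substr_cp(text, seg_start, ent$start - 1L)
    pre <- sub("[ \t]+$", "", pre)
    wm <- gregexpr("[^ \t]+", pre)[[1]]
    if (wm[1] == -1) next
    w_starts <- seg_start + as.integer(wm) - 1L
    w_ends <- w_starts + attr(wm, "match.length")
    nw <- length(w_starts)
    max_words <- min(nchar(sf) + 5L, 2L * nchar(sf))
    first_w <- max(1L, nw - max_words + 1L)
    lf_span <- NULL
    for (w in seq(nw, first_w)) { # shortest suffix first
      lf_txt <- substr_cp(text, w_starts[w], w_ends[nw])
      if (short_matches_long(sf, lf_txt, eq)) {
        lf_span <- c(w_starts[w], w_ends[nw])
        break
      }
    }
    if (is.null(lf_span)) next
    others <- entities[-i, , drop = FALSE]
    overlaps_entity <- nrow(others) &&
      any(others$start < lf_span[2] & lf_span[1] < others$end)
    if (!overlaps_entity) drop_text <- c(drop_text, sf)
  }
  if (length(drop_text)) {
    entities <- entities[!(entities$text %in% drop_text), , drop = FALSE]
    rownames(entities) <- NULL
  }
  entities
}
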