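# Filter-and-expand pipeline turning a raw synonym dump into a precise
# lexicon. Filters run in a fixed, documented order (the order below); the
# first failing filter sets the machine-readable reason code. Qualifier
# stripping happens before the downstream filters so "paracetamol (INN)"
# is judged on "paracetamol". Expansion rules are applied to accepted
# terms only.

#' Curation configuration
#'
#' @param known_qualifiers Bracketed qualifiers stripped from term ends
#'   (without brackets), e.g. `"INN"`.
#' @param context_qualifiers Words that, appearing as first or last word,
#'   reject the term ("derivative", "analog", "solution", ...).
#' @param dubious_synonyms Exact terms known to be wrong ("AstraZeneca").
#' @param dubious_words Words whose presence anywhere rejects the term
#'   ("gene", "inhibitor").
#' @param english_words Non-chemical English word list (first-word test).
#' @param catalogue_number_patterns Regular expressions for supplier
#'   catalogue numbers.
#' @param forbidden_characters Characters that reject a term outright.
#' @param blocking_lexicons List of `chem_lexicon`s; a term matched in
#'   full by any of them is rejected ("matched by another dictionary").
#' @param max_peptide,max_saccharide Structure-derived limits: peptides of
#'   at least `max_peptide` residues (hexadecapeptide and longer) and
#'   saccharides of at least `max_saccharide` units (tetrasaccharide and
#'   longer) are biopolymers, not chemicals, under CHEMDNER-style
#'   annotation rules.
#' @param greek Greek spelling table for variant expansion.
#' @return A `curation_config`.
#' @export
curation_config <- function(
    known_qualifiers = c("INN", "TN", "JAN", "USAN", "BAN", "USP", "JP17",
                         "NF", "VAN"),
    context_qualifiers = c("derivative", "derivatives", "analog", "analogs",
                           "analogue", "analogues", "solution", "solutions",
                           "mixture", "preparation"),
    dubious_synonyms = c("AstraZeneca", "Pfizer", "Aldrich", "Sigma",
                         "component", "reagent"),
    dubious_words = c("gene", "genes", "inhibitor", "inhibitors", "protein",
                      "proteins", "receptor", "receptors", "antibody",
                      "enzyme"),
    english_words = default_english_words(),
    catalogue_number_patterns = c(
      "^MFCD[0-9]{8}$",          # MDL file numbers
      "^(ZINC|AKOS|CHEMBL)[0-9]{4,}$",
      "^(SC|CS|HY|AB|BD)-[0-9]{4,}$",
      "^NSC-?[0-9]{3,}$"
    ),
    forbidden_characters = c("?", "!", "\\", "|", "%", "@", ";"),
    blocking_lexicons = list(),
    max_peptide = 16L,
    max_saccharide = 4L,
    greek = greek_letter_table()) {
  structure(
    list(known_qualifiers = known_qualifiers,
         context_qualifiers = tolower(context_qualifiers),
         dubious_synonyms = dubious_synonyms,
         dubious_words = tolower(dubious_words),
         english_words = tolower(english_words),
         catalogue_number_patterns = catalogue_number_patterns,
         forbidden_characters = forbidden_characters,
         blocking_lexicons = blocking_lexicons,
         max_peptide = as.integer(max_peptide),
         max_saccharide = as.integer(max_saccharide),
         greek = greek),
    class = "curation_config"
  )
}

#' A raw synonym record
#'
#' @param term The synonym text.
#' @param peptide_length,saccharide_length Optional structure-derived
#'   lengths (residue / monosaccharide counts); `NA` when no structure
#'   information is available.
#' @param is_depositor_external_name Whether the synonym is a depositor's
#'   external name (i.e. a catalogue number).
#' @return A `raw_synonym`.
#' @export
raw_synonym <- function(term, peptide_length = NA_integer_,
                        saccharide_length = NA_integer_,
                        is_depositor_external_name = FALSE) {
  stopifnot(is.character(term), length(term) == 1, nzchar(term))
  structure(
    list(term = term, peptide_length = peptide_length,
         saccharide_length = saccharide_length,
         is_depositor_external_name = isTRUE(is_depositor_external_name)),
    class = "raw_synonym"
  )
}

brackets_balanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (!length(chars)) return(TRUE)
  ok <- bracket_ok_prefix(chars, 1L, length(chars))
  ok[length(ok)]
}

words_of <- function(s) {
  w <- strsplit(trimws(s), "[ \t]+")[[1]]
  w[nzchar(w)]
}

is_pdb_code <- function(s) grepl("^[0-9][A-Za-z0-9]{3}$", s)
is_inchi_key <- function(s) grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", s)

#' Curate one raw synonym
#'
#' Applies the reject filters in their fixed order; the first failure sets
#' the reason code. Qualifier stripping (e.g. `"(INN)"`) happens early so
#' downstream filters see the cleaned term. Accepted terms get variant
#' expansion via [expand_variants()].
#'
#' Reason codes: `biopolymer`, `unbalanced_brackets`, `unknown_qualifier`,
#' `context_qualifier`, `too_short`, `hyphen_boundary`, `comma_space`,
#' `blocked_by_dictionary`, `dubious_synonym`, `english_word`,
#' `dubious_word`, `catalogue_number`, `forbidden_character`, `pdb_code`,
#' `inchi_key`.
#'
#' @param s A [raw_synonym()] (a bare string is promoted).
#' @param cfg A [curation_config()].
#' @return A `curation_result`: `status` (`"accepted"`/`"rejected"`),
#'   `reason` (code of the first failing filter, `NA` if accepted),
#'   `cleaned_term`, and `variants` (including the cleaned term itself;
#'   empty when rejected).
#' @export
curate_synonym <- function(s, cfg = curation_config()) {
  if (is.character(s)) s <- raw_synonym(s)
  stopifnot(inherits(s, "raw_synonym"))
  term <- trimws(s$term)

  reject <- function(reason) {
    structure(list(status = "rejected", reason = reason,
                   cleaned_term = NA_character_, variants = character(0)),
              class = "curation_result")
  }

  # biopolymers (structure-derived)
  if (!is.na(s$peptide_length) && s$peptide_length >= cfg$max_peptide)
    return(reject("biopolymer"))
  if (!is.na(s$saccharide_length) && s$saccharide_length >= cfg$max_saccharide)
    return(reject("biopolymer"))

  if (!brackets_balanced(term)) return(reject("unbalanced_brackets"))

  # strip a trailing bracketed qualifier; unknown qualifiers reject
  m <- regmatches(term, regexpr(" \\(([A-Za-z][A-Za-z0-9]*)\\)$", term))
  if (length(m) && nzchar(m)) {
    qual <- sub("^ \\(", "", sub("\\)$", "", m))
    if (qual %in% cfg$known_qualifiers) {
      term <- trimws(sub(" \\([A-Za-z][A-Za-z0-9]*\\)$", "", term))
    } else {
      return(reject("unknown_qualifier"))
    }
  }

  w <- words_of(term)
  lw <- tolower(w)

  # preceded/followed by a context qualifier
  if (length(w) > 1 &&
      (lw[1] %in% cfg$context_qualifiers ||
       lw[length(lw)] %in% cfg$context_qualifiers))
    return(reject("context_qualifier"))

  if (nchar(term) <= 3) return(reject("too_short"))
  if (startsWith(term, "-") || endsWith(term, "-"))
    return(reject("hyphen_boundary"))
  if (grepl(", ", term, fixed = TRUE)) return(reject("comma_space"))

  for (bl in cfg$blocking_lexicons) {
    if (accepts(bl, term)) return(reject("blocked_by_dictionary"))
  }

  if (term %in% cfg$dubious_synonyms) return(reject("dubious_synonym"))

  # first word a non-chemical English word, unless the next word is 'acid'
  if (lw[1] %in% cfg$english_words &&
      !(length(lw) > 1 && lw[2] == "acid"))
    return(reject("english_word"))

  if (any(lw %in% cfg$dubious_words)) return(reject("dubious_word"))

  if (s$is_depositor_external_name) return(reject("catalogue_number"))
  for (p in cfg$catalogue_number_patterns) {
    if (grepl(p, term)) return(reject("catalogue_number"))
  }

  chars <- strsplit(term, "")[[1]]
  if (any(chars %in% cfg$forbidden_characters))
    return(reject("forbidden_character"))

  if (is_pdb_code(term)) return(reject("pdb_code"))
  if (is_inchi_key(term)) return(reject("inchi_key"))

  structure(
    list(status = "accepted", reason = NA_character_, cleaned_term = term,
         variants = expand_variants(term, cfg)),
    class = "curation_result"
  )
}

#' @export
print.curation_result <- function(x, ...) {
  if (x$status == "accepted") {
    cat("<curation_result> accepted: '", x$cleaned_term, "' (",
        length(x$variants), " variant(s))\n", sep = "")
  } else {
    cat("<curation_result> rejected: ", x$reason, "\n", sep = "")
  }
  invisible(x)
}

#' Expand an accepted term into spelling variants
#'
#' Three expansion rules, applied to an accepted (cleaned) term; the
#' original term is always retained:
#'
#' * Latin-spelled Greek letters (`"alpha-"`, or a standalone word
#'   `"alpha"`) generate a variant using the Greek character (`"α-"`).
#' * If the last word consists of digits, variants with the preceding
#'   space deleted and replaced by a hyphen are generated
#'   (`"KF 17837"` also gives `"KF17837"` and `"KF-17837"`).
#' * If the last word is a single letter or a letter followed by a digit,
#'   a variant with the preceding space replaced by a hyphen is generated
#'   (`"Bisphenol A"` also gives `"Bisphenol-A"`).
#'
#' @param term Accepted term.
#' @param cfg A [curation_config()] (supplies the Greek table).
#' @return Character vector of variants, first element the original term.
#' @export
expand_variants <- function(term, cfg = curation_config()) {
  out <- term

  # Greek spellings: attached ("alpha-") and standalone-word forms
  g <- cfg$greek
  greekified <- term
  for (i in seq_len(nrow(g))) {
    lat <- g$latin[i]
    gr <- g$greek[i]
    greekified <- gsub(paste0("(?i)\\b", lat, "(?=-)"), gr, greekified,
                       perl = TRUE)
    greekified <- gsub(paste0("(?i)(?<![A-Za-z])", lat, "(?![A-Za-z])"), gr,
                       greekified, perl = TRUE)
  }
  if (greekified != term) out <- c(out, greekified)

  w <- words_of(term)
  if (length(w) > 1) {
    last <- w[length(w)]
    head_part <- paste(w[-length(w)], collapse = " ")
    if (grepl("^[0-9]+$", last)) {
      out <- c(out, paste0(head_part, last), paste0(head_part, "-", last))
    } else if (grepl("^[A-Za-z][0-9]?$", last)) {
      out <- c(out, paste0(head_part, "-", last))
    }
  }
  unique(out)
}

#' Curate a table of raw synonyms
#'
#' @param synonyms Data frame with columns `term` and optionally
#'   `peptide_length`, `saccharide_length`, `is_depositor_external_name`.
#' @param cfg A [curation_config()].
#' @return Audit data frame: `term`, `status`, `reason`, `cleaned_term`,
#'   `variants` (comma-joined).
#' @export
curate_synonyms <- function(synonyms, cfg = curation_config()) {
  stopifnot(is.data.frame(synonyms), "term" %in% names(synonyms))
  n <- nrow(synonyms)
  getcol <- function(col, default) {
    if (col %in% names(synonyms)) synonyms[[col]] else rep(default, n)
  }
  pep <- getcol("peptide_length", NA_integer_)
  sac <- getcol("saccharide_length", NA_integer_)
  dep <- getcol("is_depositor_external_name", FALSE)
  rows <- lapply(seq_len(n), function(i) {
    r <- curate_synonym(
      raw_synonym(synonyms$term[i], pep[i], sac[i], isTRUE(dep[i])), cfg
    )
    data.frame(term = synonyms$term[i], status = r$status,
               reason = r$reason, cleaned_term = r$cleaned_term,
               variants = paste(r$variants, collapse = "|"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Curate a raw synonym TSV into a lexicon file
#'
#' Input columns (tab-separated, `#` comments): `term`, and optionally
#' `peptide_length`, `saccharide_length`, `is_depositor_external_name`.
#' Writes the accepted terms (all variants, one per line) to `out` and an
#' audit TSV (`term`, `status`, `reason`, `cleaned_term`, `variants`) to
#' `audit` when given.
#'
#' @param in_path Raw synonym TSV.
#' @param out Output lexicon file.
#' @param audit Optional audit TSV path.
#' @param cfg A [curation_config()].
#' @return The audit data frame, invisibly.
#' @export
curate_dictionary_file <- function(in_path, out, audit = NULL,
                                   cfg = curation_config()) {
  tab <- utils::read.delim(in_path, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"term" %in% names(tab)) names(tab)[1] <- "term"
  res <- curate_synonyms(tab, cfg)
  accepted <- res[res$status == "accepted", , drop = FALSE]
  terms <- unique(unlist(strsplit(accepted$variants, "|", fixed = TRUE)))
  writeLines(enc2utf8(terms), out, useBytes = TRUE)
  if (!is.null(audit)) {
    utils::write.table(res, audit, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(res)
}
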