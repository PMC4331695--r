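# Named term collections compiled for scanning, with per-lexicon policy:
# entity class, case policy, matching vs blocking role, token-boundary
# enforcement, and spelling-correction settings.

#' Build a compiled lexicon
#'
#' Compiles a set of terms into scannable automata. Case policy:
#' `"sensitive"` matches terms verbatim; `"insensitive"` folds both terms
#' and text to lower case; `"first-insensitive"` (the default for chemical
#' name lists) additionally admits each term with its first letter's case
#' flipped, so sentence-initial capitalization does not break a match while
#' interior (acronym) case is preserved. Individual terms can be forced to
#' full case-insensitivity via `ci_terms`.
#'
#' A lexicon with role `"blocking"` is scanned like any other but its
#' matches only suppress entities from other resources; they are never
#' emitted themselves.
#'
#' @param terms Character vector of terms (at least one, all non-empty).
#' @param name Lexicon name (unique within a resource set).
#' @param entity_class Class label carried by emitted entities.
#' @param case_policy `"sensitive"`, `"insensitive"`, or
#'   `"first-insensitive"`.
#' @param role `"matching"` or `"blocking"`.
#' @param token_boundary If `TRUE`, matches must start and end at a token
#'   boundary (start/end of text, whitespace, or a non-alphanumeric
#'   character outside the match). Chemical-name lexicons leave this off so
#'   sub-word matches remain available to entity extension.
#' @param specific Whether terms denote specific compounds (concrete
#'   structures) rather than generic chemical classes; consulted by the
#'   hyphen-mixture exception during entity extension.
#' @param correction A [correction_config()] or `NULL` (no correction).
#' @param ci_terms Terms to match fully case-insensitively regardless of
#'   `case_policy`.
#' @return A `chem_lexicon`.
#' @export
build_lexicon <- function(terms, name = "lexicon",
                          entity_class = "chemical",
                          case_policy = c("first-insensitive", "sensitive",
                                          "insensitive"),
                          role = c("matching", "blocking"),
                          token_boundary = FALSE,
                          specific = TRUE,
                          correction = NULL,
                          ci_terms = character(0)) {
  case_policy <- match.arg(case_policy)
  role <- match.arg(role)
  terms <- unique(as.character(terms))
  if (!length(terms)) stop("a lexicon needs at least one term")
  if (any(!nzchar(terms))) stop("lexicon terms must be non-empty")

  ci <- intersect(ci_terms, terms)
  plain <- setdiff(terms, ci)
  automata <- list()
  if (length(plain)) {
    if (case_policy == "insensitive") {
      automata <- c(automata, list(compile_terms(plain, fold = "lower")))
    } else {
      expanded <- plain
      if (case_policy == "first-insensitive") {
        swap_first <- function(x) {
          f <- substring(x, 1, 1)
          g <- if (f == toupper(f)) tolower(f) else toupper(f)
          paste0(g, substring(x, 2))
        }
        expanded <- unique(c(plain, vapply(plain, swap_first, character(1))))
      }
      automata <- c(automata, list(compile_terms(expanded, fold = "none")))
    }
  }
  if (length(ci)) {
    automata <- c(automata, list(compile_terms(ci, fold = "lower")))
  }

  structure(
    list(name = name, terms = terms, entity_class = entity_class,
         case_policy = case_policy, role = role,
         token_boundary = token_boundary, specific = specific,
         correction = correction, automata = automata),
    class = "chem_lexicon"
  )
}

#' Read a lexicon from a term-list file
#'
#' One term per line, UTF-8. An optional second tab-separated column of
#' per-term flags is honored: `ci` marks the term fully case-insensitive.
#' `#` lines are comments.
#'
#' @param path File path.
#' @param ... Passed to [build_lexicon()].
#' @return A `chem_lexicon`.
#' @export
read_lexicon <- function(path, ...) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1L)
  flags <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else "",
                  character(1))
  build_lexicon(terms, ci_terms = terms[flags == "ci"], ...)
}

#' Write a lexicon's terms to a file
#'
#' @param lex A `chem_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(enc2utf8(lex$terms), path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.chem_lexicon <- function(x, ...) {
  cat("<chem_lexicon> '", x$name, "': ", length(x$terms), " term(s), class '",
      x$entity_class, "', ", x$case_policy, ", role ", x$role, "\n", sep = "")
  invisible(x)
}

#' Longest lexicon term at a position
#'
#' Longest term of the lexicon matching at `pos` (0-based) whose brackets
#' end balanced and well-nested, or `NULL`.
#'
#' @param lex A `chem_lexicon`.
#' @param text Text to scan.
#' @param pos 0-based position.
#' @return Integer span `c(start, end)` or `NULL`.
#' @export
match_lexicon <- function(lex, text, pos = 0L) {
  match_longest(lex, text, pos)
}

#' @export
match_longest.chem_lexicon <- function(x, text, start = 0L, ...) {
  best <- NULL
  for (a in x$automata) {
    m <- match_longest(a, text, start)
    if (!is.null(m) && (is.null(best) || m[2] > best[2])) best <- m
  }
  best
}

#' @export
accepts.chem_lexicon <- function(x, s, ...) {
  any(vapply(x$automata, accepts, logical(1), s))
}

#' @export
scan_matches.chem_lexicon <- function(x, text, ...) {
  out <- lapply(x$automata, scan_matches, text = text)
  out <- do.call(rbind, out)
  if (!nrow(out)) return(out)
  # longest per start across the sub-automata
  out <- out[order(out$start, -out$end), , drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# token-boundary test for a candidate span over text chars (0-based span)
at_token_boundary <- function(chars, start, end) {
  is_word <- function(ch) grepl("[[:alnum:]]", ch)
  left_ok <- start == 0L || !is_word(chars[start])
  right_ok <- end == length(chars) || !is_word(chars[end + 1L])
  left_ok && right_ok
}
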