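#' Default character normalization table
#'
#' Maps Unicode characters with equivalent typographic meaning onto the
#' plain ASCII characters that grammars and lexicons are written over:
#' backtick, curly single quotes and prime to apostrophe; curly double
#' quotes to `"`; en/em dash and the minus sign to `-`; the oe/ae ligatures
#' to their two-letter spellings; non-breaking space to space.
#'
#' Greek letters are deliberately *not* folded to Latin spellings: the
#' lexicon curation step instead generates Greek-character variants of
#' Latin-spelled terms, so dictionaries carry both forms.
#'
#' @return Named character vector: names are source characters (or short
#'   source sequences), values are replacement sequences (possibly longer
#'   than one character).
#' @export
default_normalization_table <- function() {
  c(
    "`"      = "'",
    "‘" = "'",  # left single quote
    "’" = "'",  # right single quote
    "′" = "'",  # prime
    "“" = "\"", # left double quote
    "”" = "\"", # right double quote
    "–" = "-",  # en dash
    "—" = "-",  # em dash
    "−" = "-",  # minus sign
    "œ" = "oe", # oe ligature
    "Œ" = "Oe",
    "æ" = "ae", # ae ligature
    "Æ" = "Ae",
    " " = " "   # non-breaking space
  )
}

#' Read a normalization table from a key=value config file
#'
#' One mapping per line, `source<TAB>replacement` (or `source=replacement`);
#' `#` starts a comment. Unicode escapes of the form `\uXXXX` are expanded
#' on both sides.
#'
#' @param path File path.
#' @return Named character vector usable as `table` in [normalize_text()].
#' @export
read_normalization_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  unesc <- function(x) {
    while (grepl("\\\\u[0-9a-fA-F]{4}", x)) {
      m <- regmatches(x, regexpr("\\\\u[0-9a-fA-F]{4}", x))
      x <- sub("\\\\u[0-9a-fA-F]{4}",
               intToUtf8(strtoi(substring(m, 3), 16L)), x)
    }
    x
  }
  out <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t|=", fixed = FALSE)[[1]]
    if (length(parts) < 2) stop("bad normalization table line: ", ln)
    out[unesc(parts[1])] <- unesc(parts[2])
  }
  out
}

chemner_parse_error <- function(msg, offset) {
  stop(errorCondition(
    sprintf("%s (offset %d)", msg, offset),
    offset = offset,
    class = c("chemner_parse_error", "error")
  ))
}

# Named XML/HTML character entities understood in xml_mode.
.xml_entities <- c(amp = "&", lt = "<", gt = ">", quot = "\"", apos = "'")

#' Normalize text while retaining an index map to source coordinates
#'
#' Applies a character normalization table to `raw` and, in `xml_mode`,
#' strips markup: stylistic tags (default `sub`, `sup`, `i`, `b`) are
#' removed outright while every other tag forces a paragraph break
#' (a single newline mapped to an empty source range). Character entities
#' (`&amp;`, `&#NNN;`, `&#xHH;`) are decoded before table lookup.
#'
#' Every normalized character records the half-open source range (0-based,
#' counted in code points of the original string) it was produced from, so
#' entity spans found over the normalized text can be reported in source
#' coordinates via [map_span()]. A one-to-many replacement such as the oe
#' ligature gives both output characters the full one-character source
#' range of the ligature.
#'
#' @param raw Input string (UTF-8).
#' @param table Named character vector mapping source characters/sequences
#'   to replacements; see [default_normalization_table()].
#' @param xml_mode Treat `raw` as an XML fragment.
#' @param stylistic_tags Tag names removed without forcing a break.
#' @return An object of class `normalized_text` with fields `text`,
#'   `src_start`, `src_end` (per normalized character, 0-based half-open),
#'   `para_breaks` (0-based normalized positions of inserted breaks),
#'   `n_source`, and `source`.
#' @export
normalize_text <- function(raw, table = default_normalization_table(),
                           xml_mode = FALSE,
                           stylistic_tags = c("sub", "sup", "i", "b")) {
  stopifnot(is.character(raw), length(raw) == 1)
  chars <- strsplit(raw, "", fixed = FALSE)[[1]]
  n <- length(chars)
  keys <- names(table)
  key_len <- nchar(keys)
  multi <- keys[key_len > 1]
  single_map <- table[key_len == 1]

  out_ch <- character(0)
  out_s <- integer(0)
  out_e <- integer(0)
  breaks <- integer(0)
  pending_break <- FALSE
  emitted_any <- FALSE

  emit <- function(ch_seq, s0, e0) {
    # flush a pending paragraph break before real content
    if (pending_break && emitted_any) {
      out_ch[[length(out_ch) + 1L]] <<- "\n"
      out_s[[length(out_s) + 1L]] <<- s0
      out_e[[length(out_e) + 1L]] <<- s0
      breaks[[length(breaks) + 1L]] <<- length(out_ch) - 1L
    }
    pending_break <<- FALSE
    for (ch in ch_seq) {
      out_ch[[length(out_ch) + 1L]] <<- ch
      out_s[[length(out_s) + 1L]] <<- s0
      out_e[[length(out_e) + 1L]] <<- e0
    }
    emitted_any <<- TRUE
  }

  # emit one source char (or decoded entity char), applying the table
  emit_norm <- function(ch, s0, e0) {
    if (length(multi)) {
      # multi-char source keys are only checked against the literal stream
      # in the plain-text path below; decoded entities are single chars
    }
    repl <- single_map[ch]
    if (!is.na(repl)) {
      emit(strsplit(repl, "")[[1]], s0, e0)
    } else {
      emit(ch, s0, e0)
    }
  }

  tag_stack <- character(0)
  i <- 1L
  while (i <= n) {
    c0 <- chars[i]
    if (xml_mode && c0 == "<") {
      rest <- paste(chars[i:n], collapse = "")
      if (startsWith(rest, "<!--")) {
        close <- regexpr("-->", rest, fixed = TRUE)
        if (close < 0) chemner_parse_error("unterminated comment", i - 1L)
        i <- i + as.integer(close) + 2L
        next
      }
      gt <- which(chars[i:n] == ">")
      if (!length(gt)) chemner_parse_error("unterminated tag", i - 1L)
      j <- i + gt[1] - 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!nzchar(trimws(inner)))
        chemner_parse_error("empty tag", i - 1L)
      closing <- startsWith(inner, "/")
      selfclosing <- endsWith(inner, "/")
      name <- tolower(sub("[ \t/].*$", "", sub("^/", "", inner)))
      if (!grepl("^[a-z][a-z0-9:_-]*$", name))
        chemner_parse_error(paste0("malformed tag <", inner, ">"), i - 1L)
      if (closing) {
        if (!length(tag_stack) || tag_stack[length(tag_stack)] != name)
          chemner_parse_error(paste0("mismatched closing tag </", name, ">"),
                              i - 1L)
        tag_stack <- tag_stack[-length(tag_stack)]
      } else if (!selfclosing) {
        tag_stack <- c(tag_stack, name)
      }
      if (!(name %in% tolower(stylistic_tags))) pending_break <- TRUE
      i <- j + 1L
      next
    }
    if (xml_mode && c0 == "&") {
      rest <- paste(chars[i:min(n, i + 11L)], collapse = "")
      m <- regmatches(rest, regexpr("^&(#x[0-9a-fA-F]+|#[0-9]+|[a-z]+);", rest))
      if (length(m) == 1 && nzchar(m)) {
        body <- substring(m, 2, nchar(m) - 1)
        ch <- if (startsWith(body, "#x")) {
          intToUtf8(strtoi(substring(body, 3), 16L))
        } else if (startsWith(body, "#")) {
          intToUtf8(strtoi(substring(body, 2), 10L))
        } else {
          val <- .xml_entities[body]
          if (is.na(val)) NA_character_ else val
        }
        if (!is.na(ch)) {
          emit_norm(ch, i - 1L, i - 1L + nchar(m))
          i <- i + nchar(m)
          next
        }
      }
      emit_norm("&", i - 1L, i)
      i <- i + 1L
      next
    }
    # multi-character table keys (longest first) against the raw stream
    hit <- FALSE
    if (length(multi)) {
      for (k in multi[order(-nchar(multi))]) {
        kl <- nchar(k)
        if (i + kl - 1L <= n &&
            paste(chars[i:(i + kl - 1L)], collapse = "") == k) {
          emit(strsplit(table[[k]], "")[[1]], i - 1L, i - 1L + kl)
          i <- i + kl
          hit <- TRUE
          break
        }
      }
    }
    if (hit) next
    emit_norm(c0, i - 1L, i)
    i <- i + 1L
  }
  if (xml_mode && length(tag_stack))
    chemner_parse_error(paste0("unclosed tag <", tag_stack[length(tag_stack)],
                               ">"), n)

  structure(
    list(
      text = paste(out_ch, collapse = ""),
      src_start = as.integer(out_s),
      src_end = as.integer(out_e),
      para_breaks = as.integer(breaks),
      n_source = n,
      source = raw
    ),
    class = "normalized_text"
  )
}

#' @export
print.normalized_text <- function(x, ...) {
  cat("<normalized_text> ", nchar(x$text), " chars (from ", x$n_source,
      " source chars, ", length(x$para_breaks), " breaks)\n", sep = "")
  invisible(x)
}

#' Map a normalized span back to source coordinates
#'
#' Returns the minimal half-open source range covering every source
#' character that produced the normalized span. Offsets are 0-based and
#' counted in code points. An empty span maps to an empty range at the
#' corresponding source boundary.
#'
#' @param nt A `normalized_text`.
#' @param start,end 0-based half-open span over `nt$text`.
#' @return Integer vector `c(start, end)` in source coordinates.
#' @export
map_span <- function(nt, start, end) {
  stopifnot(inherits(nt, "normalized_text"))
  nn <- nchar(nt$text)
  if (start < 0 || end < start || end > nn)
    stop("span [", start, ",", end, ") out of bounds for normalized text of ",
         "length ", nn)
  if (start == end) {
    b <- if (start < nn) nt$src_start[start + 1L] else nt$n_source
    return(c(b, b))
  }
  idx <- (start + 1L):end
  s <- nt$src_start[idx]
  e <- nt$src_end[idx]
  real <- e > s
  if (!any(real)) {
    p <- min(s)
    return(c(p, p))
  }
  c(min(s[real]), max(e[real]))
}

# source slice by 0-based half-open code-point range
substr_cp <- function(x, start, end) {
  if (end <= start) return("")
  substring(x, start + 1L, end)
}
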