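# Five-step entity modification pipeline: 1. boundary extension,
# 2. trimming of non-essential modifiers, 3. merging, 4. stop-word
# removal (with re-trimming), 5. the S-transferase special case.
#
# All steps operate on the entities of ONE document section together with
# that section's source text. Word tests are case-insensitive whole-word.
# Extension stops only at whitespace, a mismatched bracket, or a
# non-chemical English/noise word; sentence punctuation (, . ; : ! ?) is
# treated as whitespace-equivalent so trailing commas and periods never
# join an entity.

.boundary_chars <- c(" ", "\t", "\n", ",", ".", ";", ":", "!", "?")

is_stop_word_seg <- function(seg, wl) {
  core <- tolower(gsub("[^A-Za-z]", "", seg))
  nzchar(core) && (core %in% wl$english_words || core %in% wl$noise_words)
}

# segment adjacent to a hyphen: chars from just beyond the hyphen up to the
# next hyphen or boundary char. dir = -1 (leftwards) or +1 (rightwards).
hyphen_segment <- function(chars, hyphen_i, dir) {
  n <- length(chars)
  i <- hyphen_i + dir
  seg <- character(0)
  while (i >= 1L && i <= n) {
    ch <- chars[i]
    if (ch %in% c(.boundary_chars, "-")) break
    seg <- c(seg, ch)
    i <- i + dir
  }
  if (dir < 0) seg <- rev(seg)
  paste(seg, collapse = "")
}

# extend one boundary; s, e are 1-based inclusive char indices of the
# current span. Returns the new boundary index (1-based, inclusive).
extend_left <- function(chars, s, e, wl) {
  good <- s
  pending <- character(0) # closers seen, awaiting their openers
  i <- s
  while (i > 1L) {
    c0 <- chars[i - 1L]
    if (c0 %in% .boundary_chars) break
    if (c0 == "-") {
      seg <- hyphen_segment(chars, i - 1L, -1L)
      if (!nzchar(seg) || is_stop_word_seg(seg, wl)) break
      i <- i - 1L
      if (!length(pending)) good <- i
      next
    }
    if (c0 %in% .close_brackets) {
      pending <- c(pending, c0)
      i <- i - 1L
      next
    }
    if (c0 %in% .open_brackets) {
      expected <- .close_brackets[[c0]]
      if (length(pending) && pending[length(pending)] == expected) {
        pending <- pending[-length(pending)]
        i <- i - 1L
        if (!length(pending)) good <- i
        next
      }
      break # mismatched opener
    }
    i <- i - 1L
    if (!length(pending)) good <- i
  }
  good
}

extend_right <- function(chars, s, e, wl) {
  n <- length(chars)
  good <- e
  pending <- character(0) # openers seen, awaiting their closers
  i <- e
  while (i < n) {
    c0 <- chars[i + 1L]
    if (c0 %in% .boundary_chars) break
    if (c0 == "-") {
      seg <- hyphen_segment(chars, i + 1L, 1L)
      if (!nzchar(seg) || is_stop_word_seg(seg, wl)) break
      i <- i + 1L
      if (!length(pending)) good <- i
      next
    }
    if (c0 %in% .open_brackets) {
      pending <- c(pending, c0)
      i <- i + 1L
      next
    }
    if (c0 %in% .close_brackets) {
      expected <- .opener_for[[c0]]
      if (length(pending) && pending[length(pending)] == expected) {
        pending <- pending[-length(pending)]
        i <- i + 1L
        if (!length(pending)) good <- i
        next
      }
      break # mismatched closer
    }
    i <- i + 1L
    if (!length(pending)) good <- i
  }
  good
}

span_balanced <- function(chars, s, e) {
  if (e < s) return(TRUE)
  ok <- bracket_ok_prefix(chars, s, e)
  ok[length(ok)]
}

#' Extend entity boundaries
#'
#' Each entity is grown left and right until whitespace (or sentence
#' punctuation), a mismatched bracket, or a non-chemical English/noise
#' word is reached; hyphen-joined segments are crossed unless the segment
#' beyond the hyphen is such a word. If the entity ends up entirely
#' enclosed in a balanced bracket pair, extension is retried from outside
#' the brackets and kept when it reaches beyond them (so "ethylene
#' glycol" inside "poly(ethylene glycol)" grows to the full name, while a
#' merely parenthesized mention keeps its own boundaries).
#'
#' Exception: two entities separated by a single hyphen where both denote
#' specific compounds are left unextended across that hyphen — such a
#' construct usually names a mixture, not one compound.
#'
#' @param entities Entity data frame for one section.
#' @param text The section's source text.
#' @param wl A [word_lists()].
#' @param specific_resources Names of resources whose matches denote
#'   specific compounds (for the hyphen-mixture exception). Defaults to
#'   all resources present.
#' @return Updated entity data frame.
#' @export
extend_entities <- function(entities, text, wl = word_lists(),
                            specific_resources = NULL) {
  if (!nrow(entities)) return(entities)
  chars <- strsplit(text, "")[[1]]
  if (is.null(specific_resources))
    specific_resources <- unique(entities$resource)
  entities <- entities[order(entities$start), , drop = FALSE]

  # hyphen-mixture exception: mark boundaries that must not be crossed
  no_right <- logical(nrow(entities))
  no_left <- logical(nrow(entities))
  for (i in seq_len(nrow(entities) - 1L)) {
    j <- i + 1L
    hy <- entities$end[i] # 0-based char position just after entity i
    if (entities$start[j] == entities$end[i] + 1L &&
        hy + 1L <= length(chars) && chars[hy + 1L] == "-" &&
        entities$resource[i] %in% specific_resources &&
        entities$resource[j] %in% specific_resources) {
      no_right[i] <- TRUE
      no_left[j] <- TRUE
    }
  }

  for (i in seq_len(nrow(entities))) {
    s <- entities$start[i] + 1L # to 1-based inclusive
    e <- entities$end[i]
    s2 <- if (no_left[i]) s else extend_left(chars, s, e, wl)
    e2 <- if (no_right[i]) e else extend_right(chars, s2, e, wl)
    # enclosed-in-brackets retry: only adopt boundaries that actually
    # reach beyond the bracket pair
    repeat {
      if (s2 > 1L && e2 < length(chars) &&
          chars[s2 - 1L] %in% .open_brackets &&
          chars[e2 + 1L] == .close_brackets[[chars[s2 - 1L]]] &&
          span_balanced(chars, s2, e2)) {
        s3 <- extend_left(chars, s2 - 1L, e2 + 1L, wl)
        e3 <- extend_right(chars, s3, e2 + 1L, wl)
        if (s3 < s2 - 1L || e3 > e2 + 1L) {
          s2 <- s3
          e2 <- e3
          next
        }
      }
      break
    }
    if (s2 != s || e2 != e) {
      entities$start[i] <- s2 - 1L
      entities$end[i] <- e2
      entities$text[i] <- substr_cp(text, s2 - 1L, e2)
      entities$extended[i] <- TRUE
    }
  }
  rownames(entities) <- NULL
  entities
}

# trim boundaries of one entity text; returns c(new_start_offset,
# new_end_offset) relative to the entity text (0-based half-open), or NULL
# if everything is trimmed away
trim_offsets <- function(txt, wl) {
  chars <- strsplit(txt, "")[[1]]
  n <- length(chars)
  s <- 0L
  e <- n
  repeat {
    changed <- FALSE
    # leading word
    m <- regmatches(substr_cp(txt, s, e),
                    regexpr("^[A-Za-z]+", substr_cp(txt, s, e)))
    if (length(m) && nzchar(m) && tolower(m) %in% wl$trim_terms) {
      s2 <- s + nchar(m)
      while (s2 < e && chars[s2 + 1L] %in% c(" ", "-")) s2 <- s2 + 1L
      if (s2 > s) {
        s <- s2
        changed <- TRUE
      }
    }
    cur <- substr_cp(txt, s, e)
    m <- regmatches(cur, regexpr("[A-Za-z]+$", cur))
    if (length(m) && nzchar(m) && tolower(m) %in% wl$trim_terms) {
      e2 <- e - nchar(m)
      while (e2 > s && chars[e2] %in% c(" ", "-")) e2 <- e2 - 1L
      if (e2 < e) {
        e <- e2
        changed <- TRUE
      }
    }
    if (!changed || s >= e) break
  }
  if (s >= e) return(NULL)
  c(s, e)
}

#' Trim non-essential modifiers from entity boundaries
#'
#' Leading and trailing trim terms ("group", "colloidal", "dye", ...),
#' with their connecting whitespace or hyphens, are removed from each
#' entity; an entity trimmed down to nothing is dropped.
#'
#' @inheritParams extend_entities
#' @return Updated entity data frame.
#' @export
trim_entities <- function(entities, text, wl = word_lists()) {
  if (!nrow(entities)) return(entities)
  keep <- logical(nrow(entities))
  for (i in seq_len(nrow(entities))) {
    off <- trim_offsets(entities$text[i], wl)
    if (is.null(off)) next
    keep[i] <- TRUE
    if (off[1] > 0L || off[2] < nchar(entities$text[i])) {
      ns <- entities$start[i] + off[1]
      ne <- entities$start[i] + off[2]
      entities$start[i] <- ns
      entities$end[i] <- ne
      entities$text[i] <- substr_cp(text, ns, ne)
      entities$trimmed[i] <- TRUE
    }
  }
  out <- entities[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

entity_core <- function(txt) tolower(trimws(txt))

#' Merge overlapping and adjacent entities
#'
#' Entities that overlap are merged unconditionally. Entities separated by
#' exactly one space are merged unless one is an instance of the other
#' according to the instance-of table (in either order): "monoterpene
#' pyridine alkaloids" becomes one entity, while "genistein isoflavonoid"
#' stays two because genistein IS an isoflavonoid. A merged entity records
#' a composite class/resource (constituents joined by `+`) and sets the
#' `merged` flag.
#'
#' @inheritParams extend_entities
#' @return Updated entity data frame.
#' @export
merge_entities <- function(entities, text, wl = word_lists()) {
  if (nrow(entities) < 2) return(entities)
  entities <- entities[order(entities$start), , drop = FALSE]
  chars <- strsplit(text, "")[[1]]
  inst <- wl$instance_of
  is_instance_pair <- function(a, b) {
    a <- entity_core(a)
    b <- entity_core(b)
    # singular/plural leniency on the class side
    norm <- function(x) sub("s$", "", x)
    any((norm(tolower(inst$specific)) == norm(a) &
           norm(tolower(inst$class)) == norm(b)) |
          (norm(tolower(inst$specific)) == norm(b) &
             norm(tolower(inst$class)) == norm(a)))
  }
  out <- entities[1, , drop = FALSE]
  for (i in 2:nrow(entities)) {
    cur <- out[nrow(out), , drop = FALSE]
    nxt <- entities[i, , drop = FALSE]
    overlap <- nxt$start < cur$end
    adjacent <- nxt$start == cur$end + 1L &&
      cur$end + 1L <= length(chars) && chars[cur$end + 1L] == " "
    do_merge <- overlap ||
      (adjacent && !is_instance_pair(cur$text, nxt$text))
    if (do_merge && nxt$end > cur$start) {
      s <- min(cur$start, nxt$start)
      e <- max(cur$end, nxt$end)
      comb <- function(a, b) paste(unique(c(strsplit(a, "+", fixed = TRUE)[[1]],
                                            strsplit(b, "+", fixed = TRUE)[[1]])),
                                   collapse = "+")
      out$start[nrow(out)] <- s
      out$end[nrow(out)] <- e
      out$text[nrow(out)] <- substr_cp(text, s, e)
      out$class[nrow(out)] <- comb(cur$class, nxt$class)
      out$resource[nrow(out)] <- comb(cur$resource, nxt$resource)
      out$merged[nrow(out)] <- TRUE
      out$extended[nrow(out)] <- cur$extended || nxt$extended
      out$trimmed[nrow(out)] <- cur$trimmed || nxt$trimmed
      if (nzchar(nxt$corrections)) {
        out$corrections[nrow(out)] <-
          paste(c(cur$corrections[nzchar(cur$corrections)],
                  nxt$corrections), collapse = "; ")
      }
    } else {
      out <- rbind(out, nxt)
    }
  }
  rownames(out) <- NULL
  out
}

#' Remove entities that reduce to stop terms
#'
#' Trimming is re-applied; if what remains of an entity is exactly a stop
#' term (e.g. "gold" after "nanoparticles" is trimmed from "gold
#' nanoparticles"), the entity is removed. Entities whose remaining text
#' merely contains a stop term are kept.
#'
#' @inheritParams extend_entities
#' @return Updated entity data frame.
#' @export
remove_stop_entities <- function(entities, text, wl = word_lists()) {
  entities <- trim_entities(entities, text, wl)
  if (!nrow(entities)) return(entities)
  keep <- !(entity_core(entities$text) %in% wl$stop_terms)
  out <- entities[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' S-transferase special case
#'
#' In "glutathione S-transferase" the lone "S" belongs with the
#' glutathione entity even though whitespace blocks ordinary extension;
#' it is annotated using its proximity to that entity. The hyphenated
#' spelling "glutathione-S-transferase" is normally already handled by
#' entity extension (which stops at the English word "transferase"), but
#' is covered here too for direct use.
#'
#' @inheritParams extend_entities
#' @param patterns Data frame of `(head, following, action)` rows: when an
#'   entity's text equals `head` (case-insensitively) and the text after
#'   it matches the `following` regular expression, either the entity is
#'   extended over the first capture group (`action = "extend"`) or a new
#'   entity covering it is added (`action = "separate"`).
#' @return Updated entity data frame.
#' @export
s_transferase_rule <- function(entities, text, wl = word_lists(),
                               patterns = default_s_patterns()) {
  if (!nrow(entities)) return(entities)
  added <- empty_entities()
  for (i in seq_len(nrow(entities))) {
    for (p in seq_len(nrow(patterns))) {
      if (tolower(entities$text[i]) != tolower(patterns$head[p])) next
      after <- substr_cp(text, entities$end[i], nchar(text))
      m <- regexec(patterns$following[p], after)[[1]]
      if (m[1] != 1L) next
      g_start <- entities$end[i] + m[2] - 1L # capture group, 0-based
      g_end <- g_start + attr(m, "match.length")[2]
      if (patterns$action[p] == "extend") {
        entities$end[i] <- g_end
        entities$text[i] <- substr_cp(text, entities$start[i], g_end)
        entities$extended[i] <- TRUE
      } else {
        nr <- entity_rows(entities$doc_id[i], entities$section[i],
                          g_start, g_end, substr_cp(text, g_start, g_end),
                          entities$class[i], entities$resource[i])
        nr$extended <- TRUE
        added <- rbind(added, nr)
      }
      break
    }
  }
  out <- rbind(entities, added)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname s_transferase_rule
#' @export
default_s_patterns <- function() {
  data.frame(
    head = c("glutathione", "glutathione"),
    following = c("^-(S)-transferase", "^ (S)-transferase"),
    action = c("extend", "separate"),
    stringsAsFactors = FALSE
  )
}

#' Run the full five-step entity modification pipeline
#'
#' Extension, trimming, merging, stop-term removal (which re-applies
#' trimming), and the S-transferase special case, in that order.
#'
#' @inheritParams extend_entities
#' @return Updated entity data frame.
#' @export
modify_entities <- function(entities, text, wl = word_lists(),
                            specific_resources = NULL) {
  entities <- extend_entities(entities, text, wl, specific_resources)
  entities <- trim_entities(entities, text, wl)
  entities <- merge_entities(entities, text, wl)
  entities <- remove_stop_entities(entities, text, wl)
  entities <- s_transferase_rule(entities, text, wl)
  entities
}
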