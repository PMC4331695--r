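# Annotation engine: scan a document against all configured resources,
# resolve overlaps (longest span wins; equal spans by resource priority),
# suppress spans inside blocking matches, optionally correct near-miss
# tokens, and emit provenance-tagged entities in source coordinates.

#' Empty entity table
#'
#' Entities are plain data frames, one row per mention: `doc_id`,
#' `section` (`T`/`A`/`P`), `start`/`end` (0-based half-open source
#' coordinates within the section), `text` (the source slice), `class`,
#' `resource` (which grammar/dictionary produced it — the system's core
#' auditability property), `corrections` (human-readable summary, `""` if
#' none), and logical provenance flags `extended`, `trimmed`, `merged`,
#' `abbreviation`, `propagated`.
#'
#' @return Zero-row entity data frame.
#' @export
empty_entities <- function() {
  data.frame(
    doc_id = character(0), section = character(0),
    start = integer(0), end = integer(0), text = character(0),
    class = character(0), resource = character(0),
    corrections = character(0),
    extended = logical(0), trimmed = logical(0), merged = logical(0),
    abbreviation = logical(0), propagated = logical(0),
    stringsAsFactors = FALSE
  )
}

#' Construct entity rows
#'
#' Vectorized constructor for entity data-frame rows (see
#' [empty_entities()] for the column contract); mainly useful for building
#' fixtures and adapting external annotations.
#'
#' @param doc_id,section,start,end,text,class,resource,corrections Column
#'   values, recycled to the length of `start`.
#' @return Entity data frame.
#' @export
entity_rows <- function(doc_id, section, start, end, text, class, resource,
                        corrections = "") {
  n <- length(start)
  if (!n) return(empty_entities())
  data.frame(
    doc_id = rep_len(doc_id, n), section = rep_len(section, n),
    start = as.integer(start), end = as.integer(end), text = text,
    class = rep_len(class, n), resource = rep_len(resource, n),
    corrections = rep_len(corrections, n),
    extended = FALSE, trimmed = FALSE, merged = FALSE,
    abbreviation = FALSE, propagated = FALSE,
    stringsAsFactors = FALSE
  )
}

#' A source document
#'
#' @param doc_id Non-empty document identifier.
#' @param title,abstract Section texts (CHEMDNER-style title/abstract
#'   pair); either may be empty.
#' @param paragraphs Optional additional paragraphs (section label `P`).
#' @param is_xml Whether section texts carry markup to be stripped during
#'   normalization.
#' @return A `source_document` with a `sections` data frame
#'   (`label`, `text`).
#' @export
source_document <- function(doc_id, title = "", abstract = "",
                            paragraphs = character(0), is_xml = FALSE) {
  stopifnot(is.character(doc_id), length(doc_id) == 1, nzchar(doc_id))
  sections <- data.frame(
    label = c("T", "A", rep("P", length(paragraphs))),
    text = c(title, abstract, paragraphs),
    stringsAsFactors = FALSE
  )
  sections <- sections[nzchar(sections$text), , drop = FALSE]
  structure(list(doc_id = doc_id, sections = sections, is_xml = is_xml),
            class = "source_document")
}

#' @export
print.source_document <- function(x, ...) {
  cat("<source_document> ", x$doc_id, ": ",
      paste(x$sections$label, collapse = ""), " (",
      sum(nchar(x$sections$text)), " chars)",
      if (x$is_xml) " [xml]", "\n", sep = "")
  invisible(x)
}

#' Declare an annotation resource
#'
#' Wraps a compiled matcher (grammar automaton, layered automaton, or
#' lexicon) with the policy the annotation engine needs: entity class,
#' matching vs blocking role, priority for equal-length overlap
#' resolution, token-boundary enforcement, whether matches denote specific
#' compounds, and per-resource correction settings.
#'
#' @param name Unique resource name (entities carry it as provenance).
#' @param object A `char_automaton`, `layered_automaton`, or
#'   `chem_lexicon`.
#' @param entity_class Class label for emitted entities.
#' @param role `"matching"` or `"blocking"`.
#' @param priority Smaller wins among equal-length overlaps (defaults to
#'   declaration order).
#' @param token_boundary Require matches to start/end at token boundaries.
#' @param specific Matches denote specific compounds (concrete
#'   structures); consulted by the hyphen-mixture rule.
#' @param correction A [correction_config()] or `NULL`.
#' @param digit_filter Minimum number of digit characters a match must
#'   contain to be kept (0 = no requirement). The sum-formula grammar uses
#'   3, so strings like "CDK2" or a lone element symbol are not
#'   recognized as formulae.
#' @param correction_object Optional automaton used as the spelling
#'   correction target instead of `object` (a layered automaton is
#'   corrected against a flattened machine of the same language).
#' @return A `chem_resource`.
#' @export
resource <- function(name, object, entity_class = "chemical",
                     role = c("matching", "blocking"), priority = NA_integer_,
                     token_boundary = FALSE, specific = TRUE,
                     correction = NULL, digit_filter = 0L,
                     correction_object = NULL) {
  role <- match.arg(role)
  if (inherits(object, "chem_lexicon")) {
    if (missing(entity_class)) entity_class <- object$entity_class
    if (missing(role)) role <- object$role
    if (missing(token_boundary)) token_boundary <- object$token_boundary
    if (missing(specific)) specific <- object$specific
    if (is.null(correction)) correction <- object$correction
  }
  structure(
    list(name = name, object = object, entity_class = entity_class,
         role = role, priority = priority, token_boundary = token_boundary,
         specific = specific, correction = correction,
         digit_filter = as.integer(digit_filter),
         correction_object = correction_object),
    class = "chem_resource"
  )
}

#' Assemble a resource set
#'
#' @param ... `chem_resource` objects (or one list of them).
#' @param include_list Optional `chem_lexicon` of terms to force-annotate
#'   (applied by [apply_include_stop_lists()]).
#' @param stop_list Optional `chem_lexicon` of terms to force-suppress.
#' @param word_lists A [word_lists()] bundle for post-processing.
#' @param equivalence Equivalence map for abbreviation detection.
#' @return A `resource_set`.
#' @export
resource_set <- function(..., include_list = NULL, stop_list = NULL,
                         word_lists = chemner::word_lists(),
                         equivalence = default_equivalence_map()) {
  res <- list(...)
  if (length(res) == 1 && !inherits(res[[1]], "chem_resource"))
    res <- res[[1]]
  stopifnot(all(vapply(res, inherits, logical(1), "chem_resource")))
  nms <- vapply(res, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate resource name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  for (i in seq_along(res)) {
    if (is.na(res[[i]]$priority)) res[[i]]$priority <- i
  }
  names(res) <- nms
  structure(
    list(resources = res, include_list = include_list,
         stop_list = stop_list, word_lists = word_lists,
         equivalence = equivalence),
    class = "resource_set"
  )
}

#' @export
print.resource_set <- function(x, ...) {
  cat("<resource_set> ", length(x$resources), " resource(s): ",
      paste(names(x$resources), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# candidate spans from one resource over normalized text
resource_candidates <- function(res, text) {
  m <- scan_matches(res$object, text)
  if (res$token_boundary && nrow(m)) {
    chars <- strsplit(text, "")[[1]]
    keep <- vapply(seq_len(nrow(m)), function(i) {
      at_token_boundary(chars, m$start[i], m$end[i])
    }, logical(1))
    m <- m[keep, , drop = FALSE]
  }
  df <- if (is.null(res$digit_filter)) 0L else res$digit_filter
  if (df > 0L && nrow(m)) {
    keep <- vapply(seq_len(nrow(m)), function(i) {
      txt <- substr_cp(text, m$start[i], m$end[i])
      sum(grepl("[0-9]", strsplit(txt, "")[[1]])) >= df
    }, logical(1))
    m <- m[keep, , drop = FALSE]
  }
  m
}

# greedy overlap resolution: longest span wins, ties by priority then start
resolve_overlaps <- function(cand) {
  if (!nrow(cand)) return(cand)
  len <- cand$end - cand$start
  ord <- order(-len, cand$priority, cand$start)
  cand <- cand[ord, , drop = FALSE]
  taken_s <- integer(0)
  taken_e <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]
    e <- cand$end[i]
    if (!any(taken_s < e & s < taken_e)) {
      keep[i] <- TRUE
      taken_s <- c(taken_s, s)
      taken_e <- c(taken_e, e)
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# whitespace-delimited tokens of a text, with punctuation-stripped cores;
# returns 0-based half-open spans of the cores
text_tokens <- function(text) {
  if (!nchar(text)) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0)))
  }
  ml <- gregexpr("[^ \t\n]+", text)
  m <- ml[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0)))
  }
  starts <- as.integer(m) - 1L
  toks <- regmatches(text, ml)[[1]]
  # strip surrounding punctuation to get the core token
  lead <- nchar(sub("^[[:punct:]]*", "", toks, perl = TRUE))
  core_start <- starts + (nchar(toks) - lead)
  core <- sub("^[[:punct:]]*", "", toks, perl = TRUE)
  core <- sub("[],.;:!?)('\"]*$", "", core, perl = TRUE)
  data.frame(start = core_start, end = core_start + nchar(core),
             text = core, stringsAsFactors = FALSE)
}

#' Annotate a document against a resource set
#'
#' For every position of the (normalized) section text, candidate matches
#' are collected from all matching-role resources (longest bracket-valid
#' match per resource per start). Candidates lying inside a blocking
#' resource's match are suppressed. Overlaps are resolved longest-first
#' (ties by resource priority, i.e. manifest order). When correction is
#' enabled, whitespace-delimited tokens not covered by any entity are
#' offered to each correction-enabled resource and annotated if a
#' within-budget correction to an accepted string exists. Entities are
#' reported in source coordinates with resource attribution.
#'
#' @param doc A [source_document()].
#' @param resources A [resource_set()].
#' @param correction Logical: attempt spelling correction of uncovered
#'   tokens using each resource's correction settings.
#' @param correction_override Optional [correction_config()] applied to
#'   every correction-enabled resource (e.g. to grant a generic-edit
#'   budget corpus-wide).
#' @param model An [edit_cost_model()].
#' @param table Normalization table.
#' @return Entity data frame (see [empty_entities()]).
#' @export
annotate <- function(doc, resources, correction = FALSE,
                     correction_override = NULL,
                     model = edit_cost_model(),
                     table = default_normalization_table()) {
  stopifnot(inherits(doc, "source_document"),
            inherits(resources, "resource_set"))
  out <- empty_entities()
  for (si in seq_len(nrow(doc$sections))) {
    label <- doc$sections$label[si]
    raw <- doc$sections$text[si]
    nt <- normalize_text(raw, table = table, xml_mode = doc$is_xml)
    text <- nt$text

    cands <- list()
    blocks <- list()
    for (res in resources$resources) {
      m <- resource_candidates(res, text)
      if (!nrow(m)) next
      m$resource <- res$name
      m$class <- res$entity_class
      m$priority <- res$priority
      if (res$role == "blocking") {
        blocks[[length(blocks) + 1L]] <- m
      } else {
        cands[[length(cands) + 1L]] <- m
      }
    }
    cand <- if (length(cands)) do.call(rbind, cands) else
      data.frame(start = integer(0), end = integer(0),
                 resource = character(0), class = character(0),
                 priority = integer(0))
    if (length(blocks) && nrow(cand)) {
      blk <- do.call(rbind, blocks)
      inside <- vapply(seq_len(nrow(cand)), function(i) {
        any(blk$start <= cand$start[i] & cand$end[i] <= blk$end)
      }, logical(1))
      cand <- cand[!inside, , drop = FALSE]
    }
    cand <- resolve_overlaps(cand)
    corrections <- rep("", nrow(cand))

    if (correction) {
      toks <- text_tokens(text)
      if (nrow(toks)) {
        covered <- vapply(seq_len(nrow(toks)), function(i) {
          any(cand$start < toks$end[i] & toks$start[i] < cand$end)
        }, logical(1))
        toks <- toks[!covered & nchar(toks$text) > 0, , drop = FALSE]
      }
      for (i in seq_len(nrow(toks))) {
        best <- NULL
        best_res <- NULL
        for (res in resources$resources) {
          if (res$role != "matching") next
          ccfg <- res$correction
          if (is.null(ccfg) || !ccfg$enabled) next
          if (!is.null(correction_override)) ccfg <- correction_override
          target <- res$correction_object %||% res$object
          r <- correct_against(target, toks$text[i], model, ccfg)
          if (is.null(r) || is_correction_skipped(r)) next
          if (r$cost == 0) next # exact match was already handled by scanning
          if (is.null(best) || r$cost < best$cost) {
            best <- r
            best_res <- res
          }
        }
        if (!is.null(best)) {
          cand <- rbind(cand, data.frame(
            start = toks$start[i], end = toks$end[i],
            resource = best_res$name, class = best_res$entity_class,
            priority = best_res$priority
          ))
          corrections <- c(corrections, paste0(
            toks$text[i], " -> ", best$corrected,
            " (cost ", format(best$cost), ")"
          ))
        }
      }
      ord <- order(cand$start)
      cand <- cand[ord, , drop = FALSE]
      corrections <- corrections[ord]
    }

    if (!nrow(cand)) next
    # map normalized spans back to source coordinates
    rows <- lapply(seq_len(nrow(cand)), function(i) {
      sp <- map_span(nt, cand$start[i], cand$end[i])
      entity_rows(doc$doc_id, label, sp[1], sp[2],
                  substr_cp(raw, sp[1], sp[2]),
                  cand$class[i], cand$resource[i], corrections[i])
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  rownames(out) <- NULL
  out
}

#' Sum-formula digit filter
#'
#' Keep a sum-formula entity only if its text contains more than two digit
#' characters; short letter-heavy strings like "CDK2" or "CaCo" are then
#' no longer recognized as sum formulae. Entities of other classes pass
#' through untouched.
#'
#' @param entities Entity data frame.
#' @param formula_class Class label of sum-formula entities.
#' @return Filtered entity data frame.
#' @export
filter_sum_formula <- function(entities, formula_class = "formula") {
  if (!nrow(entities)) return(entities)
  digits <- vapply(strsplit(entities$text, ""), function(ch) {
    sum(grepl("[0-9]", ch))
  }, integer(1))
  keep <- entities$class != formula_class | digits > 2L
  out <- entities[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply include and stop lists
#'
#' The include list is an ordinary lexicon: its matches (token-bounded)
#' are added as entities where they do not overlap existing ones. The stop
#' list removes entities whose text equals one of its terms; it is
#' disabled by default (passing `NULL` leaves entities untouched) —
#' corpus-derived stop lists cost more recall than they buy precision.
#'
#' @param entities Entity data frame for `doc`.
#' @param include_list,stop_list `chem_lexicon` or `NULL`.
#' @param doc The [source_document()] the entities came from.
#' @param table Normalization table.
#' @return Updated entity data frame.
#' @export
apply_include_stop_lists <- function(entities, include_list, stop_list, doc,
                                     table = default_normalization_table()) {
  if (!is.null(include_list)) {
    for (si in seq_len(nrow(doc$sections))) {
      label <- doc$sections$label[si]
      raw <- doc$sections$text[si]
      nt <- normalize_text(raw, table = table, xml_mode = doc$is_xml)
      m <- scan_matches(include_list, nt$text)
      if (!nrow(m)) next
      chars <- strsplit(nt$text, "")[[1]]
      keep <- vapply(seq_len(nrow(m)), function(i) {
        at_token_boundary(chars, m$start[i], m$end[i])
      }, logical(1))
      m <- m[keep, , drop = FALSE]
      here <- entities[entities$section == label, , drop = FALSE]
      for (i in seq_len(nrow(m))) {
        sp <- map_span(nt, m$start[i], m$end[i])
        if (nrow(here) && any(here$start < sp[2] & sp[1] < here$end)) next
        entities <- rbind(entities, entity_rows(
          doc$doc_id, label, sp[1], sp[2], substr_cp(raw, sp[1], sp[2]),
          include_list$entity_class, include_list$name
        ))
      }
    }
  }
  if (!is.null(stop_list)) {
    drop <- vapply(entities$text, accepts, logical(1), x = stop_list)
    entities <- entities[!drop, , drop = FALSE]
  }
  entities <- entities[order(entities$section, entities$start), , drop = FALSE]
  rownames(entities) <- NULL
  entities
}
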