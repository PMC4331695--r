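# Weighted-edit spelling correction against an automaton: find the
# lowest-cost edit sequence turning a near-miss token into a string the
# automaton accepts. Generic insertions/deletions/substitutions/
# transpositions carry base costs and are limited by a per-resource budget;
# parameterized error classes (OCR confusions, known typos, erroneous
# space, comma-for-period, missing hyphen) carry reduced costs and are not
# counted against that budget.

#' Edit cost model
#'
#' @param insertion,deletion,substitution,transposition Base costs for the
#'   generic (unparameterized) edits; all must be positive.
#' @param parameterized Data frame with columns `pattern`, `replacement`,
#'   `cost`, `context` describing known error classes: `pattern` is the
#'   erroneous text in the candidate, `replacement` what it should have
#'   been, `cost` the reduced cost (must be below the corresponding base
#'   cost), and `context` one of `""` (always applicable),
#'   `"digit_letter"` (position lies at a digit–letter boundary), or
#'   `"between_digits"`. Defaults to [default_parameterized_errors()].
#' @return An `edit_cost_model`.
#' @export
edit_cost_model <- function(insertion = 1, deletion = 1, substitution = 1,
                            transposition = 1,
                            parameterized = default_parameterized_errors()) {
  stopifnot(insertion > 0, deletion > 0, substitution > 0, transposition > 0)
  if (nrow(parameterized)) {
    stopifnot(all(parameterized$cost > 0),
              all(parameterized$cost <
                    max(insertion, deletion, substitution, transposition)))
  }
  structure(
    list(insertion = insertion, deletion = deletion,
         substitution = substitution, transposition = transposition,
         parameterized = parameterized),
    class = "edit_cost_model"
  )
}

#' Default parameterized error classes
#'
#' OCR confusions (`rn` vs `m`, `l` vs `1`, `O` vs `0`), the common typo
#' `floro` for `fluoro`, erroneous space insertion/deletion at digit–letter
#' boundaries, comma for period between digits, and a missing hyphen. Each
#' is assigned cost 0.3 against base costs of 1.
#'
#' @return Data frame with columns `pattern`, `replacement`, `cost`,
#'   `context`.
#' @export
default_parameterized_errors <- function() {
  data.frame(
    pattern = c("rn", "m", "l", "1", "O", "0", "floro", " ", "", ",", ""),
    replacement = c("m", "rn", "1", "l", "0", "O", "fluoro", "", " ", ".",
                    "-"),
    cost = 0.3,
    context = c("", "", "", "", "", "", "", "", "digit_letter",
                "between_digits", ""),
    stringsAsFactors = FALSE
  )
}

#' Per-resource correction settings
#'
#' @param enabled Whether correction is attempted at all.
#' @param max_unparameterized_edits Budget for generic edits; parameterized
#'   (known-error) edits are not counted against it. `0` restricts
#'   correction to the parameterized error classes only.
#' @param min_entity_length Minimum candidate length for correction to be
#'   attempted.
#' @return A `correction_config`.
#' @export
correction_config <- function(enabled = TRUE, max_unparameterized_edits = 0L,
                              min_entity_length = 6L) {
  stopifnot(max_unparameterized_edits >= 0, min_entity_length >= 0)
  structure(
    list(enabled = enabled,
         max_unparameterized_edits = as.integer(max_unparameterized_edits),
         min_entity_length = as.integer(min_entity_length)),
    class = "correction_config"
  )
}

correction_skipped <- function(reason) {
  structure(list(reason = reason), class = "correction_skipped")
}

#' Was correction skipped (disabled / candidate too short)?
#'
#' Distinguishes "correction was not attempted" from "no correction found"
#' (`NULL`).
#'
#' @param x Result of [correct_against()].
#' @return Logical scalar.
#' @export
is_correction_skipped <- function(x) inherits(x, "correction_skipped")

param_context_ok <- function(ctx, cand_chars, pos) {
  # pos: number of candidate chars consumed so far (edit applies after it)
  if (ctx == "") return(TRUE)
  n <- length(cand_chars)
  prev <- if (pos >= 1L) cand_chars[pos] else ""
  nxt <- if (pos < n) cand_chars[pos + 1L] else ""
  if (ctx == "digit_letter") {
    (grepl("[0-9]", prev) && grepl("[A-Za-z]", nxt)) ||
      (grepl("[A-Za-z]", prev) && grepl("[0-9]", nxt))
  } else if (ctx == "between_digits") {
    nxt2 <- if (pos + 1L < n) cand_chars[pos + 2L] else ""
    grepl("[0-9]", prev) && grepl("[0-9]", nxt2)
  } else {
    stop("unknown parameterized-edit context '", ctx, "'")
  }
}

# feed a string through the automaton from state st; NA if it dies
feed_chars <- function(a, st, chars) {
  if (!length(chars)) return(st)
  enc <- encode_chars(a, chars)
  for (sy in enc) {
    if (is.na(sy)) return(NA_integer_)
    st <- a$trans[st, sy]
    if (st == 0L) return(NA_integer_)
  }
  st
}

#' Correct a candidate string against an automaton
#'
#' Best-first search over (automaton state, candidate position, budget
#' spent) for the minimum-total-cost sequence of edits that transforms
#' `candidate` into a string accepted by `a`. Among equal-cost corrections
#' the tie-break is: fewest edits, then earliest first-edit position, then
#' lexicographically smallest corrected string.
#'
#' @param a A `char_automaton` (or `chem_lexicon`, in which case the best
#'   correction across its automata is returned).
#' @param candidate Candidate string.
#' @param model An [edit_cost_model()].
#' @param cfg A [correction_config()].
#' @return A `correction_result` (fields `corrected`, `edits`, `cost`,
#'   `n_unparameterized`), `NULL` if no accepted string is reachable within
#'   the budget, or a `correction_skipped` sentinel when correction was not
#'   attempted (disabled, or candidate shorter than
#'   `cfg$min_entity_length`); see [is_correction_skipped()].
#' @export
correct_against <- function(a, candidate, model = edit_cost_model(),
                            cfg = correction_config()) {
  if (!cfg$enabled) return(correction_skipped("disabled"))
  if (nchar(candidate) < cfg$min_entity_length)
    return(correction_skipped("too_short"))
  if (inherits(a, "chem_lexicon")) {
    best <- NULL
    for (auto in a$automata) {
      r <- correct_against(auto, candidate, model, cfg)
      if (!is.null(r) && !is_correction_skipped(r) &&
          (is.null(best) || r$cost < best$cost)) {
        best <- r
      }
    }
    return(best)
  }
  stopifnot(inherits(a, "char_automaton"))

  cand_chars <- strsplit(candidate, "")[[1]]
  if (a$fold == "lower") cand_chars <- tolower(cand_chars)
  n <- length(cand_chars)
  pr <- model$parameterized
  max_unp <- cfg$max_unparameterized_edits

  # search nodes
  nodes <- list()
  push <- function(st, pos, unp, cost, nedits, first_edit, out, edits) {
    nodes[[length(nodes) + 1L]] <<- list(
      st = st, pos = pos, unp = unp, cost = cost, nedits = nedits,
      first_edit = first_edit, out = out, edits = edits
    )
  }
  push(1L, 0L, 0L, 0, 0L, Inf, character(0), list())
  best_seen <- new.env(parent = emptyenv()) # key -> best cost
  goals <- list()
  min_goal <- Inf
  expansions <- 0L

  while (length(nodes)) {
    costs <- vapply(nodes, `[[`, numeric(1), "cost")
    ned <- vapply(nodes, `[[`, integer(1), "nedits")
    k <- order(costs, ned)[1]
    node <- nodes[[k]]
    nodes[[k]] <- NULL
    if (node$cost > min_goal + 1e-9) break
    key <- paste(node$st, node$pos, node$unp, sep = ":")
    prev <- best_seen[[key]]
    if (!is.null(prev) && node$cost > prev + 1e-9) next
    assign(key, min(if (is.null(prev)) Inf else prev, node$cost),
           envir = best_seen)
    expansions <- expansions + 1L
    if (expansions > 200000L) break # safety valve; toy resources never hit it

    if (node$pos == n && a$accept[node$st]) {
      if (node$cost < min_goal - 1e-9) {
        min_goal <- node$cost
        goals <- list(node)
      } else if (node$cost <= min_goal + 1e-9) {
        goals[[length(goals) + 1L]] <- node
      }
      next
    }

    st <- node$st
    pos <- node$pos
    nxt_ch <- if (pos < n) cand_chars[pos + 1L] else NA_character_
    nxt_sy <- if (pos < n) match(nxt_ch, a$alphabet) else NA_integer_

    # exact consume
    if (pos < n && !is.na(nxt_sy) && a$trans[st, nxt_sy] != 0L) {
      push(a$trans[st, nxt_sy], pos + 1L, node$unp, node$cost, node$nedits,
           node$first_edit, c(node$out, nxt_ch), node$edits)
    }

    # parameterized errors
    if (nrow(pr)) {
      for (r in seq_len(nrow(pr))) {
        pat <- pr$pattern[r]
        pl <- nchar(pat)
        if (pl > 0) {
          if (pos + pl > n) next
          if (paste(cand_chars[(pos + 1L):(pos + pl)], collapse = "") != pat)
            next
        }
        if (!param_context_ok(pr$context[r], cand_chars, pos)) next
        rep_chars <- if (nchar(pr$replacement[r]))
          strsplit(pr$replacement[r], "")[[1]] else character(0)
        st2 <- feed_chars(a, st, rep_chars)
        if (is.na(st2)) next
        ed <- list(type = "parameterized", at = pos, from = pat,
                   to = pr$replacement[r], cost = pr$cost[r])
        push(st2, pos + pl, node$unp, node$cost + pr$cost[r],
             node$nedits + 1L, min(node$first_edit, pos),
             c(node$out, rep_chars), c(node$edits, list(ed)))
      }
    }

    # generic edits
    if (node$unp < max_unp) {
      live <- which(a$trans[st, ] != 0L)
      # substitution
      if (pos < n) {
        for (sy in live) {
          ch <- a$alphabet[sy]
          if (!is.na(nxt_ch) && ch == nxt_ch) next
          ed <- list(type = "substitution", at = pos, from = nxt_ch, to = ch,
                     cost = model$substitution)
          push(a$trans[st, sy], pos + 1L, node$unp + 1L,
               node$cost + model$substitution, node$nedits + 1L,
               min(node$first_edit, pos), c(node$out, ch),
               c(node$edits, list(ed)))
        }
        # deletion of the candidate char
        ed <- list(type = "deletion", at = pos, from = nxt_ch, to = "",
                   cost = model$deletion)
        push(st, pos + 1L, node$unp + 1L, node$cost + model$deletion,
             node$nedits + 1L, min(node$first_edit, pos), node$out,
             c(node$edits, list(ed)))
        # transposition of the next two candidate chars
        if (pos + 2L <= n) {
          c1 <- cand_chars[pos + 1L]
          c2 <- cand_chars[pos + 2L]
          if (c1 != c2) {
            st2 <- feed_chars(a, st, c(c2, c1))
            if (!is.na(st2)) {
              ed <- list(type = "transposition", at = pos,
                         from = paste0(c1, c2), to = paste0(c2, c1),
                         cost = model$transposition)
              push(st2, pos + 2L, node$unp + 1L,
                   node$cost + model$transposition, node$nedits + 1L,
                   min(node$first_edit, pos), c(node$out, c2, c1),
                   c(node$edits, list(ed)))
            }
          }
        }
      }
      # insertion of an automaton char
      for (sy in live) {
        ch <- a$alphabet[sy]
        ed <- list(type = "insertion", at = pos, from = "", to = ch,
                   cost = model$insertion)
        push(a$trans[st, sy], pos, node$unp + 1L,
             node$cost + model$insertion, node$nedits + 1L,
             min(node$first_edit, pos), c(node$out, ch),
             c(node$edits, list(ed)))
      }
    }
  }

  if (!length(goals)) return(NULL)
  # tie-break: fewest edits, earliest first edit, lexicographically smallest
  ned <- vapply(goals, `[[`, integer(1), "nedits")
  goals <- goals[ned == min(ned)]
  fe <- vapply(goals, `[[`, numeric(1), "first_edit")
  goals <- goals[fe == min(fe)]
  outs <- vapply(goals, function(g) paste(g$out, collapse = ""), character(1))
  win <- goals[[order(outs)[1]]]

  edits_df <- if (length(win$edits)) {
    do.call(rbind, lapply(win$edits, function(e) {
      data.frame(type = e$type, at = e$at, from = e$from, to = e$to,
                 cost = e$cost, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(type = character(0), at = integer(0), from = character(0),
               to = character(0), cost = numeric(0))
  }
  structure(
    list(corrected = paste(win$out, collapse = ""), edits = edits_df,
         cost = win$cost,
         n_unparameterized = win$unp),
    class = "correction_result"
  )
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result> '", x$corrected, "' cost ", format(x$cost),
      " (", nrow(x$edits), " edit(s))\n", sep = "")
  invisible(x)
}
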