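# Grammar rule files: one rule per line, "name : production".
# Productions are built from single-quoted literals, rule or lexicon
# references, juxtaposition (concatenation), '|' (alternation), postfix '*'
# (Kleene star) and '?' (optional), with '(' ')' for grouping. '#' starts a
# comment. Only regular grammars are admitted: the rule-reference graph must
# be acyclic (a rule may not reference itself, directly or indirectly).

tokenize_rule_line <- function(line, lineno) {
  pat <- "'(?:[^'\\\\]|\\\\.)*'|[A-Za-z_][A-Za-z0-9_]*|[|*?():]"
  toks <- character(0)
  rest <- line
  consumed <- 0L
  while (nzchar(trimws(rest))) {
    ws <- regmatches(rest, regexpr("^[ \t]+", rest))
    if (length(ws) && nzchar(ws)) {
      rest <- substring(rest, nchar(ws) + 1L)
      consumed <- consumed + nchar(ws)
      next
    }
    m <- regmatches(rest, regexpr(paste0("^(?:", pat, ")"), rest, perl = TRUE))
    if (!length(m) || !nzchar(m))
      stop("grammar syntax error at line ", lineno, " near: ", rest)
    toks <- c(toks, m)
    rest <- substring(rest, nchar(m) + 1L)
    consumed <- consumed + nchar(m)
  }
  toks
}

unquote_lit <- function(tok) {
  body <- substring(tok, 2, nchar(tok) - 1L)
  body <- gsub("\\\\(.)", "\\1", body)
  body
}

# recursive-descent parser over the token vector
parse_production <- function(toks, lineno) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  parse_alt <- function() {
    parts <- list(parse_cat())
    while (identical(peek(), "|")) {
      take()
      parts[[length(parts) + 1L]] <- parse_cat()
    }
    ex_alt(parts)
  }
  parse_cat <- function() {
    parts <- list()
    repeat {
      t <- peek()
      if (is.na(t) || t %in% c("|", ")")) break
      parts[[length(parts) + 1L]] <- parse_post()
    }
    if (!length(parts))
      stop("empty production at line ", lineno)
    ex_cat(parts)
  }
  parse_post <- function() {
    x <- parse_atom()
    repeat {
      t <- peek()
      if (identical(t, "*")) {
        take()
        x <- ex_star(x)
      } else if (identical(t, "?")) {
        take()
        x <- ex_opt(x)
      } else break
    }
    x
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of production at line ", lineno)
    if (startsWith(t, "'")) {
      v <- unquote_lit(t)
      if (!nzchar(v)) stop("empty literal at line ", lineno)
      return(ex_lit(v))
    }
    if (t == "(") {
      x <- parse_alt()
      if (!identical(take(), ")"))
        stop("unbalanced '(' at line ", lineno)
      return(x)
    }
    if (grepl("^[A-Za-z_]", t)) return(ex_ref(t))
    stop("unexpected token '", t, "' at line ", lineno)
  }
  out <- parse_alt()
  if (pos <= length(toks))
    stop("trailing tokens at line ", lineno, ": ",
         paste(toks[pos:length(toks)], collapse = " "))
  out
}

expr_refs <- function(e) {
  switch(e$kind,
    ref = e$name,
    cat = ,
    alt = unique(unlist(lapply(e$parts, expr_refs))),
    star = ,
    opt = expr_refs(e$x),
    character(0)
  )
}

#' Parse a grammar definition
#'
#' Parses grammar source in the package's rule dialect (see Details) into a
#' `chem_grammar`. Referenced names that are not rules must be declared in
#' `lexicons`; they become dictionary terminals. Regularity is enforced by
#' requiring the rule-reference graph to be acyclic — a rule may not
#' reference itself, directly or indirectly.
#'
#' @details One rule per line, `name : production`. Productions use
#' single-quoted literals, rule/lexicon references, juxtaposition for
#' concatenation, `|` for alternation, postfix `*` and `?`, and `( )` for
#' grouping; `#` starts a comment. For example:
#'
#' ```
#' alkaneStem : 'meth' | 'eth' | 'prop'
#' alkane : alkaneStem 'ane'
#' ```
#'
#' @param source Grammar text (single string with newlines, or a character
#'   vector of lines).
#' @param root Name of the root rule. Defaults to the unique rule that no
#'   other rule references (the top of the grammar), or the last rule if
#'   that is ambiguous.
#' @param lexicons Character vector of lexicon names usable as terminals.
#' @param case_sensitive Logical; if `FALSE` the compiled machine folds case.
#' @return A `chem_grammar`: named list of rules plus `root`,
#'   `lexicon_refs`, and `case_sensitive`.
#' @export
parse_grammar <- function(source, root = NULL, lexicons = character(),
                          case_sensitive = TRUE) {
  lines <- if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
  rules <- list()
  order <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    toks <- tokenize_rule_line(ln, i)
    if (length(toks) < 3 || !grepl("^[A-Za-z_]", toks[1]) || toks[2] != ":")
      stop("expected 'name : production' at line ", i)
    name <- toks[1]
    if (name %in% names(rules))
      stop("duplicate rule '", name, "' at line ", i)
    rules[[name]] <- parse_production(toks[-(1:2)], i)
    order <- c(order, name)
  }
  if (!length(rules)) stop("grammar contains no rules")

  # resolve references; unknown names must be declared lexicons
  lex_refs <- character(0)
  resolve <- function(e) {
    switch(e$kind,
      ref = {
        if (e$name %in% names(rules)) {
          e
        } else if (e$name %in% lexicons) {
          lex_refs <<- unique(c(lex_refs, e$name))
          ex_lex(e$name)
        } else {
          stop("unresolved reference '", e$name, "'")
        }
      },
      cat = ,
      alt = {
        e$parts <- lapply(e$parts, resolve)
        e
      },
      star = ,
      opt = {
        e$x <- resolve(e$x)
        e
      },
      e
    )
  }
  rules <- lapply(rules, resolve)

  # regularity: reference graph must be acyclic
  state <- new.env(parent = emptyenv()) # 1 = visiting, 2 = done
  visit <- function(name, path) {
    s <- state[[name]]
    if (identical(s, 2L)) return(invisible())
    if (identical(s, 1L))
      stop("non-regular grammar: a rule may not reference itself (cycle: ",
           paste(c(path, name), collapse = " -> "), ")")
    assign(name, 1L, envir = state)
    for (r in expr_refs(rules[[name]])) visit(r, c(path, name))
    assign(name, 2L, envir = state)
  }
  for (nm in order) visit(nm, character(0))

  if (is.null(root)) {
    referenced <- unique(unlist(lapply(rules, expr_refs)))
    top <- setdiff(order, referenced)
    root <- if (length(top) == 1) top else order[length(order)]
  }
  if (!root %in% names(rules)) stop("root rule '", root, "' not defined")

  structure(
    list(rules = rules, root = root, lexicon_refs = lex_refs,
         case_sensitive = case_sensitive),
    class = "chem_grammar"
  )
}

#' Read a grammar from a file
#'
#' @param path Path to a grammar file in the rule dialect of
#'   [parse_grammar()].
#' @inheritParams parse_grammar
#' @return A `chem_grammar`.
#' @export
read_grammar <- function(path, root = NULL, lexicons = character(),
                         case_sensitive = TRUE) {
  parse_grammar(readLines(path, encoding = "UTF-8", warn = FALSE),
                root = root, lexicons = lexicons,
                case_sensitive = case_sensitive)
}

#' @export
print.chem_grammar <- function(x, ...) {
  cat("<chem_grammar> ", length(x$rules), " rule(s), root '", x$root, "'",
      if (length(x$lexicon_refs))
        paste0(", lexicon terminals: ", paste(x$lexicon_refs, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# inline every reference so the root becomes a closed expression
inline_grammar <- function(g, lexicon_terms = list()) {
  memo <- new.env(parent = emptyenv())
  inline_expr <- function(e) {
    switch(e$kind,
      ref = inline_rule(e$name),
      lex = {
        terms <- lexicon_terms[[e$name]]
        if (is.null(terms))
          stop("lexicon terminal '", e$name, "' has no terms supplied")
        ex_alt(lapply(terms, ex_lit))
      },
      cat = ,
      alt = {
        e$parts <- lapply(e$parts, inline_expr)
        e
      },
      star = ,
      opt = {
        e$x <- inline_expr(e$x)
        e
      },
      e
    )
  }
  inline_rule <- function(name) {
    got <- memo[[name]]
    if (!is.null(got)) return(got)
    out <- inline_expr(g$rules[[name]])
    assign(name, out, envir = memo)
    out
  }
  inline_rule(g$root)
}

#' Compile a grammar to a deterministic finite-state machine
#'
#' Inlines all rule references (the grammar is acyclic, so this terminates),
#' expands lexicon terminals into alternations over their terms, builds a
#' nondeterministic machine by Thompson construction, and determinizes it by
#' subset construction. The result accepts exactly the language of the
#' grammar's root rule.
#'
#' @param g A `chem_grammar` from [parse_grammar()].
#' @param lexicons Named list supplying terms for lexicon terminals; each
#'   element is a character vector of terms or a `chem_lexicon`.
#' @return A `char_automaton` usable with [match_longest()], [accepts()].
#' @export
compile_grammar <- function(g, lexicons = list()) {
  stopifnot(inherits(g, "chem_grammar"))
  terms <- lapply(lexicons, function(l) {
    if (inherits(l, "chem_lexicon")) l$terms else as.character(l)
  })
  expr <- inline_grammar(g, terms)
  fold <- if (g$case_sensitive) "none" else "lower"
  if (fold == "lower") expr <- fold_expr(expr)
  compile_expr(expr, fold = fold)
}

fold_expr <- function(e) {
  switch(e$kind,
    lit = {
      e$value <- tolower(e$value)
      e
    },
    cat = ,
    alt = {
      e$parts <- lapply(e$parts, fold_expr)
      e
    },
    star = ,
    opt = {
      e$x <- fold_expr(e$x)
      e
    },
    e
  )
}

#' Compile a two-level (layered) automaton
#'
#' The master grammar is compiled over an alphabet of sub-machine labels:
#' each transition of the master machine corresponds to a whole sub-machine
#' rather than a single character. This keeps global nomenclature context
#' (what may follow a substituent in this position) separate from the local
#' machines that consume actual text, so one sub-machine can be reused in
#' different contexts.
#'
#' Literals appearing in the master grammar are wrapped into implicit
#' single-string sub-machines.
#'
#' @param master A `chem_grammar` whose terminals are names in `subs` (or
#'   literals).
#' @param subs Named list of compiled sub-machines (`char_automaton`) and/or
#'   `chem_lexicon` objects.
#' @return A `layered_automaton`.
#' @export
compile_layered <- function(master, subs) {
  stopifnot(inherits(master, "chem_grammar"))
  subs <- as.list(subs)
  extra <- list()
  to_syms <- function(e) {
    switch(e$kind,
      ref = {
        if (e$name %in% names(master$rules)) {
          to_syms(inline_grammar_rule(master, e$name))
        } else stop("unresolved sub-machine name '", e$name, "'")
      },
      lex = {
        if (!e$name %in% names(subs))
          stop("unresolved sub-machine name '", e$name, "'")
        ex_sym(e$name)
      },
      lit = {
        label <- paste0(".lit:", e$value)
        if (is.null(extra[[label]]))
          extra[[label]] <<- compile_terms(e$value)
        ex_sym(label)
      },
      cat = ,
      alt = {
        e$parts <- lapply(e$parts, to_syms)
        e
      },
      star = ,
      opt = {
        e$x <- to_syms(e$x)
        e
      },
      e
    )
  }
  # treat unknown refs as sub names: re-resolve with subs as "lexicons"
  resolved <- parse_ready_master(master, names(subs))
  expr <- to_syms(inline_master(resolved))
  mast <- compile_expr(expr, fold = "none")
  layered_automaton(mast, c(subs, extra))
}

# Rules of the master may reference other master rules; inline those, leaving
# lex nodes (sub-machine references) intact.
inline_master <- function(g) {
  memo <- new.env(parent = emptyenv())
  go <- function(e) {
    switch(e$kind,
      ref = rule(e$name),
      cat = ,
      alt = {
        e$parts <- lapply(e$parts, go)
        e
      },
      star = ,
      opt = {
        e$x <- go(e$x)
        e
      },
      e
    )
  }
  rule <- function(name) {
    got <- memo[[name]]
    if (!is.null(got)) return(got)
    out <- go(g$rules[[name]])
    assign(name, out, envir = memo)
    out
  }
  rule(g$root)
}

inline_grammar_rule <- function(g, name) g$rules[[name]]

# If the master grammar was parsed without declaring the sub names as
# lexicons, its unknown references were already rejected at parse time; this
# helper lets compile_layered accept a master parsed with
# `lexicons = names(subs)` and passes through otherwise.
parse_ready_master <- function(master, sub_names) {
  ok <- vapply(master$rules, function(r) {
    length(setdiff(expr_refs(r), names(master$rules))) == 0
  }, logical(1))
  if (all(ok)) return(master)
  stop("master grammar has unresolved references; parse it with ",
       "lexicons = names(subs)")
}
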