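# Finite-state machinery: expression trees -> NFA (Thompson construction)
# -> DFA (subset construction), plus a direct trie compiler for term lists,
# longest-match scanning with bracket tracking, and the two-level
# ("layered") automaton used for context-dependent nomenclature.

# --- expression tree constructors (internal) --------------------------------
ex_lit <- function(s) list(kind = "lit", value = s)
ex_sym <- function(label) list(kind = "sym", label = label)
ex_ref <- function(name) list(kind = "ref", name = name)
ex_lex <- function(name) list(kind = "lex", name = name)
ex_cat <- function(parts) {
  if (length(parts) == 1) parts[[1]] else list(kind = "cat", parts = parts)
}
ex_alt <- function(parts) {
  if (length(parts) == 1) parts[[1]] else list(kind = "alt", parts = parts)
}
ex_star <- function(x) list(kind = "star", x = x)
ex_opt <- function(x) list(kind = "opt", x = x)

expr_symbols <- function(e) {
  switch(e$kind,
    lit = strsplit(e$value, "")[[1]],
    sym = e$label,
    cat = ,
    alt = unlist(lapply(e$parts, expr_symbols)),
    star = ,
    opt = expr_symbols(e$x),
    stop("unresolved node of kind '", e$kind, "' at compile time")
  )
}

# --- Thompson construction --------------------------------------------------
# NFA held in an environment: integer edge lists (from, to, sym), sym 0 = eps.
nfa_env <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$from <- integer(0)
  env$to <- integer(0)
  env$sym <- integer(0)
  env
}
nfa_state <- function(env) {
  env$n <- env$n + 1L
  env$n
}
nfa_edge <- function(env, f, t, s) {
  k <- length(env$from) + 1L
  env$from[k] <- f
  env$to[k] <- t
  env$sym[k] <- s
}

thompson <- function(e, env, symtab) {
  switch(e$kind,
    lit = {
      syms <- match(strsplit(e$value, "")[[1]], symtab)
      s <- nfa_state(env)
      cur <- s
      for (sy in syms) {
        nxt <- nfa_state(env)
        nfa_edge(env, cur, nxt, sy)
        cur <- nxt
      }
      c(s, cur)
    },
    sym = {
      s <- nfa_state(env)
      t <- nfa_state(env)
      nfa_edge(env, s, t, match(e$label, symtab))
      c(s, t)
    },
    cat = {
      frags <- lapply(e$parts, thompson, env = env, symtab = symtab)
      for (i in seq_len(length(frags) - 1L))
        nfa_edge(env, frags[[i]][2], frags[[i + 1L]][1], 0L)
      c(frags[[1]][1], frags[[length(frags)]][2])
    },
    alt = {
      s <- nfa_state(env)
      t <- nfa_state(env)
      for (p in e$parts) {
        f <- thompson(p, env, symtab)
        nfa_edge(env, s, f[1], 0L)
        nfa_edge(env, f[2], t, 0L)
      }
      c(s, t)
    },
    star = {
      s <- nfa_state(env)
      t <- nfa_state(env)
      f <- thompson(e$x, env, symtab)
      nfa_edge(env, s, f[1], 0L)
      nfa_edge(env, f[2], t, 0L)
      nfa_edge(env, f[2], f[1], 0L)
      nfa_edge(env, s, t, 0L)
      c(s, t)
    },
    opt = {
      s <- nfa_state(env)
      t <- nfa_state(env)
      f <- thompson(e$x, env, symtab)
      nfa_edge(env, s, f[1], 0L)
      nfa_edge(env, f[2], t, 0L)
      nfa_edge(env, s, t, 0L)
      c(s, t)
    },
    stop("cannot compile node of kind '", e$kind, "'")
  )
}

# --- subset construction ----------------------------------------------------
char_automaton <- function(alphabet, trans, accept, fold = "none") {
  structure(
    list(alphabet = alphabet, trans = trans, accept = accept, fold = fold),
    class = "char_automaton"
  )
}

#' @export
print.char_automaton <- function(x, ...) {
  cat("<char_automaton> ", nrow(x$trans), " states, alphabet size ",
      length(x$alphabet), if (x$fold == "lower") ", case-folded" else "",
      "\n", sep = "")
  invisible(x)
}

compile_expr <- function(expr, fold = "none") {
  symtab <- sort(unique(expr_symbols(expr)))
  env <- nfa_env()
  frag <- thompson(expr, env, symtab)
  nsym <- length(symtab)

  # adjacency lists
  eps_adj <- vector("list", env$n)
  sym_adj <- vector("list", env$n) # each: list per symbol of targets
  ef <- env$from[env$sym == 0L]
  et <- env$to[env$sym == 0L]
  for (i in seq_along(ef)) eps_adj[[ef[i]]] <- c(eps_adj[[ef[i]]], et[i])
  sf <- env$from[env$sym != 0L]
  st <- env$to[env$sym != 0L]
  ss <- env$sym[env$sym != 0L]

  closure <- function(states) {
    seen <- states
    queue <- states
    while (length(queue)) {
      s <- queue[[1]]
      queue <- queue[-1]
      for (t in eps_adj[[s]]) {
        if (!(t %in% seen)) {
          seen <- c(seen, t)
          queue <- c(queue, t)
        }
      }
    }
    sort(unique(seen))
  }

  start_set <- closure(frag[1])
  key <- function(s) paste(s, collapse = ",")
  ids <- new.env(parent = emptyenv())
  assign(key(start_set), 1L, envir = ids)
  sets <- list(start_set)
  trans_rows <- list()
  accept <- logical(0)
  q <- 1L
  while (q <= length(sets)) {
    cur <- sets[[q]]
    accept[q] <- frag[2] %in% cur
    row <- integer(nsym)
    for (sy in seq_len(nsym)) {
      tgt <- st[ss == sy & sf %in% cur]
      if (length(tgt)) {
        cl <- closure(unique(tgt))
        k <- key(cl)
        id <- ids[[k]]
        if (is.null(id)) {
          sets[[length(sets) + 1L]] <- cl
          id <- length(sets)
          assign(k, id, envir = ids)
        }
        row[sy] <- id
      }
    }
    trans_rows[[q]] <- row
    q <- q + 1L
  }
  trans <- do.call(rbind, trans_rows)
  char_automaton(symtab, trans, accept, fold = fold)
}

# --- direct trie compiler for term lists ------------------------------------
compile_terms <- function(terms, fold = "none") {
  stopifnot(length(terms) >= 1)
  if (fold == "lower") terms <- tolower(terms)
  split_terms <- strsplit(terms, "")
  alphabet <- sort(unique(unlist(split_terms)))
  nsym <- length(alphabet)
  cap <- sum(nchar(terms)) + 1L
  trans <- matrix(0L, nrow = cap, ncol = nsym)
  accept <- logical(cap)
  nstate <- 1L
  for (tc in split_terms) {
    cur <- 1L
    for (sy in match(tc, alphabet)) {
      nxt <- trans[cur, sy]
      if (nxt == 0L) {
        nstate <- nstate + 1L
        trans[cur, sy] <- nstate
        nxt <- nstate
      }
      cur <- nxt
    }
    accept[cur] <- TRUE
  }
  char_automaton(alphabet, trans[seq_len(nstate), , drop = FALSE],
                 accept[seq_len(nstate)], fold = fold)
}

# --- matching ---------------------------------------------------------------
.open_brackets <- c("(", "[", "{")
.close_brackets <- c(")", "]", "}")
names(.close_brackets) <- .open_brackets
.opener_for <- c(")" = "(", "]" = "[", "}" = "{")

encode_chars <- function(a, chars) {
  if (a$fold == "lower") chars <- tolower(chars)
  match(chars, a$alphabet)
}

# All end positions (1-based char index of last consumed char) of accepted,
# bracket-valid prefixes starting at start_i. With check_brackets = FALSE all
# accepted prefixes are returned (used by sub-machines, whose bracket state
# is tracked globally by the caller).
automaton_ends <- function(a, enc, chars, start_i, check_brackets = TRUE) {
  trans <- a$trans
  accept <- a$accept
  st <- 1L
  i <- start_i
  n <- length(enc)
  ends <- integer(0)
  stack <- character(0)
  while (i <= n) {
    sy <- enc[i]
    if (is.na(sy)) break
    st <- trans[st, sy]
    if (st == 0L) break
    if (check_brackets) {
      ch <- chars[i]
      if (ch %in% .open_brackets) {
        stack <- c(stack, ch)
      } else if (ch %in% names(.opener_for)) {
        if (length(stack) && stack[length(stack)] == .opener_for[[ch]]) {
          stack <- stack[-length(stack)]
        } else {
          break # ill-nested: no longer prefix can be valid
        }
      }
      if (accept[st] && !length(stack)) ends <- c(ends, i)
    } else if (accept[st]) {
      ends <- c(ends, i)
    }
    i <- i + 1L
  }
  ends
}

# bracket validity per prefix of chars[start_i..]: ok[k] says the prefix
# ending at absolute index k is balanced and well-nested
bracket_ok_prefix <- function(chars, start_i, end_i) {
  ok <- logical(end_i - start_i + 1L)
  stack <- character(0)
  broken <- FALSE
  for (i in start_i:end_i) {
    ch <- chars[i]
    if (!broken) {
      if (ch %in% .open_brackets) {
        stack <- c(stack, ch)
      } else if (ch %in% names(.opener_for)) {
        if (length(stack) && stack[length(stack)] == .opener_for[[ch]])
          stack <- stack[-length(stack)]
        else broken <- TRUE
      }
    }
    ok[i - start_i + 1L] <- !broken && !length(stack)
  }
  ok
}

#' Longest accepted match at a position
#'
#' Returns the longest prefix of `text` starting at `start` (0-based) that
#' is accepted by the automaton and whose brackets `( ) [ ] { }` end
#' balanced and well-nested, as a half-open span `c(start, end)`; `NULL`
#' if no non-empty prefix qualifies.
#'
#' @param x A `char_automaton`, `layered_automaton`, or `chem_lexicon`.
#' @param text Character scalar to scan.
#' @param start 0-based start position.
#' @param ... Unused.
#' @return Integer span `c(start, end)` (0-based half-open) or `NULL`.
#' @export
match_longest <- function(x, text, start = 0L, ...) UseMethod("match_longest")

#' @export
match_longest.char_automaton <- function(x, text, start = 0L, ...) {
  chars <- strsplit(text, "")[[1]]
  if (start < 0 || start > length(chars)) stop("start out of bounds")
  if (start == length(chars)) return(NULL)
  enc <- encode_chars(x, chars)
  ends <- automaton_ends(x, enc, chars, start + 1L)
  if (!length(ends)) return(NULL)
  as.integer(c(start, max(ends)))
}

#' Whole-string acceptance
#'
#' `TRUE` iff the entire string is accepted by the automaton (including the
#' bracket-validity requirement applied during matching).
#'
#' @inheritParams match_longest
#' @param s Candidate string.
#' @return Logical scalar.
#' @export
accepts <- function(x, s, ...) UseMethod("accepts")

#' @export
accepts.char_automaton <- function(x, s, ...) {
  if (!nchar(s)) return(FALSE)
  m <- match_longest(x, s, 0L)
  !is.null(m) && m[2] == nchar(s)
}

# All matches over a text: longest bracket-valid match per start position.
# Returns data.frame(start, end), 0-based half-open.
scan_matches <- function(x, text, ...) UseMethod("scan_matches")

#' @export
scan_matches.char_automaton <- function(x, text, ...) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  if (!n) return(data.frame(start = integer(0), end = integer(0)))
  enc <- encode_chars(x, chars)
  # candidate starts: first transition exists
  first <- x$trans[1L, ]
  starts <- which(!is.na(enc) & first[enc] != 0L)
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in starts) {
    ends <- automaton_ends(x, enc, chars, i)
    if (length(ends)) {
      out_s <- c(out_s, i - 1L)
      out_e <- c(out_e, max(ends))
    }
  }
  data.frame(start = out_s, end = out_e)
}

# --- random sampling from an automaton's language ---------------------------
# Used by the synthetic corpus generator. Biased walk that stops at an
# accepting state with probability p_stop; length capped (fixture strings
# stay readable).
sample_automaton <- function(a, max_len = 20L, p_stop = 0.5, max_tries = 50L) {
  # distance-to-accept so walks can't strand in dead ends
  nst <- nrow(a$trans)
  dist <- rep(Inf, nst)
  dist[a$accept] <- 0
  repeat {
    changed <- FALSE
    for (s in seq_len(nst)) {
      tg <- a$trans[s, ]
      tg <- tg[tg != 0L]
      if (length(tg)) {
        d <- min(dist[tg]) + 1
        if (d < dist[s]) {
          dist[s] <- d
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  for (try in seq_len(max_tries)) {
    st <- 1L
    out <- character(0)
    repeat {
      if (a$accept[st] && (stats::runif(1) < p_stop ||
                           length(out) >= max_len)) {
        return(paste(out, collapse = ""))
      }
      syms <- which(a$trans[st, ] != 0L)
      # only follow transitions that can still reach acceptance in budget
      syms <- syms[dist[a$trans[st, syms]] <= max_len - length(out) - 1L]
      if (!length(syms)) {
        if (a$accept[st]) return(paste(out, collapse = ""))
        break
      }
      sy <- if (length(syms) == 1L) syms else sample(syms, 1L)
      out <- c(out, a$alphabet[sy])
      st <- a$trans[st, sy]
    }
  }
  stop("could not sample an accepted string within length ", max_len)
}

# --- layered (two-level) automaton ------------------------------------------
layered_automaton <- function(master, subs) {
  stopifnot(inherits(master, "char_automaton"))
  missing <- setdiff(master$alphabet, names(subs))
  if (length(missing))
    stop("unresolved sub-machine name(s): ", paste(missing, collapse = ", "))
  structure(list(master = master, subs = subs), class = "layered_automaton")
}

#' @export
print.layered_automaton <- function(x, ...) {
  cat("<layered_automaton> master over {",
      paste(x$master$alphabet, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# flatten a sub-machine (char_automaton or chem_lexicon) into its list of
# automata with text encodings precomputed once per scan
sub_parts <- function(sub, chars) {
  autos <- if (inherits(sub, "chem_lexicon")) sub$automata else list(sub)
  lapply(autos, function(a) list(a = a, enc = encode_chars(a, chars)))
}

sub_ends <- function(parts, chars, start_i) {
  ends <- integer(0)
  for (p in parts) {
    ends <- c(ends, automaton_ends(p$a, p$enc, chars, start_i,
                                   check_brackets = FALSE))
  }
  sort(unique(ends))
}

layered_ends <- function(x, chars, start_i, parts_by_sym = NULL) {
  n <- length(chars)
  if (start_i > n) return(integer(0))
  if (is.null(parts_by_sym))
    parts_by_sym <- lapply(x$master$alphabet,
                           function(nm) sub_parts(x$subs[[nm]], chars))
  master <- x$master
  # states_at[[pos offset]] = set of master states reachable having consumed
  # chars start_i..pos (1-based absolute; offset pos - start_i + 2 with
  # offset 1 meaning "nothing consumed")
  width <- n - start_i + 2L
  states_at <- vector("list", width)
  states_at[[1L]] <- 1L
  accept_ends <- integer(0)
  for (off in seq_len(width)) {
    sts <- states_at[[off]]
    if (is.null(sts)) next
    pos <- start_i + off - 1L # next char to consume (absolute, 1-based)
    for (st in sts) {
      if (off > 1L && master$accept[st])
        accept_ends <- c(accept_ends, pos - 1L)
      if (pos > n) next
      for (sy in which(master$trans[st, ] != 0L)) {
        ends <- sub_ends(parts_by_sym[[sy]], chars, pos)
        nst <- master$trans[st, sy]
        for (e in ends) {
          o2 <- e - start_i + 2L
          states_at[[o2]] <- unique(c(states_at[[o2]], nst))
        }
      }
    }
  }
  sort(unique(accept_ends))
}

#' @export
match_longest.layered_automaton <- function(x, text, start = 0L, ...) {
  chars <- strsplit(text, "")[[1]]
  if (start < 0 || start > length(chars)) stop("start out of bounds")
  if (start == length(chars)) return(NULL)
  ends <- layered_ends(x, chars, start + 1L)
  if (!length(ends)) return(NULL)
  ok <- bracket_ok_prefix(chars, start + 1L, max(ends))
  ends <- ends[ok[ends - start]]
  if (!length(ends)) return(NULL)
  as.integer(c(start, max(ends)))
}

#' @export
accepts.layered_automaton <- function(x, s, ...) {
  if (!nchar(s)) return(FALSE)
  m <- match_longest(x, s, 0L)
  !is.null(m) && m[2] == nchar(s)
}

#' @export
scan_matches.layered_automaton <- function(x, text, ...) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  out_s <- integer(0)
  out_e <- integer(0)
  if (n) {
    parts <- lapply(x$master$alphabet,
                    function(nm) sub_parts(x$subs[[nm]], chars))
    for (i in seq_len(n)) {
      ends <- layered_ends(x, chars, i, parts_by_sym = parts)
      if (!length(ends)) next
      ok <- bracket_ok_prefix(chars, i, max(ends))
      ends <- ends[ok[ends - i + 1L]]
      if (length(ends)) {
        out_s <- c(out_s, i - 1L)
        out_e <- c(out_e, max(ends))
      }
    }
  }
  data.frame(start = out_s, end = out_e)
}

# --- portable serialization -------------------------------------------------

#' Write/read a compiled automaton in a portable text format
#'
#' The format is line-oriented UTF-8, suitable for caching compiled
#' grammars: a header (`chemner-automaton 1`), the fold mode, the
#' alphabet (one symbol per line, `\uXXXX`-escaped), the accepting-state
#' flags, and one transition-matrix row per state (0 = no transition).
#'
#' @param a A `char_automaton`.
#' @param path File path.
#' @return `path` (write) or the restored `char_automaton` (read).
#' @export
write_automaton <- function(a, path) {
  stopifnot(inherits(a, "char_automaton"))
  esc <- function(x) {
    vapply(x, function(s) {
      cp <- utf8ToInt(s)
      if (length(cp) == 1 && (cp < 32 || cp > 126 || cp == 92)) {
        sprintf("\\u%04x", cp)
      } else s
    }, character(1), USE.NAMES = FALSE)
  }
  lines <- c(
    "chemner-automaton 1",
    paste("fold", a$fold),
    paste("alphabet", length(a$alphabet)),
    esc(a$alphabet),
    paste("states", nrow(a$trans)),
    paste("accept", paste(as.integer(a$accept), collapse = " ")),
    vapply(seq_len(nrow(a$trans)), function(i) {
      paste(a$trans[i, ], collapse = " ")
    }, character(1))
  )
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_automaton
#' @export
read_automaton <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!identical(lines[1], "chemner-automaton 1"))
    stop("not a chemner automaton file: ", path)
  fold <- sub("^fold ", "", lines[2])
  nsym <- as.integer(sub("^alphabet ", "", lines[3]))
  unesc <- function(s) {
    if (grepl("^\\\\u[0-9a-fA-F]{4}$", s)) {
      intToUtf8(strtoi(substring(s, 3), 16L))
    } else s
  }
  alphabet <- vapply(lines[3L + seq_len(nsym)], unesc, character(1),
                     USE.NAMES = FALSE)
  i <- 4L + nsym
  nstate <- as.integer(sub("^states ", "", lines[i]))
  accept <- as.logical(as.integer(strsplit(sub("^accept ", "",
                                               lines[i + 1L]), " ")[[1]]))
  rows <- lapply(lines[i + 1L + seq_len(nstate)], function(l) {
    as.integer(strsplit(l, " ", fixed = TRUE)[[1]])
  })
  char_automaton(alphabet, do.call(rbind, rows), accept, fold = fold)
}
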