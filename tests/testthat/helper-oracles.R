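# Independent oracles used across the test suite. These deliberately do
# NOT share code with the package: regular-expression/enumeration oracles
# for the grammar automata, and a dynamic-programming weighted edit
# distance for spelling correction.

# regular-expression oracles for the built-in grammars, written directly
# from the printed rules
oracle_regexes <- function() {
  elements <- c("Na", "Mg", "Al", "Si", "Cl", "Ca", "Fe", "Cu", "Zn", "Br",
                "Ag", "Au", "Li", "Se", "C", "H", "N", "O", "S", "P", "F",
                "B", "I", "K", "W", "U") # two-letter symbols first
  stems <- c("undec", "dodec", "meth", "eth", "prop", "but", "pent", "hex",
             "hept", "oct", "non", "dec")
  list(
    cid = "^CID:[1-9][0-9]*$",
    cas = "^[1-9][0-9]{1,6}-[0-9]{2}-[0-9]$",
    registry = "^[A-Z]{2,4}[1-9][0-9]{3,}$",
    alkane = paste0("^(cyclo)?(", paste(stems, collapse = "|"), ")ane$"),
    sum_formula = paste0("^((", paste(elements, collapse = "|"),
                         ")([1-9][0-9]*)?)+$")
  )
}

# all strings over `alphabet` of length 1..max_len
enumerate_strings <- function(alphabet, max_len) {
  out <- character(0)
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), l),
                      list(stringsAsFactors = FALSE)))
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# single-character perturbations of a string over an alphabet
perturb_strings <- function(s, alphabet) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- character(0)
  for (i in seq_len(n)) {
    for (a in alphabet) {
      sub <- chars
      sub[i] <- a
      out <- c(out, paste(sub, collapse = ""))
    }
    out <- c(out, paste(chars[-i], collapse = ""))
  }
  for (a in alphabet) out <- c(out, paste0(s, a), paste0(a, s))
  unique(out[nzchar(out)])
}

# --- DP oracle for weighted edit distance against a single target -----------
# Mirrors the cost model semantics: generic insert/delete/substitute/
# transpose with base costs and a budget, parameterized (pattern ->
# replacement) rewrites at reduced cost, not counted against the budget.
oracle_param_ok <- function(ctx, cand_chars, pos) {
  if (ctx == "") return(TRUE)
  n <- length(cand_chars)
  prev <- if (pos >= 1) cand_chars[pos] else ""
  nxt <- if (pos < n) cand_chars[pos + 1] else ""
  if (ctx == "digit_letter") {
    (grepl("[0-9]", prev) && grepl("[A-Za-z]", nxt)) ||
      (grepl("[A-Za-z]", prev) && grepl("[0-9]", nxt))
  } else if (ctx == "between_digits") {
    nxt2 <- if (pos + 1 < n) cand_chars[pos + 2] else ""
    grepl("[0-9]", prev) && grepl("[0-9]", nxt2)
  } else {
    FALSE
  }
}

oracle_edit_cost <- function(cand, target, model, max_unp) {
  cc <- strsplit(cand, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  n <- length(cc)
  m <- length(tc)
  pr <- model$parameterized
  INF <- Inf
  # d[i+1, j+1, k+1]: min cost consuming i cand chars -> j target chars
  # with k generic edits spent
  d <- array(INF, dim = c(n + 1, m + 1, max_unp + 1))
  d[1, 1, 1] <- 0
  for (i in 0:n) {
    for (j in 0:m) {
      for (k in 0:max_unp) {
        cur <- d[i + 1, j + 1, k + 1]
        if (!is.finite(cur)) next
        relax <- function(i2, j2, k2, cost) {
          if (k2 > max_unp) return()
          if (cur + cost < d[i2 + 1, j2 + 1, k2 + 1]) {
            d[i2 + 1, j2 + 1, k2 + 1] <<- cur + cost
          }
        }
        if (i < n && j < m && cc[i + 1] == tc[j + 1]) relax(i + 1, j + 1, k, 0)
        if (i < n && j < m && cc[i + 1] != tc[j + 1])
          relax(i + 1, j + 1, k + 1, model$substitution)
        if (i < n) relax(i + 1, j, k + 1, model$deletion)
        if (j < m) relax(i, j + 1, k + 1, model$insertion)
        if (i + 2 <= n && j + 2 <= m && cc[i + 1] != cc[i + 2] &&
            cc[i + 1] == tc[j + 2] && cc[i + 2] == tc[j + 1])
          relax(i + 2, j + 2, k + 1, model$transposition)
        for (r in seq_len(nrow(pr))) {
          pat <- pr$pattern[r]
          rep_ <- pr$replacement[r]
          pl <- nchar(pat)
          ql <- nchar(rep_)
          if (i + pl > n || j + ql > m) next
          if (pl > 0 &&
              paste(cc[(i + 1):(i + pl)], collapse = "") != pat) next
          if (ql > 0 &&
              paste(tc[(j + 1):(j + ql)], collapse = "") != rep_) next
          if (!oracle_param_ok(pr$context[r], cc, i)) next
          relax(i + pl, j + ql, k, pr$cost[r])
        }
      }
    }
  }
  min(d[n + 1, m + 1, ])
}

oracle_lexicon_cost <- function(cand, terms, model, max_unp) {
  min(vapply(terms, oracle_edit_cost, numeric(1), cand = cand,
             model = model, max_unp = max_unp))
}

# enumeration oracle for the alkane language
oracle_alkane_terms <- function() {
  stems <- c("meth", "eth", "prop", "but", "pent", "hex", "hept", "oct",
             "non", "dec", "undec", "dodec")
  c(paste0(stems, "ane"), paste0("cyclo", stems, "ane"))
}

# brute-force bracket balance check
oracle_brackets_balanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  pairs <- c("(" = ")", "[" = "]", "{" = "}")
  stack <- character(0)
  for (ch in chars) {
    if (ch %in% names(pairs)) {
      stack <- c(stack, pairs[[ch]])
    } else if (ch %in% pairs) {
      if (!length(stack) || stack[length(stack)] != ch) return(FALSE)
      stack <- stack[-length(stack)]
    }
  }
  length(stack) == 0
}

# vectorized acceptance over many strings
accepts_all <- function(a, strings) {
  vapply(strings, function(s) accepts(a, s), logical(1), USE.NAMES = FALSE)
}

# tiny corpus builder used by evaluation / include-list tests
tiny_doc <- function(id, abstract) source_document(id, abstract = abstract)
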