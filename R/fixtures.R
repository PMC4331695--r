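# Built-in demonstrative resources (toy stand-ins for the real large
# dictionaries and the full nomenclature grammar) and a seeded synthetic
# corpus generator, so the entire pipeline is exercisable with no external
# downloads. Gold spans are recorded at injection time, which makes the
# noise-free corpus perfectly recoverable by construction.

#' Sources of the built-in grammars
#'
#' The demonstrative grammar subset shipped with the package, in the rule
#' dialect of [parse_grammar()]: PubChem compound identifiers (CID), CAS
#' registry numbers (2-7 digits, 2 digits, 1 digit, hyphen-separated),
#' company registry numbers, sum formulae, and alkanes.
#'
#' @return Named list of grammar source strings.
#' @export
builtin_grammar_sources <- function() {
  digits <- paste0("digit1to9 : ", paste(sprintf("'%d'", 1:9), collapse = "|"),
                   "\ndigit : digit1to9 | '0'\n")
  list(
    cid = paste0(digits, "cid : 'CID:' digit1to9 digit*\n"),
    cas = paste0(digits,
                 "cas : digit1to9 digit digit? digit? digit? digit? digit?",
                 " '-' digit digit '-' digit\n"),
    registry = paste0(
      digits,
      "upper : ", paste(sprintf("'%s'", LETTERS), collapse = "|"), "\n",
      "registry : upper upper upper? upper? digit1to9 digit digit digit",
      " digit* \n"
    ),
    sum_formula = paste0(
      digits,
      "element : ", paste(sprintf("'%s'",
                                  c("C", "H", "N", "O", "S", "P", "F", "B",
                                    "I", "K", "W", "U", "Na", "Mg", "Al",
                                    "Si", "Cl", "Ca", "Fe", "Cu", "Zn",
                                    "Br", "Ag", "Au", "Li", "Se")),
                          collapse = "|"), "\n",
      "count : digit1to9 digit*\n",
      "part : element count?\n",
      "formula : part part*\n"
    ),
    alkane = paste0(
      "alkaneStem : 'meth' | 'eth' | 'prop' | 'but' | 'pent' | 'hex' |",
      " 'hept' | 'oct' | 'non' | 'dec' | 'undec' | 'dodec'\n",
      "alkane : 'cyclo'? alkaneStem 'ane'\n"
    )
  )
}

# enumerate the (finite) alkane language; used as parents of the
# semi-systematic layered grammar
alkane_terms <- function() {
  stems <- c("meth", "eth", "prop", "but", "pent", "hex", "hept", "oct",
             "non", "dec", "undec", "dodec")
  c(paste0(stems, "ane"), paste0("cyclo", stems, "ane"))
}

builtin_term_sets <- function() {
  list(
    drug = c("vancomycin", "paracetamol", "aspirin", "ibuprofen", "caffeine",
             "morphine", "nicotine", "nornicotine", "codeine", "quercetin",
             "genistein", "daidzein", "limonene", "menthol", "cholesterol",
             "estradiol", "testosterone", "glucose", "fructose", "ethanol",
             "resorcinol", "formaldehyde", "acetone", "glutathione",
             "tetrahydrofuran", "methylmercury", "proline", "leucine",
             "glycine", "tyrosine", "dopamine", "serotonin", "melatonin",
             "guanosine", "adenosine", "pyridine",
             "cyclic guanosine monophosphate"),
    element = c("silver", "mercury", "sodium", "potassium", "calcium",
                "magnesium", "copper", "zinc", "platinum", "palladium",
                "protactinium", "indium", "arsenic", "gold", "iron"),
    allotrope = c("red phosphorus", "white phosphorus", "graphite",
                  "diamond", "ozone", "fullerene"),
    alloy = c("pig iron", "brass", "bronze", "solder", "amalgam"),
    chem_abbrev = c("TMEDA", "DMSO", "DMF", "EDTA", "EtOH", "MeOH"),
    chem_class = c("alkaloid", "alkaloids", "isoflavonoid", "isoflavonoids",
                   "flavonoid", "flavonoids", "monoterpene", "monoterpenes",
                   "terpenoid", "terpenoids", "sterol", "sterols", "steroid",
                   "steroids", "monosaccharide", "glycopeptide", "arene",
                   "quaternary amine", "keto steroids"),
    polymer = c("polyethylene", "polystyrene", "polypropylene",
                "polyethylene glycol"),
    biopolymer_block = c("insulin", "hemoglobin", "albumin", "myoglobin",
                         "keratin")
  )
}

semi_substituents <- function() {
  c("methyl", "ethyl", "propyl", "butyl", "pentyl", "hexyl", "phenyl",
    "chloro", "bromo", "fluoro", "iodo", "nitro", "amino", "hydroxy")
}

semi_parents <- function() {
  c("benzene", "phenol", "aniline", "naphthalene", "furan", alkane_terms())
}

#' Built-in demonstrative resource set
#'
#' The shipped toy configuration: CID, CAS-number, registry-number,
#' sum-formula and alkane grammars; a two-level (layered) semi-systematic
#' grammar (substituents + parent); drug, element, allotrope, alloy,
#' common-abbreviation, generic chemical class and polymer lexicons seeded
#' from small example term sets; a blocking lexicon of biopolymer names;
#' and the default word lists and abbreviation equivalence map.
#'
#' Spelling correction is enabled (parameterized errors only, by default)
#' on the chemical-name-like resources: drug lexicon, alkanes, and the
#' semi-systematic grammar.
#'
#' @param correction Default [correction_config()] attached to the
#'   correction-enabled resources.
#' @return A [resource_set()].
#' @export
builtin_resources <- function(correction = correction_config()) {
  gs <- builtin_grammar_sources()
  autos <- lapply(gs, function(src) compile_grammar(parse_grammar(src)))
  ts <- builtin_term_sets()

  semi_master <- parse_grammar("name : substituent substituent* parent",
                               lexicons = c("substituent", "parent"))
  semi <- compile_layered(semi_master, list(
    substituent = compile_terms(semi_substituents()),
    parent = compile_terms(semi_parents())
  ))
  # flattened machine over the same language, for spelling correction
  semi_flat <- compile_grammar(semi_master,
                               lexicons = list(substituent = semi_substituents(),
                                               parent = semi_parents()))

  resource_set(
    resource("cid", autos$cid, entity_class = "identifier"),
    resource("cas", autos$cas, entity_class = "identifier"),
    resource("registry", autos$registry, entity_class = "identifier"),
    resource("sum_formula", autos$sum_formula, entity_class = "formula",
             digit_filter = 3L),
    resource("alkane", autos$alkane, entity_class = "chemical",
             correction = correction),
    resource("semi_systematic", semi, entity_class = "chemical",
             correction = correction, correction_object = semi_flat),
    resource("drug", build_lexicon(ts$drug, "drug"),
             entity_class = "chemical", correction = correction),
    resource("element", build_lexicon(ts$element, "element"),
             entity_class = "element"),
    resource("allotrope", build_lexicon(ts$allotrope, "allotrope"),
             entity_class = "chemical"),
    resource("alloy", build_lexicon(ts$alloy, "alloy"),
             entity_class = "chemical"),
    resource("chem_abbrev",
             build_lexicon(ts$chem_abbrev, "chem_abbrev",
                           case_policy = "sensitive"),
             entity_class = "chemical"),
    resource("chem_class",
             build_lexicon(ts$chem_class, "chem_class"),
             entity_class = "chemical_class", specific = FALSE),
    resource("polymer", build_lexicon(ts$polymer, "polymer"),
             entity_class = "polymer"),
    resource("biopolymer_block",
             build_lexicon(ts$biopolymer_block, "biopolymer_block",
                           token_boundary = TRUE),
             role = "blocking", entity_class = "blocked")
  )
}

#' Synthetic corpus settings
#'
#' The generator emulates short title/abstract documents: lower-case
#' filler prose drawn from the English word list with chemical mentions
#' injected at a controlled density, optionally perturbed by single typos
#' and/or given parenthetical abbreviation definitions in the six
#' supported surface patterns.
#'
#' @param seed Integer seed; corpora are byte-identical given the same
#'   spec.
#' @param n_docs Number of documents.
#' @param entity_density Expected entities per 100 tokens.
#' @param typo_rate Proportion of (eligible) injected entities perturbed
#'   by one random character edit.
#' @param abbrev_rate Proportion of eligible lexicon entities given a
#'   parenthetical abbreviation definition.
#' @param pattern_mix Weights over the 6 abbreviation surface patterns.
#' @param title_tokens,abstract_tokens Approximate token counts.
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_docs = 10L, entity_density = 12,
                         typo_rate = 0, abbrev_rate = 0.1,
                         pattern_mix = rep(1, 6), title_tokens = 6L,
                         abstract_tokens = 45L) {
  stopifnot(n_docs >= 1, entity_density >= 0, typo_rate >= 0, typo_rate <= 1,
            abbrev_rate >= 0, abbrev_rate <= 1, length(pattern_mix) == 6,
            all(pattern_mix >= 0), sum(pattern_mix) > 0)
  structure(
    list(seed = as.integer(seed), n_docs = as.integer(n_docs),
         entity_density = entity_density, typo_rate = typo_rate,
         abbrev_rate = abbrev_rate, pattern_mix = pattern_mix,
         title_tokens = as.integer(title_tokens),
         abstract_tokens = as.integer(abstract_tokens)),
    class = "fixture_spec"
  )
}

# sample one string from a resource's language
sample_language <- function(obj) {
  if (inherits(obj, "chem_lexicon")) {
    sample(obj$terms, 1L)
  } else if (inherits(obj, "char_automaton")) {
    sample_automaton(obj)
  } else if (inherits(obj, "layered_automaton")) {
    # random walk over the master, sampling each sub-machine
    m <- obj$master
    st <- 1L
    out <- character(0)
    for (guard in 1:20) {
      if (m$accept[st] && stats::runif(1) < 0.6) break
      syms <- which(m$trans[st, ] != 0L)
      if (!length(syms)) break
      sy <- if (length(syms) == 1L) syms else sample(syms, 1L)
      out <- c(out, sample_language(obj$subs[[m$alphabet[sy]]]))
      st <- m$trans[st, sy]
    }
    paste(out, collapse = "")
  } else {
    stop("cannot sample from object of class ", class(obj)[1])
  }
}

.fixture_cache <- new.env(parent = emptyenv())

# filler words safe w.r.t. the resource set: no resource matches anywhere
# inside them, they are not words of any multi-word term, and (when
# `edit_vet` is on) no correction-enabled resource can reach them within a
# one-generic-edit budget
safe_fillers <- function(resources, edit_vet = FALSE,
                         model = edit_cost_model()) {
  key <- paste(c(names(resources$resources), edit_vet), collapse = "|")
  got <- .fixture_cache[[key]]
  if (!is.null(got)) return(got)
  pool <- default_english_words()
  pool <- pool[nchar(pool) >= 2]
  multi_words <- unlist(lapply(resources$resources, function(r) {
    if (inherits(r$object, "chem_lexicon")) {
      unlist(strsplit(r$object$terms[grepl(" ", r$object$terms)], " "))
    } else character(0)
  }))
  pool <- setdiff(pool, tolower(multi_words))
  ok <- vapply(pool, function(w) {
    for (r in resources$resources) {
      if (nrow(resource_candidates(r, w))) return(FALSE)
    }
    TRUE
  }, logical(1))
  pool <- pool[ok]
  if (edit_vet) {
    vet_cfg <- correction_config(TRUE, max_unparameterized_edits = 1L,
                                 min_entity_length = 6L)
    ok <- vapply(pool, function(w) {
      if (nchar(w) < vet_cfg$min_entity_length) return(TRUE)
      for (r in resources$resources) {
        if (is.null(r$correction)) next
        res <- correct_against(r$correction_object %||% r$object, w, model,
                               vet_cfg)
        if (!is.null(res) && !is_correction_skipped(res)) return(FALSE)
      }
      TRUE
    }, logical(1))
    pool <- pool[ok]
  }
  assign(key, pool, envir = .fixture_cache)
  pool
}

# one random character edit on a lower-case token
random_typo <- function(word) {
  chars <- strsplit(word, "")[[1]]
  n <- length(chars)
  op <- sample(c("sub", "del", "ins", "transpose"), 1L)
  letters_pool <- letters
  if (op == "sub") {
    i <- sample(n, 1L)
    repl <- sample(setdiff(letters_pool, chars[i]), 1L)
    chars[i] <- repl
  } else if (op == "del") {
    chars <- chars[-sample(n, 1L)]
  } else if (op == "ins") {
    i <- sample(n + 1L, 1L)
    chars <- append(chars, sample(letters_pool, 1L), after = i - 1L)
  } else {
    if (n < 2) return(word)
    i <- sample(n - 1L, 1L)
    if (chars[i] == chars[i + 1L]) return(word)
    tmp <- chars[i]
    chars[i] <- chars[i + 1L]
    chars[i + 1L] <- tmp
  }
  paste(chars, collapse = "")
}

# is `tok` free of any resource match (so it cannot produce an entity)?
# Applies the same per-resource candidate filters as the annotator (digit
# requirement, token boundaries), since matches those filters drop can
# never become entities.
token_unmatched <- function(tok, resources) {
  for (r in resources$resources) {
    if (nrow(resource_candidates(r, tok))) return(FALSE)
  }
  TRUE
}

#' Generate a synthetic annotated corpus
#'
#' Documents are assembled from a vetted filler-word pool with injected
#' entities drawn from the resources' languages (lexicon terms sampled
#' directly, grammar entities by random automaton walks; sum formulae are
#' resampled until they carry more than two digits so the digit filter
#' never removes a gold mention). Gold spans are recorded at injection
#' time. Per `spec`, a proportion of entities is perturbed by one random
#' character edit (recorded in the audit trail, and vetted so that a
#' one-edit correction budget recovers exactly the original surface), and
#' a proportion receives a parenthetical abbreviation definition in one of
#' the six supported patterns, with one further standalone instance of the
#' short form injected later in the document.
#'
#' @param spec A [fixture_spec()].
#' @param resources A [resource_set()]; defaults to [builtin_resources()].
#' @return List with `docs` (list of [source_document()]), `gold` (data
#'   frame: doc_id, section, start, end, text, class), and `audit` (data
#'   frame of typo and abbreviation injections).
#' @export
generate_corpus <- function(spec = fixture_spec(),
                            resources = builtin_resources()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  fillers <- safe_fillers(resources, edit_vet = spec$typo_rate > 0)
  if (length(fillers) < 50)
    stop("filler pool too small after vetting against the resource set")

  matching <- Filter(function(r) r$role == "matching", resources$resources)
  stop_terms <- resources$word_lists$stop_terms
  samp_cfg <- correction_config(TRUE, max_unparameterized_edits = 1L,
                                min_entity_length = 5L)
  model <- edit_cost_model()

  sample_entity <- function() {
    for (guard in 1:100) {
      r <- matching[[sample(length(matching), 1L)]]
      tm <- sample_language(r$object)
      if (r$entity_class == "formula") {
        tries <- 0L
        while (sum(strsplit(tm, "")[[1]] %in% as.character(0:9)) <= 2L &&
               tries < 50L) {
          tm <- sample_language(r$object)
          tries <- tries + 1L
        }
        if (sum(strsplit(tm, "")[[1]] %in% as.character(0:9)) <= 2L) next
      }
      if (tolower(tm) %in% stop_terms) next
      if (!nzchar(tm) || nchar(tm) > 30) next
      return(list(resource = r, term = tm))
    }
    stop("could not sample an injectable entity")
  }

  gold <- list()
  audit <- list()
  docs <- vector("list", spec$n_docs)
  p_entity <- spec$entity_density / 100

  for (d in seq_len(spec$n_docs)) {
    doc_id <- sprintf("SYN%04d", d)
    used_sf <- character(0)

    build_section <- function(label, n_tokens, allow_abbrev) {
      txt <- ""
      pending_sf <- list()
      cursor <- function() nchar(txt)
      append_txt <- function(s) txt <<- paste0(txt, s)
      add_gold <- function(start, piece, class) {
        gold[[length(gold) + 1L]] <<- data.frame(
          doc_id = doc_id, section = label, start = start,
          end = start + nchar(piece), text = piece, class = class,
          stringsAsFactors = FALSE
        )
      }
      tokens_done <- 0L
      since_sentence <- 0L
      prev_entity <- FALSE # adjacent entities would be merged downstream
      while (tokens_done < n_tokens) {
        if (nzchar(txt)) append_txt(" ")
        emit_pending <- !prev_entity && length(pending_sf) > 0 &&
          stats::runif(1) < 0.4
        if (emit_pending) {
          sf <- pending_sf[[1]]
          pending_sf <- pending_sf[-1]
          add_gold(cursor(), sf$sf, sf$class)
          append_txt(sf$sf)
          prev_entity <- TRUE
        } else if (!prev_entity && stats::runif(1) < p_entity) {
          ent <- sample_entity()
          tm <- ent$term
          cls <- ent$resource$entity_class
          sf <- toupper(gsub("[^A-Za-z]", "", substr(tm, 1, 6)))
          sf <- substr(sf, 1, 3)
          can_abbrev <- allow_abbrev &&
            inherits(ent$resource$object, "chem_lexicon") &&
            stats::runif(1) < spec$abbrev_rate &&
            nchar(sf) == 3 && is_valid_short_form(sf) &&
            !(sf %in% used_sf) && token_unmatched(sf, resources) &&
            short_matches_long(sf, tm, resources$equivalence)
          if (can_abbrev) {
            used_sf <<- c(used_sf, sf)
            patt <- sample(6L, 1L, prob = spec$pattern_mix)
            filler <- sample(fillers, 1L)
            if (patt == 1L) { # LF (SF)
              add_gold(cursor(), tm, cls)
              append_txt(paste0(tm, " ("))
              add_gold(cursor(), sf, cls)
              append_txt(paste0(sf, ")"))
            } else if (patt == 2L) { # SF (LF)
              add_gold(cursor(), sf, cls)
              append_txt(paste0(sf, " ("))
              add_gold(cursor(), tm, cls)
              append_txt(paste0(tm, ")"))
            } else if (patt == 3L) { # LF (SF;
              add_gold(cursor(), tm, cls)
              append_txt(paste0(tm, " ("))
              add_gold(cursor(), sf, cls)
              append_txt(paste0(sf, "; ", filler, ")"))
            } else if (patt == 4L) { # LF (SF,
              add_gold(cursor(), tm, cls)
              append_txt(paste0(tm, " ("))
              add_gold(cursor(), sf, cls)
              append_txt(paste0(sf, ", ", filler, ")"))
            } else if (patt == 5L) { # (LF, SF)
              append_txt("(")
              add_gold(cursor(), tm, cls)
              append_txt(paste0(tm, ", "))
              add_gold(cursor(), sf, cls)
              append_txt(paste0(sf, ")"))
            } else { # SF = LF
              add_gold(cursor(), sf, cls)
              append_txt(paste0(sf, " = "))
              add_gold(cursor(), tm, cls)
              append_txt(tm)
            }
            pending_sf[[length(pending_sf) + 1L]] <-
              list(sf = sf, class = cls)
            audit[[length(audit) + 1L]] <<- data.frame(
              doc_id = doc_id, section = label, kind = "abbrev",
              original = tm, surface = sf, pattern = patt,
              stringsAsFactors = FALSE
            )
          } else {
            surface <- tm
            do_typo <- spec$typo_rate > 0 &&
              stats::runif(1) < spec$typo_rate &&
              !grepl(" ", tm) && nchar(tm) >= 7 &&
              grepl("^[a-z]+$", tm) &&
              inherits(ent$resource$object, "chem_lexicon") &&
              !is.null(ent$resource$correction)
            if (do_typo) {
              ok <- FALSE
              for (try in 1:20) {
                cand <- random_typo(tm)
                if (cand == tm) next
                if (!token_unmatched(cand, resources)) next
                # a one-edit budget must recover exactly the original
                best <- NULL
                for (r2 in matching) {
                  if (is.null(r2$correction)) next
                  cr <- correct_against(r2$correction_object %||% r2$object,
                                        cand, model, samp_cfg)
                  if (is.null(cr) || is_correction_skipped(cr)) next
                  if (is.null(best) || cr$cost < best$cost) best <- cr
                }
                if (!is.null(best) && best$corrected == tm) {
                  surface <- cand
                  ok <- TRUE
                  break
                }
              }
              if (ok) {
                audit[[length(audit) + 1L]] <<- data.frame(
                  doc_id = doc_id, section = label, kind = "typo",
                  original = tm, surface = surface, pattern = NA_integer_,
                  stringsAsFactors = FALSE
                )
              }
            }
            add_gold(cursor(), surface, cls)
            append_txt(surface)
          }
          prev_entity <- TRUE
        } else {
          append_txt(sample(fillers, 1L))
          prev_entity <- FALSE
        }
        tokens_done <- tokens_done + 1L
        since_sentence <- since_sentence + 1L
        if (label == "A" && since_sentence >= 12L &&
            tokens_done < n_tokens) {
          append_txt(".")
          since_sentence <- 0L
          prev_entity <- FALSE
        }
      }
      # flush pending short-form instances (filler-separated)
      for (sf in pending_sf) {
        append_txt(paste0(" ", sample(fillers, 1L), " "))
        add_gold(cursor(), sf$sf, sf$class)
        append_txt(sf$sf)
      }
      if (label == "A") append_txt(".")
      txt
    }

    title <- build_section("T", spec$title_tokens, allow_abbrev = FALSE)
    abstract <- build_section("A", spec$abstract_tokens, allow_abbrev = TRUE)
    docs[[d]] <- source_document(doc_id, title = title, abstract = abstract)
  }

  gold_df <- if (length(gold)) do.call(rbind, gold) else
    data.frame(doc_id = character(0), section = character(0),
               start = integer(0), end = integer(0), text = character(0),
               class = character(0), stringsAsFactors = FALSE)
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(doc_id = character(0), section = character(0),
               kind = character(0), original = character(0),
               surface = character(0), pattern = integer(0),
               stringsAsFactors = FALSE)
  list(docs = docs, gold = gold_df, audit = audit_df)
}

#' Write corpus, gold and resource files to a directory
#'
#' Writes `docs.tsv` (doc_id, title, abstract), `gold.tsv` (gold dialect),
#' the built-in grammar and lexicon files, word lists, and a resource
#' manifest, producing a self-contained annotation setup.
#'
#' @param corpus Result of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  docs <- corpus$docs
  tab <- data.frame(
    doc_id = vapply(docs, `[[`, character(1), "doc_id"),
    title = vapply(docs, function(d) {
      t <- d$sections$text[d$sections$label == "T"]
      if (length(t)) t else ""
    }, character(1)),
    abstract = vapply(docs, function(d) {
      t <- d$sections$text[d$sections$label == "A"]
      if (length(t)) t else ""
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, file.path(dir, "docs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_gold(corpus$gold, file.path(dir, "gold.tsv"))
  write_builtin_resource_files(dir)
  invisible(dir)
}

#' Read a docs.tsv corpus file
#'
#' @param path TSV with columns doc_id, title, abstract.
#' @param is_xml Whether section texts carry markup.
#' @return List of [source_document()].
#' @export
read_corpus <- function(path, is_xml = FALSE) {
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = c(doc_id = "character"))
  lapply(seq_len(nrow(tab)), function(i) {
    source_document(tab$doc_id[i], title = tab$title[i],
                    abstract = tab$abstract[i], is_xml = is_xml)
  })
}
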