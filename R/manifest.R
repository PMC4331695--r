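# Declarative resource manifest (YAML): resource name, kind, file(s),
# class, role, priority, case policy, boundary/specific flags and
# correction settings, plus word lists, include/stop lists and the
# abbreviation equivalence map. Paths are resolved relative to the
# manifest's directory.

manifest_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("chemner_config_error",
                                             "error")))
}

correction_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  if (isFALSE(x)) return(NULL)
  if (isTRUE(x)) return(correction_config())
  correction_config(
    enabled = !isFALSE(x$enabled),
    max_unparameterized_edits = x$max_unparameterized_edits %||% 0L,
    min_entity_length = x$min_entity_length %||% 6L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a resource set from a manifest file
#'
#' The manifest is a YAML document with a `resources` list; each entry
#' has `name`, `kind` (`grammar`, `lexicon`, or `layered`), `file` (or
#' `master`/`subs` for layered resources), and optional `class`, `role`,
#' `case_policy`/`case_sensitive`, `token_boundary`, `specific`, and
#' `correction` settings. Optional top-level entries: `include_list`,
#' `stop_list` (lexicon files), `word_lists` (files for
#' `english`, `noise`, `trim`, `stop`, `instance_of`), and `equivalence`.
#'
#' @param path Manifest path.
#' @return A [resource_set()].
#' @export
load_resource_set <- function(path) {
  if (!file.exists(path)) manifest_error("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(f) if (file.exists(f)) f else file.path(base, f)
  if (is.null(man$resources) || !length(man$resources))
    manifest_error("manifest has no resources: ", path)

  build_one <- function(entry, idx) {
    for (field in c("name", "kind")) {
      if (is.null(entry[[field]]))
        manifest_error("resource #", idx, " is missing '", field, "'")
    }
    kind <- entry$kind
    corr <- correction_from_list(entry$correction)
    if (kind == "lexicon") {
      lex <- read_lexicon(
        rel(entry$file), name = entry$name,
        entity_class = entry$class %||% "chemical",
        case_policy = entry$case_policy %||% "first-insensitive",
        role = entry$role %||% "matching",
        token_boundary = isTRUE(entry$token_boundary),
        specific = entry$specific %||% TRUE,
        correction = corr
      )
      resource(entry$name, lex, entity_class = lex$entity_class,
               role = lex$role, token_boundary = lex$token_boundary,
               specific = lex$specific, correction = corr)
    } else if (kind == "grammar") {
      g <- read_grammar(rel(entry$file), root = entry$root,
                        case_sensitive = !isFALSE(entry$case_sensitive))
      resource(entry$name, compile_grammar(g),
               entity_class = entry$class %||% "chemical",
               role = entry$role %||% "matching",
               token_boundary = isTRUE(entry$token_boundary),
               specific = entry$specific %||% TRUE, correction = corr,
               digit_filter = entry$digit_filter %||% 0L)
    } else if (kind == "layered") {
      sub_terms <- lapply(entry$subs, function(f) {
        readLines(rel(f), encoding = "UTF-8", warn = FALSE)
      })
      subs <- lapply(sub_terms, compile_terms)
      g <- read_grammar(rel(entry$master), lexicons = names(subs))
      # correction runs against a flattened machine of the same language
      flat <- if (!is.null(corr)) compile_grammar(g, lexicons = sub_terms)
      resource(entry$name, compile_layered(g, subs),
               entity_class = entry$class %||% "chemical",
               role = entry$role %||% "matching",
               token_boundary = isTRUE(entry$token_boundary),
               specific = entry$specific %||% TRUE, correction = corr,
               correction_object = flat)
    } else {
      manifest_error("resource '", entry$name, "': unknown kind '", kind,
                     "'")
    }
  }

  res <- lapply(seq_along(man$resources),
                function(i) build_one(man$resources[[i]], i))

  include_list <- NULL
  if (!is.null(man$include_list)) {
    include_list <- read_lexicon(rel(man$include_list),
                                 name = "include_list",
                                 entity_class = "chemical")
  }
  stop_list <- NULL
  if (!is.null(man$stop_list)) {
    stop_list <- read_lexicon(rel(man$stop_list), name = "stop_list")
  }

  wl_files <- man$word_lists
  read_words <- function(f) {
    x <- readLines(rel(f), encoding = "UTF-8", warn = FALSE)
    x[nzchar(x) & !startsWith(x, "#")]
  }
  wl <- word_lists(
    english_words = if (!is.null(wl_files$english))
      read_words(wl_files$english) else default_english_words(),
    noise_words = if (!is.null(wl_files$noise))
      read_words(wl_files$noise) else default_noise_words(),
    trim_terms = if (!is.null(wl_files$trim))
      read_words(wl_files$trim) else default_trim_terms(),
    stop_terms = if (!is.null(wl_files$stop))
      read_words(wl_files$stop) else default_stop_terms(),
    instance_of = if (!is.null(wl_files$instance_of))
      read_pair_tsv(rel(wl_files$instance_of), c("specific", "class"))
    else default_instance_of()
  )
  eq <- if (!is.null(man$equivalence)) {
    read_pair_tsv(rel(man$equivalence), c("long", "short"))
  } else {
    default_equivalence_map()
  }

  resource_set(res, include_list = include_list, stop_list = stop_list,
               word_lists = wl, equivalence = eq)
}

#' Write the built-in resources as files plus a manifest
#'
#' Materializes the built-in grammars, lexicons, word lists, instance-of
#' table and equivalence map as plain-text files under `dir`, with a
#' `manifest.yaml` tying them together, so the files can be inspected,
#' edited and reloaded with [load_resource_set()].
#'
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_builtin_resource_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- builtin_grammar_sources()
  for (nm in names(gs)) {
    writeLines(gs[[nm]], file.path(dir, paste0(nm, ".grammar")))
  }
  ts <- builtin_term_sets()
  for (nm in names(ts)) {
    writeLines(enc2utf8(ts[[nm]]), file.path(dir, paste0(nm, ".txt")),
               useBytes = TRUE)
  }
  writeLines("name : substituent substituent* parent",
             file.path(dir, "semi_master.grammar"))
  writeLines(semi_substituents(), file.path(dir, "substituent.txt"))
  writeLines(semi_parents(), file.path(dir, "parent.txt"))
  writeLines(default_english_words(), file.path(dir, "english_words.txt"))
  writeLines(default_noise_words(), file.path(dir, "noise_words.txt"))
  writeLines(default_trim_terms(), file.path(dir, "trim_terms.txt"))
  writeLines(default_stop_terms(), file.path(dir, "stop_terms.txt"))
  io <- default_instance_of()
  writeLines(paste(io$specific, io$class, sep = "\t"),
             file.path(dir, "instance_of.tsv"))
  eq <- default_equivalence_map()
  writeLines(paste(eq$long, eq$short, sep = "\t"),
             file.path(dir, "equivalence.tsv"))

  grammar_entry <- function(name, class) {
    list(name = name, kind = "grammar", file = paste0(name, ".grammar"),
         class = class)
  }
  lex_entry <- function(name, class, ...) {
    c(list(name = name, kind = "lexicon", file = paste0(name, ".txt"),
           class = class), list(...))
  }
  corr <- list(enabled = TRUE, max_unparameterized_edits = 0L,
               min_entity_length = 6L)
  man <- list(
    resources = list(
      grammar_entry("cid", "identifier"),
      grammar_entry("cas", "identifier"),
      grammar_entry("registry", "identifier"),
      c(grammar_entry("sum_formula", "formula"),
        list(digit_filter = 3L)),
      c(grammar_entry("alkane", "chemical"), list(correction = corr)),
      list(name = "semi_systematic", kind = "layered",
           master = "semi_master.grammar",
           subs = list(substituent = "substituent.txt",
                       parent = "parent.txt"),
           class = "chemical", correction = corr),
      lex_entry("drug", "chemical", correction = corr),
      lex_entry("element", "element"),
      lex_entry("allotrope", "chemical"),
      lex_entry("alloy", "chemical"),
      lex_entry("chem_abbrev", "chemical", case_policy = "sensitive"),
      lex_entry("chem_class", "chemical_class", specific = FALSE),
      lex_entry("polymer", "polymer"),
      lex_entry("biopolymer_block", "blocked", role = "blocking",
                token_boundary = TRUE)
    ),
    word_lists = list(english = "english_words.txt",
                      noise = "noise_words.txt", trim = "trim_terms.txt",
                      stop = "stop_terms.txt",
                      instance_of = "instance_of.tsv"),
    equivalence = "equivalence.tsv"
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}
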