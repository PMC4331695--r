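# Word lists consulted by curation, entity post-processing, and
# abbreviation detection. All lists are plain text / two-column TSV so a
# real resource export (e.g. an ontology dump) could be dropped in.

.wordlist_cache <- new.env(parent = emptyenv())

#' Default non-chemical English word list
#'
#' A small documented list of common English words shipped with the
#' package (`inst/extdata/english_words.txt`). It is deliberately minimal:
#' a production deployment would substitute a full word list via
#' [word_lists()].
#'
#' @return Character vector of lower-case words.
#' @export
default_english_words <- function() {
  got <- .wordlist_cache$english
  if (is.null(got)) {
    path <- system.file("extdata", "english_words.txt", package = "chemner")
    if (!nzchar(path)) path <- "inst/extdata/english_words.txt"
    got <- readLines(path, encoding = "UTF-8", warn = FALSE)
    got <- got[!startsWith(got, "#")]
    got <- got[nzchar(got)]
    assign("english", got, envir = .wordlist_cache)
  }
  got
}

#' Default noise words
#'
#' Short connective words that terminate entity extension inside
#' hyphenated constructs (so "leucine-to-proline" splits into two
#' entities rather than one).
#'
#' @return Character vector.
#' @export
default_noise_words <- function() {
  c("to", "of", "and", "or", "in", "on", "by", "for", "with", "from",
    "via", "vs", "versus", "per", "non", "like", "based", "related",
    "induced", "dependent", "mediated", "free", "rich", "type")
}

#' Default trim terms
#'
#' Non-essential modifiers trimmed from entity starts/ends ("group",
#' "colloidal", "dye", ...).
#'
#' @return Character vector.
#' @export
default_trim_terms <- function() {
  c("group", "groups", "colloidal", "dye", "dyes", "nanoparticle",
    "nanoparticles", "particles", "particle", "powder", "solution",
    "solutions", "anhydrous", "aqueous", "moiety", "moieties", "residue",
    "residues", "crystalline", "substituted", "derived")
}

#' Default stop terms
#'
#' Terms that, when an entity reduces to them after trimming, cause the
#' entity to be excluded entirely (annotation-guideline exclusions such as
#' "gold").
#'
#' @return Character vector.
#' @export
default_stop_terms <- function() {
  c("gold", "salt", "salts")
}

#' Default instance-of table
#'
#' A small fixture of (specific term, class term) pairs in the spirit of an
#' ontology's "is a" relations: "genistein IS an isoflavonoid", so the two
#' adjacent entities are not merged. A real ontology export in the same
#' two-column TSV format can be substituted.
#'
#' @return Data frame with columns `specific`, `class`.
#' @export
default_instance_of <- function() {
  data.frame(
    specific = c("genistein", "quercetin", "morphine", "caffeine",
                 "nicotine", "limonene", "cholesterol", "glucose",
                 "ethanol", "benzene", "vancomycin", "pinene",
                 "daidzein", "codeine", "menthol", "estradiol",
                 "fructose", "testosterone"),
    class = c("isoflavonoid", "flavonoid", "alkaloid", "alkaloid",
              "alkaloid", "monoterpene", "sterol", "monosaccharide",
              "alcohol", "arene", "glycopeptide", "monoterpene",
              "isoflavonoid", "alkaloid", "monoterpene", "steroid",
              "monosaccharide", "steroid"),
    stringsAsFactors = FALSE
  )
}

#' Default abbreviation equivalence map
#'
#' Long token to short token pairs consulted by the abbreviation
#' character-correspondence test, so that e.g. "methylmercury" can be
#' abbreviated "MeHg".
#'
#' @return Data frame with columns `long`, `short`.
#' @export
default_equivalence_map <- function() {
  data.frame(
    long = c("mercury", "methyl", "ethyl", "propyl", "butyl", "phenyl",
             "benzyl", "acetyl", "glutathione"),
    short = c("Hg", "Me", "Et", "Pr", "Bu", "Ph", "Bn", "Ac", "GSH"),
    stringsAsFactors = FALSE
  )
}

#' Greek letter spelling table
#'
#' Latin spellings of Greek letters and the corresponding Greek
#' characters, used by the curation variant expansion (`"alpha-"` gives a
#' variant using `"α-"`).
#'
#' @return Data frame with columns `latin`, `greek`.
#' @export
greek_letter_table <- function() {
  data.frame(
    latin = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
              "theta", "iota", "kappa", "lambda", "mu", "nu", "xi",
              "omicron", "pi", "rho", "sigma", "tau", "upsilon", "phi",
              "chi", "psi", "omega"),
    greek = c("α", "β", "γ", "δ", "ε", "ζ",
              "η", "θ", "ι", "κ", "λ", "μ",
              "ν", "ξ", "ο", "π", "ρ", "σ",
              "τ", "υ", "φ", "χ", "ψ", "ω"),
    stringsAsFactors = FALSE
  )
}

#' Bundle of word lists used by entity post-processing
#'
#' @param english_words,noise_words,trim_terms,stop_terms Character
#'   vectors (lower-cased internally).
#' @param instance_of Data frame with columns `specific`, `class`.
#' @return A `word_lists` object.
#' @export
word_lists <- function(english_words = default_english_words(),
                       noise_words = default_noise_words(),
                       trim_terms = default_trim_terms(),
                       stop_terms = default_stop_terms(),
                       instance_of = default_instance_of()) {
  stopifnot(is.data.frame(instance_of),
            all(c("specific", "class") %in% names(instance_of)))
  structure(
    list(english_words = tolower(english_words),
         noise_words = tolower(noise_words),
         trim_terms = tolower(trim_terms),
         stop_terms = tolower(stop_terms),
         instance_of = instance_of),
    class = "word_lists"
  )
}

#' Read a two-column TSV into a data frame
#'
#' Helper for the instance-of table and equivalence map formats (`#`
#' comments allowed).
#'
#' @param path File path.
#' @param col_names Names for the two columns.
#' @return Data frame.
#' @export
read_pair_tsv <- function(path, col_names = c("from", "to")) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    a = vapply(parts, `[[`, character(1), 1L),
    b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  names(out) <- col_names
  out
}
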