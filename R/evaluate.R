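# Mention-level evaluation: exact-span matching pooled over all documents
# (micro-averaging), CHEMDNER-dialect TSV readers/writers, and the
# corpus-driven include-list derivation.

#' Micro-averaged mention-level evaluation
#'
#' A prediction is a true positive iff some gold annotation has the
#' identical (doc_id, section, start, end); class labels are ignored for
#' matching (mention-level task) and each gold annotation can be matched
#' at most once. Counts are pooled over all documents before computing
#' precision, recall and F1 (micro-averaging). Duplicate identical
#' predictions are counted once, with a warning.
#'
#' @param pred Entity data frame (or anything with `doc_id`, `section`,
#'   `start`, `end`).
#' @param gold Gold annotation data frame with the same columns.
#' @return An `eval_result` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`. Precision/recall are 1 when their denominator is 0; F1 is 0
#'   when P + R = 0.
#' @export
evaluate <- function(pred, gold) {
  key <- function(d) {
    if (!nrow(d)) return(character(0))
    paste(d$doc_id, d$section, d$start, d$end, sep = "\r")
  }
  pk <- key(pred)
  if (anyDuplicated(pk)) {
    warning("duplicate identical predictions counted once")
    pk <- unique(pk)
  }
  gk <- unique(key(gold))
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d fn=%d  P=%.4f R=%.4f F1=%.4f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Read/write gold annotations
#'
#' Gold TSV dialect: columns `doc_id`, `section` (T|A|P), `start`, `end`
#' (0-based half-open), `text`, `class`, with a header line.
#'
#' @param path File path.
#' @return Data frame of gold annotations.
#' @export
read_gold <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                    colClasses = c(doc_id = "character"))
}

#' @rdname read_gold
#' @param gold Gold data frame.
#' @export
write_gold <- function(gold, path) {
  utils::write.table(gold, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read/write predictions in the CHEMDNER-style dialect
#'
#' Prediction TSV dialect (no header): `doc_id`, `SECTION:start:end`,
#' `rank`, `confidence`. Rank is sequential per document; the engine does
#' not score entities, so confidence is a constant 1.
#'
#' @param path File path.
#' @return Data frame with `doc_id`, `section`, `start`, `end`, `rank`,
#'   `confidence`.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c(V1 = "character"))
  names(tab) <- c("doc_id", "span", "rank", "confidence")[seq_len(ncol(tab))]
  parts <- strsplit(tab$span, ":", fixed = TRUE)
  data.frame(
    doc_id = tab$doc_id,
    section = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[[`, character(1), 3L)),
    rank = tab$rank,
    confidence = tab$confidence,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_predictions
#' @param entities Entity data frame.
#' @export
write_predictions <- function(entities, path) {
  if (!nrow(entities)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ord <- order(entities$doc_id, entities$section, entities$start)
  e <- entities[ord, , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(e)), e$doc_id, FUN = seq_along)
  lines <- paste(e$doc_id, paste(e$section, e$start, e$end, sep = ":"),
                 rank, 1, sep = "\t")
  writeLines(enc2utf8(lines), path, useBytes = TRUE)
  invisible(path)
}

#' Entities as gold-format annotations
#'
#' @param entities Entity data frame.
#' @return Data frame in the gold dialect columns.
#' @export
entities_as_gold <- function(entities) {
  entities[, c("doc_id", "section", "start", "end", "text", "class"),
           drop = FALSE]
}

#' Derive an include list from system false negatives
#'
#' Greedy pass over candidate terms ordered by descending false-negative
#' frequency (ties broken lexicographically): a candidate is retained iff
#' adding it to the include-list lexicon and re-evaluating the pipeline
#' strictly increases micro-averaged F1 on the corpus. Highly ambiguous
#' terms — strings that also occur in many non-entity contexts — fail the
#' test because the precision they cost exceeds the recall they add.
#'
#' @param candidates Character vector of candidate terms, or a data frame
#'   with columns `term` and `count` (FN frequency).
#' @param eval_fn Function taking a character vector of include terms and
#'   returning an [evaluate()] result for the full pipeline run with that
#'   include list.
#' @return Character vector of accepted include terms.
#' @export
derive_include_list <- function(candidates, eval_fn) {
  if (is.data.frame(candidates)) {
    ord <- order(-candidates$count, candidates$term)
    cand <- candidates$term[ord]
  } else if (!length(candidates)) {
    cand <- character(0)
  } else {
    tab <- table(candidates)
    cand <- names(tab)[order(-as.integer(tab), names(tab))]
  }
  cand <- unique(cand)
  accepted <- character(0)
  base <- eval_fn(accepted)$f1
  for (tm in cand) {
    f1 <- eval_fn(c(accepted, tm))$f1
    if (f1 > base + 1e-12) {
      accepted <- c(accepted, tm)
      base <- f1
    }
  }
  accepted
}
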