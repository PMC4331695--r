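# Full annotation workflow: normalization -> annotation (grammars +
# lexicons + spelling correction) -> five-step entity modification ->
# abbreviation detection -> non-entity abbreviation removal ->
# include/stop lists -> sum-formula digit filter. Every step after
# annotation is post-processing and can be toggled off independently.

#' Pipeline configuration
#'
#' @param correction Attempt spelling correction of uncovered tokens
#'   (per-resource correction settings apply).
#' @param correction_override Optional [correction_config()] overriding
#'   every correction-enabled resource's settings (e.g. to grant a
#'   generic-edit budget).
#' @param entity_modification Run the five-step boundary refinement.
#' @param abbreviation_detection Detect and propagate abbreviations of
#'   found entities.
#' @param nonentity_removal Remove entities that are abbreviations of
#'   non-entities.
#' @param include_list Apply the resource set's include list (if any).
#' @param stop_list Apply the resource set's stop list. Off by default:
#'   corpus-derived stop lists cost more recall than they buy precision.
#' @param formula_filter Apply the sum-formula digit filter.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(correction = TRUE, correction_override = NULL,
                            entity_modification = TRUE,
                            abbreviation_detection = TRUE,
                            nonentity_removal = TRUE,
                            include_list = TRUE, stop_list = FALSE,
                            formula_filter = TRUE) {
  structure(
    list(correction = correction, correction_override = correction_override,
         entity_modification = entity_modification,
         abbreviation_detection = abbreviation_detection,
         nonentity_removal = nonentity_removal,
         include_list = include_list, stop_list = stop_list,
         formula_filter = formula_filter),
    class = "pipeline_config"
  )
}

#' Run the full annotation pipeline
#'
#' @param docs A [source_document()] or list of them.
#' @param resources A [resource_set()].
#' @param cfg A [pipeline_config()].
#' @param verbose Print per-stage entity counts.
#' @return List with `entities` (all documents pooled) and `report` (data
#'   frame of per-stage entity counts).
#' @export
run_pipeline <- function(docs, resources, cfg = pipeline_config(),
                         verbose = FALSE) {
  if (inherits(docs, "source_document")) docs <- list(docs)
  stopifnot(inherits(resources, "resource_set"),
            inherits(cfg, "pipeline_config"))
  wl <- resources$word_lists
  specific <- names(Filter(function(r) isTRUE(r$specific),
                           resources$resources))
  counts <- c(annotation = 0L, entity_modification = 0L,
              abbreviation_detection = 0L, nonentity_removal = 0L,
              include_stop_lists = 0L, formula_filter = 0L)
  all_ents <- list()

  for (doc in docs) {
    ents <- annotate(doc, resources, correction = cfg$correction,
                     correction_override = cfg$correction_override)
    counts["annotation"] <- counts["annotation"] + nrow(ents)

    per_section <- lapply(seq_len(nrow(doc$sections)), function(si) {
      label <- doc$sections$label[si]
      text <- doc$sections$text[si]
      sub <- ents[ents$section == label, , drop = FALSE]
      if (cfg$entity_modification) {
        sub <- modify_entities(sub, text, wl, specific_resources = specific)
      }
      sub
    })
    ents <- do.call(rbind, c(list(empty_entities()), per_section))
    counts["entity_modification"] <- counts["entity_modification"] +
      nrow(ents)

    per_section <- lapply(seq_len(nrow(doc$sections)), function(si) {
      label <- doc$sections$label[si]
      text <- doc$sections$text[si]
      sub <- ents[ents$section == label, , drop = FALSE]
      if (cfg$abbreviation_detection) {
        sub <- detect_abbreviations(sub, text, resources$equivalence)$entities
      }
      if (cfg$nonentity_removal) {
        sub <- remove_nonentity_abbreviations(sub, text)
      }
      sub
    })
    ents <- do.call(rbind, c(list(empty_entities()), per_section))
    counts["abbreviation_detection"] <- counts["abbreviation_detection"] +
      nrow(ents)
    counts["nonentity_removal"] <- counts["nonentity_removal"] + nrow(ents)

    ents <- apply_include_stop_lists(
      ents,
      if (cfg$include_list) resources$include_list else NULL,
      if (cfg$stop_list) resources$stop_list else NULL,
      doc
    )
    counts["include_stop_lists"] <- counts["include_stop_lists"] + nrow(ents)

    if (cfg$formula_filter) ents <- filter_sum_formula(ents)
    counts["formula_filter"] <- counts["formula_filter"] + nrow(ents)

    all_ents[[length(all_ents) + 1L]] <- ents
  }

  entities <- do.call(rbind, c(list(empty_entities()), all_ents))
  rownames(entities) <- NULL
  report <- data.frame(stage = names(counts), entities = as.integer(counts),
                       stringsAsFactors = FALSE)
  if (verbose) {
    for (i in seq_len(nrow(report))) {
      message(sprintf("%-24s %d entities", report$stage[i],
                      report$entities[i]))
    }
  }
  list(entities = entities, report = report)
}
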