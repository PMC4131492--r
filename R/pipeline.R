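#' Run the full multi-topic assignment pipeline
#'
#' Convenience wrapper chaining the modules end to end: annotate the
#' corpus with the lexicon, run the concept-filtering cascade, assign
#' topics by subject intersection with the (optionally graph-expanded)
#' topic CUI-sets, assign topics by concept-extent voting over the
#' CUI-question context seeded with the corpus's original single-topic
#' labels, and combine the two assignments into the topic-question
#' context.
#'
#' @param corpus Tibble `id`, `subject`, `body`, `topic` (original
#'   single topic).
#' @param lex Lexicon tibble.
#' @param topics Topic definitions tibble.
#' @param graph Optional concept graph for topic expansion.
#' @param rules Optional hierarchical topic rules.
#' @param vocabulary Optional concept whitelist.
#' @param config A [pipeline_config()] supplying `k`,
#'   `min_term_strength`, `min_votes` and the excluded semantic types.
#' @return A list of class `topic_pipeline_result`: `subject_assignment`,
#'   `vote_assignment`, `combined`, `topic_question_context`,
#'   `topic_subject_context`, `cui_filter` (the `cui_filter_result`),
#'   and `annotations`.
#' @export
run_pipeline <- function(corpus, lex, topics, graph = NULL, rules = NULL,
                         vocabulary = NULL, config = pipeline_config()) {
  annotations <- annotate_questions(corpus, lex)
  topics <- expand_topics(topics, graph)
  ts_ctx <- build_topic_subject_context(
    subject_cui_sets(annotations), topics, question_ids = corpus$id
  )
  subject_assignment <- assign_by_subject(ts_ctx, rules)
  filt <- filter_cuis(
    annotations, lex,
    excluded = config$excluded_semantic_types,
    k = config$k,
    min_term_strength = config$min_term_strength,
    vocabulary = vocabulary
  )
  original <- tibble::tibble(question_id = corpus$id, topic = corpus$topic)
  vote_assignment <- vote_assign(filt$context, original,
                                 min_votes = config$min_votes)
  combined <- combine_assignments(subject_assignment, vote_assignment)
  structure(
    list(
      subject_assignment = subject_assignment,
      vote_assignment = vote_assignment,
      combined = combined,
      topic_question_context = build_topic_question_context(combined),
      topic_subject_context = ts_ctx,
      cui_filter = filt,
      annotations = annotations
    ),
    class = "topic_pipeline_result"
  )
}

#' @export
print.topic_pipeline_result <- function(x, ...) {
  cat("<topic_pipeline_result>\n")
  cat(sprintf("  subject assignment: %d labels over %d questions\n",
              nrow(x$subject_assignment),
              dplyr::n_distinct(x$subject_assignment$question_id)))
  cat(sprintf("  vote assignment:    %d labels over %d questions\n",
              nrow(x$vote_assignment),
              dplyr::n_distinct(x$vote_assignment$question_id)))
  cat(sprintf("  combined:           %d labels over %d questions\n",
              nrow(x$combined),
              dplyr::n_distinct(x$combined$question_id)))
  invisible(x)
}
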