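#' Read topic definitions
#'
#' TSV with columns `topic`, `key_cuis` (pipe-separated) and optionally
#' `cui_set` (pipe-separated expanded set). When `cui_set` is absent it
#' defaults to the key CUIs; [expand_topics()] can grow it from a concept
#' graph.
#'
#' @param path File path.
#' @return Tibble `topic`, list-columns `key_cuis` and `cui_set`
#'   (key CUIs always included in `cui_set`).
#' @export
read_topics <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("topic", "key_cuis") %in% names(df))) {
    rlang::abort("topic file needs columns: topic, key_cuis")
  }
  key <- strsplit(df$key_cuis, "|", fixed = TRUE)
  set <- if ("cui_set" %in% names(df)) {
    strsplit(dplyr::coalesce(df$cui_set, df$key_cuis), "|", fixed = TRUE)
  } else {
    key
  }
  topic_definitions(tibble::tibble(topic = df$topic, key_cuis = key,
                                   cui_set = set))
}

#' @rdname read_topics
#' @param topics Topic tibble.
#' @export
write_topics <- function(topics, path) {
  out <- tibble::tibble(
    topic = topics$topic,
    key_cuis = vapply(topics$key_cuis, paste, "", collapse = "|"),
    cui_set = vapply(topics$cui_set, paste, "", collapse = "|")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Construct a topic-definition table
#'
#' @param df Data frame with `topic` and list-columns `key_cuis`,
#'   optional `cui_set`.
#' @return Validated tibble; `cui_set` always contains `key_cuis`.
#' @export
topic_definitions <- function(df) {
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$topic)) rlang::abort("topic labels must be unique")
  if (!"cui_set" %in% names(df)) df$cui_set <- df$key_cuis
  df$cui_set <- purrr::map2(df$cui_set, df$key_cuis,
                            function(s, k) unique(c(k, s)))
  if (any(lengths(df$cui_set) == 0)) {
    rlang::abort("every topic needs a nonempty CUI-set")
  }
  df
}

#' Read a concept graph
#'
#' TSV with columns `cui_a`, `relation` (`synonym` or `child_of`, read as
#' "cui_a is a synonym / child of cui_b"), `cui_b`.
#'
#' @param path File path.
#' @return Tibble `cui_a`, `relation`, `cui_b`.
#' @export
read_concept_graph <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  need <- c("cui_a", "relation", "cui_b")
  if (!all(need %in% names(df))) {
    rlang::abort("concept graph needs columns: cui_a, relation, cui_b")
  }
  bad <- setdiff(unique(df$relation), c("synonym", "child_of"))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown relation(s): ", paste(bad, collapse = ", ")))
  }
  df
}

#' @rdname read_concept_graph
#' @param graph Concept-graph tibble.
#' @export
write_concept_graph <- function(graph, path) {
  readr::write_tsv(graph, path, progress = FALSE)
  invisible(path)
}

#' Expand a key CUI-set through synonym and descendant edges
#'
#' Collects the key CUIs plus everything reachable from them through
#' synonym edges (undirected) and descendant chains (transitively, via
#' `child_of` edges pointing child -> parent). Traversal is breadth-first
#' with a visited set, so cycles are harmless. Key CUIs absent from the
#' graph are kept as-is.
#'
#' @param key_cuis Nonempty character vector of CUIs.
#' @param graph Concept-graph tibble (`cui_a`, `relation`, `cui_b`) or
#'   `NULL`/empty for no expansion.
#' @return Character vector: the expanded CUI-set (sorted).
#' @export
expand_cui_set <- function(key_cuis, graph = NULL) {
  stopifnot(length(key_cuis) > 0)
  if (is.null(graph) || nrow(graph) == 0) return(sort(unique(key_cuis)))
  syn <- graph[graph$relation == "synonym", ]
  chd <- graph[graph$relation == "child_of", ]
  # neighbours reachable in one step from a set of cuis
  step <- function(cuis) {
    unique(c(
      syn$cui_b[syn$cui_a %in% cuis],
      syn$cui_a[syn$cui_b %in% cuis],
      chd$cui_a[chd$cui_b %in% cuis]   # descendants
    ))
  }
  seen <- unique(key_cuis)
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(step(frontier), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Expand every topic's CUI-set through a concept graph
#'
#' @param topics Topic tibble ([topic_definitions()]).
#' @param graph Concept-graph tibble.
#' @return The topic tibble with `cui_set` replaced by the expansion of
#'   the existing `cui_set` (which contains the key CUIs).
#' @export
expand_topics <- function(topics, graph = NULL) {
  topics$cui_set <- lapply(topics$cui_set, expand_cui_set, graph = graph)
  topics
}

#' Build the topic-subject formal context
#'
#' Objects are question subjects (keyed by question id), attributes are
#' topic labels; a subject is incident with a topic exactly when its
#' subject CUI-set intersects the topic's CUI-set.
#'
#' @param subject_cuis Tibble `question_id`, `cui` of subject
#'   annotations (see [subject_cui_sets()]).
#' @param topics Topic tibble with expanded `cui_set`.
#' @param question_ids Optional full roster of question ids (so subjects
#'   with no topic overlap still appear as empty rows); defaults to the
#'   ids present in `subject_cuis`.
#' @return A [formal_context()] with questions as objects and topics as
#'   attributes.
#' @export
build_topic_subject_context <- function(subject_cuis, topics,
                                        question_ids = NULL) {
  topic_long <- tibble::tibble(
    topic = rep(topics$topic, lengths(topics$cui_set)),
    cui = unlist(topics$cui_set, use.names = FALSE)
  )
  hits <- dplyr::distinct(
    dplyr::inner_join(subject_cuis, topic_long, by = "cui",
                      relationship = "many-to-many"),
    .data$question_id, .data$topic
  )
  formal_context(
    data.frame(object = hits$question_id, attribute = hits$topic),
    objects = question_ids %||% unique(subject_cuis$question_id),
    attributes = topics$topic
  )
}

#' Assign topics from the topic-subject context
#'
#' Each question receives every topic its subject CUI-set intersects
#' (the attribute row of the topic-subject context). An optional rule
#' table expressing the hierarchical relationships between topics is
#' applied afterwards: `implies` rules add the consequent topic whenever
#' the antecedent is present (iterated to a fixed point), then
#' `suppresses` rules remove the consequent when the antecedent is
#' present.
#'
#' @param ctx Topic-subject [formal_context()].
#' @param rules Optional tibble `antecedent`, `relation`
#'   (`implies`/`suppresses`), `consequent`; default none.
#' @return A multi-label assignment: tibble `question_id`, `topic`
#'   (one row per assigned label).
#' @export
assign_by_subject <- function(ctx, rules = NULL) {
  assignment <- tibble::tibble(
    question_id = ctx$pairs$object,
    topic = ctx$pairs$attribute
  )
  apply_topic_rules(dplyr::arrange(assignment, .data$question_id,
                                   .data$topic), rules)
}

#' Apply hierarchical topic rules to an assignment
#'
#' @param assignment Tibble `question_id`, `topic`.
#' @param rules Tibble `antecedent`, `relation`, `consequent` or `NULL`.
#' @return The transformed assignment tibble.
#' @export
apply_topic_rules <- function(assignment, rules = NULL) {
  if (is.null(rules) || nrow(rules) == 0) return(assignment)
  imp <- rules[rules$relation == "implies", ]
  sup <- rules[rules$relation == "suppresses", ]
  if (nrow(imp) > 0) {
    repeat {
      add <- dplyr::distinct(
        dplyr::inner_join(assignment, imp, by = c(topic = "antecedent"),
                          relationship = "many-to-many"),
        .data$question_id, topic = .data$consequent
      )
      add <- dplyr::anti_join(add, assignment,
                              by = c("question_id", "topic"))
      if (nrow(add) == 0) break
      assignment <- dplyr::bind_rows(assignment, add)
    }
  }
  if (nrow(sup) > 0) {
    drop <- dplyr::distinct(
      dplyr::inner_join(assignment, sup, by = c(topic = "antecedent"),
                        relationship = "many-to-many"),
      .data$question_id, topic = .data$consequent
    )
    assignment <- dplyr::anti_join(assignment, drop,
                                   by = c("question_id", "topic"))
  }
  dplyr::arrange(dplyr::distinct(assignment), .data$question_id, .data$topic)
}

#' Read and write hierarchical topic rules
#'
#' TSV with columns `antecedent`, `relation` (`implies`/`suppresses`),
#' `consequent`.
#'
#' @param path File path.
#' @return `read_topic_rules()` returns the rules tibble.
#' @export
read_topic_rules <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  need <- c("antecedent", "relation", "consequent")
  if (!all(need %in% names(df))) {
    rlang::abort("rules file needs columns: antecedent, relation, consequent")
  }
  df
}

#' @rdname read_topic_rules
#' @param rules Rules tibble.
#' @export
write_topic_rules <- function(rules, path) {
  readr::write_tsv(rules, path, progress = FALSE)
  invisible(path)
}

#' Assign topics by concept-extent voting over the CUI-question context
#'
#' Every question starts with its original single topic. For a question
#' q, its CUI-set determines a formal concept of the CUI-question
#' context; the concept's extent is the set of questions sharing all of
#' q's concepts. Among those, the questions whose CUI-set is *exactly*
#' q's CUI-set each cast one vote for their original topic; topics
#' reaching at least `min_votes` votes (topics with a single vote never
#' win) are added to every question in the extent. Because votes come
#' only from original topics and exact CUI-set matches, the result is
#' independent of the order in which questions are processed, and
#' re-running on its own output changes nothing.
#'
#' @param ctx CUI-question [formal_context()] (questions as objects,
#'   concepts as attributes).
#' @param original Tibble `question_id`, `topic`: the original
#'   single-topic assignment. Must cover every object of `ctx`; may
#'   cover questions outside the context (e.g. dropped by filtering),
#'   which then keep their original topic only.
#' @param min_votes Minimum votes for a topic to be assigned (default 2).
#' @return Multi-label assignment tibble `question_id`, `topic`.
#' @export
vote_assign <- function(ctx, original, min_votes = 2) {
  stopifnot(inherits(ctx, "formal_context"), min_votes >= 1)
  original <- dplyr::distinct(tibble::as_tibble(original)[c("question_id",
                                                            "topic")])
  if (anyDuplicated(original$question_id)) {
    rlang::abort("original assignment must give one topic per question")
  }
  uncovered <- setdiff(ctx$objects, original$question_id)
  if (length(uncovered) > 0) {
    rlang::abort(paste0("no original topic for question(s): ",
                        paste(utils::head(uncovered, 5), collapse = ", ")))
  }
  orig_topic <- stats::setNames(original$topic, original$question_id)
  n_obj <- length(ctx$objects)
  keys <- vapply(ctx$obj_attrs, paste, "", collapse = ",")
  extra <- list()
  for (key in unique(keys[nzchar(keys)])) {
    members <- which(keys == key)           # questions with exactly this set
    attr_idx <- ctx$obj_attrs[[members[1]]]
    extent <- derive_objects_idx(ctx, attr_idx)
    votes <- table(orig_topic[ctx$objects[members]])
    winners <- names(votes)[votes >= min_votes]
    if (length(winners) > 0) {
      extra[[length(extra) + 1]] <- tidyr::expand_grid(
        question_id = ctx$objects[sort(extent)], topic = winners
      )
    }
  }
  empties <- ctx$objects[!nzchar(keys)]
  if (length(empties) > 0) {
    rlang::inform(paste0(
      length(empties),
      " question(s) with empty CUI-set keep only their original topic"
    ))
  }
  out <- dplyr::distinct(dplyr::bind_rows(c(list(original), extra)))
  dplyr::arrange(out, .data$question_id, .data$topic)
}

#' Combine multi-label assignments
#'
#' Per-question union of the label sets over the union of question ids;
#' commutative and idempotent.
#'
#' @param ... Assignment tibbles (`question_id`, `topic`).
#' @return The combined assignment tibble.
#' @export
combine_assignments <- function(...) {
  dplyr::arrange(
    dplyr::distinct(dplyr::bind_rows(...)),
    .data$question_id, .data$topic
  )
}

#' Build the topic-question formal context
#'
#' Objects are question ids, attributes topic labels, and a question is
#' incident with exactly the topics assigned to it; the number of
#' incidences equals the total number of assigned labels.
#'
#' @param assignment Assignment tibble (`question_id`, `topic`).
#' @param topics Optional attribute roster (topic labels); defaults to
#'   the sorted labels present.
#' @return A [formal_context()].
#' @export
build_topic_question_context <- function(assignment, topics = NULL) {
  assignment <- dplyr::distinct(tibble::as_tibble(assignment))
  formal_context(
    data.frame(object = assignment$question_id,
               attribute = assignment$topic),
    objects = sort(unique(assignment$question_id)),
    attributes = topics %||% sort(unique(assignment$topic))
  )
}

#' Read and write multi-label assignments
#'
#' TSV with columns `question_id` and `topics` (pipe-separated label
#' set).
#'
#' @param path File path.
#' @return `read_assignment()` returns a long tibble `question_id`,
#'   `topic`.
#' @export
read_assignment <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  if (!all(c("question_id", "topics") %in% names(df))) {
    rlang::abort("assignment file needs columns: question_id, topics")
  }
  labels <- strsplit(df$topics, "|", fixed = TRUE)
  tibble::tibble(
    question_id = rep(df$question_id, lengths(labels)),
    topic = as.character(unlist(labels, use.names = FALSE) %||% character())
  )
}

#' @rdname read_assignment
#' @param assignment Long assignment tibble (`question_id`, `topic`).
#' @export
write_assignment <- function(assignment, path) {
  wide <- dplyr::summarise(
    dplyr::group_by(dplyr::arrange(assignment, .data$question_id,
                                   .data$topic), .data$question_id),
    topics = paste(.data$topic, collapse = "|"), .groups = "drop"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
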