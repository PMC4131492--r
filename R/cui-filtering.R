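#' @importFrom rlang .data %||%
NULL

#' Concept term frequency within questions
#'
#' For each (question, concept) pair, the number of occurrences of the
#' concept in the question and its subject, normalized by the number of
#' all concept occurrences in that question and its subject.
#'
#' @param annotations Annotation tibble ([annotate_questions()]).
#' @return Tibble `question_id`, `cui`, `count`, `tf` with `tf` in (0, 1].
#' @export
cui_tf <- function(annotations) {
  counts <- cui_counts(annotations)
  dplyr::mutate(
    dplyr::group_by(counts, .data$question_id),
    tf = .data$count / sum(.data$count)
  ) |>
    dplyr::ungroup()
}

#' Concept inverse document frequency over a corpus
#'
#' The natural logarithm of the quotient of the number of all questions
#' and the number of questions containing the concept. (The logarithm
#' base only rescales weights and leaves every ranking unchanged; the
#' natural log is fixed for reproducibility.)
#'
#' @param annotations Annotation tibble covering the whole corpus.
#' @param cuis Optional concepts to look up; an error names any concept
#'   contained in zero questions (the quotient is undefined).
#' @return Tibble `cui`, `n_questions`, `idf`.
#' @export
cui_idf <- function(annotations, cuis = NULL) {
  n_total <- dplyr::n_distinct(annotations$question_id)
  tab <- dplyr::count(
    dplyr::distinct(annotations, .data$question_id, .data$cui),
    .data$cui, name = "n_questions"
  )
  tab <- dplyr::mutate(tab, idf = log(n_total / .data$n_questions))
  if (!is.null(cuis)) {
    missing <- setdiff(cuis, tab$cui)
    if (length(missing) > 0) {
      rlang::abort(paste0("IDF undefined for concept(s) in no question: ",
                          paste(missing, collapse = ", ")))
    }
    tab <- tab[match(cuis, tab$cui), ]
  }
  tab
}

#' Select each question's top-k concepts by TF-IDF
#'
#' Ranks a question's concepts by TF x IDF and keeps the `k`
#' highest-weighted; questions with at most `k` concepts keep them all.
#' Ties at the k-th rank break deterministically by weight descending,
#' then CUI ascending (lexical), keeping exactly `k`.
#'
#' @param annotations Annotation tibble.
#' @param k Number of concepts to keep per question (default 5).
#' @return Per-question CUI-sets: tibble `question_id`, `cui`.
#' @export
tfidf_top_k <- function(annotations, k = 5) {
  stopifnot(k >= 1)
  weights <- dplyr::inner_join(cui_tf(annotations), cui_idf(annotations),
                               by = "cui")
  dplyr::group_by(weights, .data$question_id) |>
    dplyr::arrange(dplyr::desc(.data$tf * .data$idf), .data$cui,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::ungroup() |>
    dplyr::select("question_id", "cui") |>
    dplyr::arrange(.data$question_id, .data$cui)
}

#' Concept co-occurrence profiles
#'
#' For every concept C, the list of its co-occurring concepts with the
#' number of questions containing both. The relation is symmetric: C
#' lists D with n exactly when D lists C with n.
#'
#' @param cui_sets Per-question CUI-sets: tibble `question_id`, `cui`
#'   (set semantics; duplicated pairs are collapsed).
#' @return Tibble `cui`, `co_cui`, `n_questions` with `cui != co_cui`.
#' @export
cooccurrence_profiles <- function(cui_sets) {
  sets <- dplyr::distinct(cui_sets, .data$question_id, .data$cui)
  pairs <- dplyr::inner_join(sets, sets, by = "question_id",
                             relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$cui.x != .data$cui.y)
  dplyr::count(pairs, cui = .data$cui.x, co_cui = .data$cui.y,
               name = "n_questions") |>
    dplyr::arrange(.data$cui, .data$co_cui)
}

#' Term-strength index of a co-occurrence count vector
#'
#' The h-index of the multiset of co-occurrence counts: the largest n
#' such that at least n co-occurring concepts share at least n questions
#' each. An empty profile has strength 0.
#'
#' @param counts Integer vector of per-co-concept shared-question counts.
#' @return A single non-negative integer.
#' @export
term_strength <- function(counts) {
  if (length(counts) == 0) return(0L)
  s <- sort(as.integer(counts), decreasing = TRUE)
  sum(s >= seq_along(s))
}

#' Term-strength index for every concept in a profile table
#'
#' @param profiles Tibble as from [cooccurrence_profiles()].
#' @return Tibble `cui`, `strength`.
#' @export
term_strength_table <- function(profiles) {
  dplyr::summarise(
    dplyr::group_by(profiles, .data$cui),
    strength = term_strength(.data$n_questions), .groups = "drop"
  )
}

#' Filter question CUI-sets by term strength
#'
#' Drops concepts whose term-strength index falls below `min_index`
#' (default 2) from every question's CUI-set. Concepts never co-occurring
#' with anything have strength 0.
#'
#' @param cui_sets Per-question CUI-sets (tibble `question_id`, `cui`).
#' @param profiles Optional precomputed [cooccurrence_profiles()]; by
#'   default computed from `cui_sets` itself.
#' @param min_index Minimum term-strength index to survive.
#' @return The filtered CUI-set tibble.
#' @export
filter_by_term_strength <- function(cui_sets, profiles = NULL, min_index = 2) {
  stopifnot(min_index >= 0)
  if (min_index == 0) return(cui_sets)
  profiles <- profiles %||% cooccurrence_profiles(cui_sets)
  strengths <- term_strength_table(profiles)
  keep <- strengths$cui[strengths$strength >= min_index]
  dplyr::filter(cui_sets, .data$cui %in% keep)
}

#' Restrict question CUI-sets to a vocabulary
#'
#' Intersects every CUI-set with a whitelist of concepts (for instance a
#' consumer health vocabulary exported as one CUI per line). With
#' `vocabulary = NULL` the step is skipped.
#'
#' @param cui_sets Per-question CUI-sets.
#' @param vocabulary Character vector of CUIs, or `NULL` to skip.
#' @return The restricted CUI-set tibble.
#' @export
filter_by_vocabulary <- function(cui_sets, vocabulary = NULL) {
  if (is.null(vocabulary)) return(cui_sets)
  dplyr::filter(cui_sets, .data$cui %in% vocabulary)
}

#' Read a vocabulary file (one CUI per line)
#'
#' @param path File path.
#' @return Character vector of CUIs.
#' @export
read_vocabulary <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' Build the CUI-question formal context
#'
#' Objects are the questions with a nonempty surviving CUI-set,
#' attributes the surviving concepts (lexically ordered), and a question
#' is incident with every concept in its set. Questions whose CUI-sets
#' were emptied by filtering are excluded from the context.
#'
#' @param cui_sets Per-question CUI-sets (tibble `question_id`, `cui`).
#' @return A [formal_context()].
#' @export
build_cui_question_context <- function(cui_sets) {
  sets <- dplyr::distinct(cui_sets, .data$question_id, .data$cui)
  formal_context(
    data.frame(object = sets$question_id, attribute = sets$cui),
    objects = unique(sets$question_id),
    attributes = sort(unique(sets$cui))
  )
}

#' Run the full concept-filtering cascade
#'
#' Applies, in order: (1) semantic-type exclusion, (2) per-question
#' TF-IDF top-k selection, (3) term-strength filtering (co-occurrence is
#' computed on the sets surviving step 2, following the sequential
#' cascade), and (4) optional vocabulary restriction; then builds the
#' CUI-question context. A trace of distinct-concept counts per step is
#' returned so corpus-level filtering behaviour can be inspected.
#'
#' @param annotations Annotation tibble for the corpus.
#' @param lex Lexicon tibble (used by the semantic-type step).
#' @param excluded Semantic types to exclude
#'   ([default_excluded_types()]).
#' @param k TF-IDF concepts kept per question (default 5).
#' @param min_term_strength Minimum term-strength index (default 2).
#' @param vocabulary Optional concept whitelist (`NULL` skips step 4).
#' @return A list of class `cui_filter_result`: `cui_sets` (tibble
#'   `question_id`, `cui`), `context` (the [formal_context()]), `trace`
#'   (tibble `step`, `n_cuis` of distinct surviving concepts, plus
#'   `n_questions` with nonempty sets) and `dropped_questions`.
#' @export
filter_cuis <- function(annotations, lex,
                        excluded = default_excluded_types(),
                        k = 5, min_term_strength = 2, vocabulary = NULL) {
  trace <- tibble::tibble(step = character(), n_cuis = integer(),
                          n_questions = integer())
  note <- function(step, sets) {
    tibble::tibble(step = step,
                   n_cuis = dplyr::n_distinct(sets$cui),
                   n_questions = dplyr::n_distinct(sets$question_id))
  }
  all_qids <- unique(annotations$question_id)
  trace <- dplyr::bind_rows(trace, note("annotated", annotations))
  ann1 <- filter_semantic_types(annotations, lex, excluded)
  trace <- dplyr::bind_rows(trace, note("semantic_types", ann1))
  sets2 <- tfidf_top_k(ann1, k = k)
  trace <- dplyr::bind_rows(trace, note("tfidf_top_k", sets2))
  sets3 <- filter_by_term_strength(sets2, min_index = min_term_strength)
  trace <- dplyr::bind_rows(trace, note("term_strength", sets3))
  sets4 <- filter_by_vocabulary(sets3, vocabulary)
  if (!is.null(vocabulary)) {
    trace <- dplyr::bind_rows(trace, note("vocabulary", sets4))
  }
  structure(
    list(
      cui_sets = sets4,
      context = build_cui_question_context(sets4),
      trace = trace,
      dropped_questions = setdiff(all_qids, unique(sets4$question_id))
    ),
    class = "cui_filter_result"
  )
}

#' @export
print.cui_filter_result <- function(x, ...) {
  cat("<cui_filter_result>\n")
  print(x$trace)
  cat(sprintf("%d question(s) dropped (empty CUI-set)\n",
              length(x$dropped_questions)))
  invisible(x)
}

#' Write a filter trace as TSV
#'
#' @param result A `cui_filter_result` (or its `trace` tibble).
#' @param path File path.
#' @export
write_filter_trace <- function(result, path) {
  trace <- if (inherits(result, "cui_filter_result")) result$trace else result
  readr::write_tsv(trace, path, progress = FALSE)
  invisible(path)
}
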