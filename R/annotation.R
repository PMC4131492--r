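#' Default semantic types excluded from concept filtering
#'
#' Semantic types regarded as uninformative for topic assignment of
#' consumer health questions. Concepts all of whose types appear here are
#' removed in the first filtering step; the list is user-extensible.
#'
#' @return Character vector of semantic-type labels.
#' @export
default_excluded_types <- function() {
  c("Quantitative Concept", "Intellectual Product",
    "Geographic Area", "Organization")
}

#' Read a concept lexicon
#'
#' Tab-separated lexicon mapping surface strings to concepts: columns
#' `cui`, `preferred_name`, `semantic_types` (pipe-separated) and
#' `surface_forms` (pipe-separated). The lexicon stands behind the
#' pluggable annotator interface: a dictionary built from any concept
#' source (e.g. an exported UMLS subset) can be supplied, since the full
#' vocabulary is licensed and not redistributable.
#'
#' @param path Path to the lexicon TSV.
#' @return A tibble with columns `cui`, `preferred_name` and list-columns
#'   `semantic_types`, `surface_forms`.
#' @export
read_lexicon <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  need <- c("cui", "preferred_name", "semantic_types", "surface_forms")
  if (!all(need %in% names(df))) {
    rlang::abort(paste0("lexicon is missing columns: ",
                        paste(setdiff(need, names(df)), collapse = ", ")))
  }
  lexicon(dplyr::mutate(
    df,
    semantic_types = strsplit(.data$semantic_types, "|", fixed = TRUE),
    surface_forms = strsplit(.data$surface_forms, "|", fixed = TRUE)
  ))
}

#' @rdname read_lexicon
#' @param lex A lexicon tibble as returned by [read_lexicon()] or
#'   [lexicon()].
#' @export
write_lexicon <- function(lex, path) {
  out <- dplyr::mutate(
    lex,
    semantic_types = vapply(.data$semantic_types, paste, "", collapse = "|"),
    surface_forms = vapply(.data$surface_forms, paste, "", collapse = "|")
  )
  readr::write_tsv(out[, c("cui", "preferred_name", "semantic_types",
                           "surface_forms")], path, progress = FALSE)
  invisible(path)
}

#' Construct a lexicon from vectors
#'
#' @param df Data frame with columns `cui`, `preferred_name`, and
#'   list-columns (or pipe-separated strings) `semantic_types`,
#'   `surface_forms`.
#' @return A validated lexicon tibble.
#' @export
lexicon <- function(df) {
  df <- tibble::as_tibble(df)
  if (is.character(df$semantic_types)) {
    df$semantic_types <- strsplit(df$semantic_types, "|", fixed = TRUE)
  }
  if (is.character(df$surface_forms)) {
    df$surface_forms <- strsplit(df$surface_forms, "|", fixed = TRUE)
  }
  bad <- !grepl("^C[0-9]+$", df$cui)
  if (any(bad)) {
    rlang::abort(paste0("invalid CUI(s): ",
                        paste(unique(df$cui[bad]), collapse = ", ")))
  }
  if (any(lengths(df$surface_forms) == 0)) {
    rlang::abort("every lexicon entry needs at least one surface form")
  }
  df
}

tokenize <- function(text) {
  toks <- stringr::str_split(stringr::str_to_lower(text), "[^a-z0-9']+")[[1]]
  toks[nzchar(toks)]
}

# dictionary compiled for longest-match scanning: normalized surface ->
# character vector of CUIs, plus the token lengths present
compile_dictionary <- function(lex) {
  surf <- tibble::tibble(
    cui = rep(lex$cui, lengths(lex$surface_forms)),
    form = unlist(lex$surface_forms, use.names = FALSE)
  )
  toks <- lapply(surf$form, tokenize)
  keep <- lengths(toks) > 0
  surf <- surf[keep, ]
  toks <- toks[keep]
  key <- vapply(toks, paste, "", collapse = " ")
  list(
    map = split(surf$cui, key),
    lens = sort(unique(lengths(toks)), decreasing = TRUE)
  )
}

match_tokens <- function(toks, dict) {
  n <- length(toks)
  hits <- character()
  i <- 1L
  while (i <= n) {
    advanced <- FALSE
    for (len in dict$lens) {
      if (i + len - 1L > n) next
      key <- paste(toks[i:(i + len - 1L)], collapse = " ")
      cuis <- dict$map[[key]]
      if (!is.null(cuis)) {
        hits <- c(hits, unique(cuis))
        i <- i + len
        advanced <- TRUE
        break
      }
    }
    if (!advanced) i <- i + 1L
  }
  hits
}

#' Annotate questions with concept identifiers
#'
#' Dictionary-based concept annotation standing in for a full biomedical
#' named-entity annotator (such as MetaMap): case-insensitive,
#' whitespace/punctuation-tokenized, longest-match-wins, non-overlapping,
#' left-to-right matching of lexicon surface forms over each question's
#' subject and body. The result is the long annotation table the rest of
#' the pipeline consumes; externally produced annotations in the same
#' shape can be used instead (see [read_annotations()]).
#'
#' @param questions Data frame with columns `id`, `subject`, `body` (and
#'   optionally `topic`, carried along elsewhere).
#' @param lex A lexicon tibble ([lexicon()]).
#' @return A tibble with one row per (question, concept, field):
#'   columns `question_id`, `cui`, `field` (`"subject"` or `"body"`) and
#'   `count` (number of mentions, >= 1). Questions with no matches
#'   contribute no rows.
#' @export
annotate_questions <- function(questions, lex) {
  stopifnot(all(c("id", "subject", "body") %in% names(questions)))
  dict <- compile_dictionary(lex)
  one_field <- function(texts) {
    lapply(texts, function(t) match_tokens(tokenize(t), dict))
  }
  subj <- one_field(questions$subject)
  body <- one_field(questions$body)
  bind_hits <- function(hits, field) {
    n <- lengths(hits)
    if (sum(n) == 0) {
      return(tibble::tibble(question_id = character(), cui = character(),
                            field = character(), count = integer()))
    }
    tibble::tibble(
      question_id = rep(questions$id, n),
      cui = unlist(hits, use.names = FALSE),
      field = field
    ) |>
      dplyr::count(.data$question_id, .data$cui, .data$field, name = "count")
  }
  dplyr::arrange(
    dplyr::bind_rows(bind_hits(subj, "subject"), bind_hits(body, "body")),
    match(.data$question_id, questions$id), .data$cui, .data$field
  )
}

#' Filter annotations by excluded semantic types
#'
#' Removes every concept all of whose semantic types are excluded; a
#' concept with at least one non-excluded type is kept (mixed-typed
#' concepts still carry topical information). Concepts not resolvable in
#' the lexicon are kept with a warning, since annotations may come from
#' an external annotator with a larger vocabulary.
#'
#' @param annotations Annotation tibble as from [annotate_questions()].
#' @param lex A lexicon tibble.
#' @param excluded Character vector of semantic-type labels to exclude;
#'   defaults to [default_excluded_types()].
#' @return The filtered annotation tibble.
#' @export
filter_semantic_types <- function(annotations, lex,
                                  excluded = default_excluded_types()) {
  if (length(excluded) == 0) return(annotations)
  cuis <- unique(annotations$cui)
  idx <- match(cuis, lex$cui)
  unresolved <- cuis[is.na(idx)]
  if (length(unresolved) > 0) {
    rlang::warn(paste0("retaining concept(s) not in lexicon: ",
                       paste(unresolved, collapse = ", ")))
  }
  drop <- vapply(seq_along(cuis), function(i) {
    if (is.na(idx[i])) return(FALSE)
    types <- lex$semantic_types[[idx[i]]]
    length(types) > 0 && all(types %in% excluded)
  }, logical(1))
  annotations[!(annotations$cui %in% cuis[drop]), ]
}

#' Per-question subject CUI-sets from an annotation table
#'
#' @param annotations Annotation tibble.
#' @return Tibble `question_id`, `cui` restricted to subject mentions
#'   (one row per distinct pair).
#' @export
subject_cui_sets <- function(annotations) {
  dplyr::distinct(
    dplyr::filter(annotations, .data$field == "subject"),
    .data$question_id, .data$cui
  )
}

#' Per-question combined CUI occurrence counts
#'
#' Sums subject and body mentions per concept, the count used by the
#' term-frequency step.
#'
#' @param annotations Annotation tibble.
#' @return Tibble `question_id`, `cui`, `count`.
#' @export
cui_counts <- function(annotations) {
  dplyr::summarise(
    dplyr::group_by(annotations, .data$question_id, .data$cui),
    count = sum(.data$count), .groups = "drop"
  )
}

#' Read and write annotation tables
#'
#' TSV interchange with external annotators: columns `question_id`,
#' `cui`, `field` (`subject`/`body`), `count`.
#'
#' @param path File path.
#' @return `read_annotations()` returns the annotation tibble.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = "ccci", progress = FALSE)
  need <- c("question_id", "cui", "field", "count")
  if (!all(need %in% names(df))) {
    rlang::abort(paste0("annotation file missing columns: ",
                        paste(setdiff(need, names(df)), collapse = ", ")))
  }
  df
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations, path, progress = FALSE)
  invisible(path)
}

#' Read and write question corpora as JSON Lines
#'
#' One JSON object per line with keys `id`, `subject`, `body`, `topic`
#' (the original single-topic assignment).
#'
#' @param path File path.
#' @return `read_corpus_jsonl()` returns a tibble with those columns.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(id = character(), subject = character(),
                          body = character(), topic = character()))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble::tibble(
    id = vapply(recs, function(r) as.character(r$id), ""),
    subject = vapply(recs, function(r) as.character(r$subject), ""),
    body = vapply(recs, function(r) as.character(r$body), ""),
    topic = vapply(recs, function(r) as.character(r$topic %||% NA_character_), "")
  )
}

#' @rdname read_corpus_jsonl
#' @param corpus Corpus tibble (`id`, `subject`, `body`, `topic`).
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      id = corpus$id[i], subject = corpus$subject[i],
      body = corpus$body[i], topic = corpus$topic[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
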