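#' Specification for a synthetic consumer-health question corpus
#'
#' Describes a corpus with known multi-topic ground truth, emulating a
#' community question-answering archive in which each question was
#' originally filed under a single topic although several are relevant.
#' Topics own disjoint (or deliberately overlapping) concept pools;
#' each question mentions concepts from every one of its true topics in
#' the subject and repeats them (plus optional noise concepts) in the
#' body. Bodies are token sequences sufficient for the dictionary
#' annotator, not natural language.
#'
#' @param n_topics Number of topics.
#' @param cuis_per_topic Concepts in each topic's pool.
#' @param n_shared_cuis Concepts each topic (after the first) shares
#'   with the previous topic's pool (0 = disjoint pools).
#' @param n_questions Number of questions.
#' @param labels_per_question Integer vector of possible true-topic
#'   counts per question, sampled uniformly (e.g. `1`, or `1:3`).
#' @param subject_mentions Concepts mentioned in the subject per true
#'   topic.
#' @param body_mentions Concepts mentioned in the body per true topic
#'   (the subject concepts are always among them, so key concepts
#'   repeat).
#' @param noise_cui_rate Probability, per body mention slot, of adding
#'   one noise-concept mention drawn from an off-topic pool.
#' @param annotation_miss_rate Probability that any single body mention
#'   is corrupted so the dictionary annotator misses it.
#' @param n_noise_cuis Size of the off-topic noise-concept pool.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_topics = 50, cuis_per_topic = 8,
                           n_shared_cuis = 0, n_questions = 2000,
                           labels_per_question = 1,
                           subject_mentions = 1, body_mentions = 2,
                           noise_cui_rate = 0, annotation_miss_rate = 0,
                           n_noise_cuis = 40, seed = 1L) {
  spec <- list(
    n_topics = as.integer(n_topics),
    cuis_per_topic = as.integer(cuis_per_topic),
    n_shared_cuis = as.integer(n_shared_cuis),
    n_questions = as.integer(n_questions),
    labels_per_question = as.integer(labels_per_question),
    subject_mentions = as.integer(subject_mentions),
    body_mentions = as.integer(body_mentions),
    noise_cui_rate = as.numeric(noise_cui_rate),
    annotation_miss_rate = as.numeric(annotation_miss_rate),
    n_noise_cuis = as.integer(n_noise_cuis),
    seed = as.integer(seed)
  )
  with(spec, {
    if (n_topics < 1 || cuis_per_topic < 1 || n_questions < 0) {
      rlang::abort("n_topics and cuis_per_topic must be >= 1, n_questions >= 0")
    }
    if (n_shared_cuis >= cuis_per_topic) {
      rlang::abort("n_shared_cuis must be smaller than cuis_per_topic")
    }
    if (any(labels_per_question < 1) || max(labels_per_question) > n_topics) {
      rlang::abort("labels_per_question must lie in [1, n_topics]")
    }
    if (subject_mentions < 1 || subject_mentions > cuis_per_topic) {
      rlang::abort("subject_mentions must lie in [1, cuis_per_topic]")
    }
    if (body_mentions < subject_mentions || body_mentions > cuis_per_topic) {
      rlang::abort("body_mentions must lie in [subject_mentions, cuis_per_topic]")
    }
    if (noise_cui_rate < 0 || noise_cui_rate > 1 ||
        annotation_miss_rate < 0 || annotation_miss_rate > 1) {
      rlang::abort("rates must lie in [0, 1]")
    }
  })
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic corpus with known ground truth
#'
#' Draws, for each question: a set of true topics (uniform over topic
#' subsets of the sampled size), a subject mentioning `subject_mentions`
#' concepts from each true topic, and a body mentioning `body_mentions`
#' concepts per true topic (always including the subject concepts, each
#' repeated once more in the body) plus noise-concept mentions. The
#' original single-topic label -- emulating the archive's manual
#' assignment -- is one of the true topics chosen uniformly; the ground
#' truth records all of them. All randomness flows from `spec$seed`
#' through one generator stream, so a fixed spec reproduces the corpus
#' exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_corpus` with tibbles `questions`
#'   (`id`, `subject`, `body`, `topic`), `lexicon` ([lexicon()] shape),
#'   `topics` ([topic_definitions()] shape), `concept_graph` and
#'   `truth` (`question_id`, `topic`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n_topic_cuis <- spec$n_topics * spec$cuis_per_topic -
    (spec$n_topics - 1) * spec$n_shared_cuis
  n_cuis <- n_topic_cuis + spec$n_noise_cuis
  cuis <- sprintf("C%07d", seq_len(n_cuis))
  tokens <- sprintf("term%05d", seq_len(n_cuis))

  # topic pools: consecutive blocks, overlapping by n_shared_cuis
  stride <- spec$cuis_per_topic - spec$n_shared_cuis
  topic_cuis <- lapply(seq_len(spec$n_topics), function(t) {
    start <- (t - 1) * stride
    cuis[start + seq_len(spec$cuis_per_topic)]
  })
  topic_labels <- sprintf("T%03d", seq_len(spec$n_topics))
  noise_cuis <- if (spec$n_noise_cuis > 0) {
    cuis[n_topic_cuis + seq_len(spec$n_noise_cuis)]
  } else {
    character()
  }

  lex <- tibble::tibble(
    cui = cuis,
    preferred_name = tokens,
    semantic_types = as.list(rep("Finding", n_cuis)),
    surface_forms = as.list(tokens)
  )
  token_of <- stats::setNames(tokens, cuis)

  topics <- tibble::tibble(
    topic = topic_labels,
    key_cuis = topic_cuis,
    cui_set = topic_cuis
  )

  n <- spec$n_questions
  qid <- sprintf("Q%05d", seq_len(n))
  subjects <- character(n)
  bodies <- character(n)
  original <- character(n)
  truth_topics <- vector("list", n)
  for (i in seq_len(n)) {
    n_lab <- if (length(spec$labels_per_question) == 1) {
      spec$labels_per_question
    } else {
      sample(spec$labels_per_question, 1)
    }
    labs <- sort(sample.int(spec$n_topics, n_lab))
    truth_topics[[i]] <- topic_labels[labs]
    original[i] <- topic_labels[labs[[sample.int(n_lab, 1)]]]
    subj_toks <- character()
    body_toks <- character()
    for (t in labs) {
      pool <- topic_cuis[[t]]
      picked <- pool[sample.int(length(pool), spec$body_mentions)]
      subj_cuis <- picked[seq_len(spec$subject_mentions)]
      subj_toks <- c(subj_toks, token_of[subj_cuis])
      # body repeats the subject concepts and adds the remaining picks
      body_toks <- c(body_toks, token_of[picked], token_of[subj_cuis])
      if (spec$noise_cui_rate > 0 && length(noise_cuis) > 0) {
        n_noise <- stats::rbinom(1, spec$body_mentions, spec$noise_cui_rate)
        if (n_noise > 0) {
          body_toks <- c(body_toks,
                         token_of[sample(noise_cuis, n_noise, replace = TRUE)])
        }
      }
    }
    if (spec$annotation_miss_rate > 0 && length(body_toks) > 0) {
      hit <- stats::runif(length(body_toks)) < spec$annotation_miss_rate
      body_toks[hit] <- paste0("zz", body_toks[hit])
    }
    subjects[i] <- paste(subj_toks, collapse = " and ")
    bodies[i] <- paste(c("i have a question about",
                         sample(body_toks)), collapse = " ")
  }

  truth <- tibble::tibble(
    question_id = rep(qid, lengths(truth_topics)),
    topic = as.character(unlist(truth_topics, use.names = FALSE) %||%
                           character())
  )
  structure(
    list(
      questions = tibble::tibble(id = qid, subject = subjects,
                                 body = bodies, topic = original),
      lexicon = lex,
      topics = topics,
      concept_graph = tibble::tibble(cui_a = character(),
                                     relation = character(),
                                     cui_b = character()),
      truth = truth,
      spec = spec
    ),
    class = "synthetic_corpus"
  )
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus> %d questions, %d topics, %d lexicon entries\n",
    nrow(x$questions), nrow(x$topics), nrow(x$lexicon)
  ))
  invisible(x)
}

#' Write a synthetic corpus to a directory
#'
#' Writes `corpus.jsonl`, `lexicon.tsv`, `topics.tsv`,
#' `concept_graph.tsv` and `truth.tsv`.
#'
#' @param corpus A `synthetic_corpus` ([generate_corpus()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus_files <- function(corpus, dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_corpus_jsonl(corpus$questions, file.path(dir, "corpus.jsonl"))
  write_lexicon(corpus$lexicon, file.path(dir, "lexicon.tsv"))
  write_topics(corpus$topics, file.path(dir, "topics.tsv"))
  write_concept_graph(corpus$concept_graph,
                      file.path(dir, "concept_graph.tsv"))
  write_assignment(corpus$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

# save/restore the global RNG state so generation is a pure function of
# the spec seed without disturbing the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
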