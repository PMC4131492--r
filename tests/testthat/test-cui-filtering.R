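# bare annotation table: one row per (question, cui) with given counts
ann_table <- function(...) {
  sets <- list(...)
  tibble::tibble(
    question_id = rep(names(sets), lengths(sets)),
    cui = unlist(lapply(sets, names), use.names = FALSE),
    field = "body",
    count = as.integer(unlist(sets, use.names = FALSE))
  )
}

test_that("term frequency is the occurrence share within a question", {
  ann <- ann_table(q1 = c(A = 2, B = 1, C = 1), q2 = c(A = 1))
  tf <- cui_tf(ann)
  expect_equal(tf$tf[tf$question_id == "q1" & tf$cui == "A"], 0.5)
  expect_equal(tf$tf[tf$question_id == "q1" & tf$cui == "B"], 0.25)
  expect_equal(tf$tf[tf$question_id == "q2" & tf$cui == "A"], 1)
  ann2 <- ann_table(q = c(A = 1, B = 1))
  expect_equal(cui_tf(ann2)$tf, c(0.5, 0.5))
})

test_that("inverse document frequency uses the natural log of N/n", {
  ann <- ann_table(q1 = c(A = 1, B = 1), q2 = c(A = 1), q3 = c(A = 1),
                   q4 = c(A = 2, B = 3))
  idf <- cui_idf(ann)
  expect_equal(idf$idf[idf$cui == "A"], 0)          # in every question
  expect_equal(idf$idf[idf$cui == "B"], log(2))     # 4 questions, in 2
  ann8 <- ann_table(q1 = c(B = 1), q2 = c(B = 1),
                    q3 = c(X = 1), q4 = c(X = 1), q5 = c(X = 1),
                    q6 = c(X = 1), q7 = c(X = 1), q8 = c(X = 1))
  expect_equal(cui_idf(ann8, "B")$idf, log(4))      # 8 questions, in 2
  expect_error(cui_idf(ann, "Z"), "Z")
})

test_that("top-k selection keeps small sets whole and breaks ties lexically", {
  small <- ann_table(q = c(A = 3, B = 2, C = 1))
  expect_equal(nrow(tfidf_top_k(small, k = 5)), 3L)
  # 6 concepts with strictly decreasing weights in a 2-question corpus
  ann <- ann_table(
    q1 = c(A = 6, B = 5, C = 4, D = 3, E = 2, F = 1),
    q2 = c(Z = 1)
  )
  kept <- tfidf_top_k(ann, k = 5)
  expect_setequal(kept$cui[kept$question_id == "q1"],
                  c("A", "B", "C", "D", "E"))
  # tie at the k-th rank: equal counts give equal weights; lexical order
  tie <- ann_table(q1 = c(A = 1, B = 1), q2 = c(Z = 1))
  kept1 <- tfidf_top_k(tie, k = 1)
  expect_equal(kept1$cui[kept1$question_id == "q1"], "A")
})

test_that("co-occurrence profiles are symmetric and count shared questions", {
  cq <- example_fixture("cui_question_context")
  sets <- tibble::tibble(question_id = cq$pairs$object,
                         cui = cq$pairs$attribute)
  prof <- cooccurrence_profiles(sets)
  expect_equal(
    prof$n_questions[prof$cui == "C0439531" & prof$co_cui == "C0025874"], 6L
  )
  # symmetry: C lists D with n iff D lists C with n
  flipped <- dplyr::rename(prof, cui = co_cui, co_cui = cui)
  expect_equal(
    dplyr::arrange(prof, cui, co_cui),
    dplyr::arrange(flipped, cui, co_cui)[names(prof)]
  )
  # a concept alone in its questions has an empty profile
  solo <- tibble::tibble(question_id = c("q1", "q2"), cui = c("A", "B"))
  expect_equal(nrow(cooccurrence_profiles(solo)), 0L)
  # two questions both {A,B}
  two <- tibble::tibble(question_id = c("q1", "q1", "q2", "q2"),
                        cui = c("A", "B", "A", "B"))
  p2 <- cooccurrence_profiles(two)
  expect_equal(p2$n_questions[p2$cui == "A" & p2$co_cui == "B"], 2L)
})

test_that("term strength is the h-index of co-occurrence counts", {
  expect_equal(term_strength(integer()), 0L)
  expect_equal(term_strength(c(5, 4, 3, 2, 1)), 3L)
  expect_equal(term_strength(c(10, 10)), 2L)
  expect_equal(term_strength(1), 1L)
  set.seed(11)
  for (rep in 1:300) {
    counts <- sample.int(100, sample(0:50, 1), replace = TRUE)
    got <- term_strength(counts)
    expect_identical(got, brute_term_strength(counts))
    expect_identical(got, as.integer(sorted_prefix_strength(counts)))
    # bounded by both the profile size and the largest count
    expect_lte(got, length(counts))
    if (length(counts) > 0) expect_lte(got, max(counts))
    # monotone under adding an entry
    expect_gte(term_strength(c(counts, 100L)), got)
  }
})

test_that("term-strength filtering drops weakly co-occurring concepts", {
  # two disjoint single-concept questions: every strength is 0
  solo <- tibble::tibble(question_id = c("q1", "q2"), cui = c("A", "B"))
  expect_equal(nrow(filter_by_term_strength(solo, min_index = 2)), 0L)
  expect_identical(filter_by_term_strength(solo, min_index = 0), solo)
  # A,B,C mutually co-occur in 2 questions (strength 2 each); D tags
  # along once (strength 1) and is dropped
  sets <- tibble::tibble(
    question_id = c("q1", "q1", "q1", "q2", "q2", "q2", "q3", "q3"),
    cui = c("A", "B", "C", "A", "B", "C", "A", "D")
  )
  kept <- filter_by_term_strength(sets, min_index = 2)
  expect_setequal(unique(kept$cui), c("A", "B", "C"))
})

test_that("vocabulary restriction intersects CUI-sets", {
  sets <- tibble::tibble(question_id = c("q1", "q1", "q2"),
                         cui = c("A", "B", "B"))
  expect_identical(filter_by_vocabulary(sets, NULL), sets)
  expect_identical(filter_by_vocabulary(sets, c("A", "B")), sets)
  expect_equal(nrow(filter_by_vocabulary(sets, character())), 0L)
  only_a <- filter_by_vocabulary(sets, "A")
  expect_equal(only_a$question_id, "q1")
  expect_equal(only_a$cui, "A")
})

test_that("the CUI-question context mirrors surviving CUI-sets exactly", {
  cq <- example_fixture("cui_question_context")
  sets <- tibble::tibble(question_id = cq$pairs$object,
                         cui = cq$pairs$attribute)
  rebuilt <- build_cui_question_context(sets)
  expect_identical(fc_matrix(rebuilt)[cq$objects, cq$attributes],
                   fc_matrix(cq))
  expect_equal(nrow(rebuilt$pairs), 18L)
  # empty corpus and single-question corner cases
  empty <- build_cui_question_context(
    tibble::tibble(question_id = character(), cui = character())
  )
  expect_equal(dim(empty), c(0L, 0L))
  one <- build_cui_question_context(
    tibble::tibble(question_id = "q", cui = "A")
  )
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(nrow(one$pairs), 1L)
})

test_that("the filtering cascade only shrinks CUI-sets and logs a trace", {
  set.seed(5)
  spec <- synthetic_spec(n_topics = 6, cuis_per_topic = 4,
                         n_questions = 60, labels_per_question = 1:2,
                         noise_cui_rate = 0.3, seed = 99)
  corpus <- generate_corpus(spec)
  ann <- annotate_questions(corpus$questions, corpus$lexicon)
  res <- filter_cuis(ann, corpus$lexicon)
  expect_s3_class(res$context, "formal_context")
  # non-increasing distinct-CUI counts across the cascade
  expect_true(all(diff(res$trace$n_cuis) <= 0))
  # per-question sets only shrink relative to the annotated sets
  before <- as_label_sets(
    dplyr::rename(dplyr::distinct(ann, question_id, cui), topic = cui)
  )
  after <- as_label_sets(dplyr::rename(res$cui_sets, topic = cui))
  for (q in names(after)) {
    expect_true(all(after[[q]] %in% before[[q]]))
  }
  # dropped questions are exactly those with emptied sets
  expect_setequal(res$dropped_questions,
                  setdiff(names(before), names(after)))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_filter_trace(res, p)
  expect_equal(nrow(readr::read_tsv(p, show_col_types = FALSE)),
               nrow(res$trace))
})
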