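test_that("CUI-set expansion follows synonym and descendant edges", {
  graph <- example_fixture("concept_graph")
  # empty graph: identity
  expect_equal(expand_cui_set("C0032961", NULL), "C0032961")
  got <- expand_cui_set("C0032961", graph)
  expect_true(all(c("C0032961", "C0553641", "C0549206") %in% got))
  # transitive descendant chain and cycle safety
  chain <- tibble::tibble(
    cui_a = c("C2", "C3", "C1"),
    relation = c("child_of", "child_of", "child_of"),
    cui_b = c("C1", "C2", "C3")   # cycle C1 -> C2 -> C3 -> C1
  )
  expect_setequal(expand_cui_set("C1", chain), c("C1", "C2", "C3"))
  # a key CUI absent from the graph is kept as-is
  expect_setequal(expand_cui_set(c("C9", "C1"), chain),
                  c("C9", "C1", "C2", "C3"))
})

test_that("topic-subject context reproduces the worked incidence table", {
  ctx <- build_topic_subject_context(
    example_fixture("subjects"),
    example_fixture("topics")
  )
  expected <- example_fixture("topic_subject_context")
  expect_identical(fc_matrix(ctx)[expected$objects, expected$attributes],
                   fc_matrix(expected))
  expect_equal(nrow(ctx$pairs), 11L)
  expect_setequal(
    derive_attributes(ctx, "Breast feeding and asthma medications"),
    c("Asthma", "Breast Feeding", "Pharmacy and Medications")
  )
  # a subject with no overlapping concepts keeps an empty row
  with_orphan <- build_topic_subject_context(
    dplyr::bind_rows(example_fixture("subjects"),
                     tibble::tibble(question_id = "orphan", cui = "C9999999")),
    example_fixture("topics")
  )
  expect_true("orphan" %in% with_orphan$objects)
  expect_length(derive_attributes(with_orphan, "orphan"), 0)
  expect_equal(nrow(with_orphan$pairs), 11L)
})

test_that("subject assignment returns each row's topics and applies rules", {
  ctx <- example_fixture("topic_subject_context")
  asn <- assign_by_subject(ctx)
  sets <- as_label_sets(asn)
  expect_setequal(sets[["Asthma and pregnancy"]], c("Asthma", "Pregnancy"))
  expect_setequal(sets[["Pregnancy while on TB Medications"]],
                  c("Pharmacy and Medications", "Pregnancy"))
  # implies rules iterate to a fixed point; suppresses runs after
  rules <- tibble::tibble(
    antecedent = c("Asthma", "Lung Disease", "Pregnancy"),
    relation = c("implies", "implies", "suppresses"),
    consequent = c("Lung Disease", "Internal Medicine", "Asthma")
  )
  ruled <- as_label_sets(assign_by_subject(ctx, rules))
  expect_setequal(ruled[["Asthma and pregnancy"]],
                  c("Pregnancy", "Lung Disease", "Internal Medicine"))
  expect_setequal(ruled[["Breast feeding and asthma medications"]],
                  c("Asthma", "Breast Feeding", "Pharmacy and Medications",
                    "Lung Disease", "Internal Medicine"))
})

test_that("concept-extent voting reproduces the worked example verbatim", {
  ctx <- example_fixture("cui_question_context")
  original <- example_fixture("original_topics")
  got <- as_label_sets(vote_assign(ctx, original, min_votes = 2))
  expect_setequal(got$Q1, "Gynecology")
  expect_setequal(got$Q2, "Pregnancy")
  expect_setequal(got$Q3, "Pregnancy")
  expect_setequal(got$Q4, c("Pregnancy", "Gynecology"))
  expect_setequal(got$Q5, "Gynecology")
  expect_setequal(got$Q6, c("Infertility", "Gynecology"))
  expect_setequal(got$Q7, c("Women's Health", "Gynecology", "Pregnancy"))
  expect_setequal(got$Q8, "Gynecology")
})

test_that("voting is order-invariant, extensive, and a fixed point", {
  ctx <- example_fixture("cui_question_context")
  original <- example_fixture("original_topics")
  base <- vote_assign(ctx, original)
  set.seed(3)
  for (rep in 1:5) {
    perm <- sample(nrow(original))
    m <- fc_matrix(ctx)
    shuffled_ctx <- fc_from_matrix(m[sample(nrow(m)), , drop = FALSE])
    got <- vote_assign(shuffled_ctx, original[perm, ])
    expect_equal(as_label_sets(got), as_label_sets(base))
  }
  # superset of the original assignment
  expect_equal(nrow(dplyr::anti_join(original, base,
                                     by = c("question_id", "topic"))), 0L)
  # re-running with votes still drawn from original topics changes nothing
  again <- vote_assign(ctx, original)
  expect_equal(as_label_sets(again), as_label_sets(base))
})

test_that("voting never assigns a topic on a single vote", {
  # every question has a unique CUI-set and a unique topic
  sets <- tibble::tibble(
    question_id = c("q1", "q2", "q2", "q3", "q3", "q3"),
    cui = c("A", "A", "B", "A", "B", "C")
  )
  ctx <- build_cui_question_context(sets)
  original <- tibble::tibble(question_id = c("q1", "q2", "q3"),
                             topic = c("T1", "T2", "T3"))
  got <- vote_assign(ctx, original)
  expect_equal(as_label_sets(got), as_label_sets(original))
  # one-vote topics lose even when 1 is the maximum tally
  expect_equal(nrow(got), 3L)
})

test_that("voting validates its original-topic input", {
  ctx <- example_fixture("cui_question_context")
  expect_error(
    vote_assign(ctx, tibble::tibble(question_id = "Q1", topic = "X")),
    "no original topic"
  )
  dup <- dplyr::bind_rows(example_fixture("original_topics"),
                          tibble::tibble(question_id = "Q1", topic = "Other"))
  expect_error(vote_assign(ctx, dup), "one topic per question")
})

test_that("assignments combine as per-question unions", {
  a <- as_assignment(list(q1 = "T1", q2 = c("T1", "T2")))
  b <- as_assignment(list(q1 = "T2", q3 = "T3"))
  ab <- combine_assignments(a, b)
  expect_equal(as_label_sets(ab),
               list(q1 = c("T1", "T2"), q2 = c("T1", "T2"), q3 = "T3"))
  expect_equal(combine_assignments(a, a), dplyr::arrange(a, question_id))
  expect_equal(as_label_sets(combine_assignments(b, a)), as_label_sets(ab))
})

test_that("topic-question context has one incidence per assigned label", {
  ctx <- example_fixture("cui_question_context")
  final <- vote_assign(ctx, example_fixture("original_topics"))
  tq <- build_topic_question_context(final)
  expect_equal(nrow(tq$pairs), 12L)  # 8 original + 4 added labels
  expect_equal(nrow(tq$pairs), nrow(final))
  empty <- build_topic_question_context(
    tibble::tibble(question_id = character(), topic = character())
  )
  expect_equal(dim(empty), c(0L, 0L))
  single <- build_topic_question_context(
    as_assignment(list(q = c("T1", "T2", "T3")))
  )
  expect_equal(dim(single), c(1L, 3L))
  expect_equal(nrow(single$pairs), 3L)
})

test_that("topic and assignment tables round-trip through TSV", {
  topics <- example_fixture("topics")
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_topics(topics, pt)
  back <- read_topics(pt)
  expect_equal(back$topic, topics$topic)
  expect_equal(lapply(back$cui_set, sort), lapply(topics$cui_set, sort))

  asn <- example_fixture("original_topics")
  pa <- withr::local_tempfile(fileext = ".tsv")
  write_assignment(asn, pa)
  expect_equal(as_label_sets(read_assignment(pa)), as_label_sets(asn))

  graph <- example_fixture("concept_graph")
  pg <- withr::local_tempfile(fileext = ".tsv")
  write_concept_graph(graph, pg)
  expect_identical(read_concept_graph(pg), graph)
  expect_error(read_concept_graph({
    bad <- withr::local_tempfile(fileext = ".tsv")
    readr::write_tsv(tibble::tibble(cui_a = "C1", relation = "broader",
                                    cui_b = "C2"), bad)
    bad
  }), "unknown relation")
})
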