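test_that("example-based metrics reproduce the four worked examples", {
  ex <- example_fixture("eval_examples")
  ev <- evaluate_assignment(ex$reference, ex$predicted)
  expect_equal(ev$example_based$precision, mean(c(1, 1, 1, 0.5)))   # 0.875
  expect_equal(ev$example_based$recall, mean(c(1, 1, 1, 0.1)))     # 0.775
  expect_equal(ev$example_based$f1, mean(c(1, 1, 1, 1 / 6)))       # 0.792
  terms <- tidy(ev)
  x4 <- terms[terms$question_id == "x4", ]
  expect_equal(x4$precision, 0.5)
  expect_equal(x4$recall, 0.1)
  expect_equal(round(x4$f1, 3), 0.167)
})

test_that("traditional micro metrics pool counts over examples", {
  ex <- example_fixture("eval_examples")
  tr <- evaluate_assignment(ex$reference, ex$predicted)$traditional
  # overlaps are 2, 2, 1, 1; |Y| sums to 15, |Z| to 7
  expect_equal(tr$tp, 6L)
  expect_equal(tr$fn, 9L)
  expect_equal(tr$fp, 1L)
  expect_equal(tr$precision, 6 / 7)
  expect_equal(tr$recall, 6 / 15)
  expect_equal(tr$f1, 2 * (6 / 7) * (6 / 15) / (6 / 7 + 6 / 15))
  # invariants tying the counts to the label totals
  expect_equal(tr$tp + tr$fn, nrow(ex$reference))
  expect_equal(tr$tp + tr$fp, nrow(ex$predicted))
})

test_that("a few heavily labelled examples depress micro recall more", {
  # the reason example-based metrics exist: x4's ten labels dominate the
  # pooled recall but count as one example in the macro average
  ex <- example_fixture("eval_examples")
  ev <- evaluate_assignment(ex$reference, ex$predicted)
  expect_gt(ev$example_based$recall, ev$traditional$recall)
  expect_gt(ev$example_based$f1, ev$traditional$f1)
})

test_that("perfect and disjoint predictions hit the boundary values", {
  ref <- as_assignment(list(q1 = c("a", "b"), q2 = "c"))
  perfect <- evaluate_assignment(ref, ref)
  expect_equal(perfect$example_based, list(precision = 1, recall = 1, f1 = 1))
  expect_equal(perfect$traditional$fp, 0L)
  expect_equal(perfect$traditional$fn, 0L)
  disjoint <- evaluate_assignment(
    as_assignment(list(q = "a")), as_assignment(list(q = "b"))
  )
  expect_equal(disjoint$traditional[c("tp", "fp", "fn")],
               list(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(disjoint$example_based$f1, 0)
})

test_that("an empty prediction scores zero precision by convention", {
  ev <- evaluate_assignment(
    as_assignment(list(q1 = "a", q2 = "b")),
    as_assignment(list(q1 = "a"))   # q2 predicts nothing
  )
  terms <- tidy(ev)
  expect_equal(terms$precision[terms$question_id == "q2"], 0)
  expect_equal(terms$recall[terms$question_id == "q2"], 0)
  expect_error(evaluate_assignment(
    tibble::tibble(question_id = character(), topic = character()),
    as_assignment(list(q = "a"))
  ), "no examples")
})

test_that("swapping reference and prediction swaps P and R, keeps F1", {
  set.seed(21)
  labels <- letters[1:8]
  for (rep in 1:20) {
    y <- lapply(1:6, function(i) sample(labels, sample(1:4, 1)))
    z <- lapply(1:6, function(i) sample(labels, sample(1:4, 1)))
    names(y) <- names(z) <- paste0("q", 1:6)
    fwd <- evaluate_assignment(as_assignment(y), as_assignment(z))
    rev <- evaluate_assignment(as_assignment(z), as_assignment(y))
    expect_equal(fwd$example_based$precision, rev$example_based$recall)
    expect_equal(fwd$example_based$recall, rev$example_based$precision)
    expect_equal(fwd$example_based$f1, rev$example_based$f1)
    expect_equal(fwd$traditional$f1, rev$traditional$f1)
    # all rates within [0,1]; per-example F1 between its P and R terms
    terms <- tidy(fwd)
    expect_true(all(terms$precision >= 0 & terms$precision <= 1))
    expect_true(all(terms$recall >= 0 & terms$recall <= 1))
    expect_true(all(
      terms$f1 >= pmin(terms$precision, terms$recall) - 1e-12 &
        terms$f1 <= pmax(terms$precision, terms$recall) + 1e-12
    ))
  }
})

test_that("macro recall equals micro recall under uniform label counts", {
  set.seed(8)
  y <- lapply(1:10, function(i) sample(letters[1:10], 3))  # |Y_i| = 3 all
  names(y) <- paste0("q", 1:10)
  z <- lapply(y, function(s) {
    unique(c(sample(s, sample(0:3, 1)), sample(letters[11:15], 1)))
  })
  ev <- evaluate_assignment(as_assignment(y), as_assignment(z))
  expect_equal(ev$example_based$recall, ev$traditional$recall)
})

test_that("exclusion lists drop questions before any computation", {
  ref <- as_assignment(list(q1 = "a", q2 = "b", junk = "c"))
  pred <- as_assignment(list(q1 = "a", q2 = "x", junk = "y"))
  ev <- evaluate_assignment(ref, pred, exclude = "junk")
  expect_equal(ev$m, 2L)
  expect_false("junk" %in% tidy(ev)$question_id)
})

test_that("outcome counts mirror the micro confusion counts", {
  ex <- example_fixture("eval_examples")
  out <- count_assignment_outcomes(ex$reference, ex$predicted)
  tr <- evaluate_assignment(ex$reference, ex$predicted)$traditional
  expect_equal(out$correct, tr$tp)
  expect_equal(out$wrong, tr$fp)
  expect_equal(out$missing, tr$fn)
  same <- count_assignment_outcomes(ex$reference, ex$reference)
  expect_equal(same$correct, nrow(ex$reference))
  expect_equal(same$wrong + same$missing, 0L)
})

test_that("pairwise agreement is the example-based F1 over shared ids", {
  a <- as_assignment(list(q1 = c("a", "b"), q2 = "c"))
  b <- as_assignment(list(q1 = "a", q2 = "c"))
  iaa <- pairwise_iaa(list(A1 = a, A2 = b))
  expect_equal(iaa$f1, mean(c(2 / 3, 1)))
  # identical annotators agree perfectly
  expect_equal(pairwise_iaa(list(x = a, y = a))$f1, 1)
  # three annotators: mean over the three pairs
  c3 <- as_assignment(list(q1 = "b", q2 = "c"))
  iaa3 <- pairwise_iaa(list(A1 = a, A2 = b, A3 = c3))
  expect_equal(nrow(iaa3), 3L)
  expect_equal(attr(iaa3, "mean_f1"), mean(iaa3$f1))
  # no shared examples is an error
  expect_error(
    pairwise_iaa(list(A1 = a, A2 = as_assignment(list(zz = "a")))),
    "share no examples"
  )
})

test_that("per-topic restriction evaluates the right example subsets", {
  ref <- as_assignment(list(q1 = c("a", "b"), q2 = "a", q3 = "c"))
  pred <- as_assignment(list(q1 = "a", q2 = c("a", "c"), q3 = "c"))
  per <- per_topic_metrics(ref, pred)
  row_a <- per[per$topic == "a", ]
  expect_equal(row_a$m, 2L)      # q1, q2 mention topic a
  row_c <- per[per$topic == "c", ]
  expect_equal(row_c$m, 2L)      # q2 (predicted) and q3 (reference)
  only_ref <- per_topic_metrics(ref, pred, restrict = "reference")
  expect_equal(only_ref$m[only_ref$topic == "c"], 1L)
})

test_that("tidy, glance and reports expose both metric families", {
  ex <- example_fixture("eval_examples")
  ev <- evaluate_assignment(ex$reference, ex$predicted)
  g <- glance(ev)
  expect_equal(g$m, 4L)
  expect_equal(g$precision, 0.875)
  expect_equal(g$micro_precision, 6 / 7)
  pj <- withr::local_tempfile(fileext = ".json")
  write_eval_report(ev, pj)
  rep <- jsonlite::fromJSON(pj)
  expect_equal(rep$example_based$recall, 0.775)
  expect_equal(nrow(rep$per_example), 4L)
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(ev, pt)
  expect_equal(readr::read_tsv(pt, show_col_types = FALSE)$f1,
               ev$example_based$f1)
})
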