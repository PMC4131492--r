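#' Evaluate a multi-label assignment against a reference standard
#'
#' Computes both metric families for multi-label topic assignment.
#'
#' Example-based metrics macro-average per-question terms: with
#' reference set Y and predicted set Z for each of m examples,
#' P = mean(|Y n Z| / |Z|), R = mean(|Y n Z| / |Y|) and
#' F1 = mean(2 |Y n Z| / (|Z| + |Y|)). They are designed so that a few
#' questions with unusually many labels cannot dominate the score.
#' Traditional (micro-averaged) metrics pool counts over all examples:
#' TP = sum |Y n Z|, FN = sum(|Y| - |Y n Z|), FP = sum(|Z| - |Y n Z|),
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R).
#'
#' Examples are the question ids of `reference`; every reference set
#' must be nonempty (drop non-informative questions *before* evaluating,
#' via `exclude`). A question with no predicted labels scores a
#' per-example precision of 0 by convention (documented; the reference
#' setting never evaluates empty predictions). A traditional rate with a
#' zero denominator is reported as `NaN`.
#'
#' @param reference Tibble `question_id`, `topic`: the reference
#'   standard label sets (Y).
#' @param predicted Tibble `question_id`, `topic`: the predicted label
#'   sets (Z). Ids absent here predict the empty set.
#' @param exclude Optional character vector of question ids to drop
#'   before computing anything.
#' @return An object of class `ml_eval`: list with `examples` (tibble
#'   of per-example terms), `example_based` (named list P/R/F1),
#'   `traditional` (named list tp/fn/fp/precision/recall/f1) and `m`
#'   (number of examples). Has [tidy()], [glance()] and `autoplot()`
#'   methods.
#' @examples
#' ref <- data.frame(question_id = c("q1", "q1", "q2"),
#'                   topic = c("a", "b", "a"))
#' pred <- data.frame(question_id = c("q1", "q2", "q2"),
#'                    topic = c("a", "a", "c"))
#' glance(evaluate_assignment(ref, pred))
#' @export
evaluate_assignment <- function(reference, predicted, exclude = NULL) {
  reference <- dplyr::distinct(tibble::as_tibble(reference)[c("question_id",
                                                              "topic")])
  predicted <- dplyr::distinct(tibble::as_tibble(predicted)[c("question_id",
                                                              "topic")])
  if (!is.null(exclude)) {
    reference <- reference[!reference$question_id %in% exclude, ]
    predicted <- predicted[!predicted$question_id %in% exclude, ]
  }
  ids <- unique(reference$question_id)
  if (length(ids) == 0) rlang::abort("no examples to evaluate")
  y <- split(reference$topic, factor(reference$question_id, levels = ids))
  z_raw <- predicted[predicted$question_id %in% ids, ]
  z <- split(z_raw$topic, factor(z_raw$question_id, levels = ids))
  n_y <- unname(lengths(y))
  n_z <- unname(lengths(z))
  n_tp <- unname(mapply(function(a, b) length(intersect(a, b)), y, z))
  examples <- tibble::tibble(
    question_id = ids,
    n_reference = as.integer(n_y),
    n_predicted = as.integer(n_z),
    n_correct = as.integer(n_tp),
    precision = ifelse(n_z == 0, ifelse(n_y == 0, 1, 0), n_tp / n_z),
    recall = n_tp / n_y,
    f1 = 2 * n_tp / (n_z + n_y)
  )
  tp <- sum(n_tp)
  fn <- sum(n_y - n_tp)
  fp <- sum(n_z - n_tp)
  prec <- if (tp + fp == 0) NaN else tp / (tp + fp)
  rec <- if (tp + fn == 0) NaN else tp / (tp + fn)
  f1 <- if (is.nan(prec) || is.nan(rec) || prec + rec == 0) {
    NaN
  } else {
    2 * prec * rec / (prec + rec)
  }
  structure(
    list(
      examples = examples,
      example_based = list(
        precision = mean(examples$precision),
        recall = mean(examples$recall),
        f1 = mean(examples$f1)
      ),
      traditional = list(
        tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
        precision = prec, recall = rec, f1 = f1
      ),
      m = length(ids)
    ),
    class = "ml_eval"
  )
}

#' @export
print.ml_eval <- function(x, digits = 3, ...) {
  cat(sprintf("<ml_eval> %d examples\n", x$m))
  cat(sprintf("  example-based: P %.*f  R %.*f  F1 %.*f\n",
              digits, x$example_based$precision,
              digits, x$example_based$recall,
              digits, x$example_based$f1))
  cat(sprintf("  traditional:   TP %d  FN %d  FP %d  P %.*f  R %.*f  F1 %.*f\n",
              x$traditional$tp, x$traditional$fn, x$traditional$fp,
              digits, x$traditional$precision,
              digits, x$traditional$recall,
              digits, x$traditional$f1))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-example evaluation terms
#'
#' @param x An `ml_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per example: label-set sizes, overlap and
#'   the per-example precision/recall/F1 terms.
#' @export
tidy.ml_eval <- function(x, ...) {
  x$examples
}

#' One-row summary of an evaluation
#'
#' @param x An `ml_eval` object.
#' @param ... Unused.
#' @return One-row tibble with the example-based and traditional
#'   metrics.
#' @export
glance.ml_eval <- function(x, ...) {
  tibble::tibble(
    m = x$m,
    precision = x$example_based$precision,
    recall = x$example_based$recall,
    f1 = x$example_based$f1,
    tp = x$traditional$tp,
    fn = x$traditional$fn,
    fp = x$traditional$fp,
    micro_precision = x$traditional$precision,
    micro_recall = x$traditional$recall,
    micro_f1 = x$traditional$f1
  )
}

#' Correct / wrong / missing label counts
#'
#' Corpus-level outcome counts of an assignment against a reference:
#' correct = sum |Y n Z|, wrong = sum |Z \ Y|, missing = sum |Y \ Z|.
#'
#' @inheritParams evaluate_assignment
#' @return One-row tibble `correct`, `wrong`, `missing`.
#' @export
count_assignment_outcomes <- function(reference, predicted, exclude = NULL) {
  ev <- evaluate_assignment(reference, predicted, exclude = exclude)
  tibble::tibble(
    correct = ev$traditional$tp,
    wrong = ev$traditional$fp,
    missing = ev$traditional$fn
  )
}

#' Pairwise inter-annotator agreement by example-based F1
#'
#' Chance-corrected kappa statistics assume a single label per item, so
#' agreement between multi-label annotators is measured instead by
#' taking one annotator of each pair as the reference standard and
#' computing the example-based F1 of the other, restricted to the
#' example ids both annotated. F1 is symmetric in the pair, so the
#' orientation does not matter.
#'
#' @param annotations Named list of assignment tibbles (`question_id`,
#'   `topic`), one per annotator; at least two.
#' @return Tibble with one row per unordered pair: `annotator_a`,
#'   `annotator_b`, `n_shared`, `f1`; the mean pairwise F1 is attached
#'   as attribute `mean_f1` and reported by `glance()` via the
#'   `iaa_report` class.
#' @export
pairwise_iaa <- function(annotations) {
  stopifnot(is.list(annotations), length(annotations) >= 2)
  who <- names(annotations) %||% paste0("A", seq_along(annotations))
  combos <- utils::combn(seq_along(annotations), 2)
  rows <- lapply(seq_len(ncol(combos)), function(j) {
    i1 <- combos[1, j]; i2 <- combos[2, j]
    a <- annotations[[i1]]; b <- annotations[[i2]]
    shared <- intersect(unique(a$question_id), unique(b$question_id))
    if (length(shared) == 0) {
      rlang::abort(sprintf("annotators %s and %s share no examples",
                           who[i1], who[i2]))
    }
    ev <- evaluate_assignment(
      a[a$question_id %in% shared, ],
      b[b$question_id %in% shared, ]
    )
    tibble::tibble(annotator_a = who[i1], annotator_b = who[i2],
                   n_shared = length(shared), f1 = ev$example_based$f1)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_f1") <- mean(out$f1)
  class(out) <- c("iaa_report", class(out))
  out
}

#' @export
print.iaa_report <- function(x, ...) {
  NextMethod()
  cat(sprintf("mean pairwise F1: %.3f\n", attr(x, "mean_f1")))
  invisible(x)
}

#' Per-topic restriction of an evaluation
#'
#' Restricts the example set to questions whose reference or predicted
#' label set contains the topic, then computes example-based metrics for
#' each topic. The restriction rule is configurable because per-topic
#' breakdowns of multi-label metrics have no single canonical choice.
#'
#' @inheritParams evaluate_assignment
#' @param topics Topics to report; default all appearing in either set.
#' @param restrict One of `"either"` (reference or prediction contains
#'   the topic), `"reference"`, or `"predicted"`.
#' @return Tibble with one row per topic: `topic`, `m`, `precision`,
#'   `recall`, `f1`.
#' @export
per_topic_metrics <- function(reference, predicted,
                              topics = NULL, restrict = c("either",
                                                          "reference",
                                                          "predicted"),
                              exclude = NULL) {
  restrict <- match.arg(restrict)
  reference <- dplyr::distinct(tibble::as_tibble(reference))
  predicted <- dplyr::distinct(tibble::as_tibble(predicted))
  topics <- topics %||% sort(unique(c(reference$topic, predicted$topic)))
  rows <- lapply(topics, function(tp) {
    in_ref <- unique(reference$question_id[reference$topic == tp])
    in_pred <- unique(predicted$question_id[predicted$topic == tp])
    ids <- switch(restrict,
      either = union(in_ref, in_pred),
      reference = in_ref,
      predicted = in_pred
    )
    ids <- intersect(ids, unique(reference$question_id))  # Y must be nonempty
    if (!is.null(exclude)) ids <- setdiff(ids, exclude)
    if (length(ids) == 0) {
      return(tibble::tibble(topic = tp, m = 0L, precision = NA_real_,
                            recall = NA_real_, f1 = NA_real_))
    }
    ev <- evaluate_assignment(
      reference[reference$question_id %in% ids, ],
      predicted[predicted$question_id %in% ids, ]
    )
    tibble::tibble(topic = tp, m = ev$m,
                   precision = ev$example_based$precision,
                   recall = ev$example_based$recall,
                   f1 = ev$example_based$f1)
  })
  dplyr::bind_rows(rows)
}

#' Write an evaluation report
#'
#' Writes the global metrics and per-example terms as TSV (`.tsv`) or a
#' single JSON document (`.json`).
#'
#' @param ev An `ml_eval` object.
#' @param path Output path ending in `.tsv` or `.json`.
#' @export
write_eval_report <- function(ev, path) {
  stopifnot(inherits(ev, "ml_eval"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(
        example_based = ev$example_based,
        traditional = ev$traditional,
        m = ev$m,
        per_example = ev$examples
      ),
      path, auto_unbox = TRUE, digits = NA
    )
  } else if (ext == "tsv") {
    readr::write_tsv(glance(ev), path, progress = FALSE)
  } else {
    rlang::abort("report path must end in .tsv or .json")
  }
  invisible(path)
}
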