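#' Built-in worked-example fixtures
#'
#' Small, fully printed inputs used throughout the documentation and
#' tests: a six-topic inventory with key concepts, the 21-concept
#' expanded set for the topic "Pregnancy", annotated question subjects,
#' the topic-subject context they determine, an eight-question
#' subcontext of a CUI-question context together with the original
#' single-topic assignment of its questions, a tiny concept graph, and
#' four multi-label evaluation examples. These are the canonical small
#' inputs of the method and double as oracle material for the test
#' suite.
#'
#' Available names:
#' \describe{
#'   \item{`topics`}{Topic definitions: key CUIs plus expanded
#'     `cui_set` (the Pregnancy set of `pregnancy_cuis`; Pain
#'     Management additionally covers Abdominal Pain, a descendant of
#'     Pain).}
#'   \item{`pregnancy_cuis`}{The 21-concept expanded CUI-set for
#'     "Pregnancy" (tibble `cui`, `name`).}
#'   \item{`subjects`}{Subject annotations: tibble `question_id`,
#'     `subject`, `cui` (one row per annotated concept).}
#'   \item{`topic_subject_context`}{The [formal_context()] determined
#'     by `topics` and `subjects` (11 incidences).}
#'   \item{`cui_question_context`}{The eight-question, three-concept
#'     subcontext of a CUI-question context (18 incidences).}
#'   \item{`original_topics`}{Original single-topic assignment of the
#'     eight questions (tibble `question_id`, `topic`).}
#'   \item{`concept_graph`}{Synonym/descendant edges behind the
#'     expanded sets in `topics`.}
#'   \item{`eval_examples`}{Four multi-label examples: list with
#'     `reference` and `predicted` assignment tibbles.}
#' }
#'
#' @param name One of the fixture names above.
#' @return The fixture object (see above).
#' @examples
#' ctx <- example_fixture("cui_question_context")
#' derive_objects(ctx, c("C0025874", "C0439531"))
#' @export
example_fixture <- function(name) {
  switch(
    name,
    topics = fixture_topics(),
    pregnancy_cuis = fixture_pregnancy_cuis(),
    subjects = fixture_subjects(),
    topic_subject_context = fixture_topic_subject_context(),
    cui_question_context = fixture_cui_question_context(),
    original_topics = fixture_original_topics(),
    concept_graph = fixture_concept_graph(),
    eval_examples = fixture_eval_examples(),
    rlang::abort(paste0("unknown fixture: ", name))
  )
}

fixture_topics <- function() {
  key <- list(
    Anesthesia = c("C0278134", "C0002915", "C0002903"),
    Asthma = c("C0004096", "C2984299"),
    `Breast Feeding` = c("C0006147", "C1623040"),
    `Pain Management` = c("C0002766", "C0030193"),
    `Pharmacy and Medications` = c("C0031322", "C0013227", "C0802604"),
    Pregnancy = c("C0032961", "C0553641", "C0549206")
  )
  set <- key
  # Abdominal Pain is a descendant of Pain
  set[["Pain Management"]] <- c(set[["Pain Management"]], "C0000737")
  set[["Pregnancy"]] <- unique(c(set[["Pregnancy"]],
                                 fixture_pregnancy_cuis()$cui))
  topic_definitions(tibble::tibble(
    topic = names(key),
    key_cuis = unname(key),
    cui_set = unname(set)
  ))
}

fixture_pregnancy_cuis <- function() {
  tibble::tribble(
    ~cui, ~name,
    "C0032961", "Pregnancy",
    "C0553641", "Pregnant",
    "C0585066", "Mother currently breast-feeding",
    "C0041747", "Unplanned pregnancy",
    "C0232989", "Normal pregnancy",
    "C0404831", "Multigravida",
    "C0549206", "Patient currently pregnant",
    "C0032995", "Unwanted pregnancy",
    "C1291689", "Number of pregnancies, currently pregnant",
    "C0242786", "High-Risk Pregnancy",
    "C0425984", "Pregnant - on history",
    "C0425983", "Pregnant - on abdominal palpation",
    "C0425986", "Pregnant - blood test confirms",
    "C0425985", "Pregnant - V.E. confirms",
    "C0149973", "Intrauterine pregnancy",
    "C0425987", "Pregnant - urine test confirms",
    "C0232993", "Extrachorial pregnancy",
    "C0232992", "Extra-amniotic pregnancy",
    "C0232990", "Precocious pregnancy",
    "C0404842", "Surrogate pregnancy",
    "C2586154", "Intends to continue pregnancy"
  )
}

fixture_subjects <- function() {
  tibble::tribble(
    ~question_id, ~cui,
    "Safety of general anesthesia", "C1705187",
    "Safety of general anesthesia", "C0002915",
    "Breast feeding and asthma medications", "C1623040",
    "Breast feeding and asthma medications", "C0004096",
    "Breast feeding and asthma medications", "C0013227",
    "Asthma and pregnancy", "C0004096",
    "Asthma and pregnancy", "C0032961",
    "Hemorrhoids accompanied by abdominal pain", "C0019112",
    "Hemorrhoids accompanied by abdominal pain", "C0000737",
    "Breastfeeding and getting pregnant", "C0006147",
    "Breastfeeding and getting pregnant", "C0549206",
    "Pregnancy while on TB Medications", "C0032961",
    "Pregnancy while on TB Medications", "C0802604"
  )
}

fixture_topic_subject_context <- function() {
  inc <- tibble::tribble(
    ~object, ~attribute,
    "Safety of general anesthesia", "Anesthesia",
    "Breast feeding and asthma medications", "Asthma",
    "Breast feeding and asthma medications", "Breast Feeding",
    "Breast feeding and asthma medications", "Pharmacy and Medications",
    "Asthma and pregnancy", "Asthma",
    "Asthma and pregnancy", "Pregnancy",
    "Hemorrhoids accompanied by abdominal pain", "Pain Management",
    "Breastfeeding and getting pregnant", "Breast Feeding",
    "Breastfeeding and getting pregnant", "Pregnancy",
    "Pregnancy while on TB Medications", "Pharmacy and Medications",
    "Pregnancy while on TB Medications", "Pregnancy"
  )
  formal_context(inc,
                 objects = unique(fixture_subjects()$question_id),
                 attributes = fixture_topics()$topic)
}

fixture_cui_question_context <- function() {
  # C0232908 "conceived", C0025874 "Metrorrhagia", C0439531 "period"
  sets <- list(
    Q1 = c("C0025874", "C0439531"),
    Q2 = c("C0232908", "C0025874"),
    Q3 = c("C0232908", "C0025874"),
    Q4 = c("C0232908", "C0025874", "C0439531"),
    Q5 = c("C0025874", "C0439531"),
    Q6 = c("C0025874", "C0439531"),
    Q7 = c("C0232908", "C0025874", "C0439531"),
    Q8 = c("C0025874", "C0439531")
  )
  formal_context(
    data.frame(
      object = rep(names(sets), lengths(sets)),
      attribute = unlist(sets, use.names = FALSE)
    ),
    objects = names(sets),
    attributes = c("C0232908", "C0025874", "C0439531")
  )
}

fixture_original_topics <- function() {
  tibble::tribble(
    ~question_id, ~topic,
    "Q1", "Gynecology",
    "Q2", "Pregnancy",
    "Q3", "Pregnancy",
    "Q4", "Pregnancy",
    "Q5", "Gynecology",
    "Q6", "Infertility",
    "Q7", "Women's Health",
    "Q8", "Gynecology"
  )
}

fixture_concept_graph <- function() {
  tibble::tribble(
    ~cui_a, ~relation, ~cui_b,
    "C0000737", "child_of", "C0030193",   # Abdominal Pain under Pain
    "C0553641", "synonym", "C0032961",    # Pregnant ~ Pregnancy
    "C0549206", "child_of", "C0032961"    # Patient currently pregnant
  )
}

fixture_eval_examples <- function() {
  ref <- list(
    x1 = c("a", "b"),
    x2 = c("a", "c"),
    x3 = "d",
    x4 = c("a", "b", "c", "d", "e", "f", "g", "h", "k", "l")
  )
  pred <- list(
    x1 = c("a", "b"),
    x2 = c("a", "c"),
    x3 = "d",
    x4 = c("a", "s")
  )
  to_tbl <- function(l) {
    tibble::tibble(
      question_id = rep(names(l), lengths(l)),
      topic = unlist(l, use.names = FALSE)
    )
  }
  list(reference = to_tbl(ref), predicted = to_tbl(pred))
}
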