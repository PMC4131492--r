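#' Pipeline configuration
#'
#' Centralizes every tunable of the assignment pipeline with its
#' default: `k` concepts kept per question by TF-IDF (5), the minimum
#' term-strength index (2), the minimum votes for a topic to win in the
#' voting scheme (2), and the excluded semantic types (the four in
#' [default_excluded_types()]). Paths point at the input files; `NULL`
#' paths disable the corresponding optional input (vocabulary, concept
#' graph, rules). Unknown keys are rejected so typos in config files
#' fail loudly.
#'
#' @param corpus,lexicon,topics,graph,vocabulary,rules Optional file
#'   paths.
#' @param k Concepts kept per question by TF-IDF.
#' @param min_term_strength Minimum term-strength index.
#' @param min_votes Minimum votes in the voting scheme.
#' @param excluded_semantic_types Semantic types removed in filtering
#'   step 1.
#' @param seed Integer seed for any randomized step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus = NULL, lexicon = NULL, topics = NULL,
                            graph = NULL, vocabulary = NULL, rules = NULL,
                            k = 5, min_term_strength = 2, min_votes = 2,
                            excluded_semantic_types = default_excluded_types(),
                            seed = NULL) {
  stopifnot(k >= 1, min_term_strength >= 0, min_votes >= 1)
  structure(
    list(
      corpus = corpus, lexicon = lexicon, topics = topics, graph = graph,
      vocabulary = vocabulary, rules = rules,
      k = as.integer(k),
      min_term_strength = as.integer(min_term_strength),
      min_votes = as.integer(min_votes),
      excluded_semantic_types = excluded_semantic_types,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()]; unknown keys are an error.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config key(s) in ", path, ": ",
                        paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(v)) "<unset>" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
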