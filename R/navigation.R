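#' Conjunctive category selection over the category-topic context
#'
#' The first tier of the chained-context navigation engine. Selecting a
#' set of categories narrows the visible topics to the *intersection* of
#' the categories' extents (conjunctive drill-down, not a union). The
#' implied categories are the closure of the selection: categories every
#' visible topic also carries, which follow logically from the selection
#' and whose addition cannot change the visible topics. Categories whose
#' addition would empty the extent are reported as unavailable, the
#' usual affordance for greying out dead-end facets.
#'
#' @param ctx Category-topic [formal_context()] (topics as objects,
#'   categories as attributes).
#' @param selected Character vector of selected categories (may be
#'   empty: all topics visible).
#' @return A list of class `nav_state`: `selected`, `implied`
#'   (closure, always a superset of `selected`), `extent` (visible
#'   topics) and `unavailable` (categories that would empty the
#'   extent).
#' @export
select_categories <- function(ctx, selected = character()) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- check_attrs(ctx, selected)
  ext <- derive_objects_idx(ctx, idx)
  implied <- close_attributes_idx(ctx, idx)
  remaining <- setdiff(seq_along(ctx$attributes), implied)
  dead <- remaining[vapply(remaining, function(a) {
    length(intersect(ext, ctx$attr_objs[[a]])) == 0
  }, logical(1))]
  structure(
    list(
      selected = ctx$attributes[sort(idx)],
      implied = ctx$attributes[sort(implied)],
      extent = ctx$objects[sort(ext)],
      unavailable = ctx$attributes[sort(dead)]
    ),
    class = "nav_state"
  )
}

#' @export
print.nav_state <- function(x, ...) {
  cat("<nav_state>\n")
  cat("  selected:   ", paste(x$selected, collapse = ", "), "\n")
  cat("  implied:    ", paste(x$implied, collapse = ", "), "\n")
  cat(sprintf("  extent:      %d object(s)\n", length(x$extent)))
  cat("  unavailable:", paste(x$unavailable, collapse = ", "), "\n")
  invisible(x)
}

#' Conjunctive topic selection over the topic-question context
#'
#' The second navigation tier: the questions carrying *every* selected
#' topic.
#'
#' @param ctx Topic-question [formal_context()].
#' @param selected Character vector of selected topics.
#' @return Character vector of question ids.
#' @export
select_topics <- function(ctx, selected = character()) {
  derive_objects(ctx, selected)
}

#' @export
format.nav_state <- function(x, ...) {
  jsonlite::toJSON(unclass(x), auto_unbox = FALSE)
}
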