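#' Formal contexts
#'
#' A formal context is a triple (O, A, R): a set of objects O, a set of
#' attributes A, and a binary incidence relation R between them. It is the
#' universal substrate of Formal Concept Analysis (FCA): every derived
#' structure here -- extents, intents, closures, concepts, the concept
#' lattice -- is computed from a context. In this package objects are
#' typically questions (or question subjects, or health topics) and
#' attributes are concept identifiers (CUIs), topics, or categories.
#'
#' `formal_context()` builds a context from a two-column data frame of
#' incidence pairs. Objects or attributes with no incidence can be declared
#' through `objects` / `attributes`, which also fix the roster order used
#' for deterministic output. Identifier comparison is exact, case-sensitive
#' string equality.
#'
#' @param incidence Data frame whose first two columns are object and
#'   attribute identifiers (one row per incidence pair), or `NULL` for an
#'   incidence-free context. Extra columns are ignored. Duplicated pairs
#'   are collapsed.
#' @param objects,attributes Optional character vectors giving the full
#'   roster (and order) of objects/attributes. Defaults to first-appearance
#'   order in `incidence`. Must contain every identifier used in
#'   `incidence` and no duplicates.
#' @return An object of class `formal_context` with fields `objects`,
#'   `attributes`, `pairs` (a tibble of incidence pairs), and precomputed
#'   adjacency (per-object attribute indices and per-attribute object
#'   indices) so derivation is fast on sparse contexts.
#' @examples
#' ctx <- formal_context(
#'   data.frame(object = c("q1", "q1", "q2"),
#'              attribute = c("a", "b", "a"))
#' )
#' derive_objects(ctx, "a")
#' @export
formal_context <- function(incidence = NULL, objects = NULL, attributes = NULL) {
  if (is.null(incidence)) {
    pairs <- tibble::tibble(object = character(), attribute = character())
  } else {
    stopifnot(is.data.frame(incidence), ncol(incidence) >= 2)
    pairs <- tibble::tibble(
      object = as.character(incidence[[1]]),
      attribute = as.character(incidence[[2]])
    )
    pairs <- dplyr::distinct(pairs)
  }
  if (is.null(objects)) objects <- unique(pairs$object)
  if (is.null(attributes)) attributes <- unique(pairs$attribute)
  objects <- as.character(objects)
  attributes <- as.character(attributes)
  if (anyDuplicated(objects)) {
    rlang::abort("duplicate object identifiers in context roster")
  }
  if (anyDuplicated(attributes)) {
    rlang::abort("duplicate attribute identifiers in context roster")
  }
  oi <- match(pairs$object, objects)
  ai <- match(pairs$attribute, attributes)
  if (anyNA(oi)) {
    rlang::abort(paste0(
      "incidence references undeclared object(s): ",
      paste(unique(pairs$object[is.na(oi)]), collapse = ", ")
    ))
  }
  if (anyNA(ai)) {
    rlang::abort(paste0(
      "incidence references undeclared attribute(s): ",
      paste(unique(pairs$attribute[is.na(ai)]), collapse = ", ")
    ))
  }
  obj_attrs <- lapply(seq_along(objects), function(i) integer())
  attr_objs <- lapply(seq_along(attributes), function(i) integer())
  if (nrow(pairs) > 0) {
    oa <- split(ai, factor(oi, levels = seq_along(objects)))
    ao <- split(oi, factor(ai, levels = seq_along(attributes)))
    obj_attrs <- lapply(oa, function(x) sort(unique(x)))
    attr_objs <- lapply(ao, function(x) sort(unique(x)))
  }
  structure(
    list(
      objects = objects,
      attributes = attributes,
      pairs = pairs,
      obj_attrs = obj_attrs,
      attr_objs = attr_objs
    ),
    class = "formal_context"
  )
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf(
    "<formal_context> %d objects x %d attributes, %d incidences\n",
    length(x$objects), length(x$attributes), nrow(x$pairs)
  ))
  invisible(x)
}

#' @export
dim.formal_context <- function(x) {
  c(length(x$objects), length(x$attributes))
}

#' Convert a formal context to a logical incidence matrix
#'
#' @param ctx A [formal_context()].
#' @return A logical matrix with objects as rows and attributes as columns.
#' @export
fc_matrix <- function(ctx) {
  stopifnot(inherits(ctx, "formal_context"))
  m <- matrix(FALSE, length(ctx$objects), length(ctx$attributes),
              dimnames = list(ctx$objects, ctx$attributes))
  if (nrow(ctx$pairs) > 0) {
    m[cbind(match(ctx$pairs$object, ctx$objects),
            match(ctx$pairs$attribute, ctx$attributes))] <- TRUE
  }
  m
}

#' Build a formal context from a logical (or 0/1) matrix
#'
#' @param m Matrix with objects as rows and attributes as columns; row and
#'   column names supply identifiers (defaults are generated).
#' @return A [formal_context()].
#' @export
fc_from_matrix <- function(m) {
  m <- m != 0
  objs <- rownames(m) %||% paste0("o", seq_len(nrow(m)))
  attrs <- colnames(m) %||% paste0("a", seq_len(ncol(m)))
  idx <- which(m, arr.ind = TRUE)
  formal_context(
    data.frame(object = objs[idx[, 1]], attribute = attrs[idx[, 2]]),
    objects = objs, attributes = attrs
  )
}

check_attrs <- function(ctx, attrs) {
  attrs <- as.character(attrs)
  unknown <- setdiff(attrs, ctx$attributes)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown attribute(s): ", paste(unknown, collapse = ", ")))
  }
  match(unique(attrs), ctx$attributes)
}

check_objs <- function(ctx, objs) {
  objs <- as.character(objs)
  unknown <- setdiff(objs, ctx$objects)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown object(s): ", paste(unknown, collapse = ", ")))
  }
  match(unique(objs), ctx$objects)
}

# index-level derivations; the exported functions wrap these
derive_objects_idx <- function(ctx, attr_idx) {
  if (length(attr_idx) == 0) return(seq_along(ctx$objects))
  Reduce(intersect, ctx$attr_objs[attr_idx])
}

derive_attributes_idx <- function(ctx, obj_idx) {
  if (length(obj_idx) == 0) return(seq_along(ctx$attributes))
  Reduce(intersect, ctx$obj_attrs[obj_idx])
}

close_attributes_idx <- function(ctx, attr_idx) {
  derive_attributes_idx(ctx, derive_objects_idx(ctx, attr_idx))
}

#' Galois derivation: objects common to a set of attributes
#'
#' Returns the extent of an attribute set: every object incident with all
#' of the given attributes. The empty attribute set derives all objects
#' (an empty conjunction holds vacuously).
#'
#' @param ctx A [formal_context()].
#' @param attrs Character vector of attribute identifiers (a set).
#' @return Character vector of object identifiers, in roster order.
#' @export
derive_objects <- function(ctx, attrs = character()) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- check_attrs(ctx, attrs)
  ctx$objects[sort(derive_objects_idx(ctx, idx))]
}

#' Galois derivation: attributes common to a set of objects
#'
#' The dual of [derive_objects()]: every attribute incident with all of
#' the given objects. The empty object set derives all attributes.
#'
#' @inheritParams derive_objects
#' @param objs Character vector of object identifiers (a set).
#' @return Character vector of attribute identifiers, in roster order.
#' @export
derive_attributes <- function(ctx, objs = character()) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- check_objs(ctx, objs)
  ctx$attributes[sort(derive_attributes_idx(ctx, idx))]
}

#' Attribute closure
#'
#' Computes `attrs''` -- the attributes shared by every object that has all
#' attributes in `attrs`. The closure is a superset of `attrs` and is
#' idempotent; attributes it adds are implicants of the selection (they
#' follow from it in this context).
#'
#' @inheritParams derive_objects
#' @return Character vector of attribute identifiers (the closed set), in
#'   roster order.
#' @export
close_attributes <- function(ctx, attrs = character()) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- check_attrs(ctx, attrs)
  ctx$attributes[sort(close_attributes_idx(ctx, idx))]
}

#' Formal concept generated by an attribute set
#'
#' The formal concept determined by `attrs`: its extent is
#' `derive_objects(ctx, attrs)` and its intent the closure `attrs''`.
#' The pair satisfies extent' = intent and intent' = extent.
#'
#' @inheritParams derive_objects
#' @return A list of class `formal_concept` with character fields `extent`
#'   and `intent`.
#' @export
concept_of <- function(ctx, attrs = character()) {
  stopifnot(inherits(ctx, "formal_context"))
  idx <- check_attrs(ctx, attrs)
  ext <- derive_objects_idx(ctx, idx)
  int <- derive_attributes_idx(ctx, ext)
  structure(
    list(extent = ctx$objects[sort(ext)], intent = ctx$attributes[sort(int)]),
    class = "formal_concept"
  )
}

#' @export
print.formal_concept <- function(x, ...) {
  cat("<formal_concept>\n")
  cat("  extent:", paste(x$extent, collapse = ", "), "\n")
  cat("  intent:", paste(x$intent, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate all formal concepts of a context
#'
#' Lists every formal concept exactly once using Ganter's NextClosure
#' algorithm: intents are generated in lectic order over the attribute
#' roster, which is deterministic and needs no duplicate bookkeeping.
#' The number of concepts can be exponential in the context size in the
#' worst case; contexts in this pipeline are sparse and small in one
#' dimension, which keeps enumeration practical.
#'
#' @param ctx A [formal_context()].
#' @return A tibble with list-columns `extent` and `intent` (character
#'   vectors, roster order) and integer columns `n_extent`, `n_intent`.
#'   Rows are in lectic order of the intent.
#' @export
enumerate_concepts <- function(ctx) {
  stopifnot(inherits(ctx, "formal_context"))
  m <- length(ctx$attributes)
  intents <- list()
  a <- sort(close_attributes_idx(ctx, integer()))
  intents[[1]] <- a
  if (m > 0) {
    repeat {
      if (length(a) == m) break
      nxt <- NULL
      for (i in rev(seq_len(m))) {
        if (i %in% a) next
        cand <- sort(close_attributes_idx(ctx, c(a[a < i], i)))
        added <- setdiff(cand, c(a[a < i], i))
        if (all(added > i)) {  # lectic successor test
          nxt <- cand
          break
        }
      }
      if (is.null(nxt)) break
      a <- nxt
      intents[[length(intents) + 1]] <- a
    }
  }
  extents <- lapply(intents, function(int) sort(derive_objects_idx(ctx, int)))
  tibble::tibble(
    extent = lapply(extents, function(e) ctx$objects[e]),
    intent = lapply(intents, function(i) ctx$attributes[i]),
    n_extent = lengths(extents),
    n_intent = lengths(intents)
  )
}
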