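#' Read and write formal contexts in Burmeister CXT format
#'
#' The CXT layout used by the FCA community (ConExp and relatives): a
#' header line `B`, a blank line, the object count, the attribute count,
#' a blank line, the object names one per line, the attribute names one
#' per line, then one row per object of `.`/`X` incidence characters.
#' `write_cxt()` followed by `read_cxt()` round-trips bit-exactly.
#'
#' @param path File path.
#' @return `read_cxt()` returns a [formal_context()]; `write_cxt()`
#'   returns `path` invisibly.
#' @export
read_cxt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5 || lines[1] != "B") {
    rlang::abort(paste0("not a CXT file (missing 'B' header): ", path))
  }
  n_obj <- as.integer(lines[3])
  n_attr <- as.integer(lines[4])
  if (is.na(n_obj) || is.na(n_attr)) {
    rlang::abort(paste0("malformed CXT counts at lines 3-4: ", path))
  }
  objs <- lines[5 + seq_len(n_obj)]
  attrs <- lines[5 + n_obj + seq_len(n_attr)]
  rows <- lines[5 + n_obj + n_attr + seq_len(n_obj)]
  bad <- which(nchar(rows) != n_attr)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "malformed CXT incidence row %d (expected %d cells): %s",
      bad[1], n_attr, path
    ))
  }
  if (n_obj > 0 && n_attr > 0) {
    cells <- matrix(
      unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
      nrow = n_obj, byrow = TRUE
    )
    m <- cells == "X"
    rownames(m) <- objs
    colnames(m) <- attrs
    fc_from_matrix(m)
  } else {
    formal_context(NULL, objects = objs, attributes = attrs)
  }
}

#' @rdname read_cxt
#' @param ctx A [formal_context()].
#' @export
write_cxt <- function(ctx, path) {
  stopifnot(inherits(ctx, "formal_context"))
  m <- fc_matrix(ctx)
  rows <- apply(m, 1, function(r) paste(ifelse(r, "X", "."), collapse = ""))
  if (length(ctx$objects) == 0) rows <- character()
  lines <- c(
    "B", "",
    length(ctx$objects), length(ctx$attributes), "",
    ctx$objects, ctx$attributes, rows
  )
  writeLines(as.character(lines), path)
  invisible(path)
}

#' Read and write formal contexts as CSV
#'
#' CSV dialect for inspection in spreadsheets: first column holds object
#' identifiers (header `object`), remaining header cells are attribute
#' identifiers, cells are 0/1.
#'
#' @param path File path.
#' @return `read_context_csv()` returns a [formal_context()].
#' @export
read_context_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_integer(),
    object = readr::col_character()
  ), progress = FALSE)
  attrs <- setdiff(names(df), "object")
  m <- as.matrix(df[attrs])
  rownames(m) <- df$object
  if (nrow(df) == 0) {
    formal_context(NULL, objects = character(), attributes = attrs)
  } else {
    fc_from_matrix(m)
  }
}

#' @rdname read_context_csv
#' @param ctx A [formal_context()].
#' @export
write_context_csv <- function(ctx, path) {
  stopifnot(inherits(ctx, "formal_context"))
  m <- fc_matrix(ctx)
  df <- tibble::as_tibble(m * 1L)
  df <- dplyr::bind_cols(tibble::tibble(object = ctx$objects), df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read or write a context by file extension
#'
#' Dispatches to the CXT reader/writer for `.cxt` files and the CSV
#' dialect for `.csv` files.
#'
#' @param path File path ending in `.cxt` or `.csv`.
#' @return A [formal_context()] (reader) or `path` invisibly (writer).
#' @export
read_context <- function(path) {
  switch(tolower(tools::file_ext(path)),
    cxt = read_cxt(path),
    csv = read_context_csv(path),
    rlang::abort(paste0("unknown context format (want .cxt or .csv): ", path))
  )
}

#' @rdname read_context
#' @param ctx A [formal_context()].
#' @export
write_context <- function(ctx, path) {
  switch(tolower(tools::file_ext(path)),
    cxt = write_cxt(ctx, path),
    csv = write_context_csv(ctx, path),
    rlang::abort(paste0("unknown context format (want .cxt or .csv): ", path))
  )
}

#' Export a concept lattice as Graphviz DOT
#'
#' Writes the cover (Hasse) relation of the concepts of `ctx` as a DOT
#' digraph for external rendering; nodes are labelled by intent with the
#' extent size. Drawing itself is out of scope here.
#'
#' @param ctx A [formal_context()].
#' @param path Optional output path; with `NULL` nothing is written.
#' @return The DOT source as a character vector (invisibly when `path`
#'   is given).
#' @export
lattice_dot <- function(ctx, path = NULL) {
  conc <- enumerate_concepts(ctx)
  n <- nrow(conc)
  # order by extent size so covers point from more general to more specific
  sub <- function(i, j) all(conc$extent[[i]] %in% conc$extent[[j]])
  edges <- character()
  if (n > 1) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || !sub(i, j)) next
        # cover: no k strictly between
        between <- FALSE
        for (k in seq_len(n)) {
          if (k == i || k == j) next
          if (sub(i, k) && sub(k, j) &&
              !setequal(conc$extent[[k]], conc$extent[[i]]) &&
              !setequal(conc$extent[[k]], conc$extent[[j]])) {
            between <- TRUE
            break
          }
        }
        if (!between) edges <- c(edges, sprintf("  n%d -> n%d;", j, i))
      }
    }
  }
  labels <- vapply(seq_len(n), function(i) {
    sprintf("  n%d [label=\"{%s}\\n|extent|=%d\"];", i,
            paste(conc$intent[[i]], collapse = ","), conc$n_extent[i])
  }, character(1))
  dot <- c("digraph lattice {", "  rankdir=BT;", labels, edges, "}")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
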