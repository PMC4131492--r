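# Independent oracles and random-input generators used across the suite.

# Random sparse formal context as a logical matrix.
random_context_matrix <- function(n_obj, n_attr, density = 0.4) {
  m <- matrix(stats::runif(n_obj * n_attr) < density, n_obj, n_attr)
  rownames(m) <- sprintf("o%02d", seq_len(n_obj))
  colnames(m) <- sprintf("a%02d", seq_len(n_attr))
  m
}

# Brute-force concept enumeration: close every attribute subset and keep
# the unique (extent, intent) pairs. Fully vectorised over the 2^m
# subsets so the property suites stay fast.
brute_concepts <- function(m) {
  n_obj <- nrow(m)
  n_attr <- ncol(m)
  nsub <- 2^n_attr
  subs <- vapply(
    0:(nsub - 1),
    function(x) as.integer(bitwAnd(bitwShiftR(x, 0:(n_attr - 1)), 1L)),
    integer(n_attr)
  )
  subs <- matrix(as.integer(subs), nrow = n_attr, ncol = nsub)
  mi <- matrix(as.integer(m), n_obj, n_attr)
  hit <- mi %*% subs                                  # n_obj x nsub
  ext <- sweep(hit, 2, colSums(subs), "==") * 1L      # extent indicators
  ihit <- t(mi) %*% ext                               # n_attr x nsub
  int <- sweep(ihit, 2, colSums(ext), "==") * 1L      # intent indicators
  key <- apply(rbind(ext, int), 2, paste, collapse = "")
  keep <- !duplicated(key)
  list(
    extents = lapply(which(keep), function(j) rownames(m)[ext[, j] == 1]),
    intents = lapply(which(keep), function(j) colnames(m)[int[, j] == 1])
  )
}

# Canonical string keys for a set of concepts, for set-equality checks.
concept_keys <- function(extents, intents) {
  sort(paste(
    vapply(extents, function(e) paste(sort(e), collapse = ","), ""),
    vapply(intents, function(i) paste(sort(i), collapse = ","), ""),
    sep = " | "
  ))
}

# Brute-force term strength: maximise j such that at least j counts are
# >= j, scanning every candidate j up to the profile length.
brute_term_strength <- function(counts) {
  k <- length(counts)
  if (k == 0) return(0L)
  best <- 0L
  for (j in seq_len(k)) {
    if (sum(counts >= j) >= j) best <- j
  }
  best
}

# Sorted-prefix characterisation: max{ j : N_(j) >= j } over counts
# sorted descending.
sorted_prefix_strength <- function(counts) {
  if (length(counts) == 0) return(0L)
  s <- sort(counts, decreasing = TRUE)
  ok <- which(s >= seq_along(s))
  if (length(ok) == 0) 0L else max(ok)
}

# Long assignment tibble from a named list of label vectors.
as_assignment <- function(sets) {
  tibble::tibble(
    question_id = rep(names(sets), lengths(sets)),
    topic = unlist(sets, use.names = FALSE)
  )
}

# Named list of label vectors from a long assignment tibble.
as_label_sets <- function(assignment) {
  lapply(
    split(assignment$topic, assignment$question_id),
    function(x) sort(unique(x))
  )
}
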