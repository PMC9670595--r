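#' All delete variants of a word
#'
#' Strings obtainable by deleting up to `d` characters, including the word
#' itself. This is the neighborhood the delete-only index precomputes for
#' every dictionary word, so that approximate lookup needs deletions only.
#'
#' @param word character scalar.
#' @param d maximum number of deletions (>= 0).
#' @return character vector of distinct variants.
#' @export
delete_variants <- function(word, d) {
  stopifnot(is.character(word), length(word) == 1L, d >= 0)
  out <- word
  frontier <- word
  for (step in seq_len(d)) {
    nxt <- unlist(lapply(frontier, function(w) {
      n <- nchar(w)
      if (n == 0L) return(character(0))
      vapply(seq_len(n), function(i) {
        paste0(substr(w, 1L, i - 1L), substr(w, i + 1L, n))
      }, character(1))
    }))
    frontier <- setdiff(unique(nxt), out)
    if (!length(frontier)) break
    out <- c(out, frontier)
  }
  out
}

#' Restricted Damerau-Levenshtein (optimal string alignment) distance
#'
#' Minimum number of single-character insertions, deletions, substitutions,
#' and adjacent transpositions converting `a` into `b`, with no substring
#' edited twice. Transposition counts 1 because swapped adjacent letters are
#' one of the injected typo types; plain Levenshtein would score them 2.
#'
#' @param a,b character scalars.
#' @return non-negative integer distance.
#' @export
damerau_levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      v <- min(d[i, j + 1L] + 1L,      # deletion
               d[i + 1L, j] + 1L,      # insertion
               d[i, j] + cost)         # substitution / match
      if (i > 1L && j > 1L && x[i] == y[j - 1L] && x[i - 1L] == y[j]) {
        v <- min(v, d[i - 1L, j - 1L] + 1L)  # adjacent transposition
      }
      d[i + 1L, j + 1L] <- v
    }
  }
  d[n + 1L, m + 1L]
}

#' Build the delete-neighborhood index over a dictionary
#'
#' Precomputes, for every dictionary word, all delete variants up to
#' `max_distance` (including the word itself) and maps each variant back to
#' the words that generate it. Lookup then intersects the query's own delete
#' variants with this map and verifies survivors with the exact distance.
#'
#' @param dict a `word_dictionary`.
#' @param max_distance maximum edit distance served by the index (1 or 2;
#'   default 2).
#' @return an object of class `delete_index`.
#' @export
build_index <- function(dict, max_distance = 2L) {
  stopifnot(inherits(dict, "word_dictionary"), max_distance %in% c(1L, 2L))
  vm <- new.env(parent = emptyenv(), size = max(29L, 4L * length(dict$entries)))
  for (w in names(dict$entries)) {
    for (v in delete_variants(w, max_distance)) {
      key <- paste0("k", v)  # avoid env name quirks for "" and duplicates
      vm[[key]] <- c(vm[[key]], w)
    }
  }
  structure(list(variant_map = vm, max_distance = as.integer(max_distance),
                 dictionary = dict),
            class = "delete_index")
}

#' @export
print.delete_index <- function(x, ...) {
  cat("<delete_index> ", length(x$dictionary$entries), " words, ",
      length(ls(x$variant_map, all.names = TRUE)), " delete variants, max_distance=",
      x$max_distance, "\n", sep = "")
  invisible(x)
}

#' Generate verified correction candidates for a query
#'
#' Returns exactly the dictionary words within `max_distance` restricted
#' Damerau-Levenshtein distance of the query. The delete-variant intersection
#' is a pre-filter only; every survivor is verified with
#' [damerau_levenshtein()], which removes the false positives the delete
#' trick admits for substitutions and transpositions. The query is case-folded
#' per the dictionary's policy; returned terms keep dictionary form.
#'
#' @param query non-empty character scalar.
#' @param index a `delete_index`.
#' @return data.frame with columns `term`, `distance`, `count`, sorted by
#'   distance ascending, count descending, then term; zero rows when nothing
#'   matches.
#' @export
generate_candidates <- function(query, index) {
  stopifnot(inherits(index, "delete_index"), is.character(query),
            length(query) == 1L, nzchar(query))
  q <- .apply_case(query, index$dictionary$case_policy)
  hits <- unique(unlist(lapply(delete_variants(q, index$max_distance),
                               function(v) index$variant_map[[paste0("k", v)]])))
  if (is.null(hits)) hits <- character(0)
  dist <- vapply(hits, function(w) damerau_levenshtein(q, w), numeric(1))
  keep <- dist <= index$max_distance
  out <- data.frame(term = hits[keep], distance = as.integer(dist[keep]),
                    count = as.integer(index$dictionary$entries[hits[keep]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, -out$count, out$term, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
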