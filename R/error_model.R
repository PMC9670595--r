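#' The four injected typo types
#'
#' @return character vector `c("INSERT", "DELETE", "REPLACE", "TRANSPOSE")`.
#' @export
error_types <- function() c("INSERT", "DELETE", "REPLACE", "TRANSPOSE")

.LETTER_POOL <- c(LETTERS, letters)

#' Enumerate all two-way splits of a word
#'
#' A word of n characters has n+1 splits, from `("", word)` to `(word, "")`,
#' in left-to-right order.
#'
#' @param word non-empty character scalar.
#' @return data.frame with columns `left`, `right` and n+1 rows.
#' @export
enumerate_splits <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (!nzchar(word)) stop("cannot split an empty word", call. = FALSE)
  n <- nchar(word)
  k <- 0:n
  data.frame(left = substr(rep(word, n + 1L), 1L, k),
             right = substr(rep(word, n + 1L), k + 1L, n),
             stringsAsFactors = FALSE)
}

#' Splits eligible for corruption
#'
#' Drops the two splits with an empty side, leaving n-1 pairs for a word of
#' n characters (none for a single-character word).
#'
#' @inheritParams enumerate_splits
#' @return data.frame with columns `left`, `right`.
#' @export
eligible_splits <- function(word) {
  s <- enumerate_splits(word)
  s[nzchar(s$left) & nzchar(s$right), , drop = FALSE]
}

#' Apply one corruption operator at a split
#'
#' Given a word split into non-empty `left` and `right` halves:
#' * INSERT places a random ASCII letter between the halves;
#' * DELETE removes the first character of `right`;
#' * REPLACE substitutes a random letter (always different) for the first
#'   character of `right`;
#' * TRANSPOSE swaps the first two characters of `right`.
#'
#' Every result is a true change at restricted Damerau-Levenshtein distance 1
#' from the original word. Randomness (letter draws) uses R's RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param left,right the two non-empty halves of the word.
#' @param error_type one of [error_types()].
#' @param letter optional letter for INSERT/REPLACE (drawn at random when
#'   `NULL`).
#' @return the corrupted word (character scalar).
#' @export
apply_error <- function(left, right, error_type, letter = NULL) {
  stopifnot(nzchar(left), nzchar(right))
  error_type <- match.arg(error_type, error_types())
  first <- substr(right, 1L, 1L)
  switch(error_type,
    INSERT = {
      if (is.null(letter)) letter <- sample(.LETTER_POOL, 1L)
      paste0(left, letter, right)
    },
    DELETE = paste0(left, substr(right, 2L, nchar(right))),
    REPLACE = {
      if (is.null(letter)) {
        letter <- sample(setdiff(.LETTER_POOL, first), 1L)
      } else if (identical(letter, first)) {
        stop("REPLACE letter must differ from the replaced character", call. = FALSE)
      }
      paste0(left, letter, substr(right, 2L, nchar(right)))
    },
    TRANSPOSE = {
      if (nchar(right) < 2L) {
        stop("TRANSPOSE needs at least two characters in the right half",
             call. = FALSE)
      }
      second <- substr(right, 2L, 2L)
      if (identical(first, second)) {
        stop("TRANSPOSE of equal adjacent characters is not a change",
             call. = FALSE)
      }
      paste0(left, second, first, substr(right, 3L, nchar(right)))
    })
}

#' Corrupt a single word with a random typo
#'
#' Draws an eligible split uniformly (for TRANSPOSE, among splits whose right
#' half has at least two characters) and applies the operator.
#'
#' @param word word of length >= 2 (>= 3 for TRANSPOSE).
#' @param error_type one of [error_types()].
#' @return list with `corrupted` and `split_point` (characters in the left half).
#' @export
corrupt_word <- function(word, error_type) {
  error_type <- match.arg(error_type, error_types())
  s <- eligible_splits(word)
  if (error_type == "TRANSPOSE") {
    s <- s[nchar(s$right) >= 2L &
             substr(s$right, 1L, 1L) != substr(s$right, 2L, 2L), , drop = FALSE]
  }
  if (!nrow(s)) stop("no eligible split in '", word, "' for ", error_type,
                     call. = FALSE)
  k <- if (nrow(s) == 1L) 1L else sample.int(nrow(s), 1L)
  list(corrupted = apply_error(s$left[k], s$right[k], error_type),
       split_point = nchar(s$left[k]))
}

.eligible_token <- function(tok) .is_word_token(tok) & nchar(tok) >= 2L

# A token can host a transposition iff some eligible split leaves two unequal
# characters at the head of its right half: an unequal adjacent pair at
# positions (i, i+1) with i >= 2. A 2-letter word never qualifies (its only
# eligible split leaves one character on the right).
.can_transpose <- function(tok) {
  n <- nchar(tok)
  if (n < 3L) return(FALSE)
  ch <- strsplit(tok, "", fixed = TRUE)[[1]]
  any(ch[2:(n - 1L)] != ch[3:n])
}

# Balanced type assignment: counts differ by at most one; TRANSPOSE goes only
# to tokens that can host one (type quota preserved by swapping assignments).
.assign_error_types <- function(tokens) {
  transposable <- vapply(tokens, .can_transpose, logical(1))
  n <- length(tokens)
  base <- n %/% 4L
  extra <- n %% 4L
  types <- rep(error_types(), base)
  if (extra > 0L) types <- c(types, sample(error_types(), extra))
  types <- sample(types, n)
  short <- which(!transposable & types == "TRANSPOSE")
  for (i in short) {
    swap <- which(transposable & types != "TRANSPOSE")
    if (!length(swap)) {
      stop("cannot balance error types: ", length(short),
           " TRANSPOSE corruption(s) have no token that can host one",
           call. = FALSE)
    }
    j <- swap[if (length(swap) == 1L) 1L else sample.int(length(swap), 1L)]
    tmp <- types[j]; types[j] <- types[i]; types[i] <- tmp
  }
  types
}

#' Inject balanced random typos into a corpus
#'
#' Samples `total_errors` distinct eligible token positions (alphabetic,
#' length >= 2), assigns the four error types in counts differing by at most
#' one, and corrupts each token with [corrupt_word()]. At most one typo per
#' token. Seed R's RNG beforehand for reproducible output.
#'
#' @param sentences list of `tokenized_sentence` objects (or character vector
#'   of raw lines, which are tokenized first).
#' @param total_errors absolute number of typos, or `NULL` to use `rate`.
#' @param rate fraction of eligible tokens to corrupt (used when
#'   `total_errors` is `NULL`); the count is `round(rate * n_eligible)`.
#' @return list with `sentences` (corrupted `tokenized_sentence` list) and
#'   `records`: data.frame with columns `sentence_index`, `token_index`,
#'   `original`, `corrupted`, `error_type`, `split_point`.
#' @export
corrupt_corpus <- function(sentences, total_errors = NULL, rate = NULL) {
  if (is.character(sentences)) sentences <- tokenize_lines(sentences)
  stopifnot(is.list(sentences))
  pos <- do.call(rbind, lapply(seq_along(sentences), function(i) {
    toks <- sentences[[i]]$tokens
    ok <- which(.eligible_token(toks))
    if (!length(ok)) return(NULL)
    data.frame(sentence_index = i, token_index = ok,
               token = toks[ok], stringsAsFactors = FALSE)
  }))
  n_eligible <- if (is.null(pos)) 0L else nrow(pos)
  if (is.null(total_errors)) {
    stopifnot(!is.null(rate), rate >= 0, rate < 1)
    total_errors <- as.integer(round(rate * n_eligible))
  }
  total_errors <- as.integer(total_errors)
  if (total_errors > n_eligible) {
    stop("requested ", total_errors, " typos but only ", n_eligible,
         " eligible tokens (deficit ", total_errors - n_eligible, ")",
         call. = FALSE)
  }
  empty <- data.frame(sentence_index = integer(0), token_index = integer(0),
                      original = character(0), corrupted = character(0),
                      error_type = character(0), split_point = integer(0),
                      stringsAsFactors = FALSE)
  if (total_errors == 0L) return(list(sentences = sentences, records = empty))

  pick <- if (n_eligible == 1L) 1L else sample.int(n_eligible, total_errors)
  chosen <- pos[pick, , drop = FALSE]
  types <- .assign_error_types(chosen$token)
  records <- empty[rep(1L, total_errors), , drop = FALSE]
  rownames(records) <- NULL
  for (k in seq_len(total_errors)) {
    res <- corrupt_word(chosen$token[k], types[k])
    records[k, ] <- list(chosen$sentence_index[k], chosen$token_index[k],
                         chosen$token[k], res$corrupted, types[k],
                         res$split_point)
    s <- sentences[[chosen$sentence_index[k]]]
    s$tokens[chosen$token_index[k]] <- res$corrupted
    s$raw <- paste(s$tokens, collapse = " ")
    sentences[[chosen$sentence_index[k]]] <- s
  }
  ord <- order(records$sentence_index, records$token_index)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  list(sentences = sentences, records = records)
}
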