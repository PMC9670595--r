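#' @importFrom stats setNames
#' @importFrom utils head read.delim write.table
NULL

# Token pattern: words (letters, internal hyphens/apostrophes), numbers with an
# optional decimal part, or any single non-space symbol. Applied after NFC
# normalization so composed/decomposed inputs tokenize identically.
.TOKEN_PATTERN <- "\\p{L}+(?:[-'’]\\p{L}+)*|[0-9]+(?:\\.[0-9]+)?|\\S"

#' Tokenize a line of text
#'
#' Splits a UTF-8 line into word, number, and symbol tokens. Words keep
#' internal hyphens and apostrophes ("T-cell", "O'Brien"); numbers keep a
#' decimal part ("2.1"); every other non-space character becomes a single
#' token. Input is NFC-normalized first.
#'
#' @param text a character scalar (may be empty).
#' @return an object of class `tokenized_sentence`: a list with `tokens`
#'   (character vector, possibly empty) and `raw` (the input line).
#' @examples
#' tokenize("right upper lobe")$tokens
#' tokenize("2.1 × 1.3 × 1 cm")$tokens
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  norm <- stringi::stri_trans_nfc(text)
  toks <- stringi::stri_extract_all_regex(norm, .TOKEN_PATTERN)[[1]]
  if (length(toks) == 1L && is.na(toks[1L])) toks <- character(0)
  structure(list(tokens = toks, raw = text), class = "tokenized_sentence")
}

#' Tokenize many lines at once
#'
#' @param lines character vector of sentences, one per element.
#' @return list of `tokenized_sentence` objects.
#' @export
tokenize_lines <- function(lines) {
  lapply(lines, tokenize)
}

#' @export
print.tokenized_sentence <- function(x, ...) {
  cat("<tokenized_sentence> ", length(x$tokens), " tokens: ",
      paste(utils::head(x$tokens, 12L), collapse = " "),
      if (length(x$tokens) > 12L) " ..." else "", "\n", sep = "")
  invisible(x)
}

.is_word_token <- function(tok) {
  stringi::stri_detect_regex(tok, "^\\p{L}+(?:[-'’]\\p{L}+)*$")
}

.apply_case <- function(word, case_policy) {
  if (identical(case_policy, "fold_lower")) stringi::stri_trans_tolower(word) else word
}

#' Build a word-frequency dictionary from a corpus
#'
#' Counts alphabetic tokens (length >= 2) over a one-sentence-per-line corpus
#' and keeps those whose corpus frequency reaches `min_count`; rarer words,
#' numbers and symbols are excluded. The resulting dictionary defines which
#' words are "known" to the corrector: a token absent from it is treated as a
#' candidate typo.
#'
#' @param corpus a character vector of sentences, or a path to a UTF-8 text
#'   file with one sentence per line.
#' @param min_count minimum corpus frequency for inclusion (default 20; a word
#'   seen exactly `min_count` times is retained).
#' @param case_policy `"fold_lower"` (default) to case-fold words before
#'   counting, or `"preserve"`.
#' @return an object of class `word_dictionary`: list with `entries` (named
#'   integer vector word -> count), `min_count`, `case_policy`.
#' @export
build_dictionary <- function(corpus, min_count = 20L,
                             case_policy = c("fold_lower", "preserve")) {
  case_policy <- match.arg(case_policy)
  stopifnot(is.numeric(min_count), length(min_count) == 1L, min_count >= 1)
  min_count <- as.integer(min_count)
  if (is.character(corpus) && length(corpus) == 1L && file.exists(corpus)) {
    corpus <- tryCatch(
      readLines(corpus, encoding = "UTF-8", warn = FALSE),
      error = function(e) stop("cannot read corpus file '", corpus, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  stopifnot(is.character(corpus))
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(corpus)) {
    toks <- tryCatch(tokenize(corpus[[i]])$tokens,
                     error = function(e) stop("corpus line ", i, ": ",
                                              conditionMessage(e), call. = FALSE))
    toks <- toks[.is_word_token(toks) & nchar(toks) >= 2L]
    if (!length(toks)) next
    toks <- .apply_case(toks, case_policy)
    tab <- table(toks)
    for (w in names(tab)) {
      counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + as.integer(tab[[w]])
    }
  }
  words <- ls(counts, all.names = TRUE)
  n <- vapply(words, function(w) counts[[w]], integer(1))
  keep <- n >= min_count
  entries <- setNames(n[keep], words[keep])
  entries <- entries[order(-entries, names(entries), method = "radix")]
  new_word_dictionary(entries, min_count, case_policy)
}

#' Construct a word dictionary from explicit counts
#'
#' @param entries named integer vector, word -> count; every count must be at
#'   least `min_count`.
#' @param min_count minimum-frequency threshold the entries satisfy.
#' @param case_policy `"fold_lower"` or `"preserve"`.
#' @return a `word_dictionary`.
#' @export
new_word_dictionary <- function(entries, min_count = 1L,
                                case_policy = c("fold_lower", "preserve")) {
  case_policy <- match.arg(case_policy)
  entries <- setNames(as.integer(entries), names(entries))
  if (length(entries)) {
    stopifnot(!is.null(names(entries)), all(nzchar(names(entries))),
              all(entries >= as.integer(min_count)))
  }
  structure(list(entries = entries, min_count = as.integer(min_count),
                 case_policy = case_policy),
            class = "word_dictionary")
}

#' @export
print.word_dictionary <- function(x, ...) {
  cat("<word_dictionary> ", length(x$entries), " words (min_count=",
      x$min_count, ", case_policy=", x$case_policy, ")\n", sep = "")
  invisible(x)
}

#' Look up a word's corpus frequency
#'
#' @param dict a `word_dictionary`.
#' @param word character scalar; case-folded first when the dictionary's
#'   policy is `"fold_lower"`.
#' @return integer count; 0 when the word is absent.
#' @export
dictionary_frequency <- function(dict, word) {
  stopifnot(inherits(dict, "word_dictionary"))
  w <- .apply_case(word, dict$case_policy)
  n <- unname(dict$entries[w])
  n[is.na(n)] <- 0L
  n
}

#' Test dictionary membership
#'
#' @inheritParams dictionary_frequency
#' @return logical.
#' @export
in_dictionary <- function(dict, word) {
  dictionary_frequency(dict, word) > 0L
}

#' Write a dictionary as two-column TSV
#'
#' Rows are `word<TAB>count`, sorted by descending count then lexicographic,
#' so identical dictionaries serialize byte-identically.
#'
#' @param dict a `word_dictionary`.
#' @param path output file path.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "word_dictionary"))
  e <- dict$entries
  e <- e[order(-e, names(e), method = "radix")]
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d", names(e), e), con)
}

#' Read a TSV dictionary written by [write_dictionary()]
#'
#' @param path TSV file path.
#' @param min_count threshold recorded on the loaded dictionary.
#' @param case_policy case policy recorded on the loaded dictionary.
#' @return a `word_dictionary`.
#' @export
read_dictionary <- function(path, min_count = 1L,
                            case_policy = c("fold_lower", "preserve")) {
  case_policy <- match.arg(case_policy)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(new_word_dictionary(integer(0), min_count, case_policy))
  parts <- stringi::stri_split_fixed(lines, "\t", n = 2L)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) stop("malformed dictionary line ", bad[1L], " in '", path, "'",
                        call. = FALSE)
  words <- vapply(parts, `[[`, character(1), 1L)
  n <- as.integer(vapply(parts, `[[`, character(1), 2L))
  new_word_dictionary(setNames(n, words), min_count, case_policy)
}
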