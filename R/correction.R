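#' Correction configuration
#'
#' @param lambda_weight weight of the frequency score in the final score
#'   (`FinalScore = lambda * FrequencyScore + (1 - lambda) * ContextScore`);
#'   must lie in \[0, 1\]. Default 0.5.
#' @param max_distance maximum edit distance for candidate generation.
#' @param oov_only when `TRUE` (default) only tokens absent from the
#'   dictionary are considered for correction; in-dictionary tokens pass
#'   through unchanged.
#' @return an object of class `correction_config`.
#' @export
correction_config <- function(lambda_weight = 0.5, max_distance = 2L,
                              oov_only = TRUE) {
  if (!is.numeric(lambda_weight) || length(lambda_weight) != 1L ||
      is.na(lambda_weight) || lambda_weight < 0 || lambda_weight > 1) {
    stop("lambda_weight must be a number in [0, 1]", call. = FALSE)
  }
  structure(list(lambda_weight = lambda_weight,
                 max_distance = as.integer(max_distance),
                 oov_only = isTRUE(oov_only)),
            class = "correction_config")
}

#' Frequency score over a candidate set
#'
#' Relative frequency within the candidate set: each candidate's dictionary
#' count divided by the summed counts, so the scores sum to 1 and are
#' commensurate with the renormalized context probabilities.
#'
#' @param candidates data.frame from [generate_candidates()] (columns `term`,
#'   `count`), non-empty with positive counts.
#' @return named numeric vector term -> score.
#' @export
frequency_score <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    stop("frequency_score needs a non-empty candidate set", call. = FALSE)
  }
  stopifnot(all(candidates$count > 0))
  stats::setNames(candidates$count / sum(candidates$count), candidates$term)
}

#' Final combined candidate score
#'
#' The convex combination
#' `FinalScore = lambda * FrequencyScore + (1 - lambda) * ContextSensitiveScore`.
#' With `lambda = 1` ranking reduces to frequency only; with `lambda = 0` to
#' context only.
#'
#' @param freq,context scores in \[0, 1\].
#' @param lambda_weight weight in \[0, 1\].
#' @return numeric score(s) in \[0, 1\]; vectorized over `freq`/`context`.
#' @export
final_score <- function(freq, context, lambda_weight) {
  if (!is.numeric(lambda_weight) || length(lambda_weight) != 1L ||
      is.na(lambda_weight) || lambda_weight < 0 || lambda_weight > 1) {
    stop("lambda_weight must be a number in [0, 1]", call. = FALSE)
  }
  stopifnot(all(freq >= 0 & freq <= 1), all(context >= 0 & context <= 1))
  lambda_weight * freq + (1 - lambda_weight) * context
}

# Re-apply the original token's capitalization pattern to a replacement term.
.match_case <- function(term, original) {
  if (stringi::stri_detect_regex(original, "^\\p{Lu}+$") && nchar(original) > 1L) {
    return(stringi::stri_trans_toupper(term))
  }
  if (stringi::stri_detect_regex(original, "^\\p{Lu}")) {
    return(paste0(stringi::stri_trans_toupper(substr(term, 1L, 1L)),
                  substr(term, 2L, nchar(term))))
  }
  term
}

#' Correct one token in its sentence context
#'
#' Skips tokens that are non-alphabetic, shorter than two characters, or (when
#' `oov_only`) already in the dictionary. Otherwise candidates are generated
#' from the delete index, scored by frequency and by the context backend at
#' the token's masked position, ranked by the combined final score (ties:
#' smaller edit distance, larger raw count, lexicographic), and the top
#' candidate replaces the token, inheriting its capitalization pattern.
#'
#' @param tokens the sentence's token vector (original, uncorrected context).
#' @param index 1-based position of the token to examine.
#' @param dict a `word_dictionary`.
#' @param index_struct a `delete_index` built over `dict`.
#' @param scorer a `context_scorer`.
#' @param config a [correction_config()].
#' @return an object of class `correction_result`: list with `original`,
#'   `chosen`, `changed`, `skipped`, and `candidates` (data.frame with
#'   `term`, `distance`, `count`, `frequency_score`, `context_score`,
#'   `final_score`, ranked best-first; zero rows when skipped or no match).
#' @export
correct_token <- function(tokens, index, dict, index_struct, scorer, config) {
  stopifnot(index >= 1L, index <= length(tokens),
            inherits(config, "correction_config"))
  token <- tokens[index]
  empty <- data.frame(term = character(0), distance = integer(0),
                      count = integer(0), frequency_score = numeric(0),
                      context_score = numeric(0), final_score = numeric(0),
                      stringsAsFactors = FALSE)
  result <- function(chosen, skipped, cand) {
    structure(list(original = token, chosen = chosen,
                   changed = !identical(chosen, token),
                   skipped = skipped, candidates = cand),
              class = "correction_result")
  }
  skip <- !.is_word_token(token) || nchar(token) < 2L ||
    (config$oov_only && in_dictionary(dict, token))
  if (skip) return(result(token, TRUE, empty))
  cand <- generate_candidates(token, index_struct)
  if (!nrow(cand)) return(result(token, FALSE, empty))
  cand$frequency_score <- as.numeric(frequency_score(cand))
  ctx <- score_candidates(scorer, tokens, index, cand$term)
  cand$context_score <- as.numeric(ctx[cand$term])
  cand$final_score <- final_score(cand$frequency_score, cand$context_score,
                                  config$lambda_weight)
  ord <- order(-cand$final_score, cand$distance, -cand$count, cand$term,
               method = "radix")
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  result(.match_case(cand$term[1L], token), FALSE, cand)
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result> '", x$original, "' -> '", x$chosen, "' (",
      if (x$skipped) "skipped" else if (x$changed) "changed" else "unchanged",
      ", ", nrow(x$candidates), " candidates)\n", sep = "")
  invisible(x)
}

#' Correct every token of a corpus
#'
#' Tokens are processed independently left to right, each scored against the
#' original (uncorrected) sentence context so earlier corrections never feed
#' later ones. Output is deterministic for a fixed dictionary, scorer, and
#' configuration.
#'
#' @param sentences list of `tokenized_sentence` objects or character vector
#'   of raw lines.
#' @inheritParams correct_token
#' @return list with `sentences` (corrected `tokenized_sentence` list) and
#'   `results`: a trace data.frame with one row per examined (non-skipped)
#'   token — columns `sentence_index`, `token_index`, `original`, `chosen`,
#'   `changed`, `n_candidates`, `distance`, `final_score` (NA when no
#'   candidate matched).
#' @export
correct_corpus <- function(sentences, dict, index_struct, scorer,
                           config = correction_config()) {
  if (is.character(sentences)) sentences <- tokenize_lines(sentences)
  rows <- list()
  for (i in seq_along(sentences)) {
    toks <- sentences[[i]]$tokens
    out <- toks
    for (j in seq_along(toks)) {
      r <- correct_token(toks, j, dict, index_struct, scorer, config)
      if (r$skipped) next
      out[j] <- r$chosen
      rows[[length(rows) + 1L]] <- data.frame(
        sentence_index = i, token_index = j, original = r$original,
        chosen = r$chosen, changed = r$changed,
        n_candidates = nrow(r$candidates),
        distance = if (nrow(r$candidates)) r$candidates$distance[1L] else NA_integer_,
        final_score = if (nrow(r$candidates)) r$candidates$final_score[1L] else NA_real_,
        stringsAsFactors = FALSE)
    }
    sentences[[i]] <- structure(list(tokens = out,
                                     raw = paste(out, collapse = " ")),
                                class = "tokenized_sentence")
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sentence_index = integer(0), token_index = integer(0),
               original = character(0), chosen = character(0),
               changed = logical(0), n_candidates = integer(0),
               distance = integer(0), final_score = numeric(0),
               stringsAsFactors = FALSE)
  list(sentences = sentences, results = results)
}
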