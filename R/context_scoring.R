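.BOS <- "<s>"
.EOS <- "</s>"
.SEP <- "\x1f"

#' Numerically stable softmax
#'
#' Maps raw scores `a_k` to probabilities `y_k = exp(a_k) / sum_i exp(a_i)`.
#' The maximum is subtracted before exponentiation so arbitrarily large
#' magnitudes do not overflow.
#'
#' @param raw_scores non-empty numeric vector of finite scores.
#' @return numeric vector of probabilities in (0, 1), summing to 1; names are
#'   preserved.
#' @export
softmax <- function(raw_scores) {
  if (!is.numeric(raw_scores) || length(raw_scores) == 0L) {
    stop("softmax needs a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(raw_scores))) {
    stop("softmax scores must be finite", call. = FALSE)
  }
  e <- exp(raw_scores - max(raw_scores))
  e / sum(e)
}

.ngram_key <- function(ctx, w) paste(c(ctx, w), collapse = .SEP)
.ctx_key <- function(ctx) paste(c("c", ctx), collapse = .SEP)

# Counts all n-gram orders 1..order so scoring can back off: an exact
# high-order context that never occurred in training still leaves the lower
# orders to discriminate candidates.
.count_direction <- function(env, sents, order) {
  pad <- rep(.BOS, order - 1L)
  for (toks in sents) {
    seqd <- c(pad, toks, .EOS)
    for (i in seq.int(order, length(seqd))) {
      for (k in seq_len(order)) {
        ctx <- if (k == 1L) character(0) else seqd[(i - k + 1L):(i - 1L)]
        key <- .ngram_key(ctx, seqd[i])
        ckey <- .ctx_key(ctx)
        env$ng[[key]] <- (if (is.null(env$ng[[key]])) 0L else env$ng[[key]]) + 1L
        env$ctx[[ckey]] <- (if (is.null(env$ctx[[ckey]])) 0L else env$ctx[[ckey]]) + 1L
      }
    }
  }
}

#' Train the bidirectional n-gram context backend
#'
#' A desk-scale context scorer satisfying the same contract as a masked
#' language model: the score of candidate `c` at a masked slot is the mean of
#' the left-to-right n-gram log-probability of `c` given the preceding tokens
#' and the right-to-left log-probability given the following tokens. Each
#' direction averages the additively smoothed conditional log-probabilities
#' over orders 1..`order` (a back-off interpolation), so unseen candidates and
#' unseen high-order contexts stay finite and lower orders still discriminate.
#' Sentences are padded with boundary markers.
#'
#' @param corpus character vector of sentences or list of
#'   `tokenized_sentence` objects.
#' @param order n-gram order (>= 2; default 3).
#' @param smoothing additive (Laplace-style) constant (default 0.01).
#' @return an object of class `c("ngram_scorer", "context_scorer")`.
#' @export
train_ngram_backend <- function(corpus, order = 3L, smoothing = 0.01) {
  stopifnot(order >= 2L, smoothing > 0)
  if (is.character(corpus)) corpus <- tokenize_lines(corpus)
  sents <- lapply(corpus, function(s) if (is.list(s)) s$tokens else s)
  sents <- sents[vapply(sents, length, integer(1)) > 0L]
  if (!length(sents)) stop("cannot train an n-gram backend on an empty corpus",
                           call. = FALSE)
  fwd <- list(ng = new.env(parent = emptyenv()), ctx = new.env(parent = emptyenv()))
  bwd <- list(ng = new.env(parent = emptyenv()), ctx = new.env(parent = emptyenv()))
  .count_direction(fwd, sents, order)
  .count_direction(bwd, lapply(sents, rev), order)
  vocab <- unique(c(unlist(sents), .BOS, .EOS))
  structure(list(order = as.integer(order), smoothing = smoothing,
                 forward = fwd, backward = bwd,
                 vocab_size = length(vocab) + 1L),  # +1: unseen-word mass
            class = c("ngram_scorer", "context_scorer"))
}

#' @export
print.ngram_scorer <- function(x, ...) {
  cat("<ngram_scorer> order=", x$order, ", smoothing=", x$smoothing,
      ", vocab=", x$vocab_size - 1L, " types\n", sep = "")
  invisible(x)
}

.smoothed_logp <- function(side, ctx, w, alpha, V) {
  key <- .ngram_key(ctx, w)
  ckey <- .ctx_key(ctx)
  n_cw <- side$ng[[key]]; if (is.null(n_cw)) n_cw <- 0L
  n_c <- side$ctx[[ckey]]; if (is.null(n_c)) n_c <- 0L
  log((n_cw + alpha) / (n_c + alpha * V))
}

# Directional score: mean over orders 1..order of the smoothed conditional
# log-probability of the candidate given the k-1 preceding tokens.
.directional_score <- function(scorer, side, seq_pad, i, candidate) {
  lp <- vapply(seq_len(scorer$order), function(k) {
    ctx <- if (k == 1L) character(0) else seq_pad[(i - k + 1L):(i - 1L)]
    .smoothed_logp(side, ctx, candidate, scorer$smoothing, scorer$vocab_size)
  }, numeric(1))
  mean(lp)
}

.ngram_raw_score <- function(scorer, tokens, target_index, candidate) {
  k <- scorer$order - 1L
  fwd_seq <- c(rep(.BOS, k), tokens)
  i <- target_index + k
  bwd_seq <- c(rep(.BOS, k), rev(tokens))
  j <- (length(tokens) - target_index + 1L) + k
  lf <- .directional_score(scorer, scorer$forward, fwd_seq, i, candidate)
  lb <- .directional_score(scorer, scorer$backward, bwd_seq, j, candidate)
  (lf + lb) / 2
}

#' Score candidates for a masked sentence slot
#'
#' Substitutes each candidate at the masked position, computes the backend's
#' raw log-score, and renormalizes over the candidate set, so the returned
#' probabilities sum to 1 and the ranking is invariant to any positive
#' rescaling of the raw scores. Scoring is pure: identical inputs give
#' identical outputs for a fixed backend.
#'
#' @param scorer a `context_scorer` backend.
#' @param tokens the sentence's token vector.
#' @param target_index 1-based index of the masked slot.
#' @param candidates non-empty character vector of candidate words.
#' @return named numeric vector of probabilities over `candidates`.
#' @export
score_candidates <- function(scorer, tokens, target_index, candidates) {
  UseMethod("score_candidates")
}

#' @export
score_candidates.ngram_scorer <- function(scorer, tokens, target_index, candidates) {
  stopifnot(length(candidates) >= 1L, target_index >= 1L,
            target_index <= length(tokens))
  raw <- vapply(candidates,
                function(cand) .ngram_raw_score(scorer, tokens, target_index, cand),
                numeric(1))
  stats::setNames(softmax(raw), candidates)
}

#' Pluggable transformer masked-language-model backend
#'
#' The headline context scorer of the method is a pre-trained transformer MLM
#' head; its weights are external and are not shipped. This constructor wires
#' a user-supplied scoring function (for example one calling out to a local
#' BERT-style model) into the same contract as the n-gram backend.
#' Multi-subword candidates should be scored by masking one slot per subword
#' piece and averaging the per-slot log-probabilities.
#'
#' @param score_fun `function(tokens, target_index, candidates)` returning a
#'   finite raw log-score per candidate, or `NULL` (scoring then raises a
#'   `medspell_backend_unavailable` error explaining how to enable it).
#' @return an object of class `c("transformer_mlm_scorer", "context_scorer")`.
#' @export
transformer_mlm_scorer <- function(score_fun = NULL) {
  stopifnot(is.null(score_fun) || is.function(score_fun))
  structure(list(score_fun = score_fun),
            class = c("transformer_mlm_scorer", "context_scorer"))
}

#' @export
score_candidates.transformer_mlm_scorer <- function(scorer, tokens, target_index,
                                                    candidates) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(scorer$score_fun)) {
    stop(structure(class = c("medspell_backend_unavailable", "error", "condition"),
                   list(message = paste(
                     "transformer MLM backend unavailable: supply pre-trained",
                     "model weights via transformer_mlm_scorer(score_fun =",
                     "<function(tokens, target_index, candidates)>)"),
                     call = NULL)))
  }
  raw <- scorer$score_fun(tokens, target_index, candidates)
  if (length(raw) != length(candidates) || any(!is.finite(raw))) {
    stop("MLM backend returned invalid scores for candidates: ",
         paste(candidates, collapse = ", "), call. = FALSE)
  }
  stats::setNames(softmax(as.numeric(raw)), candidates)
}

#' Serialize an n-gram backend to TSV
#'
#' Writes header lines (`#order`, `#smoothing`, `#vocab_size`) then one row
#' per n-gram: `direction<TAB>context<TAB>word<TAB>count` with context tokens
#' space-joined. [read_ngram_model()] restores an equivalent scorer.
#'
#' @param scorer an `ngram_scorer`.
#' @param path output file path.
#' @export
write_ngram_model <- function(scorer, path) {
  stopifnot(inherits(scorer, "ngram_scorer"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#order\t", scorer$order),
               paste0("#smoothing\t", format(scorer$smoothing, digits = 17)),
               paste0("#vocab_size\t", scorer$vocab_size)), con)
  for (dir in c("F", "B")) {
    side <- if (dir == "F") scorer$forward else scorer$backward
    keys <- sort(ls(side$ng, all.names = TRUE))
    for (key in keys) {
      parts <- strsplit(key, .SEP, fixed = TRUE)[[1]]
      n <- length(parts)
      writeLines(paste(dir, paste(parts[-n], collapse = " "), parts[n],
                       side$ng[[key]], sep = "\t"), con)
    }
  }
}

#' Load an n-gram backend written by [write_ngram_model()]
#'
#' @param path TSV model file.
#' @return an `ngram_scorer` equivalent to the serialized one.
#' @export
read_ngram_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(name) {
    row <- hdr[startsWith(hdr, paste0("#", name, "\t"))]
    if (!length(row)) stop("missing header '", name, "' in '", path, "'",
                           call. = FALSE)
    strsplit(row[1L], "\t", fixed = TRUE)[[1]][2L]
  }
  scorer <- structure(list(order = as.integer(get_hdr("order")),
                           smoothing = as.numeric(get_hdr("smoothing")),
                           forward = list(ng = new.env(parent = emptyenv()),
                                          ctx = new.env(parent = emptyenv())),
                           backward = list(ng = new.env(parent = emptyenv()),
                                           ctx = new.env(parent = emptyenv())),
                           vocab_size = as.integer(get_hdr("vocab_size"))),
                      class = c("ngram_scorer", "context_scorer"))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) stop("malformed model row: ", ln, call. = FALSE)
    ctx <- strsplit(f[2L], " ", fixed = TRUE)[[1]]
    side <- if (f[1L] == "F") scorer$forward else scorer$backward
    key <- .ngram_key(ctx, f[3L])
    ckey <- .ctx_key(ctx)
    n <- as.integer(f[4L])
    side$ng[[key]] <- n
    side$ctx[[ckey]] <- (if (is.null(side$ctx[[ckey]])) 0L else side$ctx[[ckey]]) + n
  }
  scorer
}
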