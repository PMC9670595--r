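#' BIO tag schemes
#'
#' Built-in schemes: `"ncbi"` (disease mentions: `B-Disease`, `I-Disease`,
#' `O`) and `"spr"` (surgical pathology records: B/I labels for ORGAN,
#' LOCATION, OPNAME, HISTOLOGIC DIAGNOSIS, plus `B-TUMOR_SIZE` — tumor sizes
#' are single-token entities — and `O`).
#'
#' @param name `"ncbi"`, `"spr"`, or `"custom"` (then supply `labels`).
#' @param labels for `"custom"`: character vector of labels including `"O"`,
#'   every other label of the form `B-X` or `I-X`.
#' @return an object of class `tag_scheme`.
#' @export
tag_scheme <- function(name = c("ncbi", "spr", "custom"), labels = NULL) {
  name <- match.arg(name)
  labels <- switch(name,
    ncbi = c("B-Disease", "I-Disease", "O"),
    spr = c("B-ORGAN", "I-ORGAN", "B-LOCATION", "I-LOCATION",
            "B-OPNAME", "I-OPNAME", "B-HISTOLOGIC DIAGNOSIS",
            "I-HISTOLOGIC DIAGNOSIS", "B-TUMOR_SIZE", "O"),
    custom = labels)
  stopifnot(is.character(labels), "O" %in% labels)
  non_o <- setdiff(labels, "O")
  ok <- grepl("^[BI]-.+$", non_o)
  if (!all(ok)) stop("invalid BIO label(s): ", paste(non_o[!ok], collapse = ", "),
                     call. = FALSE)
  structure(list(name = name, labels = labels,
                 types = unique(sub("^[BI]-", "", non_o))),
            class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("<tag_scheme '", x$name, "'> ", length(x$labels), " labels: ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' A token sequence with BIO labels
#'
#' @param tokens character vector of tokens.
#' @param labels character vector of BIO labels, same length as `tokens`.
#' @param scheme a [tag_scheme()] the labels are validated against.
#' @param policy `"strict"` rejects a dangling `I-X` (one not preceded by
#'   `B-X`/`I-X`); `"repair"` promotes it to `B-X`.
#' @return an object of class `tagged_sentence`.
#' @export
tagged_sentence <- function(tokens, labels, scheme, policy = c("strict", "repair")) {
  policy <- match.arg(policy)
  stopifnot(inherits(scheme, "tag_scheme"), length(tokens) == length(labels))
  unknown <- setdiff(labels, scheme$labels)
  if (length(unknown)) {
    stop("label(s) not in scheme '", scheme$name, "': ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  labels <- .validate_bio(labels, policy)
  structure(list(tokens = tokens, labels = labels, scheme = scheme$name),
            class = "tagged_sentence")
}

.validate_bio <- function(labels, policy) {
  prev <- "O"
  for (i in seq_along(labels)) {
    lab <- labels[i]
    if (startsWith(lab, "I-")) {
      type <- substr(lab, 3L, nchar(lab))
      prev_type <- if (prev != "O" && !startsWith(prev, "O")) {
        substr(prev, 3L, nchar(prev))
      } else ""
      if (!(prev_type == type && prev != "O")) {
        if (policy == "strict") {
          stop("dangling I- label '", lab, "' at position ", i, call. = FALSE)
        }
        labels[i] <- paste0("B-", type)
      }
    }
    prev <- labels[i]
  }
  labels
}

#' @export
print.tagged_sentence <- function(x, ...) {
  cat("<tagged_sentence> ", paste(x$tokens, x$labels, sep = "/", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Read a CoNLL-style BIO file
#'
#' One token per line (`token<TAB>label`; a space separator is accepted when
#' the label has no internal space), blank line between sentences.
#'
#' @param path input file.
#' @param scheme a [tag_scheme()] labels are validated against.
#' @param policy BIO validation policy, `"strict"` (default, for gold files)
#'   or `"repair"`.
#' @return list of `tagged_sentence`.
#' @export
read_conll <- function(path, scheme, policy = c("strict", "repair")) {
  policy <- match.arg(policy)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(0); labs <- character(0)
  flush_sentence <- function() {
    if (length(toks)) {
      sentences[[length(sentences) + 1L]] <<- tagged_sentence(toks, labs, scheme,
                                                              policy)
      toks <<- character(0); labs <<- character(0)
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) { flush_sentence(); next }
    parts <- if (grepl("\t", ln, fixed = TRUE)) {
      strsplit(ln, "\t", fixed = TRUE)[[1]]
    } else {
      m <- regmatches(ln, regexec("^(\\S+)\\s+(\\S+)$", ln))[[1]][-1]
      m
    }
    if (length(parts) != 2L || !all(nzchar(parts))) {
      stop("malformed CoNLL line ", i, " in '", path, "': ", ln, call. = FALSE)
    }
    if (!(parts[2L] %in% scheme$labels)) {
      stop("unknown label '", parts[2L], "' at line ", i, " in '", path, "'",
           call. = FALSE)
    }
    toks <- c(toks, parts[1L]); labs <- c(labs, parts[2L])
  }
  flush_sentence()
  sentences
}

#' Write tagged sentences in CoNLL format
#'
#' @param sentences list of `tagged_sentence`.
#' @param path output file; tokens and labels are tab-separated, sentences
#'   separated by a blank line.
#' @export
write_conll <- function(sentences, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (s in sentences) {
    writeLines(paste(s$tokens, s$labels, sep = "\t"), con)
    writeLines("", con)
  }
}

#' Decode entities from a BIO labeling
#'
#' Maximal runs starting at a `B-X` label and continued by `I-X` of the same
#' type become entities; `O` contributes nothing; a fresh `B-X` always starts
#' a new entity (so `B-X B-X` is two single-token entities).
#'
#' @param sentence a `tagged_sentence` (or a list with `tokens` and valid BIO
#'   `labels`).
#' @return data.frame with columns `type`, `start` (1-based, inclusive),
#'   `end` (inclusive), `text` (space-joined surface form).
#' @export
decode_entities <- function(sentence) {
  labels <- sentence$labels; tokens <- sentence$tokens
  out <- list()
  i <- 1L
  while (i <= length(labels)) {
    if (startsWith(labels[i], "B-")) {
      type <- substr(labels[i], 3L, nchar(labels[i]))
      j <- i
      while (j + 1L <= length(labels) &&
             labels[j + 1L] == paste0("I-", type)) j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        type = type, start = i, end = j,
        text = paste(tokens[i:j], collapse = " "), stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) {
    return(data.frame(type = character(0), start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Rebuild BIO labels from an entity list
#'
#' Inverse of [decode_entities()] for non-overlapping entities.
#'
#' @param entities data.frame with `type`, `start`, `end`.
#' @param n sentence length in tokens.
#' @return character vector of BIO labels of length `n`.
#' @export
entities_to_labels <- function(entities, n) {
  labels <- rep("O", n)
  if (nrow(entities)) {
    for (k in seq_len(nrow(entities))) {
      s <- entities$start[k]; e <- entities$end[k]
      stopifnot(s >= 1L, e >= s, e <= n, all(labels[s:e] == "O"))
      labels[s] <- paste0("B-", entities$type[k])
      if (e > s) labels[(s + 1L):e] <- paste0("I-", entities$type[k])
    }
  }
  labels
}

# ---- baseline HMM tagger -----------------------------------------------------

.word_shape <- function(tok) {
  s <- stringi::stri_replace_all_regex(tok, "\\p{Lu}", "X")
  s <- stringi::stri_replace_all_regex(s, "\\p{Ll}", "x")
  s <- stringi::stri_replace_all_regex(s, "[0-9]", "9")
  stringi::stri_replace_all_regex(s, "(.)\\1+", "$1")
}

#' Train the baseline sequence tagger
#'
#' A hidden-Markov-model tagger with additively smoothed transition and
#' emission probabilities, a word-shape back-off for unseen tokens, and
#' Viterbi decoding constrained to valid BIO transitions (an `I-X` state is
#' reachable only from `B-X`/`I-X`), so predictions always form a valid BIO
#' sequence. It stands behind the same predict contract as a fine-tuned
#' transformer tagger and is deterministic for fixed training data.
#'
#' @param train non-empty list of `tagged_sentence`.
#' @param scheme the [tag_scheme()] to tag with.
#' @param smoothing additive constant for transition/emission estimates.
#' @return an object of class `baseline_tagger`.
#' @export
train_baseline_tagger <- function(train, scheme, smoothing = 0.1) {
  stopifnot(inherits(scheme, "tag_scheme"))
  if (!length(train)) stop("cannot train a tagger on an empty corpus",
                           call. = FALSE)
  labs <- scheme$labels
  L <- length(labs)
  trans <- matrix(0, L + 1L, L, dimnames = list(c("<start>", labs), labs))
  emis <- new.env(parent = emptyenv())    # key: label \x1f token
  shape_emis <- new.env(parent = emptyenv())
  label_tot <- stats::setNames(numeric(L), labs)
  vocab <- new.env(parent = emptyenv())
  bump <- function(env, key) env[[key]] <- (if (is.null(env[[key]])) 0 else env[[key]]) + 1
  for (s in train) {
    prev <- "<start>"
    for (i in seq_along(s$tokens)) {
      y <- s$labels[i]; tok <- s$tokens[i]
      trans[prev, y] <- trans[prev, y] + 1
      bump(emis, paste(y, tok, sep = .SEP))
      bump(shape_emis, paste(y, .word_shape(tok), sep = .SEP))
      label_tot[y] <- label_tot[y] + 1
      vocab[[tok]] <- TRUE
      prev <- y
    }
  }
  structure(list(scheme = scheme, trans = trans, emis = emis,
                 shape_emis = shape_emis, label_tot = label_tot,
                 vocab = vocab, smoothing = smoothing,
                 n_types = length(ls(vocab, all.names = TRUE))),
            class = "baseline_tagger")
}

#' @export
print.baseline_tagger <- function(x, ...) {
  cat("<baseline_tagger> scheme '", x$scheme$name, "', ",
      x$n_types, " token types, ", sum(x$label_tot), " training tokens\n", sep = "")
  invisible(x)
}

.bio_allowed <- function(labels) {
  # allowed[i, j]: transition labels[i] -> labels[j]; row 1 is the start state
  L <- length(labels)
  allowed <- matrix(TRUE, L + 1L, L, dimnames = list(c("<start>", labels), labels))
  for (j in seq_len(L)) {
    if (startsWith(labels[j], "I-")) {
      type <- substr(labels[j], 3L, nchar(labels[j]))
      ok_prev <- c(paste0("B-", type), paste0("I-", type))
      allowed[, j] <- c("<start>", labels) %in% ok_prev
    }
  }
  allowed
}

.log_emission <- function(tagger, tok) {
  labs <- names(tagger$label_tot)
  a <- tagger$smoothing
  known <- isTRUE(tagger$vocab[[tok]])
  vapply(labs, function(y) {
    tot <- tagger$label_tot[[y]]
    if (known) {
      n <- tagger$emis[[paste(y, tok, sep = .SEP)]]
      if (is.null(n)) n <- 0
      log((n + a) / (tot + a * (tagger$n_types + 1L)))
    } else {
      n <- tagger$shape_emis[[paste(y, .word_shape(tok), sep = .SEP)]]
      if (is.null(n)) n <- 0
      log((n + a) / (tot + a * (tagger$n_types + 1L)))
    }
  }, numeric(1))
}

.log_transition <- function(tagger) {
  a <- tagger$smoothing
  tr <- tagger$trans
  log((tr + a) / (rowSums(tr) + a * ncol(tr)))
}

#' Predict BIO labels for a token sequence
#'
#' @param tagger a `baseline_tagger`.
#' @param tokens character vector of tokens.
#' @return a `tagged_sentence` with one valid BIO label per token.
#' @export
predict_tags <- function(tagger, tokens) {
  stopifnot(inherits(tagger, "baseline_tagger"))
  labs <- tagger$scheme$labels
  L <- length(labs)
  if (!length(tokens)) {
    return(tagged_sentence(character(0), character(0), tagger$scheme))
  }
  logtr <- .log_transition(tagger)
  allowed <- .bio_allowed(labs)
  n <- length(tokens)
  delta <- matrix(-Inf, n, L, dimnames = list(NULL, labs))
  back <- matrix(NA_integer_, n, L)
  e1 <- .log_emission(tagger, tokens[1L])
  init_ok <- allowed["<start>", ]
  delta[1L, init_ok] <- logtr["<start>", init_ok] + e1[init_ok]
  if (n > 1L) {
    for (t in 2:n) {
      et <- .log_emission(tagger, tokens[t])
      for (j in seq_len(L)) {
        prev_ok <- which(allowed[labs, labs[j]] & is.finite(delta[t - 1L, ]))
        if (!length(prev_ok)) next
        sc <- delta[t - 1L, prev_ok] + logtr[labs[prev_ok], labs[j]]
        k <- which.max(sc)
        delta[t, j] <- sc[k] + et[j]
        back[t, j] <- prev_ok[k]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  tagged_sentence(tokens, labs[path], tagger$scheme, policy = "repair")
}

#' Per-token label probabilities
#'
#' Forward-backward posterior marginals of the HMM: for each token position a
#' softmax-normalized distribution over the scheme's labels, each row summing
#' to 1.
#'
#' @inheritParams predict_tags
#' @return numeric matrix, one row per token, one column per scheme label.
#' @export
label_probabilities <- function(tagger, tokens) {
  stopifnot(inherits(tagger, "baseline_tagger"), length(tokens) >= 1L)
  labs <- tagger$scheme$labels
  L <- length(labs); n <- length(tokens)
  logtr <- .log_transition(tagger)
  em <- t(vapply(tokens, function(tk) .log_emission(tagger, tk), numeric(L)))
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  alpha <- matrix(-Inf, n, L); beta <- matrix(0, n, L)
  alpha[1L, ] <- logtr["<start>", ] + em[1L, ]
  if (n > 1L) {
    for (t in 2:n) for (j in seq_len(L)) {
      alpha[t, j] <- lse(alpha[t - 1L, ] + logtr[labs, labs[j]]) + em[t, j]
    }
    for (t in (n - 1L):1L) for (j in seq_len(L)) {
      beta[t, j] <- lse(logtr[labs[j], ] + em[t + 1L, ] + beta[t + 1L, ])
    }
  }
  post <- alpha + beta
  out <- t(apply(post, 1L, softmax))
  dimnames(out) <- list(NULL, labs)
  out
}

#' Hyper-parameters for transformer fine-tuning
#'
#' Defaults: learning rate 3e-5, 3 epochs, maximum sequence length 178,
#' batch size 16, Adam optimizer, softmax activation.
#'
#' @return an object of class `fine_tune_config`.
#' @export
fine_tune_config <- function() {
  structure(list(learning_rate = 3e-5, epochs = 3L, max_sequence_length = 178L,
                 batch_size = 16L, optimizer = "adam", activation = "softmax"),
            class = "fine_tune_config")
}

#' Fine-tune a transformer tagger (external backend)
#'
#' The headline tagger of the method is a fine-tuned transformer with a dense
#' softmax head; its pre-trained weights are external. Without a `model_ref`
#' this raises a `medspell_backend_unavailable` error; with one it must supply
#' a `function(tokens)` returning BIO labels, wrapped to the same predict
#' contract as the baseline tagger.
#'
#' @param train list of `tagged_sentence` (passed to the external backend).
#' @param config a [fine_tune_config()].
#' @param model_ref external backend: a function `(train, config)` returning a
#'   `function(tokens) -> labels`, or `NULL`.
#' @return a list with a `predict(tokens)` function.
#' @export
fine_tune_transformer <- function(train, config = fine_tune_config(),
                                  model_ref = NULL) {
  stopifnot(inherits(config, "fine_tune_config"))
  if (is.null(model_ref)) {
    stop(structure(class = c("medspell_backend_unavailable", "error", "condition"),
                   list(message = paste(
                     "transformer tagger unavailable: supply pre-trained",
                     "weights via model_ref = function(train, config)",
                     "returning a function(tokens) -> labels"),
                     call = NULL)))
  }
  predictor <- model_ref(train, config)
  list(predict = predictor, config = config)
}

# ---- tumor-size post-processing ---------------------------------------------

.NUM_RE <- "([0-9]+(?:\\.[0-9]+)?)"
.SEP_RE <- "\\s*[x×]\\s*"

#' Extract the maximum tumor dimension from a size expression
#'
#' Parses dimension strings of the form `"A × B × C cm"` (one to three
#' numbers, `×` or ASCII `x` separators, flexible spacing, the unit optional
#' only when all three numbers are present) as well as the writer variant
#' `"N cm IN GREATEST DIMENSION"`, and returns the largest value in
#' centimeters.
#'
#' @param text character scalar.
#' @return the maximum dimension in cm, or `NA_real_` when no size pattern is
#'   found.
#' @examples
#' extract_max_dimension("2.1 × 1.3 × 1 cm")
#' extract_max_dimension("1.2 cm IN GREATEST DIMENSION")
#' @export
extract_max_dimension <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  patterns <- c(
    paste0(.NUM_RE, .SEP_RE, .NUM_RE, .SEP_RE, .NUM_RE, "(?:\\s*cm\\b)?"),
    paste0(.NUM_RE, .SEP_RE, .NUM_RE, "\\s*cm\\b"),
    paste0(.NUM_RE, "\\s*cm\\b"))
  for (pat in patterns) {
    m <- stringi::stri_match_first_regex(text, pat, case_insensitive = TRUE)
    if (!is.na(m[1, 1])) {
      vals <- suppressWarnings(as.numeric(m[1, -1]))
      return(max(vals, na.rm = TRUE))
    }
  }
  NA_real_
}
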