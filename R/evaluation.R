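.prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' Evaluate token-level typo correction
#'
#' Correction is scored as per-token restoration against the clean corpus:
#' * tp — a corrupted token whose output equals the original;
#' * fn — a corrupted token whose output differs from the original;
#' * fp — a wrong change: either a mis-corrected typo (output differs from
#'   both the original and the injected form) or a spurious change of a clean
#'   token.
#'
#' A typo left untouched is a miss (fn) but not a false alarm; a typo fixed to
#' the wrong word counts both fn and fp, so precision is penalized by wrong
#' fixes while recall tracks restoration. Support equals the number of
#' injected typos, and `tp + fn = support` always holds.
#'
#' @param gold list of clean `tokenized_sentence` (or character lines).
#' @param records corruption records from [corrupt_corpus()].
#' @param corrected corrected sentences, token-aligned with `gold`.
#' @return an object of class `correction_eval_report`: counts, `precision`,
#'   `recall`, `f1`, `support`, and `per_error_type` (one entry per injected
#'   error type; its fp counts wrong fixes of typos of that type).
#' @export
evaluate_correction <- function(gold, records, corrected) {
  if (is.character(gold)) gold <- tokenize_lines(gold)
  if (is.character(corrected)) corrected <- tokenize_lines(corrected)
  if (length(gold) != length(corrected)) {
    stop("corpus alignment mismatch: ", length(gold), " gold vs ",
         length(corrected), " corrected sentences", call. = FALSE)
  }
  for (i in seq_along(gold)) {
    if (length(gold[[i]]$tokens) != length(corrected[[i]]$tokens)) {
      stop("token alignment mismatch at sentence ", i, ": ",
           length(gold[[i]]$tokens), " vs ", length(corrected[[i]]$tokens),
           call. = FALSE)
    }
  }
  types <- error_types()
  tp <- fp <- fn <- stats::setNames(numeric(length(types)), types)
  support <- stats::setNames(numeric(length(types)), types)
  corrupted_at <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(records))) {
    i <- records$sentence_index[k]; j <- records$token_index[k]
    ty <- records$error_type[k]
    support[ty] <- support[ty] + 1
    corrupted_at[[paste(i, j)]] <- TRUE
    g <- gold[[i]]$tokens[j]; out <- corrected[[i]]$tokens[j]
    if (identical(out, g)) {
      tp[ty] <- tp[ty] + 1
    } else {
      fn[ty] <- fn[ty] + 1
      if (!identical(out, records$corrupted[k])) fp[ty] <- fp[ty] + 1
    }
  }
  spurious <- 0
  for (i in seq_along(gold)) {
    g <- gold[[i]]$tokens; out <- corrected[[i]]$tokens
    for (j in which(g != out)) {
      if (is.null(corrupted_at[[paste(i, j)]])) spurious <- spurious + 1
    }
  }
  overall <- .prf(sum(tp), sum(fp) + spurious, sum(fn))
  per_type <- lapply(types, function(ty) {
    c(.prf(tp[[ty]], fp[[ty]], fn[[ty]]), list(support = support[[ty]]))
  })
  names(per_type) <- types
  structure(c(overall, list(support = sum(support),
                            spurious_changes = spurious,
                            per_error_type = per_type)),
            class = "correction_eval_report")
}

#' @export
print.correction_eval_report <- function(x, ...) {
  cat(sprintf("<correction_eval_report> P=%.3f R=%.3f F1=%.3f (tp=%d fp=%d fn=%d, support=%d)\n",
              x$precision, x$recall, x$f1, as.integer(x$tp), as.integer(x$fp),
              as.integer(x$fn), as.integer(x$support)))
  for (ty in names(x$per_error_type)) {
    e <- x$per_error_type[[ty]]
    cat(sprintf("  %-9s P=%.3f R=%.3f F1=%.3f support=%d\n", ty, e$precision,
                e$recall, e$f1, as.integer(e$support)))
  }
  invisible(x)
}

#' Evaluate named-entity recognition at the entity level
#'
#' Entities are decoded from gold and predicted labelings; a prediction is a
#' true positive only when entity type and token span both match exactly.
#' Micro scores pool tp/fp/fn over all entities; per-label scores break them
#' down by entity type. Token accuracy (the fraction of exactly matching
#' labels) is reported alongside.
#'
#' @param gold,pred token-aligned lists of `tagged_sentence` under the same
#'   scheme.
#' @return an object of class `ner_eval_report`: `micro` (tp/fp/fn/P/R/F1),
#'   `per_label` (same per entity type, with supports), `token_accuracy`,
#'   `n_gold_entities`.
#' @export
evaluate_ner <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and prediction differ in sentence count", call. = FALSE)
  }
  schemes <- unique(c(vapply(gold, `[[`, character(1), "scheme"),
                      vapply(pred, `[[`, character(1), "scheme")))
  if (length(schemes) > 1L) {
    stop("tag scheme mismatch: ", paste(schemes, collapse = " vs "), call. = FALSE)
  }
  all_types <- character(0)
  tp <- fp <- fn <- list()
  n_tok <- 0; n_tok_ok <- 0; n_gold <- 0
  add <- function(env_list, type, k = 1) {
    env_list[[type]] <- (if (is.null(env_list[[type]])) 0 else env_list[[type]]) + k
    env_list
  }
  for (i in seq_along(gold)) {
    g <- gold[[i]]; p <- pred[[i]]
    if (length(g$labels) != length(p$labels)) {
      stop("token alignment mismatch at sentence ", i, call. = FALSE)
    }
    n_tok <- n_tok + length(g$labels)
    n_tok_ok <- n_tok_ok + sum(g$labels == p$labels)
    ge <- decode_entities(g); pe <- decode_entities(p)
    n_gold <- n_gold + nrow(ge)
    gk <- if (nrow(ge)) paste(ge$type, ge$start, ge$end, sep = "|") else character(0)
    pk <- if (nrow(pe)) paste(pe$type, pe$start, pe$end, sep = "|") else character(0)
    all_types <- union(all_types, c(ge$type, pe$type))
    for (k in seq_len(nrow(ge))) {
      if (gk[k] %in% pk) tp <- add(tp, ge$type[k]) else fn <- add(fn, ge$type[k])
    }
    for (k in seq_len(nrow(pe))) {
      if (!(pk[k] %in% gk)) fp <- add(fp, pe$type[k])
    }
  }
  get0n <- function(lst, ty) if (is.null(lst[[ty]])) 0 else lst[[ty]]
  per_label <- lapply(sort(all_types), function(ty) {
    c(.prf(get0n(tp, ty), get0n(fp, ty), get0n(fn, ty)),
      list(support = get0n(tp, ty) + get0n(fn, ty)))
  })
  names(per_label) <- sort(all_types)
  micro <- .prf(sum(unlist(tp)), sum(unlist(fp)), sum(unlist(fn)))
  structure(list(micro = micro, per_label = per_label,
                 token_accuracy = if (n_tok > 0) n_tok_ok / n_tok else 0,
                 n_gold_entities = n_gold),
            class = "ner_eval_report")
}

#' @export
print.ner_eval_report <- function(x, ...) {
  cat(sprintf("<ner_eval_report> micro P=%.3f R=%.3f F1=%.3f, token accuracy=%.3f (%d gold entities)\n",
              x$micro$precision, x$micro$recall, x$micro$f1, x$token_accuracy,
              x$n_gold_entities))
  for (ty in names(x$per_label)) {
    e <- x$per_label[[ty]]
    cat(sprintf("  %-22s P=%.3f R=%.3f F1=%.3f support=%d\n", ty, e$precision,
                e$recall, e$f1, as.integer(e$support)))
  }
  invisible(x)
}

#' Sweep NER performance over typo rates
#'
#' For each rate, corrupts the test corpus with the typo-injection model
#' (balanced error types, rate converted to an absolute count of eligible
#' tokens), tags the corrupted tokens, then corrects them and tags again —
#' quantifying how typo rate degrades entity extraction and how much
#' correction recovers. Per-rate corruption is independently seeded from
#' `seed`, so the whole table is reproducible.
#'
#' @param test list of gold `tagged_sentence` (tagger should be trained on a
#'   disjoint clean split).
#' @param rates numeric vector of typo rates in \[0, 1).
#' @param tagger a trained `baseline_tagger`.
#' @param dict,index_struct,scorer,config corrector components as in
#'   [correct_corpus()].
#' @param seed integer seed for the typo injection.
#' @return data.frame with columns `rate`, `n_errors`,
#'   `ner_f1_with_typos`, `ner_f1_after_correction`.
#' @export
sweep_error_rate <- function(test, rates, tagger, dict, index_struct, scorer,
                             config = correction_config(), seed = 1L) {
  stopifnot(all(rates >= 0), all(rates < 1))
  scheme <- tagger$scheme
  gold_labels <- lapply(test, `[[`, "labels")
  as_tok <- lapply(test, function(s) {
    structure(list(tokens = s$tokens, raw = paste(s$tokens, collapse = " ")),
              class = "tokenized_sentence")
  })
  retag <- function(sent_list) {
    lapply(seq_along(sent_list), function(i) predict_tags(tagger, sent_list[[i]]$tokens))
  }
  as_gold <- function(sent_list) {
    lapply(seq_along(sent_list), function(i) {
      tagged_sentence(sent_list[[i]]$tokens, gold_labels[[i]], scheme,
                      policy = "strict")
    })
  }
  rows <- lapply(seq_along(rates), function(k) {
    rate <- rates[k]
    set.seed(seed + 997L * k)
    corr <- corrupt_corpus(as_tok, rate = rate)
    pred_typos <- retag(corr$sentences)
    f1_typos <- evaluate_ner(as_gold(corr$sentences), pred_typos)$micro$f1
    fixed <- correct_corpus(corr$sentences, dict, index_struct, scorer, config)
    pred_fixed <- retag(fixed$sentences)
    f1_fixed <- evaluate_ner(as_gold(fixed$sentences), pred_fixed)$micro$f1
    data.frame(rate = rate, n_errors = nrow(corr$records),
               ner_f1_with_typos = f1_typos,
               ner_f1_after_correction = f1_fixed)
  })
  do.call(rbind, rows)
}
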