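# Shared fixture builders and independent oracles. Everything is generated in
# code; nothing is read from disk except the package's own vocabulary table.

# Independent restricted Damerau-Levenshtein oracle: top-down recursion with
# memoization over prefix pairs (a different formulation from the package's
# bottom-up DP matrix).
oracle_dl <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- min(f(i - 1L, j) + 1L,
             f(i, j - 1L) + 1L,
             f(i - 1L, j - 1L) + (if (x[i] == y[j]) 0L else 1L))
    if (i > 1L && j > 1L && x[i] == y[j - 1L] && x[i - 1L] == y[j]) {
      v <- min(v, f(i - 2L, j - 2L) + 1L)
    }
    memo[[key]] <- v
    v
  }
  f(length(x), length(y))
}

random_word <- function(len, alphabet = letters[1:8]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force candidate scan: distance against every dictionary word.
brute_force_candidates <- function(query, dict, max_distance) {
  words <- names(dict$entries)
  d <- vapply(words, function(w) damerau_levenshtein(query, w), numeric(1))
  sort(words[d <= max_distance])
}

# Independent entity extractor for the NER-evaluator oracle: vectorized run
# segmentation over (type, is_begin) pairs rather than the package's scan.
reference_entities <- function(labels) {
  n <- length(labels)
  if (n == 0L) return(character(0))
  type <- ifelse(labels == "O", NA_character_, sub("^[BI]-", "", labels))
  is_b <- startsWith(labels, "B-")
  seg <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (is.na(type[i])) { seg[i] <- 0L; next }
    new_run <- is_b[i] || i == 1L || is.na(type[i - 1L]) ||
      type[i - 1L] != type[i] || seg[i - 1L] == 0L
    if (new_run) cur <- cur + 1L
    seg[i] <- cur
  }
  keep <- seg > 0L
  if (!any(keep)) return(character(0))
  spans <- split(which(keep), seg[keep])
  vapply(spans, function(ix) {
    paste(type[ix[1L]], min(ix), max(ix), sep = "|")
  }, character(1), USE.NAMES = FALSE)
}

reference_ner_micro <- function(gold, pred) {
  tp <- fp <- fn <- 0L
  for (i in seq_along(gold)) {
    g <- reference_entities(gold[[i]]$labels)
    p <- reference_entities(pred[[i]]$labels)
    tp <- tp + sum(p %in% g)
    fp <- fp + sum(!(p %in% g))
    fn <- fn + sum(!(g %in% p))
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(tp = tp, fp = fp, fn = fn, f1 = f1)
}

random_bio_sentence <- function(n, scheme) {
  labels <- sample(scheme$labels, n, replace = TRUE)
  tagged_sentence(paste0("tok", seq_len(n)), labels, scheme, policy = "repair")
}

# Corrector components trained on the synthetic prose corpus.
prose_corrector <- function(n_train = 600L, seed = 101L, min_count = 1L,
                            order = 3L) {
  train <- generate_prose_corpus(n_train, seed = seed)
  dict <- build_dictionary(train, min_count = min_count)
  list(dict = dict,
       index = build_index(dict, max_distance = 2L),
       scorer = train_ngram_backend(train, order = order),
       train = train)
}
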