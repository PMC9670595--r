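#' Default vocabulary tables for synthetic pathology lines
#'
#' Small tables of clinically plausible terms per entity type (organs,
#' locations, operation names, histologic diagnoses), shipped with the
#' package. Repeated rows act as sampling weights. The terms imitate the
#' structure of lung-cancer pathology result lines only; no real records are
#' reproduced.
#'
#' @return named list of character vectors, one per entity type.
#' @export
spr_vocabulary <- function() {
  path <- system.file("extdata", "spr_vocab.tsv", package = "medspell",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                           col.names = c("type", "term"),
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  split(tab$term, tab$type)
}

#' Specification for the synthetic pathology-record generator
#'
#' @param n_sentences number of lines to generate.
#' @param seed RNG seed; identical specs produce byte-identical corpora.
#' @param vocab named list of term tables (`ORGAN`, `LOCATION`, `OPNAME`,
#'   `HISTOLOGIC DIAGNOSIS`); defaults to [spr_vocabulary()].
#' @param size_range numeric length-2 range the tumor dimensions (cm) are
#'   drawn from.
#' @param ascii_x_prob probability a size uses ASCII `"x"` rather than `"×"`
#'   as its dimension separator.
#' @param greatest_dimension_prob probability a line uses the
#'   `"N cm IN GREATEST DIMENSION"` writer variant instead of
#'   three dimensions.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sentences = 1000L, seed = 7L, vocab = spr_vocabulary(),
                         size_range = c(0.5, 9.9), ascii_x_prob = 0.5,
                         greatest_dimension_prob = 0.05) {
  need <- c("ORGAN", "LOCATION", "OPNAME", "HISTOLOGIC DIAGNOSIS")
  missing <- need[!need %in% names(vocab)]
  if (length(missing) || any(!vapply(vocab[need], length, integer(1)))) {
    stop("fixture vocabulary must provide non-empty tables for: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  stopifnot(n_sentences >= 0, length(size_range) == 2L,
            size_range[1] > 0, diff(size_range) >= 0)
  structure(list(n_sentences = as.integer(n_sentences), seed = as.integer(seed),
                 vocab = vocab, size_range = size_range,
                 ascii_x_prob = ascii_x_prob,
                 greatest_dimension_prob = greatest_dimension_prob),
            class = "fixture_spec")
}

.draw_dim <- function(spec) {
  # one-decimal or integer sizes, as pathology writers use both
  x <- round(stats::runif(1L, spec$size_range[1], spec$size_range[2]), 1L)
  if (stats::runif(1L) < 0.3) as.character(max(1L, round(x))) else sprintf("%.1f", x)
}

#' Generate a synthetic surgical-pathology corpus with gold BIO tags
#'
#' Each line instantiates the template
#' `Organ, Location, OperationName : HistologicDiagnosis, <size>` with slots
#' drawn from the vocabulary tables. The tumor size is a single unspaced
#' token (e.g. `"2.1×1.3×1cm"` or, occasionally, `"1.2cm"` followed by
#' `IN GREATEST DIMENSION`), tagged `B-TUMOR_SIZE`; every size surface parses
#' under [extract_max_dimension()]. Gold labels always validate strictly
#' under the SPR scheme.
#'
#' @param spec a [fixture_spec()].
#' @return list with `tagged` (list of `tagged_sentence` under the SPR
#'   scheme) and `text` (character vector of the plain-text lines).
#' @export
generate_spr_corpus <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  scheme <- tag_scheme("spr")
  slot_tokens <- function(term, type) {
    toks <- strsplit(term, " ", fixed = TRUE)[[1]]
    labs <- c(paste0("B-", type),
              if (length(toks) > 1L) rep(paste0("I-", type), length(toks) - 1L))
    list(tokens = toks, labels = labs)
  }
  tagged <- vector("list", spec$n_sentences)
  text <- character(spec$n_sentences)
  for (i in seq_len(spec$n_sentences)) {
    organ <- slot_tokens(sample(spec$vocab[["ORGAN"]], 1L), "ORGAN")
    loc <- slot_tokens(sample(spec$vocab[["LOCATION"]], 1L), "LOCATION")
    op <- slot_tokens(sample(spec$vocab[["OPNAME"]], 1L), "OPNAME")
    dx <- slot_tokens(sample(spec$vocab[["HISTOLOGIC DIAGNOSIS"]], 1L),
                      "HISTOLOGIC DIAGNOSIS")
    sep <- if (stats::runif(1L) < spec$ascii_x_prob) "x" else "×"
    if (stats::runif(1L) < spec$greatest_dimension_prob) {
      size_toks <- c(paste0(.draw_dim(spec), "cm"), "IN", "GREATEST", "DIMENSION")
      size_labs <- c("B-TUMOR_SIZE", "O", "O", "O")
    } else {
      dims <- c(.draw_dim(spec), .draw_dim(spec), .draw_dim(spec))
      size_toks <- paste0(dims[1], sep, dims[2], sep, dims[3], "cm")
      size_labs <- "B-TUMOR_SIZE"
    }
    toks <- c(organ$tokens, ",", loc$tokens, ",", op$tokens, ":",
              dx$tokens, ",", size_toks)
    labs <- c(organ$labels, "O", loc$labels, "O", op$labels, "O",
              dx$labels, "O", size_labs)
    tagged[[i]] <- tagged_sentence(toks, labs, scheme, policy = "strict")
    text[i] <- paste(toks, collapse = " ")
  }
  list(tagged = tagged, text = text)
}

# Prose templates over a closed vocabulary. Collocations are deliberate: some
# words ("lung", "right", "node") are globally rarer than a near-neighbor
# confuser ("long", "night", "code") yet fully determined by their local
# context, which is exactly the regime where context scoring beats frequency
# ranking.
.PROSE_TEMPLATES <- list(
  list(w = 25, toks = c("long", "term", "follow", "up", "was", "planned",
                        "for", "the", "patient")),
  list(w = 12, toks = c("the", "left", "lung", "was", "removed", "by",
                        "wedge", "resection")),
  list(w = 8, toks = c("the", "right", "lung", "was", "examined", "for",
                       "small", "nodules")),
  list(w = 20, toks = c("the", "patient", "slept", "well", "at", "night",
                        "without", "pain")),
  list(w = 10, toks = c("one", "lymph", "node", "was", "sampled", "from",
                        "the", "chest")),
  list(w = 15, toks = c("the", "code", "was", "recorded", "in", "the",
                        "report", "by", "the", "clerk")),
  list(w = 10, toks = c("margins", "from", "the", "upper", "lobe", "were",
                        "reviewed", "in", "detail")),
  list(w = 10, toks = c("the", "right", "upper", "lobe", "showed", "a",
                        "firm", "lesion")))

#' Generate a synthetic prose corpus for dictionary and language-model training
#'
#' Emits template sentences over a small closed vocabulary with controlled
#' collocations (e.g. "right lung", "upper lobe" are frequent, and a few
#' words are rarer than a spelling-neighbor confuser but determined by
#' context), so the n-gram context backend has learnable signal and
#' context-vs-frequency experiments are well-posed.
#'
#' @param n_sentences number of lines.
#' @param seed RNG seed.
#' @return character vector of sentences, one per element.
#' @export
generate_prose_corpus <- function(n_sentences, seed = 7L) {
  stopifnot(n_sentences >= 0)
  set.seed(as.integer(seed))
  if (n_sentences == 0L) return(character(0))
  w <- vapply(.PROSE_TEMPLATES, `[[`, numeric(1), "w")
  idx <- sample.int(length(.PROSE_TEMPLATES), n_sentences, replace = TRUE,
                    prob = w / sum(w))
  vapply(idx, function(k) paste(.PROSE_TEMPLATES[[k]]$toks, collapse = " "),
         character(1))
}

#' The closed vocabulary of the prose generator
#'
#' @return sorted character vector of every token the prose templates can emit.
#' @export
prose_vocabulary <- function() {
  sort(unique(unlist(lapply(.PROSE_TEMPLATES, `[[`, "toks"))))
}
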