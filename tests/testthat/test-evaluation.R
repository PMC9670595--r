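test_that("correction evaluation matches a hand-counted fixture", {
  # 10 tokens; 4 typos: 3 restored, 1 mis-corrected; 1 clean token wrongly changed
  gold <- "alpha bravo carlo delta echo fox golf hotel india julia"
  records <- data.frame(
    sentence_index = 1L, token_index = c(1L, 2L, 3L, 4L),
    original = c("alpha", "bravo", "carlo", "delta"),
    corrupted = c("alpta", "brevo", "crlo", "deltta"),
    error_type = c("REPLACE", "REPLACE", "DELETE", "INSERT"),
    split_point = 1L, stringsAsFactors = FALSE)
  corrected <- "alpha bravo carlo dutch echo fax golf hotel india julia"
  rep <- evaluate_correction(gold, records, corrected)
  expect_equal(rep$tp, 3)
  expect_equal(rep$fn, 1)
  expect_equal(rep$fp, 2)           # wrong fix of "deltta" + spurious "fax"
  expect_equal(rep$precision, 0.6)
  expect_equal(rep$recall, 0.75)
  expect_equal(rep$f1, 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)
  expect_equal(rep$support, 4)
  expect_equal(rep$per_error_type$REPLACE$tp, 2)
  expect_equal(rep$per_error_type$INSERT$fn, 1)
  expect_equal(rep$per_error_type$INSERT$fp, 1)
})

test_that("degenerate correction outcomes use the zero conventions", {
  gold <- "alpha bravo"
  records <- data.frame(sentence_index = 1L, token_index = 1L,
                        original = "alpha", corrupted = "alpta",
                        error_type = "REPLACE", split_point = 1L,
                        stringsAsFactors = FALSE)
  perfect <- evaluate_correction(gold, records, "alpha bravo")
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  untouched <- evaluate_correction(gold, records, "alpta bravo")
  expect_equal(untouched$tp, 0)
  expect_equal(untouched$fp, 0)     # leaving the typo is a miss, not a false alarm
  expect_equal(c(untouched$precision, untouched$recall, untouched$f1), c(0, 0, 0))
})

test_that("restoration bookkeeping holds on a full corrupt-correct cycle", {
  setup <- prose_corrector(400, seed = 25)
  clean <- generate_prose_corpus(60, seed = 26)
  set.seed(27)
  corr <- corrupt_corpus(clean, rate = 0.12)
  fixed <- correct_corpus(corr$sentences, setup$dict, setup$index, setup$scorer,
                          correction_config())
  rep <- evaluate_correction(clean, corr$records, fixed$sentences)
  expect_equal(rep$tp + rep$fn, rep$support)
  expect_equal(rep$support, nrow(corr$records))
  types_sum <- sum(vapply(rep$per_error_type, `[[`, numeric(1), "support"))
  expect_equal(types_sum, rep$support)
  # f1 recomputed independently from the stored counts
  p <- rep$tp / (rep$tp + rep$fp); r <- rep$tp / (rep$tp + rep$fn)
  expect_equal(rep$f1, 2 * p * r / (p + r), tolerance = 1e-12)
})

test_that("alignment mismatches are reported with coordinates", {
  records <- data.frame(sentence_index = integer(0), token_index = integer(0),
                        original = character(0), corrupted = character(0),
                        error_type = character(0), split_point = integer(0))
  expect_error(evaluate_correction("a b", records, c("a b", "c")), "mismatch")
  expect_error(evaluate_correction("a b c", records, "a b"), "sentence 1")
})

test_that("NER evaluation requires exact span and type matches", {
  spr <- tag_scheme("spr")
  gold <- list(tagged_sentence(c("left", "lung"), c("B-ORGAN", "I-ORGAN"), spr))
  same <- evaluate_ner(gold, gold)
  expect_equal(same$micro$f1, 1)
  expect_equal(same$token_accuracy, 1)

  allo <- list(tagged_sentence(c("left", "lung"), c("O", "O"), spr))
  miss <- evaluate_ner(gold, allo)
  expect_equal(miss$micro$recall, 0)
  expect_equal(miss$per_label$ORGAN$recall, 0)

  partial <- list(tagged_sentence(c("left", "lung"), c("B-ORGAN", "O"), spr))
  p <- evaluate_ner(gold, partial)
  expect_equal(p$micro$f1, 0)      # span mismatch: one fp and one fn
  expect_equal(p$micro$fp, 1)
  expect_equal(p$micro$fn, 1)

  ncbi <- list(tagged_sentence("flu", "B-Disease", tag_scheme("ncbi")))
  expect_error(evaluate_ner(gold, ncbi), "scheme")
})

test_that("NER evaluator agrees with an independent chunk evaluator on random sequences", {
  set.seed(53)
  spr <- tag_scheme("spr")
  for (rep in 1:50) {
    n_sent <- sample(1:3, 1)
    lens <- sample(1:10, n_sent, replace = TRUE)
    gold <- lapply(lens, random_bio_sentence, scheme = spr)
    pred <- lapply(lens, random_bio_sentence, scheme = spr)
    ours <- evaluate_ner(gold, pred)
    ref <- reference_ner_micro(gold, pred)
    expect_equal(ours$micro$tp, ref$tp)
    expect_equal(ours$micro$fp, ref$fp)
    expect_equal(ours$micro$fn, ref$fn)
    expect_equal(ours$micro$f1, ref$f1, tolerance = 1e-12)
  }
})

test_that("the error-rate sweep is reproducible and anchored at rate zero", {
  spr <- tag_scheme("spr")
  fx <- generate_spr_corpus(fixture_spec(80, seed = 33))
  train <- fx$tagged[1:60]; test <- fx$tagged[61:80]
  tg <- train_baseline_tagger(train, spr)
  dict <- build_dictionary(fx$text[1:60], min_count = 1)
  idx <- build_index(dict, 2L)
  scorer <- train_ngram_backend(fx$text[1:60], order = 3)
  tab1 <- sweep_error_rate(test, c(0, 0.1), tg, dict, idx, scorer, seed = 5L)
  tab2 <- sweep_error_rate(test, c(0, 0.1), tg, dict, idx, scorer, seed = 5L)
  expect_identical(tab1, tab2)
  expect_equal(tab1$n_errors[1], 0)
  expect_equal(tab1$ner_f1_with_typos[1], tab1$ner_f1_after_correction[1])
  clean_pred <- lapply(test, function(s) predict_tags(tg, s$tokens))
  expect_equal(tab1$ner_f1_with_typos[1], evaluate_ner(test, clean_pred)$micro$f1)
})
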