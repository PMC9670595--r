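test_that("frequency score is the relative frequency within the candidate set", {
  cand <- data.frame(term = c("A", "B"), count = c(75L, 25L))
  expect_equal(frequency_score(cand), c(A = 0.75, B = 0.25))
  expect_equal(unname(frequency_score(data.frame(term = "A", count = 10L))), 1)
  eq <- frequency_score(data.frame(term = letters[1:4], count = rep(5L, 4)))
  expect_equal(unname(eq), rep(0.25, 4))
  expect_error(frequency_score(data.frame(term = character(0), count = integer(0))),
               "non-empty")
})

test_that("final score is the exact convex combination with valid-lambda guard", {
  expect_equal(final_score(0.8, 0.2, 1), 0.8)
  expect_equal(final_score(0.8, 0.2, 0), 0.2)
  expect_equal(final_score(0.6, 0.4, 0.5), 0.5)
  set.seed(3)
  for (rep in 1:50) {
    f <- runif(1); ctx <- runif(1); l <- runif(1)
    v <- final_score(f, ctx, l)
    expect_equal(v, l * f + (1 - l) * ctx, tolerance = 1e-15)
    expect_gte(v, 0); expect_lte(v, 1)
    # monotone in each score
    expect_gte(final_score(min(f + 0.1, 1), ctx, l), v - 1e-12)
    expect_gte(final_score(f, min(ctx + 0.1, 1), l), v - 1e-12)
  }
  expect_error(final_score(0.5, 0.5, 1.2), "lambda")
  expect_error(correction_config(lambda_weight = -0.1), "lambda")
})

test_that("lambda 1 ranks by raw count and lambda 0 by context ordering", {
  setup <- prose_corrector(300, seed = 61)
  toks <- c("the", "left", "lnug", "was", "removed", "by", "wedge", "resection")
  r1 <- correct_token(toks, 3, setup$dict, setup$index, setup$scorer,
                      correction_config(lambda_weight = 1))
  expect_gt(nrow(r1$candidates), 1)
  expect_identical(r1$candidates$term,
                   r1$candidates$term[order(-r1$candidates$count,
                                            r1$candidates$distance,
                                            r1$candidates$term)])
  r0 <- correct_token(toks, 3, setup$dict, setup$index, setup$scorer,
                      correction_config(lambda_weight = 0))
  expect_identical(r0$candidates$term,
                   r0$candidates$term[order(-r0$candidates$context_score,
                                            r0$candidates$distance,
                                            r0$candidates$term)])
})

test_that("context disambiguates worked correction examples", {
  # dictionary and language model where the relevant collocations are frequent
  extra <- c(rep("the lymph node was sampled from the chest", 8),
             rep("the right lung was examined for small nodules", 8),
             rep("a wedge resection of the left lung was done", 8))
  corpus <- c(generate_prose_corpus(300, seed = 71), extra)
  dict <- build_dictionary(corpus, min_count = 1)
  idx <- build_index(dict, 2L)
  scorer <- train_ngram_backend(corpus, order = 3)
  cfg <- correction_config(lambda_weight = 0.5)
  fix <- function(toks, i) correct_token(toks, i, dict, idx, scorer, cfg)$chosen
  expect_identical(fix(c("of", "the", "righ", "lung"), 3), "right")
  expect_identical(fix(c("the", "lmyph", "node", "was", "sampled"), 2), "lymph")
  expect_identical(fix(c("the", "left", "lug", "was", "removed"), 3), "lung")
  expect_identical(fix(c("a", "wedgoe", "resection", "was", "done"), 2), "wedge")
})

test_that("skip rules leave in-dictionary, short, and non-word tokens unchanged", {
  setup <- prose_corrector(200, seed = 81)
  cfg <- correction_config()
  toks <- c("the", "lung", "x", "2.1", ",")
  for (i in seq_along(toks)) {
    r <- correct_token(toks, i, setup$dict, setup$index, setup$scorer, cfg)
    expect_true(r$skipped)
    expect_false(r$changed)
    expect_equal(nrow(r$candidates), 0)
  }
  # with oov_only FALSE an in-dictionary token is examined, not skipped
  r <- correct_token(toks, 2, setup$dict, setup$index, setup$scorer,
                     correction_config(oov_only = FALSE))
  expect_false(r$skipped)
})

test_that("substitutions inherit the original capitalization pattern", {
  setup <- prose_corrector(200, seed = 91)
  cfg <- correction_config()
  expect_identical(correct_token(c("the", "Lnug", "was"), 2, setup$dict,
                                 setup$index, setup$scorer, cfg)$chosen, "Lung")
  expect_identical(correct_token(c("the", "LNUG", "was"), 2, setup$dict,
                                 setup$index, setup$scorer, cfg)$chosen, "LUNG")
})

test_that("corpus correction is deterministic and leaves clean text untouched", {
  setup <- prose_corrector(300, seed = 15)
  clean <- generate_prose_corpus(40, seed = 16)
  cfg <- correction_config()
  out <- correct_corpus(clean, setup$dict, setup$index, setup$scorer, cfg)
  expect_identical(vapply(out$sentences, `[[`, character(1), "raw"),
                   unname(clean))
  expect_equal(sum(out$results$changed), 0)

  set.seed(44)
  corr <- corrupt_corpus(clean, total_errors = 20L)
  a <- correct_corpus(corr$sentences, setup$dict, setup$index, setup$scorer, cfg)
  b <- correct_corpus(corr$sentences, setup$dict, setup$index, setup$scorer, cfg)
  expect_identical(a$results, b$results)
  expect_identical(lapply(a$sentences, `[[`, "raw"), lapply(b$sentences, `[[`, "raw"))
})

test_that("tokens are scored against the original uncorrected context", {
  # two adjacent typos: each correction must see the other *corrupted* token
  setup <- prose_corrector(300, seed = 18)
  sent <- tokenize_lines("the left lnug wsa removed by wedge resection")
  cfg <- correction_config()
  out <- correct_corpus(sent, setup$dict, setup$index, setup$scorer, cfg)
  trace <- out$results[out$results$changed, ]
  expect_setequal(trace$original, c("lnug", "wsa"))
  expect_setequal(trace$chosen, c("lung", "was"))
})
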