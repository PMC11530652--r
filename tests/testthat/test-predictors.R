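make_bedroom_lm <- function() {
  train_ngram(c("i saw him play in the bedroom",
                "i saw him play in the backyard",
                "i saw him play in the bedroom"), order = 3)
}

test_that("constrained expansion respects segments and recovers both phrases", {
  lm <- make_bedroom_lm()
  ab <- abbreviate_initials("I saw him play in the bedroom")
  out <- expand_constrained(lm, ab, n_options = 5)
  expect_true(all(c("i saw him play in the bedroom",
                    "i saw him play in the backyard") %in% out$phrase))
  expect_true(all(diff(out$score) <= 0))
  expect_true(all(vapply(out$phrase, function(p) abbrev_matches(ab, p),
                         logical(1))))
  # a full keyword pins the final word
  kw <- abbreviate_keywords("i saw him play in the bedroom",
                            data.frame(position = 7, kind = "full"))
  out_kw <- expand_constrained(lm, kw, n_options = 5)
  expect_true(all(grepl("bedroom$", out_kw$phrase)))
  # a position with no consistent vocabulary word signals failure
  zz <- abbreviate_initials("i saw zebras")
  expect_equal(nrow(expand_constrained(lm, zz, n_options = 5)), 0L)
})

test_that("beam search equals exhaustive enumeration on small problems", {
  set.seed(101)
  for (case in 1:60) {
    cs <- random_expansion_case()
    got <- expand_constrained(cs$model, cs$abbrev, n_options = 5,
                              context = cs$context, beam_width = 1e6)
    want <- enum_expand(cs$model, cs$abbrev, 5, context = cs$context)
    expect_identical(got$phrase, want)
  }
})

test_that("every expansion option satisfies its abbreviation (property)", {
  set.seed(77)
  for (case in 1:25) {
    cs <- random_expansion_case()
    # randomly promote a position to a keyword
    ab <- cs$abbrev
    p <- sample.int(length(ab), 1)
    w <- cs$truth[[p]]
    if (nchar(w) >= 2 && stats::runif(1) < 0.7) {
      kind <- sample(c("full", "prefix"), 1)
      lens <- 2:nchar(w)
      len <- if (kind == "prefix") lens[sample.int(length(lens), 1)] else NA
      ab <- abbreviate_keywords(paste(cs$truth, collapse = " "),
                                data.frame(position = p, kind = kind,
                                           length = len))
    }
    out <- expand_constrained(cs$model, ab, n_options = 8)
    for (ph in out$phrase) expect_true(abbrev_matches(ab, ph))
  }
})

test_that("ranked lists have the prefix property in n_options", {
  lm <- make_bedroom_lm()
  ab <- abbreviate_initials("i saw him play in the bedroom")
  full <- expand_constrained(lm, ab, n_options = 10)
  for (n in 1:5) {
    expect_identical(expand_constrained(lm, ab, n_options = n)$phrase,
                     head(full$phrase, n))
  }
  pred <- ngram_predictor(lm)
  full_p <- expand_options(pred, ab, n_options = 10)
  for (n in 1:5) {
    expect_identical(expand_options(pred, ab, n_options = n)$phrase,
                     head(full_p$phrase, n))
  }
})

test_that("context boosting is additive and switchable", {
  lm <- make_bedroom_lm()
  ab <- abbreviate_initials("i saw him play in the backyard")
  ctx <- "we love the backyard"
  # with zero boost, results are invariant to context
  expect_identical(
    expand_constrained(lm, ab, n_options = 5, context = ctx,
                       context_boost = 0),
    expand_constrained(lm, ab, n_options = 5, context_boost = 0)
  )
  # with a boost, the context word overtakes the corpus-frequent one
  boosted <- expand_constrained(lm, ab, n_options = 1, context = ctx,
                                context_boost = 2)
  expect_equal(boosted$phrase, "i saw him play in the backyard")
  plain <- expand_constrained(lm, ab, n_options = 1)
  expect_equal(plain$phrase, "i saw him play in the bedroom")
})

test_that("fill-mask ranks contextually plausible replacements", {
  lm <- train_ngram(c("oh i'm sorry", "oh i'm sure it was fine",
                      "i'm sorry about that", "work was long"), order = 3)
  out <- fill_mask_ngram(lm, c("oh", "i'm", NA), 3, "s")
  expect_equal(out$word[[1]], "sorry")
  # exclusion removes a candidate outright
  out2 <- fill_mask_ngram(lm, c("oh", "i'm", NA), 3, "s",
                          exclude = "sorry")
  expect_false("sorry" %in% out2$word)
  # single candidate returned at rank 1
  out3 <- fill_mask_ngram(lm, c("it", "was", NA), 3, "f")
  expect_equal(out3$word, "fine")
  expect_equal(out3$rank, 1L)
  # no candidate: empty result
  expect_equal(nrow(fill_mask_ngram(lm, c("oh", NA), 2, "z")), 0L)
  # right-neighbour context disambiguates
  lm2 <- train_ngram(c("the big dog barked", "the bad cat barked",
                       "the big cat meowed"), order = 3)
  out4 <- fill_mask_ngram(lm2, c("the", NA, "dog"), 2, "b")
  expect_equal(out4$word[[1]], "big")
})

test_that("forward prediction completes words and suggests next words", {
  lm <- train_ngram(c("in the bedroom", "in the bedroom", "in the backyard"),
                    order = 3)
  expect_true("bedroom" %in% forward_predict(lm, c("in", "the"), "bedr")$word)
  nxt <- forward_predict(lm, c("in", "the"), "")
  expect_equal(nxt$word[[1]], "bedroom")
  expect_equal(nrow(forward_predict(lm, character(), "zzz")), 0L)
})

test_that("the oracle reveals per its configuration and decoys stay consistent", {
  truth <- "I saw him play in the bedroom"
  ab <- abbreviate_initials(truth)
  perfect <- oracle_config(reveal_rank = 1, min_typed_chars = 0)
  out <- oracle_expand(perfect, truth, ab, n_options = 5)
  expect_equal(out$phrase[[1]], "i saw him play in the bedroom")
  adversarial <- oracle_config(min_typed_chars = Inf)
  out2 <- oracle_expand(adversarial, truth, ab, n_options = 5)
  expect_false("i saw him play in the bedroom" %in% out2$phrase)
  # rank-2 reveal
  rank2 <- oracle_config(reveal_rank = 2)
  out3 <- oracle_expand(rank2, truth, ab, n_options = 5)
  expect_equal(out3$phrase[[2]], "i saw him play in the bedroom")
  # near-miss decoy differs from the truth in exactly d words sharing initials
  for (d in 1:2) {
    cfg <- oracle_config(min_typed_chars = Inf, d = d)
    top <- oracle_expand(cfg, truth, ab, n_options = 5)$phrase[[1]]
    tw <- strsplit(top, " ")[[1]]
    rw <- abbrex:::normalize_words(truth)
    expect_equal(sum(tw != rw), d)
    expect_true(all(substr(tw, 1, 1) == substr(rw, 1, 1)))
    expect_true(abbrev_matches(ab, top))
  }
  # oracle options always satisfy the abbreviation, even with keywords
  kw <- abbreviate_keywords(truth, data.frame(position = 7, kind = "prefix",
                                              length = 3))
  out4 <- oracle_expand(oracle_config(min_typed_chars = Inf), truth, kw, 5)
  for (ph in out4$phrase) expect_true(abbrev_matches(kw, ph))
  # fill-mask side
  fm <- oracle_fill_mask(oracle_config(), "sorry", "s", 5)
  expect_equal(fm$word[[1]], "sorry")
  fm2 <- oracle_fill_mask(oracle_config(fm_reveal_rank = Inf), "sorry", "s", 5)
  expect_false("sorry" %in% fm2$word)
  expect_false("small" %in% oracle_fill_mask(oracle_config(), "sorry", "s", 5,
                                             exclude = "small")$word)
})

test_that("predictor caching never changes results", {
  lm <- make_bedroom_lm()
  ab <- abbreviate_initials("i saw him play in the bedroom")
  cached <- ngram_predictor(lm)
  direct <- expand_constrained(lm, ab, n_options = 5,
                               beam_width = cached$beam_width)
  expect_equal(expand_options(cached, ab, 5)$phrase, direct$phrase)
  # second call hits the cache
  expect_equal(expand_options(cached, ab, 5)$phrase, direct$phrase)
  # context distinguishes cache entries
  with_ctx <- expand_options(cached, ab, 5, context = "the backyard rocks")
  expect_false(identical(with_ctx$score, direct$score))
})
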