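test_that("the reference character count follows the text-entry convention", {
  expect_equal(ref_char_count("I saw him playing in the bedroom"), 32L)
  expect_equal(ref_char_count("hi there"), 8L)
  # mid-sentence punctuation counts, sentence-final does not
  expect_equal(ref_char_count("ok, sounds good."), 15L)
  expect_equal(ref_char_count("ok, sounds good.", include_spaces = FALSE), 13L)
})

test_that("best_match picks the candidate with most positionally correct words", {
  ref <- "I saw him play in the bedroom"
  opts <- tibble::tibble(
    phrase = c("i saw him play in the backyard", "it should have been it the b"),
    score = c(-1, -2), rank = 1:2
  )
  bm <- best_match(opts, ref)
  expect_equal(bm$index, 1L)
  expect_equal(bm$incorrect, 7L)
  # the reference itself wins with nothing incorrect
  opts2 <- tibble::tibble(phrase = c("i saw him play in the bedroom"),
                          score = 0, rank = 1)
  expect_length(best_match(opts2, ref)$incorrect, 0L)
  # ties go to the lower rank
  opts3 <- tibble::tibble(phrase = c("i saw her play in the backyard",
                                     "i saw him play in a backyard"),
                          score = c(-1, -1), rank = 1:2)
  expect_equal(best_match(opts3, ref)$index, 1L)
  # a shorter candidate counts the missing tail as incorrect
  opts4 <- tibble::tibble(phrase = "i saw him", score = 0, rank = 1)
  expect_equal(best_match(opts4, ref)$incorrect, 4:7)
  expect_error(best_match(opts4[0, ], ref), "at least one option")
})

test_that("a perfect predictor solves a turn with initials plus one selection", {
  out <- simulate_turn("I saw him playing in the bedroom", oracle_predictor(),
                       sim_config())
  expect_equal(out$solved_by, "INITIALS_ONLY")
  expect_equal(out$total_actions, 8L)  # 7 initials + select
  expect_equal(out$ref_char_count, 32L)
  expect_equal(out$ksr, 0.75)
  expect_equal(out$num_ae_calls, 1L)
  expect_equal(unname(out$ledger[c("key_char", "select_phrase")]), c(7L, 1L))
})

test_that("an adversarial predictor forces the full-spell fallback ledger", {
  adv <- oracle_predictor(oracle_config(min_typed_chars = Inf))
  out <- simulate_turn("hi there", adv,
                       sim_config(strategy = "S1", ae_version = "V1"))
  expect_equal(out$solved_by, "FULL_SPELL")
  # 2 initials + spell-mode + 2 chips + "hi" + "there" + select = 13
  expect_equal(out$total_actions, 13L)
  led <- out$ledger
  expect_equal(unname(led[c("key_char", "spell_mode_enter", "chip_select",
                            "select_phrase")]),
               c(9L, 1L, 2L, 1L))
  expect_equal(out$ksr, 1 - 13 / 8)
  expect_lt(out$ksr, 0)
})

test_that("a near-miss candidate is repaired through fill-mask", {
  nm <- oracle_predictor(oracle_config(min_typed_chars = Inf, d = 1))
  out <- simulate_turn("I saw him play in the bedroom", nm,
                       sim_config(strategy = "S2"))
  expect_equal(out$solved_by, "FILLMASK")
  led <- out$ledger
  expect_equal(unname(led[c("fm_enter", "fm_word_select", "fm_option_select",
                            "key_char", "select_phrase")]),
               c(1L, 1L, 1L, 7L, 1L))
  expect_equal(out$total_actions, 11L)
  expect_equal(out$num_fm_calls, 1L)
  expect_equal(out$ksr, 1 - 11 / 29)
})

test_that("S2A repairs two near-miss words through fill-mask", {
  nm2 <- oracle_predictor(oracle_config(min_typed_chars = Inf, d = 2))
  out <- simulate_turn("I saw him play in the bedroom", nm2,
                       sim_config(strategy = "S2A"))
  expect_equal(out$solved_by, "FILLMASK")
  led <- out$ledger
  # 7 initials + fm mode + 2 word selects + 2 option selects + final select
  expect_equal(unname(led[c("key_char", "fm_enter", "fm_word_select",
                            "fm_option_select", "select_phrase")]),
               c(7L, 1L, 2L, 2L, 1L))
  expect_equal(out$total_actions, 13L)
  # S2 would not enter fill-mask with two incorrect words
  out_s2 <- simulate_turn("I saw him play in the bedroom", nm2,
                          sim_config(strategy = "S2"))
  expect_gte(out_s2$num_fm_calls, 0L)
  expect_true(out_s2$total_actions != out$total_actions ||
                out_s2$solved_by != out$solved_by)
})

test_that("manual triggering charges one action per expansion call", {
  out <- simulate_turn("I saw him playing in the bedroom", oracle_predictor(),
                       sim_config(auto_trigger = FALSE))
  expect_equal(out$total_actions, 9L)  # 7 initials + trigger + select
  expect_equal(unname(out$ledger[["expand_trigger"]]), 1L)
})

test_that("keyword spelling in V1 types whole words and then succeeds", {
  # reveal only after one keyword has been fully spelled
  orc <- oracle_predictor(oracle_config(min_typed_chars = 8, d = 1))
  out <- simulate_turn("I saw him playing in the bedroom", orc,
                       sim_config(strategy = "S1", ae_version = "V1"))
  expect_equal(out$solved_by, "KEYWORD_AE")
  # 7 initials + spell mode + chip + "bedroom" + select = 17
  expect_equal(out$total_actions, 17L)
  expect_equal(out$num_ae_calls, 2L)
})

test_that("V2 appends letters one at a time with a call per keystroke", {
  orc <- oracle_predictor(oracle_config(min_typed_chars = 9, d = 1))
  out <- simulate_turn("I saw him playing in the bedroom", orc,
                       sim_config(strategy = "S1", ae_version = "V2"))
  expect_equal(out$solved_by, "KEYWORD_AE")
  # initials typed = 7 chars; two appended letters reach the 9-char threshold
  expect_equal(unname(out$ledger[["key_char"]]), 9L)
  expect_equal(out$num_ae_calls, 3L)
  expect_equal(out$total_actions, 7L + 2L + 1L + 1L + 1L)
})

test_that("V2 never types more characters than V1 against a monotone oracle", {
  refs <- c("hi there friend", "I saw him play in the bedroom",
            "ok, sounds good")
  for (ref in refs) {
    for (m in c(0, 9, 12, Inf)) {
      orc <- oracle_predictor(oracle_config(min_typed_chars = m, d = 1))
      k1 <- simulate_turn(ref, orc,
                          sim_config(strategy = "S1", ae_version = "V1"))
      k2 <- simulate_turn(ref, orc,
                          sim_config(strategy = "S1", ae_version = "V2"))
      expect_lte(k2$ledger[["key_char"]], k1$ledger[["key_char"]])
    }
  }
})

test_that("KSR identity holds across solve paths (property)", {
  set.seed(31)
  corpus <- generate_dialogues(6, seed = 41)
  configs <- list(
    list(p = oracle_predictor(), cfg = sim_config()),
    list(p = oracle_predictor(oracle_config(min_typed_chars = Inf)),
         cfg = sim_config(strategy = "S1", ae_version = "V1")),
    list(p = oracle_predictor(oracle_config(min_typed_chars = Inf, d = 1)),
         cfg = sim_config(strategy = "S2"))
  )
  for (cs in configs) {
    rep <- run_simulation(corpus, cs$p, cs$cfg)
    out <- tidy(rep)
    actions <- out$key_char + out$select_phrase + out$spell_mode_enter +
      out$chip_select + out$fm_enter + out$fm_word_select +
      out$fm_option_select + out$expand_trigger + out$baseline_option_select
    expect_equal(out$total_actions, actions)
    expect_equal(out$ksr, 1 - out$total_actions / out$ref_char_count)
    expect_true(all(out$ksr <= 1))
  }
})

test_that("adversarial runs terminate in full spelling on every turn", {
  corpus <- generate_dialogues(5, seed = 77)
  adv <- oracle_predictor(oracle_config(min_typed_chars = Inf))
  rep <- run_simulation(corpus, adv,
                        sim_config(strategy = "S1", ae_version = "V1"))
  expect_true(all(tidy(rep)$solved_by == "FULL_SPELL"))
  expect_equal(rep$single_call_fraction, 0)
  # perfect oracle: everything solved by the single initials-only call
  rep2 <- run_simulation(corpus, oracle_predictor(), sim_config())
  expect_equal(rep2$single_call_fraction, 1)
  expect_true(all(tidy(rep2)$num_ae_calls == 1L))
})

test_that("a predictor succeeding on alternate turns yields a half fraction", {
  parity <- structure(list(), class = c("parity_predictor",
                                        "abbrex_predictor"))
  counter <- new.env()
  counter$i <- 0L
  registerS3method("expand_options", "parity_predictor",
                   function(predictor, abbrev, n_options = 5,
                            context = character(), truth = NULL) {
                     # an initials-only query marks the start of a new turn;
                     # even turns succeed immediately, odd turns only after
                     # keyword spelling begins
                     if (all(abbrev$kind == "initial")) {
                       counter$i <- counter$i + 1L
                       cfg <- if (counter$i %% 2L == 0L) {
                         oracle_config()
                       } else {
                         oracle_config(min_typed_chars = Inf)
                       }
                     } else {
                       cfg <- oracle_config()
                     }
                     oracle_expand(cfg, truth, abbrev, n_options)
                   },
                   envir = environment(expand_options))
  registerS3method("fill_mask_options", "parity_predictor",
                   function(predictor, words, slot, initial, n_options = 5,
                            exclude = character(), context = character(),
                            truth_word = NULL) {
                     oracle_fill_mask(oracle_config(), truth_word, initial,
                                      n_options, exclude)
                   },
                   envir = environment(expand_options))
  corpus <- generate_dialogues(4, seed = 9)
  rep <- run_simulation(corpus, parity,
                        sim_config(strategy = "S2", ae_version = "V1"))
  expect_equal(rep$single_call_fraction, 0.5)
})

test_that("the forward-prediction baseline accounts keystrokes exactly", {
  never <- train_ngram("qq zz", order = 1)
  out <- simulate_baseline_turn("this test works fine", never)
  expect_equal(out$total_actions, out$ref_char_count)
  expect_equal(out$ksr, 0)
  trained <- train_ngram("this test works fine", order = 3)
  out2 <- simulate_baseline_turn("this test works fine", trained)
  # every word commits via next-word prediction: 4 selections
  expect_equal(out2$total_actions, 4L)
  expect_equal(out2$ksr, 1 - 4 / 20)
  expect_gt(out2$ksr, 0.5)
  expect_error(simulate_baseline_turn("hi", never, n_options = 0),
               "at least 1")
  # punctuated words: the mark and following space are typed literally
  lmp <- train_ngram("ok sounds good", order = 3)
  out3 <- simulate_baseline_turn("ok, sounds good", lmp)
  # 3 selections + comma + space after "ok,"
  expect_equal(out3$total_actions, 5L)
})

test_that("keystroke savings are monotone in the number of options", {
  corpus <- generate_dialogues(20, seed = 15)
  train <- generate_dialogues(60, seed = 16)
  pred <- ngram_predictor(train_ngram(corpus_sentences(train), order = 3))
  sw <- sweep_n_options(corpus, pred, sim_config(strategy = "S2", seed = 2),
                        n_options = c(1, 3, 5, 8))
  expect_false(is.unsorted(sw$mean_ksr))
  expect_false(is.unsorted(sw$single_call_fraction))
  expect_s3_class(sw, "abbrex_sweep")
})

test_that("simulation runs are deterministic and context-aware", {
  corpus <- generate_dialogues(6, seed = 3)
  train <- generate_dialogues(30, seed = 4)
  pred <- ngram_predictor(train_ngram(corpus_sentences(train), order = 3))
  r1 <- run_simulation(corpus, pred, sim_config(seed = 5))
  r2 <- run_simulation(corpus, pred, sim_config(seed = 5))
  expect_identical(tidy(r1), tidy(r2))
  expect_error(run_simulation(corpus[0, ], pred, sim_config()),
               "no turns remain")
})

test_that("time projection is a linear combination of ledger counts", {
  out <- simulate_turn("I saw him playing in the bedroom", oracle_predictor(),
                       sim_config())
  zero <- project_time(out, cost_params(0, 0, 0, 0))
  expect_equal(sum(zero$ms), 0)
  keys_only <- project_time(out, cost_params(keystroke_ms = 100,
                                             ui_action_ms = 0,
                                             option_review_ms = 0,
                                             call_latency_ms = 0))
  expect_equal(sum(keys_only$ms), 100 * out$ledger[["key_char"]])
  base <- project_time(out, cost_params(500, 500, 400, 600))
  doubled <- project_time(out, cost_params(1000, 1000, 800, 1200))
  expect_equal(sum(doubled$ms), 2 * sum(base$ms))
  expect_equal(attr(base, "total_ms"), sum(base$ms))
})

test_that("reports tidy, glance, plot and serialize", {
  corpus <- generate_dialogues(3, seed = 8)
  rep <- run_simulation(corpus, oracle_predictor(), sim_config())
  g <- glance(rep)
  expect_equal(g$n_turns, 18L)
  expect_equal(g$mean_ksr, mean(tidy(rep)$ksr))
  expect_s3_class(autoplot(rep), "ggplot")
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  summary <- read.delim(file.path(dir, "summary.tsv"))
  expect_equal(summary$mean_ksr, rep$mean_ksr)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_length(js$outcomes, 18L)
})
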