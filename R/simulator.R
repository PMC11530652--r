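action_kinds <- c("key_char", "select_phrase", "spell_mode_enter",
                  "chip_select", "fm_enter", "fm_word_select",
                  "fm_option_select", "expand_trigger",
                  "baseline_option_select")

new_ledger <- function() setNames(integer(length(action_kinds)), action_kinds)

#' Simulation configuration
#'
#' Controls the ideal-user interaction simulator. The three strategies differ
#' in how they recover when the initials-only expansion misses the intended
#' phrase: `"S1"` keeps spelling keywords; `"S2"` switches to fill-mask word
#' replacement as soon as the best-matching candidate has exactly one
#' incorrect word; `"S2A"` switches as soon as two or fewer words are
#' incorrect. Keyword spelling itself depends on the expansion model version:
#' `"V1"` requires each keyword typed in full (one prediction call per typed
#' keyword), `"V2"` appends one letter at a time to the first incorrect word
#' with a prediction call after every keystroke.
#'
#' @param strategy `"S1"`, `"S2"` or `"S2A"`.
#' @param ae_version `"V1"` or `"V2"`.
#' @param n_options Number of prediction options shown at each step.
#' @param use_context Whether prior dialogue turns are passed to the
#'   predictor.
#' @param auto_trigger If `TRUE` (the default), prediction calls are triggered
#'   automatically after keystrokes and cost no motor action; if `FALSE`, each
#'   call costs one `expand_trigger` action.
#' @param max_turn_length Maximum turn length simulated (see
#'   [filter_by_length()]).
#' @param seed Seed for any stochastic predictor; recorded in reports.
#' @param include_spaces Whether interior spaces count in the reference
#'   character total (the keystroke-saving denominator). The default follows
#'   the standard text-entry convention: spaces and mid-sentence punctuation
#'   count, sentence-final punctuation does not.
#' @return A `sim_config` list.
#' @export
sim_config <- function(strategy = c("S2", "S1", "S2A"),
                       ae_version = c("V2", "V1"),
                       n_options = 5, use_context = TRUE, auto_trigger = TRUE,
                       max_turn_length = 10, seed = NULL,
                       include_spaces = TRUE) {
  strategy <- match.arg(strategy)
  ae_version <- match.arg(ae_version)
  stopifnot(n_options >= 1, max_turn_length >= 1)
  structure(
    list(strategy = strategy, ae_version = ae_version,
         n_options = as.integer(n_options), use_context = use_context,
         auto_trigger = auto_trigger,
         max_turn_length = as.integer(max_turn_length), seed = seed,
         include_spaces = include_spaces),
    class = "sim_config"
  )
}

#' Reference character count (keystroke-saving denominator)
#'
#' The number of characters a user would type without any assistance: the
#' words of the phrase with their mid-sentence punctuation, joined by single
#' spaces, with sentence-final punctuation excluded.
#'
#' @param phrase The reference phrase.
#' @param include_spaces Count the joining spaces?
#' @inheritParams abbreviate_initials
#' @return An integer.
#' @examples
#' ref_char_count("I saw him playing in the bedroom")  # 32
#' @export
ref_char_count <- function(phrase, include_spaces = TRUE,
                           convention = punct_convention()) {
  tok <- phrase_tokens(phrase, convention)
  n <- sum(nchar(tok$core)) + sum(nchar(tok$punct))
  if (include_spaces) n <- n + tok$n - 1L
  as.integer(n)
}

#' Best-matching candidate for a reference phrase
#'
#' Picks the option maximizing the number of position-wise, case-insensitive
#' word matches with the reference (compared over the shorter of the two word
#' lists; reference positions beyond a shorter candidate count as incorrect).
#' Ties prefer a candidate with the same word count as the reference, then the
#' lower rank.
#'
#' @param options A ranked-phrase tibble (non-empty).
#' @param reference The intended phrase.
#' @inheritParams abbreviate_initials
#' @return A list with `index` (row of the winner), `words` (the winner's
#'   words), and `incorrect` (1-based reference positions the winner gets
#'   wrong).
#' @export
best_match <- function(options, reference, convention = punct_convention()) {
  if (nrow(options) == 0L) {
    abort("best_match needs at least one option")
  }
  best_match_words(options$phrase, normalize_words(reference, convention))
}

# best_match against precomputed reference words (hot path).
best_match_words <- function(phrases, ref) {
  n_ref <- length(ref)
  stats <- lapply(phrases, function(p) {
    w <- strsplit(tolower(p), " ", fixed = TRUE)[[1]]
    m <- min(length(w), n_ref)
    eq <- if (m > 0) w[seq_len(m)] == ref[seq_len(m)] else logical()
    list(n_match = sum(eq), same_len = length(w) == n_ref, words = w,
         incorrect = c(which(!eq), if (n_ref > m) (m + 1L):n_ref))
  })
  n_match <- vapply(stats, `[[`, numeric(1), "n_match")
  same_len <- vapply(stats, `[[`, logical(1), "same_len")
  best <- order(-n_match, -same_len, seq_along(stats))[[1]]
  list(index = best, words = stats[[best]]$words,
       incorrect = stats[[best]]$incorrect)
}

# Predictor phrases are lowercase cores joined by single spaces, so equality
# with the reference reduces to a string comparison.
any_matches_reference <- function(phrases, ref_phrase) {
  any(tolower(phrases) == ref_phrase)
}

make_outcome <- function(reference, ledger, solved_by, ref_chars, num_ae_calls,
                         num_fm_calls, options_reviewed) {
  total <- sum(ledger)
  structure(
    list(reference = reference, ledger = ledger, solved_by = solved_by,
         ref_char_count = ref_chars, total_actions = total,
         num_ae_calls = num_ae_calls, num_fm_calls = num_fm_calls,
         options_reviewed = options_reviewed,
         ksr = 1 - total / ref_chars),
    class = "turn_outcome"
  )
}

#' @export
print.turn_outcome <- function(x, ...) {
  cat(sprintf("<turn_outcome> '%s'\n  solved_by %s, %d actions / %d chars, KSR %.3f\n",
              x$reference, x$solved_by, x$total_actions, x$ref_char_count,
              x$ksr))
  invisible(x)
}

#' Simulate an ideal user entering one dialogue turn
#'
#' Runs the abbreviated-entry state machine: type the initials-only
#' abbreviation, call the expansion predictor, and if the intended phrase is
#' not among the options recover by keyword spelling (and, under strategies
#' S2/S2A, fill-mask word replacement) until the phrase is committed. Motor
#' actions (keystrokes plus UI actions: mode entries, chip and option
#' selections) are tallied in an action ledger, from which the
#' keystroke-saving rate `ksr = 1 - total_actions / ref_char_count` is
#' computed.
#'
#' @param reference The phrase the simulated user intends to enter.
#' @param predictor An `abbrex_predictor`.
#' @param config A [sim_config()].
#' @param context Character vector of prior dialogue turns (earliest first).
#' @return A `turn_outcome` with the ledger, the solve path
#'   (`INITIALS_ONLY`, `KEYWORD_AE`, `FILLMASK` or `FULL_SPELL`), call counts
#'   and KSR.
#' @examples
#' out <- simulate_turn("I saw him playing in the bedroom",
#'                      oracle_predictor(), sim_config())
#' out$ksr  # 0.75: 7 typed initials + 1 selection vs 32 characters
#' @export
simulate_turn <- function(reference, predictor, config = sim_config(),
                          context = character()) {
  stopifnot(inherits(config, "sim_config"))
  convention <- punct_convention()
  tok <- phrase_tokens(reference, convention)
  if (!any(grepl("[[:alpha:]]", tok$core))) {
    abort("reference phrase contains no alphabetic word")
  }
  if (turn_length(reference, convention) > config$max_turn_length) {
    abort("reference turn exceeds config$max_turn_length")
  }
  ref_words <- tok$core
  n_words <- length(ref_words)
  ref_chars <- ref_char_count(reference, config$include_spaces, convention)
  ctx <- if (config$use_context) context else character()
  ledger <- new_ledger()
  ae_calls <- 0L
  fm_calls <- 0L
  reviewed <- 0L

  abbrev <- abbreviate_initials(reference, convention)
  ledger[["key_char"]] <- ledger[["key_char"]] +
    nchar(render_abbreviation(abbrev, "compact"))

  call_ae <- function() {
    ae_calls <<- ae_calls + 1L
    if (!config$auto_trigger) {
      ledger[["expand_trigger"]] <<- ledger[["expand_trigger"]] + 1L
    }
    opts <- expand_options(predictor, abbrev, config$n_options, ctx,
                           truth = reference)
    reviewed <<- reviewed + nrow(opts)
    opts
  }
  finish <- function(solved_by) {
    make_outcome(reference, ledger, solved_by, ref_chars, ae_calls, fm_calls,
                 reviewed)
  }

  ref_phrase <- paste(ref_words, collapse = " ")
  opts <- call_ae()
  if (nrow(opts) > 0L && any_matches_reference(opts$phrase, ref_phrase)) {
    ledger[["select_phrase"]] <- ledger[["select_phrase"]] + 1L
    return(finish("INITIALS_ONLY"))
  }

  threshold <- switch(config$strategy, S1 = 0L, S2 = 1L, S2A = 2L)
  in_spell_mode <- FALSE
  current_chip <- 0L
  # typed prefix per word; starts at the initial for every position
  typed_len <- rep(1L, n_words)
  fully_spelled <- function() all(typed_len >= nchar(ref_words))

  run_fillmask <- function(cand_words, incorrect) {
    # entering fill-mask mode = clicking the near-miss phrase, once per turn
    ledger[["fm_enter"]] <<- ledger[["fm_enter"]] + 1L
    cand <- cand_words
    length(cand) <- n_words  # pad with NA if the candidate was shorter
    for (p in sort(incorrect)) {
      ledger[["fm_word_select"]] <<- ledger[["fm_word_select"]] + 1L
      fm_calls <<- fm_calls + 1L
      wrong <- cand[[p]]
      ropts <- fill_mask_options(
        predictor, words = cand, slot = p, initial = tok$initial[[p]],
        n_options = config$n_options,
        exclude = if (is.na(wrong)) character() else wrong,
        context = ctx, truth_word = ref_words[[p]]
      )
      reviewed <<- reviewed + nrow(ropts)
      if (ref_words[[p]] %in% ropts$word) {
        ledger[["fm_option_select"]] <<- ledger[["fm_option_select"]] + 1L
      } else {
        # fall back to typing the correct word in the input box
        ledger[["key_char"]] <<- ledger[["key_char"]] + nchar(ref_words[[p]])
      }
      cand[[p]] <- ref_words[[p]]
    }
    ledger[["select_phrase"]] <<- ledger[["select_phrase"]] + 1L
  }

  repeat {
    # establish the incorrect positions from the latest options
    if (nrow(opts) > 0L) {
      bm <- best_match_words(opts$phrase, ref_words)
      incorrect <- bm$incorrect
      cand_words <- bm$words
    } else {
      incorrect <- which(typed_len < nchar(ref_words))
      cand_words <- NULL
    }
    if (threshold > 0L && !is.null(cand_words) &&
        length(incorrect) >= 1L && length(incorrect) <= threshold) {
      run_fillmask(cand_words, incorrect)
      return(finish("FILLMASK"))
    }
    if (fully_spelled()) {
      ledger[["select_phrase"]] <- ledger[["select_phrase"]] + 1L
      return(finish("FULL_SPELL"))
    }
    # leftmost incorrect, not yet fully spelled, word
    todo <- incorrect[typed_len[incorrect] < nchar(ref_words[incorrect])]
    if (length(todo) == 0L) {
      # every disagreeing position is already fully constrained; the
      # remaining unspelled words must be spelled out
      todo <- which(typed_len < nchar(ref_words))
    }
    p <- min(todo)
    if (!in_spell_mode) {
      ledger[["spell_mode_enter"]] <- ledger[["spell_mode_enter"]] + 1L
      in_spell_mode <- TRUE
    }
    if (current_chip != p) {
      ledger[["chip_select"]] <- ledger[["chip_select"]] + 1L
      current_chip <- p
    }
    if (config$ae_version == "V1") {
      # the chip becomes an empty input box: the whole keyword is typed,
      # with one prediction call afterwards
      ledger[["key_char"]] <- ledger[["key_char"]] + nchar(ref_words[[p]])
      typed_len[[p]] <- nchar(ref_words[[p]])
    } else {
      # append a single letter, prediction call after every keystroke
      ledger[["key_char"]] <- ledger[["key_char"]] + 1L
      typed_len[[p]] <- typed_len[[p]] + 1L
    }
    if (fully_spelled()) {
      ledger[["select_phrase"]] <- ledger[["select_phrase"]] + 1L
      return(finish("FULL_SPELL"))
    }
    abbrev <- keyword_abbreviation(tok, typed_len)
    opts <- call_ae()
    if (nrow(opts) > 0L && any_matches_reference(opts$phrase, ref_phrase)) {
      ledger[["select_phrase"]] <- ledger[["select_phrase"]] + 1L
      return(finish("KEYWORD_AE"))
    }
  }
}

# Abbreviation for the current spelling state: positions with typed_len == 1
# stay initials; longer prefixes become prefix keywords, complete words become
# full keywords.
keyword_abbreviation <- function(tok, typed_len) {
  kind <- ifelse(typed_len <= 1L, "initial",
                 ifelse(typed_len >= nchar(tok$core), "full", "prefix"))
  typed <- ifelse(typed_len <= 1L, tok$initial,
                  substr(tok$core, 1L, typed_len))
  new_abbreviation(kind, typed, tok$punct)
}

#' Simulate the forward-prediction baseline for one turn
#'
#' Emulates a conventional predictive keyboard: the ideal user types left to
#' right and selects the intended word as soon as it appears among the top-n
#' word completions or next-word predictions. Selecting a word commits it plus
#' one following space in a single action (no space after the final word);
#' words carrying mid-sentence punctuation have the punctuation, and the
#' following space, typed literally.
#'
#' @param reference The phrase to enter.
#' @param model An `abbrex_lm`.
#' @param n_options Number of prediction slots.
#' @param context Prior dialogue turns (unused by the forward baseline; kept
#'   for interface symmetry).
#' @param include_spaces Denominator convention, as in [ref_char_count()].
#' @return A `turn_outcome` with `solved_by = "FORWARD_PREDICTION"`.
#' @export
simulate_baseline_turn <- function(reference, model, n_options = 5,
                                   context = character(),
                                   include_spaces = TRUE) {
  if (n_options < 1) {
    abort("n_options must be at least 1")
  }
  convention <- punct_convention()
  tok <- phrase_tokens(reference, convention)
  ref_words <- tok$core
  n_words <- length(ref_words)
  ref_chars <- ref_char_count(reference, include_spaces, convention)
  ledger <- new_ledger()
  reviewed <- 0L
  committed <- character()
  for (i in seq_len(n_words)) {
    word <- ref_words[[i]]
    prefix <- ""
    repeat {
      opts <- forward_predict(model, committed, prefix, n_options)
      reviewed <- reviewed + nrow(opts)
      if (word %in% opts$word) {
        ledger[["baseline_option_select"]] <-
          ledger[["baseline_option_select"]] + 1L
        sel_includes_space <- !nzchar(tok$punct[[i]]) && i < n_words
        if (!sel_includes_space) {
          extra <- nchar(tok$punct[[i]]) +
            (if (include_spaces && i < n_words) 1L else 0L)
          ledger[["key_char"]] <- ledger[["key_char"]] + extra
        }
        break
      }
      ledger[["key_char"]] <- ledger[["key_char"]] + 1L
      prefix <- substr(word, 1L, nchar(prefix) + 1L)
      if (identical(prefix, word)) {
        extra <- nchar(tok$punct[[i]]) +
          (if (include_spaces && i < n_words) 1L else 0L)
        ledger[["key_char"]] <- ledger[["key_char"]] + extra
        break
      }
    }
    committed <- c(committed, word)
  }
  make_outcome(reference, ledger, "FORWARD_PREDICTION", ref_chars,
               num_ae_calls = 0L, num_fm_calls = 0L,
               options_reviewed = reviewed)
}

outcome_row <- function(outcome, dialogue_id, turn) {
  tibble::new_tibble(c(
    list(dialogue_id = dialogue_id, turn = turn,
         reference = outcome$reference,
         solved_by = outcome$solved_by,
         total_actions = outcome$total_actions,
         ref_char_count = outcome$ref_char_count,
         ksr = outcome$ksr,
         num_ae_calls = outcome$num_ae_calls,
         num_fm_calls = outcome$num_fm_calls,
         options_reviewed = outcome$options_reviewed),
    as.list(outcome$ledger)
  ), nrow = 1L)
}

#' Run a simulation over a dialogue corpus
#'
#' Applies the turn-length filter, rebuilds each turn's conversational context
#' from the preceding turns of its dialogue, simulates every remaining turn
#' with [simulate_turn()] and aggregates the outcomes.
#'
#' @param corpus A corpus tibble.
#' @param predictor An `abbrex_predictor`.
#' @param config A [sim_config()].
#' @return An `abbrex_report`: per-turn outcomes plus the mean KSR and the
#'   single-call fraction (turns solved by the first initials-only prediction
#'   call).
#' @export
run_simulation <- function(corpus, predictor, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  keep <- filter_by_length(corpus, config$max_turn_length)
  if (nrow(keep) == 0L) {
    abort("no turns remain after length filtering")
  }
  with_seed(config$seed, {
    rows <- vector("list", nrow(keep))
    for (i in seq_len(nrow(keep))) {
      did <- keep$dialogue_id[[i]]
      t <- keep$turn[[i]]
      context <- corpus$text[corpus$dialogue_id == did & corpus$turn < t]
      out <- simulate_turn(keep$text[[i]], predictor, config, context)
      rows[[i]] <- outcome_row(out, did, t)
    }
    outcomes <- dplyr::bind_rows(rows)
    new_report(outcomes, config)
  })
}

new_report <- function(outcomes, config) {
  structure(
    list(
      outcomes = outcomes,
      config = config,
      n_turns = nrow(outcomes),
      mean_ksr = mean(outcomes$ksr),
      single_call_fraction = mean(outcomes$solved_by == "INITIALS_ONLY" &
                                    outcomes$num_ae_calls == 1L)
    ),
    class = "abbrex_report"
  )
}

#' Run the forward-prediction baseline over a corpus
#'
#' @param corpus A corpus tibble.
#' @param model An `abbrex_lm`.
#' @param n_options Number of prediction slots.
#' @param max_turn_length Turn-length filter, as in [run_simulation()].
#' @return An `abbrex_report`.
#' @export
run_baseline <- function(corpus, model, n_options = 5, max_turn_length = 10) {
  keep <- filter_by_length(corpus, max_turn_length)
  if (nrow(keep) == 0L) {
    abort("no turns remain after length filtering")
  }
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    out <- simulate_baseline_turn(keep$text[[i]], model, n_options)
    outcome_row(out, keep$dialogue_id[[i]], keep$turn[[i]])
  })
  cfg <- sim_config(n_options = max(n_options, 1),
                    max_turn_length = max_turn_length)
  cfg$strategy <- "BASELINE"
  cfg$ae_version <- NA_character_
  cfg$use_context <- FALSE
  new_report(dplyr::bind_rows(rows), cfg)
}

#' Sweep the number of prediction options
#'
#' Re-runs a simulation for each value of `n_options`, reusing the same
#' predictor (whose ranked lists are prefix-stable in the number of options),
#' and returns one summary row per run.
#'
#' @param corpus A corpus tibble.
#' @param predictor An `abbrex_predictor`.
#' @param config A [sim_config()] whose `n_options` is overridden.
#' @param n_options Integer vector of option counts.
#' @return A tibble of class `abbrex_sweep` with columns `n_options`,
#'   `strategy`, `ae_version`, `use_context`, `mean_ksr`,
#'   `single_call_fraction`, `n_turns`.
#' @export
sweep_n_options <- function(corpus, predictor, config = sim_config(),
                            n_options = 1:10) {
  rows <- lapply(n_options, function(n) {
    cfg <- config
    cfg$n_options <- as.integer(n)
    glance(run_simulation(corpus, predictor, cfg))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("abbrex_sweep", class(out))
  out
}

#' Per-action time costs
#'
#' Unit costs, in milliseconds, for projecting a turn outcome onto wall-clock
#' time. This is plumbing for what-if analysis (e.g. eye-gaze keystrokes are
#' several times slower than touch keystrokes while option review time is
#' similar); it fits no empirical timing model.
#'
#' @param keystroke_ms Cost per typed character.
#' @param ui_action_ms Cost per UI action (mode entries, chip and option
#'   selections, manual triggers).
#' @param option_review_ms Cost per prediction option reviewed.
#' @param call_latency_ms Latency per prediction call.
#' @return A `cost_params` list.
#' @export
cost_params <- function(keystroke_ms = 500, ui_action_ms = 500,
                        option_review_ms = 400, call_latency_ms = 600) {
  stopifnot(keystroke_ms >= 0, ui_action_ms >= 0, option_review_ms >= 0,
            call_latency_ms >= 0)
  structure(list(keystroke_ms = keystroke_ms, ui_action_ms = ui_action_ms,
                 option_review_ms = option_review_ms,
                 call_latency_ms = call_latency_ms),
            class = "cost_params")
}

#' Project a turn outcome onto time
#'
#' Linear combination of the outcome's ledger counts, call counts and options
#' reviewed with the unit costs in `costs`.
#'
#' @param outcome A `turn_outcome`.
#' @param costs A [cost_params()].
#' @return A tibble with one row per category (`keystrokes`, `ui_actions`,
#'   `option_review`, `call_latency`) and their `ms`, plus a `total_ms`
#'   attribute; `sum(project_time(...)$ms)` is the projected total.
#' @export
project_time <- function(outcome, costs = cost_params()) {
  stopifnot(inherits(outcome, "turn_outcome"), inherits(costs, "cost_params"))
  led <- outcome$ledger
  keystrokes <- led[["key_char"]] * costs$keystroke_ms
  ui <- sum(led[setdiff(names(led), "key_char")]) * costs$ui_action_ms
  review <- outcome$options_reviewed * costs$option_review_ms
  latency <- (outcome$num_ae_calls + outcome$num_fm_calls) *
    costs$call_latency_ms
  out <- tibble::tibble(
    category = c("keystrokes", "ui_actions", "option_review", "call_latency"),
    ms = c(keystrokes, ui, review, latency)
  )
  attr(out, "total_ms") <- sum(out$ms)
  out
}
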