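#' Count the length of a dialogue turn
#'
#' Turn length is the number of whitespace-delimited words plus the number of
#' mid-sentence punctuation marks; sentence-final punctuation does not count.
#' This is the quantity the length-10 turn filter operates on.
#'
#' @param text Character vector of turn texts.
#' @inheritParams abbreviate_initials
#' @return Integer vector of lengths.
#' @examples
#' turn_length("ok, sounds good")  # 3 words + 1 comma = 4
#' @export
turn_length <- function(text, convention = punct_convention()) {
  vapply(text, function(x) {
    tok <- phrase_tokens(x, convention)
    tok$n + sum(nchar(tok$punct))
  }, integer(1), USE.NAMES = FALSE)
}

#' Keep only dialogue turns up to a maximum length
#'
#' Filters the turn rows of a corpus tibble by [turn_length()], preserving
#' order and the `dialogue_id`/`turn` keys needed to rebuild each turn's
#' conversational context.
#'
#' @param corpus A corpus tibble as returned by [generate_dialogues()] or
#'   [read_dialogues()].
#' @param max_len Maximum turn length (words plus mid-sentence punctuation).
#' @inheritParams abbreviate_initials
#' @return The filtered corpus tibble.
#' @export
filter_by_length <- function(corpus, max_len = 10,
                             convention = punct_convention()) {
  stopifnot(max_len >= 1)
  corpus[turn_length(corpus$text, convention) <= max_len, , drop = FALSE]
}

#' Configuration for the synthetic dialogue generator
#'
#' The generator emits six-turn, two-speaker dialogues from a small template
#' grammar (an opener question followed by statements and follow-up
#' questions). Content words (nouns) are drawn from a built-in lexicon;
#' `word_reuse_prob` controls how often a noun slot is filled by a noun
#' already used earlier in the same dialogue, which is the mechanism that
#' makes conversational context informative.
#'
#' @param vocabulary_size Number of distinct nouns available to a corpus.
#' @param max_turn_length Maximum turn length (words plus mid-sentence
#'   punctuation); templates that would exceed it are never used.
#' @param word_reuse_prob Probability that a noun slot in turns 2-6 reuses a
#'   noun from an earlier turn of the same dialogue.
#' @param n_turns Turns per dialogue.
#' @return A `generator_config` list.
#' @export
generator_config <- function(vocabulary_size = 72, max_turn_length = 10,
                             word_reuse_prob = 0.5, n_turns = 6) {
  if (max_turn_length < 1) {
    abort("max_turn_length must be at least 1")
  }
  stopifnot(vocabulary_size >= 1, vocabulary_size <= length(.abbrex_nouns),
            word_reuse_prob >= 0, word_reuse_prob <= 1, n_turns >= 1)
  structure(
    list(vocabulary_size = as.integer(vocabulary_size),
         max_turn_length = as.integer(max_turn_length),
         word_reuse_prob = word_reuse_prob,
         n_turns = as.integer(n_turns)),
    class = "generator_config"
  )
}

fill_template <- function(template, pick_noun) {
  vapply(template$tokens, function(tok) {
    switch(tok,
      P = sample(.abbrex_pronouns, 1L),
      V = sample(.abbrex_verbs, 1L),
      D = sample(.abbrex_dets, 1L),
      R = sample(.abbrex_preps, 1L),
      N = pick_noun(),
      tok
    )
  }, character(1), USE.NAMES = FALSE)
}

template_max_length <- function(template, convention) {
  # template length is fixed: slots are single words
  n_words <- length(template$tokens)
  n_commas <- sum(grepl(",$", template$tokens))
  n_words + n_commas
}

#' Generate a seeded synthetic dialogue corpus
#'
#' Emits `n_dialogues` dialogues of alternating speakers A and B. Generation
#' is a pure function of `(n_dialogues, seed, config)`. Every turn satisfies
#' `turn_length(text) <= config$max_turn_length`.
#'
#' @param n_dialogues Number of dialogues.
#' @param seed Integer seed.
#' @param config A [generator_config()].
#' @return A corpus tibble with columns `dialogue_id`, `turn`, `speaker`,
#'   `text`.
#' @examples
#' corpus <- generate_dialogues(2, seed = 7)
#' corpus
#' @export
generate_dialogues <- function(n_dialogues, seed,
                               config = generator_config()) {
  stopifnot(n_dialogues >= 1)
  if (!inherits(config, "generator_config")) {
    abort("`config` must be created with generator_config()")
  }
  convention <- punct_convention()
  with_seed(seed, {
    vocab <- sort(sample(.abbrex_nouns, config$vocabulary_size))
    openers <- Filter(function(t) {
      template_max_length(t, convention) <= config$max_turn_length
    }, .abbrex_openers)
    statements <- Filter(function(t) {
      template_max_length(t, convention) <= config$max_turn_length
    }, .abbrex_statements)
    rows <- vector("list", n_dialogues * config$n_turns)
    k <- 0L
    for (d in seq_len(n_dialogues)) {
      did <- sprintf("dlg-%04d", d)
      used_nouns <- character()
      for (t in seq_len(config$n_turns)) {
        # the reuse pool holds nouns from *earlier* turns only, so that full
        # reuse (probability 1) guarantees every content word of turns 2+ was
        # already said
        turn_nouns <- character()
        pick_noun <- function() {
          w <- if (t > 1L && length(used_nouns) > 0L &&
                   stats::runif(1) < config$word_reuse_prob) {
            sample(used_nouns, 1L)
          } else {
            sample(vocab, 1L)
          }
          turn_nouns <<- unique(c(turn_nouns, w))
          w
        }
        pool <- if (t == 1L && length(openers) > 0L) openers else statements
        text <- if (length(pool) == 0L) {
          pick_noun()
        } else {
          tmpl <- pool[[sample.int(length(pool), 1L)]]
          words <- fill_template(tmpl, pick_noun)
          paste0(paste(words, collapse = " "), tmpl$end)
        }
        used_nouns <- union(used_nouns, turn_nouns)
        # capitalize the sentence
        substr(text, 1L, 1L) <- toupper(substr(text, 1L, 1L))
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          dialogue_id = did, turn = t,
          speaker = if (t %% 2L == 1L) "A" else "B",
          text = text
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

corpus_schema <- "abbrex-dialogue-v1"

#' Read a dialogue corpus from JSONL
#'
#' Expects one dialogue per line in the dialect
#' `{"schema":"abbrex-dialogue-v1","dialogue_id":...,"turns":[{"speaker":"A","text":...},...]}`.
#' Malformed lines raise an error naming the line number; duplicate dialogue
#' ids are an error; non-alternating speakers produce a warning (real
#' transcripts are tolerated), while the package's own writers always
#' alternate.
#'
#' @param path Path to a JSONL corpus file.
#' @return A corpus tibble with columns `dialogue_id`, `turn`, `speaker`,
#'   `text`.
#' @export
read_dialogues <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("corpus file '%s' does not exist", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  seen <- character()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$dialogue_id) || is.null(rec$turns)) {
      abort(sprintf("line %d of '%s' is not a valid dialogue record", i, path))
    }
    if (!is.null(rec$schema) && !identical(rec$schema, corpus_schema)) {
      abort(sprintf("line %d declares unsupported schema '%s'", i, rec$schema))
    }
    turns <- rec$turns
    if (!is.data.frame(turns) || !all(c("speaker", "text") %in% names(turns)) ||
        nrow(turns) < 1L) {
      abort(sprintf("line %d of '%s' is not a valid dialogue record", i, path))
    }
    text <- trimws(turns$text)
    if (any(!nzchar(text))) {
      abort(sprintf("line %d: empty turn text", i))
    }
    if (!all(turns$speaker %in% c("A", "B"))) {
      abort(sprintf("line %d: speakers must be 'A' or 'B'", i))
    }
    if (rec$dialogue_id %in% seen) {
      abort(sprintf("duplicate dialogue_id '%s' at line %d", rec$dialogue_id, i))
    }
    seen <- c(seen, rec$dialogue_id)
    if (nrow(turns) > 1L &&
        any(turns$speaker[-1] == turns$speaker[-nrow(turns)])) {
      warn(sprintf("dialogue '%s' has non-alternating speakers", rec$dialogue_id))
    }
    rows[[i]] <- tibble::tibble(
      dialogue_id = rec$dialogue_id,
      turn = seq_len(nrow(turns)),
      speaker = turns$speaker,
      text = text
    )
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(dialogue_id = character(), turn = integer(),
                          speaker = character(), text = character()))
  }
  dplyr::bind_rows(rows)
}

#' Write a dialogue corpus to JSONL
#'
#' @param corpus A corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dialogues <- function(corpus, path) {
  ids <- unique(corpus$dialogue_id)
  lines <- vapply(ids, function(id) {
    d <- corpus[corpus$dialogue_id == id, , drop = FALSE]
    d <- d[order(d$turn), , drop = FALSE]
    jsonlite::toJSON(list(
      schema = corpus_schema,
      dialogue_id = id,
      turns = data.frame(speaker = d$speaker, text = d$text,
                         stringsAsFactors = FALSE)
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Lowercase punctuation-stripped words of a text, for language-model training
# and scoring.
normalize_words <- function(text, convention = punct_convention()) {
  phrase_tokens(text, convention)$core
}

#' Flatten a corpus into normalized training sentences
#'
#' Each turn becomes one sentence of lowercase, punctuation-stripped words --
#' the form consumed by [train_ngram()].
#'
#' @param corpus A corpus tibble.
#' @inheritParams abbreviate_initials
#' @return A character vector, one sentence per turn.
#' @export
corpus_sentences <- function(corpus, convention = punct_convention()) {
  vapply(corpus$text, function(x) {
    paste(normalize_words(x, convention), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
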