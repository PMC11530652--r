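# Context is represented everywhere as a character vector of prior turn
# texts (earliest first); predictors only use the set of normalized words.
context_word_set <- function(context, convention = punct_convention()) {
  if (length(context) == 0L) return(character())
  unique(unlist(lapply(context, normalize_words, convention = convention),
                use.names = FALSE))
}

# Vocabulary words consistent with one abbreviation segment.
segment_candidates <- function(vocab, kind, typed, vocab_initials,
                               vocab_skeletons) {
  switch(kind,
    initial = vocab[vocab_initials == typed],
    full = vocab[vocab == typed],
    prefix = vocab[startsWith(vocab, typed)],
    consonant = vocab[startsWith(vocab_skeletons, typed)],
    abort(sprintf("unknown segment kind '%s'", kind))
  )
}

ranked_phrases <- function(phrase = character(), score = numeric()) {
  tibble::new_tibble(list(phrase = phrase, score = score,
                          rank = seq_along(phrase)), nrow = length(phrase))
}

ranked_words <- function(word = character(), score = numeric()) {
  tibble::new_tibble(list(word = word, score = score,
                          rank = seq_along(word)), nrow = length(word))
}

# Order by score (descending), breaking ties lexicographically, so every
# ranking in the package is deterministic.
order_ranked <- function(labels, scores) {
  order(-scores, labels, method = "radix")
}

#' Expand an abbreviation by constrained beam search over an n-gram model
#'
#' Performs left-to-right beam search with one step per word position. At
#' position `i` the candidate set is the vocabulary words consistent with
#' segment `i` of the abbreviation (same semantics as [abbrev_matches()]).
#' Hypotheses are scored by summed n-gram log scores, plus `context_boost`
#' (natural log units) for every word that occurs in the prior dialogue turns.
#' Returned phrases are lowercase and punctuation-free; reference casing and
#' trailing punctuation are reattached by the interaction simulator, not here.
#'
#' @param model An `abbrex_lm`.
#' @param abbrev An `abbreviation`.
#' @param n_options Maximum number of ranked phrases to return.
#' @param context Character vector of prior turn texts (earliest first).
#' @param beam_width Beam width; hypotheses kept per step is
#'   `max(beam_width, n_options)`.
#' @param context_boost Additive log-score bonus per word present in the
#'   context.
#' @return A tibble with columns `phrase`, `score`, `rank` (scores
#'   non-increasing). Empty (zero rows) when some position admits no
#'   vocabulary word, which signals predictor failure to the simulator.
#' @export
expand_constrained <- function(model, abbrev, n_options = 5,
                               context = character(), beam_width = 16,
                               context_boost = 0.5) {
  stopifnot(inherits(model, "abbrex_lm"), inherits(abbrev, "abbreviation"),
            n_options >= 1)
  vocab <- model$vocab
  vocab_initials <- substr(vocab, 1L, 1L)
  vocab_skeletons <- consonant_skeleton(vocab)
  ctx <- context_word_set(context)
  width <- max(beam_width, n_options)
  cand_sets <- lapply(seq_along(abbrev$kind), function(i) {
    segment_candidates(vocab, abbrev$kind[[i]], abbrev$typed[[i]],
                       vocab_initials, vocab_skeletons)
  })
  if (any(lengths(cand_sets) == 0L)) {
    return(ranked_phrases())
  }
  hmax <- model$order - 1L
  log_alpha <- log(model$alpha)
  # beam state: phrase string, cumulative score, and the last-j-words key
  # string for each backoff order j (maintained incrementally)
  phrases <- ""
  scores <- 0
  tails <- lapply(seq_len(hmax), function(j) {
    paste(rep("<s>", j), collapse = " ")
  })
  for (cands in cand_sets) {
    nb <- length(phrases)
    nc <- length(cands)
    idx_b <- rep(seq_len(nb), each = nc)
    idx_c <- rep.int(seq_len(nc), nb)
    cand_rep <- cands[idx_c]
    step <- rep(NA_real_, nb * nc)
    if (hmax >= 1L) {
      for (j in seq(hmax, 1L)) {
        open <- is.na(step)
        if (!any(open)) break
        keys <- paste(tails[[j]][idx_b[open]], cand_rep[open])
        vals <- unlist(mget(keys, envir = model$logp, ifnotfound = NA_real_),
                       use.names = FALSE)
        hit <- !is.na(vals)
        step[which(open)[hit]] <- vals[hit] + (hmax - j) * log_alpha
      }
    }
    open <- is.na(step)
    if (any(open)) {
      uni <- unlist(mget(cands, envir = model$logp, ifnotfound = NA_real_),
                    use.names = FALSE)
      uni[is.na(uni)] <- -Inf
      step[open] <- uni[idx_c[open]] + hmax * log_alpha
    }
    boosts <- context_boost * (cands %in% ctx)
    tot <- scores[idx_b] + step + boosts[idx_c]
    new_phrases <- if (nb == 1L && !nzchar(phrases[[1]])) {
      cand_rep
    } else {
      paste(phrases[idx_b], cand_rep)
    }
    keep <- head(order_ranked(new_phrases, tot), width)
    old_tails <- tails
    kept_b <- idx_b[keep]
    kept_c <- cand_rep[keep]
    if (hmax >= 1L) {
      tails[[1L]] <- kept_c
      for (j in seq_len(hmax)[-1]) {
        tails[[j]] <- paste(old_tails[[j - 1L]][kept_b], kept_c)
      }
    }
    phrases <- new_phrases[keep]
    scores <- tot[keep]
  }
  keep <- head(order_ranked(phrases, scores), n_options)
  ranked_phrases(phrases[keep], scores[keep])
}

#' Rank replacement words for a masked slot
#'
#' Candidates are the vocabulary words sharing the required initial letter,
#' minus `exclude`. Each candidate is scored by the n-gram score of the word
#' given its left neighbours plus the score of the right neighbour given a
#' history that includes the candidate (skipped when the slot is final), plus
#' `context_boost` if the candidate occurs in the prior turns.
#'
#' @param model An `abbrex_lm`.
#' @param words Character vector of the phrase's words (lowercase cores); the
#'   entry at `slot` is ignored.
#' @param slot 1-based index of the masked word.
#' @param initial Required initial letter.
#' @param n_options Maximum number of ranked words.
#' @param exclude Words never to propose (e.g. the rejected candidate).
#' @inheritParams expand_constrained
#' @return A tibble with columns `word`, `score`, `rank`; empty when no
#'   candidate exists.
#' @export
fill_mask_ngram <- function(model, words, slot, initial, n_options = 5,
                            exclude = character(), context = character(),
                            context_boost = 0.5) {
  stopifnot(inherits(model, "abbrex_lm"), slot >= 1, slot <= length(words),
            grepl("^[[:alpha:]]$", initial))
  initial <- tolower(initial)
  cands <- setdiff(model$vocab[substr(model$vocab, 1L, 1L) == initial],
                   tolower(exclude))
  if (length(cands) == 0L) {
    return(ranked_words())
  }
  ctx <- context_word_set(context)
  left <- if (slot > 1L) words[seq_len(slot - 1L)] else character()
  scores <- lm_next_scores(model, left, cands)
  if (slot < length(words) && !is.na(words[[slot + 1L]])) {
    scores <- scores + lm_right_scores(model, left, cands,
                                       words[[slot + 1L]])
  }
  scores <- scores + context_boost * (cands %in% ctx)
  keep <- head(order_ranked(cands, scores), n_options)
  ranked_words(cands[keep], scores[keep])
}

#' Forward word completion and next-word prediction
#'
#' The baseline predictive-keyboard primitive. With an empty `prefix` the top
#' vocabulary words by n-gram score given the committed history are returned
#' (next-word prediction); with a non-empty prefix only words having that
#' prefix are ranked (word completion).
#'
#' @param model An `abbrex_lm`.
#' @param committed Character vector of words already committed.
#' @param prefix Characters typed so far of the current word (may be `""`).
#' @param n_options Maximum number of ranked words.
#' @inheritParams expand_constrained
#' @return A tibble with columns `word`, `score`, `rank`.
#' @export
forward_predict <- function(model, committed, prefix = "", n_options = 5,
                            context = character(), context_boost = 0) {
  stopifnot(inherits(model, "abbrex_lm"), n_options >= 1)
  cands <- if (nzchar(prefix)) {
    model$vocab[startsWith(model$vocab, tolower(prefix))]
  } else {
    model$vocab
  }
  if (length(cands) == 0L) {
    return(ranked_words())
  }
  scores <- lm_next_scores(model, committed, cands)
  if (context_boost != 0) {
    scores <- scores + context_boost * (cands %in% context_word_set(context))
  }
  keep <- head(order_ranked(cands, scores), n_options)
  ranked_words(cands[keep], scores[keep])
}

#' Oracle predictor configuration
#'
#' The oracle is a test instrument: a predictor whose behaviour is fully
#' controlled. It returns the true phrase at `reveal_rank` once the
#' abbreviation carries at least `min_typed_chars` typed characters, and fills
#' the remaining slots with decoy phrases that still satisfy the abbreviation.
#' `near_miss` decoys replace exactly `d` words of the truth with different
#' words sharing their constraints; `random` decoys perturb a random number of
#' positions. Its fill-mask side reveals the true word at `fm_reveal_rank`.
#' Use `min_typed_chars = Inf` for an adversarial oracle that never succeeds
#' (forcing the full-spell fallback), and `fm_reveal_rank = Inf` for a
#' fill-mask that never contains the intended word.
#'
#' @param reveal_rank 1-based rank at which the truth appears (must be
#'   `<= n_options` to be observable).
#' @param min_typed_chars Typed characters required before the oracle
#'   "succeeds".
#' @param decoys `"near_miss"` or `"random"`.
#' @param d Number of word substitutions in a near-miss decoy.
#' @param fm_reveal_rank Rank of the true word in fill-mask responses.
#' @return An `oracle_config` list.
#' @export
oracle_config <- function(reveal_rank = 1, min_typed_chars = 0,
                          decoys = c("near_miss", "random"), d = 1,
                          fm_reveal_rank = 1) {
  decoys <- match.arg(decoys)
  stopifnot(reveal_rank >= 1, min_typed_chars >= 0, d >= 1,
            fm_reveal_rank >= 1)
  structure(
    list(reveal_rank = reveal_rank, min_typed_chars = min_typed_chars,
         decoys = decoys, d = as.integer(d), fm_reveal_rank = fm_reveal_rank),
    class = "oracle_config"
  )
}

# Deterministic decoy word for one segment: the `variant`-th lexicon word
# consistent with the segment's constraint and different from the truth word.
decoy_word <- function(kind, typed, truth_word, variant = 1L) {
  pool <- switch(kind,
    initial = .abbrex_decoy_words[startsWith(.abbrex_decoy_words, typed)],
    full = character(),  # a full keyword admits no alternative
    prefix = .abbrex_decoy_words[startsWith(.abbrex_decoy_words, typed)],
    consonant = .abbrex_decoy_words[
      startsWith(consonant_skeleton(.abbrex_decoy_words), typed)
    ]
  )
  pool <- sort(setdiff(pool, truth_word))
  if (length(pool) >= variant) {
    return(pool[[variant]])
  }
  if (kind == "full") {
    return(NA_character_)
  }
  # fabricate a distinct word still satisfying the constraint
  if (kind == "consonant") {
    paste0(substr(typed, 1L, 1L),
           paste(rep("o", variant), collapse = ""),
           substr(typed, 2L, nchar(typed)))
  } else {
    paste0(typed, paste(rep("z", variant + 1L), collapse = ""))
  }
}

#' Oracle phrase expansion
#'
#' @param config An [oracle_config()].
#' @param truth The intended phrase.
#' @param abbrev The typed `abbreviation`.
#' @param n_options Number of options to return.
#' @param context Prior turn texts (unused; present for contract symmetry).
#' @return A ranked-phrase tibble; every option satisfies the abbreviation.
#' @export
oracle_expand <- function(config, truth, abbrev, n_options = 5,
                          context = character()) {
  stopifnot(inherits(config, "oracle_config"),
            inherits(abbrev, "abbreviation"))
  truth_words <- normalize_words(truth)
  n_words <- length(truth_words)
  typed_chars <- sum(nchar(abbrev$typed))
  succeed <- typed_chars >= config$min_typed_chars
  # positions where the constraint still admits an alternative word
  open_pos <- which(abbrev$kind != "full")
  make_decoy <- function(variant) {
    n_sub <- if (config$decoys == "near_miss") {
      min(config$d, length(open_pos))
    } else {
      if (length(open_pos) == 0L) 0L else 1L + (variant %% length(open_pos))
    }
    if (n_sub == 0L) return(NULL)
    pos <- tail(open_pos, n_sub)
    words <- truth_words
    for (p in pos) {
      w <- decoy_word(abbrev$kind[[p]], abbrev$typed[[p]], truth_words[[p]],
                      variant)
      if (is.na(w)) return(NULL)
      words[[p]] <- w
    }
    paste(words, collapse = " ")
  }
  options <- character()
  variant <- 0L
  truth_phrase <- paste(truth_words, collapse = " ")
  while (length(options) < n_options && variant < n_options + 6L) {
    variant <- variant + 1L
    d <- make_decoy(variant)
    if (!is.null(d) && !(d %in% options) && d != truth_phrase) {
      options <- c(options, d)
    }
  }
  if (succeed && config$reveal_rank <= n_options) {
    at <- min(config$reveal_rank - 1L, length(options))
    options <- append(options, truth_phrase, after = at)
  }
  options <- head(options, n_options)
  ranked_phrases(options, score = 1 / seq_along(options))
}

#' Oracle fill-mask
#'
#' @inheritParams oracle_expand
#' @param truth_word The intended word for the masked slot.
#' @param initial Required initial letter.
#' @param exclude Words never to propose.
#' @return A ranked-word tibble.
#' @export
oracle_fill_mask <- function(config, truth_word, initial, n_options = 5,
                             exclude = character()) {
  stopifnot(inherits(config, "oracle_config"))
  pool <- .abbrex_decoy_words[startsWith(.abbrex_decoy_words, tolower(initial))]
  pool <- sort(setdiff(pool, c(truth_word, exclude)))
  if (length(pool) < n_options) {
    pool <- c(pool, paste0(tolower(initial),
                           strrep("z", seq_len(n_options))))
  }
  words <- head(pool, n_options)
  rank <- config$fm_reveal_rank
  if (rank <= n_options) {
    words <- head(append(head(words, rank - 1L), truth_word,
                         after = rank - 1L), n_options)
  }
  ranked_words(words, score = 1 / seq_along(words))
}

# ---- predictor contract -----------------------------------------------------

#' Predictor objects
#'
#' A predictor bundles the two prediction services the simulator consumes:
#' phrase expansion of an abbreviation and fill-mask word replacement, both
#' returning ranked options. `ngram_predictor()` wraps an n-gram model (beam
#' search + fill-mask scoring, with an internal memo cache keyed by
#' abbreviation and context so repeated queries are free);
#' `oracle_predictor()` wraps an [oracle_config()] and needs to be told the
#' truth, which the simulator supplies.
#'
#' @param model An `abbrex_lm`.
#' @param beam_width Beam width for [expand_constrained()].
#' @param context_boost Context bonus in natural-log units; set 0 to ignore
#'   dialogue context.
#' @param n_best Number of options computed and cached per query; requests for
#'   fewer options are served as prefixes of the same ranked list, which is
#'   what makes keystroke savings monotone in the number of options shown.
#' @return A predictor object.
#' @export
ngram_predictor <- function(model, beam_width = 16, context_boost = 0.5,
                            n_best = 10) {
  stopifnot(inherits(model, "abbrex_lm"))
  structure(
    list(model = model, beam_width = beam_width,
         context_boost = context_boost, n_best = n_best,
         cache = new.env(parent = emptyenv(), hash = TRUE)),
    class = c("ngram_predictor", "abbrex_predictor")
  )
}

#' @rdname ngram_predictor
#' @param config An [oracle_config()].
#' @export
oracle_predictor <- function(config = oracle_config()) {
  structure(list(config = config),
            class = c("oracle_predictor", "abbrex_predictor"))
}

#' Expand an abbreviation through a predictor
#'
#' @param predictor An `abbrex_predictor`.
#' @param abbrev An `abbreviation`.
#' @param n_options Number of options requested.
#' @param context Prior turn texts.
#' @param truth The intended phrase (used by oracle predictors; ignored by
#'   model-backed ones).
#' @return A ranked-phrase tibble.
#' @export
expand_options <- function(predictor, abbrev, n_options = 5,
                           context = character(), truth = NULL) {
  UseMethod("expand_options")
}

#' @export
expand_options.ngram_predictor <- function(predictor, abbrev, n_options = 5,
                                           context = character(),
                                           truth = NULL) {
  n_compute <- max(predictor$n_best, n_options)
  key <- paste(render_abbreviation(abbrev, "spaced"),
               paste(abbrev$kind, collapse = ","),
               paste(context, collapse = "\r"), sep = "\n")
  hit <- get0(key, envir = predictor$cache)
  if (is.null(hit) || (attr(hit, "n_computed") < n_compute &&
                       nrow(hit) == attr(hit, "n_computed"))) {
    hit <- expand_constrained(predictor$model, abbrev, n_options = n_compute,
                              context = context,
                              beam_width = predictor$beam_width,
                              context_boost = predictor$context_boost)
    attr(hit, "n_computed") <- n_compute
    assign(key, hit, envir = predictor$cache)
  }
  n_out <- min(nrow(hit), n_options)
  idx <- seq_len(n_out)
  ranked_phrases(hit$phrase[idx], hit$score[idx])
}

#' @export
expand_options.oracle_predictor <- function(predictor, abbrev, n_options = 5,
                                            context = character(),
                                            truth = NULL) {
  if (is.null(truth)) {
    abort("the oracle predictor needs the true phrase")
  }
  oracle_expand(predictor$config, truth, abbrev, n_options, context)
}

#' Fill a masked word slot through a predictor
#'
#' @inheritParams expand_options
#' @param words The candidate phrase's words (lowercase cores).
#' @param slot 1-based masked position.
#' @param initial Required initial letter.
#' @param exclude Words never to propose.
#' @param truth_word The intended word (used by oracle predictors).
#' @return A ranked-word tibble.
#' @export
fill_mask_options <- function(predictor, words, slot, initial, n_options = 5,
                              exclude = character(), context = character(),
                              truth_word = NULL) {
  UseMethod("fill_mask_options")
}

#' @export
fill_mask_options.ngram_predictor <- function(predictor, words, slot, initial,
                                              n_options = 5,
                                              exclude = character(),
                                              context = character(),
                                              truth_word = NULL) {
  fill_mask_ngram(predictor$model, words, slot, initial,
                  n_options = n_options, exclude = exclude, context = context,
                  context_boost = predictor$context_boost)
}

#' @export
fill_mask_options.oracle_predictor <- function(predictor, words, slot,
                                               initial, n_options = 5,
                                               exclude = character(),
                                               context = character(),
                                               truth_word = NULL) {
  if (is.null(truth_word)) {
    abort("the oracle predictor needs the true word")
  }
  oracle_fill_mask(predictor$config, truth_word, initial, n_options, exclude)
}
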