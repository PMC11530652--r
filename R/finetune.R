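#' Configuration for training-triplet synthesis
#'
#' Controls which shorthand schemes are emitted for abbreviation-expansion
#' (AE) triplets and how keywords are sampled. Defaults: every turn yields an
#' initials-only triplet plus, per additional scheme, one variant with one or
#' two keywords at uniformly sampled positions; prefix lengths are uniform on
#' `{2, ..., word length - 1}` and consonant lengths uniform on
#' `{2, ..., skeleton length}`. These sampling distributions are deliberate
#' package defaults and are exposed here rather than hard-coded.
#'
#' @param schemes Subset of `c("initials", "complete", "prefix",
#'   "consonant")`.
#' @param keywords_per_variant Candidate keyword counts; one is drawn
#'   uniformly per variant.
#' @param include_no_context Also emit a no-context copy of each fill-mask
#'   triplet that has context.
#' @param masks_per_turn Masked-word triplets emitted per turn (capped by the
#'   number of maskable words).
#' @param seed Seed for keyword and mask sampling.
#' @return A `synthesis_config` list.
#' @export
synthesis_config <- function(schemes = c("initials", "complete", "prefix",
                                         "consonant"),
                             keywords_per_variant = 1:2,
                             include_no_context = TRUE,
                             masks_per_turn = 1, seed = 1) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  stopifnot(all(keywords_per_variant >= 1), masks_per_turn >= 1)
  structure(
    list(schemes = schemes, keywords_per_variant = keywords_per_variant,
         include_no_context = include_no_context,
         masks_per_turn = as.integer(masks_per_turn), seed = seed),
    class = "synthesis_config"
  )
}

# sample() treats a length-1 numeric first argument as 1:x; this helper does
# not.
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# Prior turns serialized with curly-brace delimiters: "{turn 1} {turn 2}".
# Empty for the first turn of a dialogue.
context_string <- function(prior_texts) {
  if (length(prior_texts) == 0L) return("")
  paste0("{", prior_texts, "}", collapse = " ")
}

#' Synthesize abbreviation-expansion training triplets
#'
#' For every turn of every dialogue, emits a
#' `{context, shorthand, full phrase}` triplet per configured scheme. The
#' context is the concatenation of the turn's preceding turns, each wrapped in
#' curly braces (empty for first turns); the shorthand is in the spaced
#' dialect of [render_abbreviation()]. Every emitted shorthand validates
#' against its full phrase.
#'
#' @param corpus A corpus tibble.
#' @param config A [synthesis_config()].
#' @return A tibble with columns `dialogue_id`, `turn`, `scheme`, `context`,
#'   `shorthand`, `full`.
#' @export
synthesize_ae <- function(corpus, config = synthesis_config()) {
  stopifnot(nrow(corpus) > 0L)
  convention <- punct_convention()
  with_seed(config$seed, {
    rows <- list()
    for (i in seq_len(nrow(corpus))) {
      text <- corpus$text[[i]]
      did <- corpus$dialogue_id[[i]]
      t <- corpus$turn[[i]]
      ctx <- context_string(corpus$text[corpus$dialogue_id == did &
                                          corpus$turn < t])
      tok <- phrase_tokens(text, convention)
      emit <- function(scheme, abbrev) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          dialogue_id = did, turn = t, scheme = scheme, context = ctx,
          shorthand = render_abbreviation(abbrev, "spaced"), full = text
        )
      }
      if ("initials" %in% config$schemes) {
        emit("initials", abbreviate_initials(text, convention))
      }
      for (scheme in setdiff(config$schemes, "initials")) {
        eligible <- switch(scheme,
          complete = seq_len(tok$n),
          prefix = which(nchar(tok$core) >= 3L),
          consonant = which(nchar(consonant_skeleton(tok$core)) >= 2L)
        )
        if (length(eligible) == 0L) next
        n_kw <- sample1(config$keywords_per_variant)
        pos <- sort(eligible[sample.int(length(eligible),
                                        min(n_kw, length(eligible)))])
        len <- vapply(pos, function(p) {
          switch(scheme,
            complete = NA_integer_,
            prefix = as.integer(sample1(2:(nchar(tok$core[[p]]) - 1L))),
            consonant = {
              ns <- nchar(consonant_skeleton(tok$core[[p]]))
              if (ns == 2L) 2L else as.integer(sample1(2:ns))
            }
          )
        }, integer(1))
        kind <- switch(scheme, complete = "full", prefix = "prefix",
                       consonant = "consonant")
        ab <- abbreviate_keywords(
          text, data.frame(position = pos, kind = kind, length = len),
          convention
        )
        emit(scheme, ab)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Synthesize fill-mask training triplets
#'
#' For every turn, masks sampled words as their initial letter plus an
#' underscore (surrounding words and punctuation intact) and emits
#' `{context, phrase with mask, word}` triplets. Words starting with a digit
#' or punctuation mark are never masked; turns with no maskable word are
#' skipped, with the skip count available as the `"skipped"` attribute. When
#' `include_no_context` is set, each triplet with context is also emitted with
#' an empty context.
#'
#' @inheritParams synthesize_ae
#' @return A tibble with columns `dialogue_id`, `turn`, `context`,
#'   `phrase_with_mask`, `word`.
#' @export
synthesize_fillmask <- function(corpus, config = synthesis_config()) {
  stopifnot(nrow(corpus) > 0L)
  convention <- punct_convention()
  with_seed(config$seed, {
    rows <- list()
    skipped <- 0L
    for (i in seq_len(nrow(corpus))) {
      text <- corpus$text[[i]]
      did <- corpus$dialogue_id[[i]]
      t <- corpus$turn[[i]]
      raw <- strsplit(trimws(text), "\\s+")[[1]]
      tok <- phrase_tokens(text, convention)
      if (tok$n != length(raw)) {
        # pure-punctuation tokens were merged; positional masking would be
        # ambiguous, skip such turns
        skipped <- skipped + 1L
        next
      }
      maskable <- which(grepl("^[[:alpha:]]", tok$word))
      if (length(maskable) == 0L) {
        skipped <- skipped + 1L
        next
      }
      pos <- sort(maskable[sample.int(length(maskable),
                                      min(config$masks_per_turn,
                                          length(maskable)))])
      ctx <- context_string(corpus$text[corpus$dialogue_id == did &
                                          corpus$turn < t])
      for (p in pos) {
        masked_tok <- sub(tok$word[[p]],
                          paste0(substr(tok$word[[p]], 1L, 1L), "_"),
                          raw[[p]], fixed = TRUE)
        phrase <- raw
        phrase[[p]] <- masked_tok
        row <- tibble::tibble(
          dialogue_id = did, turn = t, context = ctx,
          phrase_with_mask = paste(phrase, collapse = " "),
          word = tok$word[[p]]
        )
        rows[[length(rows) + 1L]] <- row
        if (config$include_no_context && nzchar(ctx)) {
          row$context <- ""
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "skipped") <- skipped
    out
  })
}

#' Write training triplets to disk
#'
#' `"jsonl"` writes one JSON object per triplet
#' (`{"context":...,"shorthand":...,"full":...}` for AE triplets,
#' `{"context":...,"phrase_with_mask":...,"word":...}` for fill-mask ones).
#' `"lamda_text"` writes the concatenated plain-text layout used for language
#' model fine-tuning, e.g.
#' `Context: {...} Phrase: {Oh, I'm s_.} Word: {sorry}`.
#'
#' @param triplets A tibble from [synthesize_ae()] or [synthesize_fillmask()].
#' @param path Output path.
#' @param format `"jsonl"` or `"lamda_text"`.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(triplets, path, format = c("jsonl", "lamda_text")) {
  format <- match.arg(format)
  is_ae <- "shorthand" %in% names(triplets)
  lines <- if (nrow(triplets) == 0L) {
    character()
  } else if (format == "jsonl") {
    vapply(seq_len(nrow(triplets)), function(i) {
      rec <- if (is_ae) {
        list(context = triplets$context[[i]],
             shorthand = triplets$shorthand[[i]],
             full = triplets$full[[i]])
      } else {
        list(context = triplets$context[[i]],
             phrase_with_mask = triplets$phrase_with_mask[[i]],
             word = triplets$word[[i]])
      }
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
    }, character(1))
  } else if (is_ae) {
    sprintf("Context: %s Shorthand: {%s} Full: {%s}",
            ifelse(nzchar(triplets$context), triplets$context, "{}"),
            triplets$shorthand, triplets$full)
  } else {
    sprintf("Context: %s Phrase: {%s} Word: {%s}",
            ifelse(nzchar(triplets$context), triplets$context, "{}"),
            triplets$phrase_with_mask, triplets$word)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read training triplets from JSONL
#'
#' @param path Path written by [write_triplets()] with `format = "jsonl"`.
#' @return A triplet tibble (without the corpus bookkeeping columns).
#' @export
read_triplets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(context = character(), shorthand = character(),
                          full = character()))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  dplyr::bind_rows(lapply(recs, tibble::as_tibble))
}
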