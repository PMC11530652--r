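#' Punctuation convention for abbreviation and word counting
#'
#' The shorthand schemes preserve mid-sentence punctuation (most commonly the
#' comma) inside abbreviations and drop sentence-final punctuation. Which
#' characters belong to which class is configurable; the two sets must be
#' disjoint.
#'
#' @param mid_sentence Characters treated as mid-sentence punctuation, kept in
#'   abbreviations and counted towards turn length.
#' @param sentence_final Characters treated as sentence-final punctuation,
#'   dropped from abbreviations and from the keystroke-saving denominator.
#' @return An object of class `punct_convention`.
#' @examples
#' punct_convention()
#' @export
punct_convention <- function(mid_sentence = c(",", ";", ":"),
                             sentence_final = c(".", "!", "?")) {
  mid_sentence <- unique(as.character(mid_sentence))
  sentence_final <- unique(as.character(sentence_final))
  if (length(intersect(mid_sentence, sentence_final)) > 0L) {
    abort("mid-sentence and sentence-final punctuation sets must be disjoint")
  }
  structure(
    list(mid_sentence = mid_sentence, sentence_final = sentence_final),
    class = "punct_convention"
  )
}

is_punct_convention <- function(x) inherits(x, "punct_convention")

# Build a POSIX character class matching exactly `chars`: ']' must come
# first, '-' last, and '^' must not be first.
punct_class <- function(chars) {
  if (length(chars) == 0L) return(NULL)
  chars <- unique(chars)
  body <- paste0(
    if ("]" %in% chars) "]" else "",
    paste(setdiff(chars, c("]", "^", "-")), collapse = ""),
    if ("^" %in% chars) "^" else "",
    if ("-" %in% chars) "-" else ""
  )
  if (identical(body, "^")) return("\\^")
  paste0("[", body, "]")
}

# Tokenize a phrase into whitespace-delimited words. For each token the
# trailing punctuation cluster is split off: mid-sentence characters are kept
# as `punct`, sentence-final characters are dropped. Returns a plain list with
# parallel fields: `word` (original-case core), `core` (lowercase core),
# `punct` (trailing mid-sentence punctuation), `initial` (lowercase initial
# used for abbreviation), `digit_initial`, and `n` (word count). This sits on
# every hot path, hence the vectorized regex implementation and the bare-list
# return.
phrase_tokens <- function(phrase, convention = punct_convention()) {
  stopifnot(is.character(phrase), length(phrase) == 1L)
  if (grepl("’", phrase, fixed = TRUE)) {
    phrase <- gsub("’", "'", phrase, fixed = TRUE)
  }
  raw <- strsplit(trimws(phrase), "\\s+")[[1]]
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    abort("phrase contains no words")
  }
  all_cls <- punct_class(c(convention$mid_sentence, convention$sentence_final))
  fin_cls <- punct_class(convention$sentence_final)
  # split off the trailing punctuation cluster first, then strip leading
  # punctuation (quotes, stray marks) from the remainder
  m <- regexpr(paste0(all_cls, "+$"), raw)
  has_trail <- m > 0L
  trail <- ifelse(has_trail, substring(raw, m), "")
  core <- sub("^[^[:alnum:]']+", "",
              ifelse(has_trail, substring(raw, 1L, m - 1L), raw))
  punct <- if (is.null(fin_cls)) trail else gsub(fin_cls, "", trail)
  if (any(!nzchar(core))) {
    # pure-punctuation tokens: mid-sentence marks attach to the previous
    # word, sentence-final marks are dropped, anything else is an error
    keep <- rep(TRUE, length(core))
    for (i in which(!nzchar(core))) {
      if (nzchar(punct[[i]]) && i > 1L && keep[[i - 1L]]) {
        punct[[i - 1L]] <- paste0(punct[[i - 1L]], punct[[i]])
        keep[[i]] <- FALSE
      } else if (nzchar(trail[[i]]) && !nzchar(punct[[i]])) {
        keep[[i]] <- FALSE
      } else {
        abort(sprintf(
          "word %d (%s) has no letters and no recognized punctuation",
          i, raw[[i]]))
      }
    }
    core <- core[keep]
    punct <- punct[keep]
    if (length(core) == 0L) {
      abort("phrase contains no words")
    }
  }
  pos <- regexpr("[[:alnum:]]", core)
  if (any(pos < 0L)) {
    i <- which(pos < 0L)[[1]]
    abort(sprintf("word %d (%s) has no alphanumeric character", i, core[[i]]))
  }
  digit_initial <- grepl("^[0-9]", core)
  initial <- ifelse(digit_initial, substr(core, 1L, 1L),
                    tolower(substring(core, pos, pos)))
  list(word = core, core = tolower(core), punct = punct, initial = initial,
       digit_initial = digit_initial, n = length(core))
}

new_abbreviation <- function(kind, typed, punct) {
  stopifnot(length(kind) == length(typed), length(typed) == length(punct))
  structure(list(kind = kind, typed = typed, punct = punct),
            class = "abbreviation")
}

#' @export
print.abbreviation <- function(x, ...) {
  cat("<abbreviation> ", render_abbreviation(x, "compact"),
      "  [", paste(x$kind, collapse = " "), "]\n", sep = "")
  invisible(x)
}

#' @export
length.abbreviation <- function(x) length(x$kind)

#' Abbreviate a phrase as word initials
#'
#' Each whitespace-delimited word contributes its initial letter,
#' case-insensitively. Mid-sentence punctuation attached to a word is kept in
#' the abbreviation; sentence-final punctuation is dropped. A contracted word
#' (one containing an apostrophe, e.g. "you're") contributes only its initial.
#' Digit-initial words are abbreviated by their first character and flagged in
#' the `digit_initial` attribute.
#'
#' @param phrase A single non-empty string.
#' @param convention A [punct_convention()].
#' @return An `abbreviation` object with one `initial` segment per word.
#' @examples
#' render_abbreviation(abbreviate_initials("I saw him play in the bedroom"))
#' render_abbreviation(abbreviate_initials("ok, sounds good"))
#' @export
abbreviate_initials <- function(phrase, convention = punct_convention()) {
  tok <- phrase_tokens(phrase, convention)
  ab <- new_abbreviation(rep("initial", tok$n), tok$initial, tok$punct)
  if (any(tok$digit_initial)) {
    attr(ab, "digit_initial") <- which(tok$digit_initial)
  }
  ab
}

#' Abbreviate a phrase with spelled-out keywords
#'
#' Builds a shorthand in which selected words ("keywords") are spelled out,
#' fully or partially, while the remaining words contribute their initials as
#' in [abbreviate_initials()]. Three keyword kinds are supported: `"full"`
#' (the whole word), `"prefix"` (its first `length >= 2` characters) and
#' `"consonant"` (the first `length >= 2` characters of its
#' [consonant_skeleton()]).
#'
#' @param phrase A single non-empty string.
#' @param keywords A data frame with columns `position` (1-based word index),
#'   `kind` (`"full"`, `"prefix"` or `"consonant"`) and `length` (characters
#'   typed; ignored for `"full"`).
#' @inheritParams abbreviate_initials
#' @return An `abbreviation` object.
#' @examples
#' ab <- abbreviate_keywords(
#'   "I saw him playing in the bedroom",
#'   data.frame(position = 7, kind = "full", length = NA)
#' )
#' render_abbreviation(ab)  # "ishpit bedroom"
#' @export
abbreviate_keywords <- function(phrase, keywords,
                                convention = punct_convention()) {
  tok <- phrase_tokens(phrase, convention)
  ab <- abbreviate_initials(phrase, convention)
  keywords <- as.data.frame(keywords)
  if (!all(c("position", "kind") %in% names(keywords))) {
    abort("`keywords` needs columns `position` and `kind`")
  }
  if (is.null(keywords$length)) keywords$length <- NA_integer_
  for (r in seq_len(nrow(keywords))) {
    p <- keywords$position[[r]]
    kind <- keywords$kind[[r]]
    len <- keywords$length[[r]]
    if (p < 1L || p > tok$n) {
      abort(sprintf("keyword position %s out of range", p))
    }
    core <- tok$core[[p]]
    typed <- switch(kind,
      full = core,
      prefix = {
        if (is.na(len) || len < 2L) {
          abort("prefix keywords require a typed length of two or more characters")
        }
        if (len > nchar(core)) {
          abort(sprintf("prefix length %d exceeds word '%s'", len, core))
        }
        substr(core, 1L, len)
      },
      consonant = {
        skel <- consonant_skeleton(core)
        if (is.na(len) || len < 2L) {
          abort("consonant keywords require a typed length of two or more characters")
        }
        if (len > nchar(skel)) {
          abort(sprintf("consonant length %d exceeds skeleton '%s'", len, skel))
        }
        substr(skel, 1L, len)
      },
      abort(sprintf("unknown keyword kind '%s'", kind))
    )
    ab$kind[[p]] <- kind
    ab$typed[[p]] <- typed
  }
  ab
}

#' Consonant skeleton of a word
#'
#' Lowercases the word and removes vowel letters (a, e, i, o, u) that are not
#' at the beginning of the word; the first letter is always kept. Apostrophes
#' and other non-letter characters are dropped.
#'
#' @param word A character vector of words.
#' @return A character vector of skeletons.
#' @examples
#' consonant_skeleton(c("bedroom", "in", "aeiou"))  # "bdrm" "in" "a"
#' @export
consonant_skeleton <- function(word) {
  vapply(tolower(word), function(w) {
    chars <- strsplit(w, "")[[1]]
    chars <- chars[grepl("[a-z]", chars)]
    if (length(chars) == 0L) return("")
    keep <- c(TRUE, !(chars[-1] %in% c("a", "e", "i", "o", "u")))
    paste(chars[keep], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Render an abbreviation as a string
#'
#' Two dialects are supported. `"compact"` is the display form: runs of
#' initial segments are concatenated (with their trailing punctuation inline)
#' and keyword segments are space-delimited, e.g. `"ishpit bedroom"`.
#' `"spaced"` is the serialization form used for model training data: a single
#' space between every segment's typed characters, e.g.
#' `"i s h p i t bedroom"`. Trailing punctuation stays attached to its
#' segment in both dialects (`"o, s d"`).
#'
#' @param abbrev An `abbreviation`.
#' @param style `"compact"` or `"spaced"`.
#' @return A single string.
#' @export
render_abbreviation <- function(abbrev, style = c("compact", "spaced")) {
  stopifnot(inherits(abbrev, "abbreviation"))
  style <- match.arg(style)
  pieces <- paste0(abbrev$typed, abbrev$punct)
  if (style == "spaced") {
    return(paste(pieces, collapse = " "))
  }
  tokens <- character()
  run <- ""
  for (i in seq_along(pieces)) {
    if (abbrev$kind[[i]] == "initial") {
      run <- paste0(run, pieces[[i]])
    } else {
      if (nzchar(run)) tokens <- c(tokens, run)
      run <- ""
      tokens <- c(tokens, pieces[[i]])
    }
  }
  if (nzchar(run)) tokens <- c(tokens, run)
  paste(tokens, collapse = " ")
}

#' Parse a spaced-dialect shorthand
#'
#' Inverts [render_abbreviation()] for the `"spaced"` dialect on the
#' kind-erased structure: a token of one alphanumeric character (optionally
#' followed by mid-sentence punctuation) becomes an `initial` segment; a token
#' of two or more characters becomes a `prefix` keyword. Promotion of a
#' keyword to `full` (or recognition as a consonant shorthand) requires a
#' reference phrase; see [validate_shorthand()].
#'
#' @param shorthand A spaced-dialect string, e.g. `"i s h p i t bedroom"`.
#' @inheritParams abbreviate_initials
#' @return An `abbreviation`.
#' @export
parse_spaced <- function(shorthand, convention = punct_convention()) {
  stopifnot(is.character(shorthand), length(shorthand) == 1L)
  if (!nzchar(trimws(shorthand))) {
    abort("cannot parse an empty shorthand")
  }
  tokens <- strsplit(shorthand, " ", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens))) {
    abort("empty token in spaced shorthand (check for doubled spaces)")
  }
  mid <- convention$mid_sentence
  kind <- character(length(tokens))
  typed <- character(length(tokens))
  punct <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tolower(gsub("’", "'", tokens[[i]]))
    chars <- strsplit(tok, "")[[1]]
    last <- length(chars)
    while (last > 0L && chars[[last]] %in% mid) last <- last - 1L
    core <- paste(chars[seq_len(last)], collapse = "")
    trail <- if (last < length(chars)) {
      paste(chars[(last + 1L):length(chars)], collapse = "")
    } else ""
    if (!nzchar(core) || grepl("[^a-z0-9']", core)) {
      abort(sprintf("token %d ('%s') is not a valid shorthand token",
                    i, tokens[[i]]))
    }
    kind[[i]] <- if (nchar(core) == 1L) "initial" else "prefix"
    typed[[i]] <- core
    punct[[i]] <- trail
  }
  new_abbreviation(kind, typed, punct)
}

#' Does an abbreviation match a phrase?
#'
#' A phrase matches when it has exactly one word per segment and every segment
#' is consistent with its word (all comparisons case-insensitive, trailing
#' mid-sentence punctuation must agree): an `initial` segment requires equal
#' initials, a `full` keyword requires the whole word, a `prefix` keyword
#' requires its typed characters to be a prefix of the word (apostrophes
#' included), and a `consonant` keyword a prefix of the word's
#' [consonant_skeleton()].
#'
#' @param abbrev An `abbreviation`.
#' @param phrase The candidate phrase.
#' @inheritParams abbreviate_initials
#' @return `TRUE` or `FALSE`.
#' @examples
#' abbrev_matches(abbreviate_initials("ok, sounds good"), "ok sounds good")
#' @export
abbrev_matches <- function(abbrev, phrase, convention = punct_convention()) {
  stopifnot(inherits(abbrev, "abbreviation"))
  tok <- tryCatch(phrase_tokens(phrase, convention), error = function(e) NULL)
  if (is.null(tok) || tok$n != length(abbrev$kind)) {
    return(FALSE)
  }
  for (i in seq_along(abbrev$kind)) {
    if (!identical(abbrev$punct[[i]], tok$punct[[i]])) return(FALSE)
    typed <- abbrev$typed[[i]]
    ok <- switch(abbrev$kind[[i]],
      initial = identical(typed, tok$initial[[i]]),
      full = identical(typed, tok$core[[i]]),
      prefix = startsWith(tok$core[[i]], typed),
      consonant = startsWith(consonant_skeleton(tok$core[[i]]), typed),
      FALSE
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Validate a spaced shorthand against a reference phrase
#'
#' Parses the shorthand with [parse_spaced()] and checks it against the
#' phrase, allowing each multi-character token to be interpreted as whichever
#' keyword kind (full, prefix or consonant) is consistent with the
#' corresponding word. This is the validator used for synthesized training
#' triplets, where the keyword kind is not recoverable from the shorthand
#' string alone.
#'
#' @param shorthand A spaced-dialect shorthand string.
#' @param phrase The reference phrase.
#' @inheritParams abbreviate_initials
#' @return `TRUE` or `FALSE`.
#' @export
validate_shorthand <- function(shorthand, phrase,
                               convention = punct_convention()) {
  ab <- tryCatch(parse_spaced(shorthand, convention), error = function(e) NULL)
  if (is.null(ab)) return(FALSE)
  tok <- tryCatch(phrase_tokens(phrase, convention), error = function(e) NULL)
  if (is.null(tok) || tok$n != length(ab$kind)) return(FALSE)
  for (i in seq_along(ab$kind)) {
    if (!identical(ab$punct[[i]], tok$punct[[i]])) return(FALSE)
    typed <- ab$typed[[i]]
    ok <- if (ab$kind[[i]] == "initial") {
      identical(typed, tok$initial[[i]])
    } else {
      startsWith(tok$core[[i]], typed) ||
        startsWith(consonant_skeleton(tok$core[[i]]), typed)
    }
    if (!ok) return(FALSE)
  }
  TRUE
}
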