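#' Train a stupid-backoff n-gram language model
#'
#' Fits maximum-likelihood conditional scores for all observed n-grams up to
#' `order` over a closed vocabulary (the corpus tokens plus a sentence-start
#' marker). Scoring uses stupid backoff: the score of a word given a history
#' is its highest-order observed conditional relative frequency, discounted by
#' `alpha` once per backed-off order. Stupid backoff yields scores, not a
#' normalized distribution, except at the unigram level where the scores are
#' exact relative frequencies summing to one.
#'
#' @param sentences Character vector of training sentences (whitespace-
#'   delimited tokens; [corpus_sentences()] produces the expected lowercase,
#'   punctuation-stripped form).
#' @param order Model order `k >= 1`.
#' @param alpha Backoff discount in `(0, 1]`; the conventional value is 0.4.
#' @return An object of class `abbrex_lm`.
#' @examples
#' lm <- train_ngram(c("a b", "a b", "a c"), order = 2)
#' lm_score(lm, "b", history = "a") > lm_score(lm, "c", history = "a")
#' @export
train_ngram <- function(sentences, order = 3, alpha = 0.4) {
  stopifnot(order >= 1, alpha > 0, alpha <= 1)
  sentences <- sentences[nzchar(trimws(sentences))]
  if (length(sentences) == 0L) {
    abort("cannot train an n-gram model on an empty corpus")
  }
  bos <- "<s>"
  tokens <- lapply(strsplit(tolower(sentences), "\\s+"), function(x) x[nzchar(x)])
  counts <- new.env(parent = emptyenv(), hash = TRUE)
  bump <- function(key) {
    assign(key, (get0(key, envir = counts) %||% 0L) + 1L, envir = counts)
  }
  n_words <- 0L
  for (sent in tokens) {
    padded <- c(rep(bos, order - 1L), sent)
    for (i in seq_along(padded)) {
      if (padded[[i]] == bos) next
      n_words <- n_words + 1L
      for (k in seq_len(order)) {
        if (i - k + 1L < 1L) break
        bump(paste(padded[(i - k + 1L):i], collapse = " "))
      }
    }
  }
  # context totals: count(h) = sum over w of count(h w), so conditional
  # scores are exact relative frequencies over observed continuations
  ctx <- new.env(parent = emptyenv(), hash = TRUE)
  for (key in ls(counts)) {
    gram <- strsplit(key, " ", fixed = TRUE)[[1]]
    if (length(gram) < 2L) next
    h <- paste(gram[-length(gram)], collapse = " ")
    assign(h, (get0(h, envir = ctx) %||% 0L) + get(key, envir = counts),
           envir = ctx)
  }
  # convert counts to natural-log conditional MLE scores
  logp <- new.env(parent = emptyenv(), hash = TRUE)
  gram_counts <- integer(order)
  for (key in ls(counts)) {
    gram <- strsplit(key, " ", fixed = TRUE)[[1]]
    k <- length(gram)
    denom <- if (k == 1L) {
      n_words
    } else {
      get0(paste(gram[-k], collapse = " "), envir = ctx) %||% NA_integer_
    }
    if (is.na(denom) || denom <= 0L) next
    assign(key, log(get(key, envir = counts) / denom), envir = logp)
    gram_counts[[k]] <- gram_counts[[k]] + 1L
  }
  vocab <- sort(setdiff(
    unique(unlist(tokens, use.names = FALSE)), bos
  ))
  structure(
    list(order = as.integer(order), alpha = alpha, vocab = vocab,
         logp = logp, gram_counts = gram_counts),
    class = "abbrex_lm"
  )
}

#' @export
print.abbrex_lm <- function(x, ...) {
  cat(sprintf("<abbrex_lm> order %d, alpha %.2f, |vocab| = %d, n-grams: %s\n",
              x$order, x$alpha, length(x$vocab),
              paste(x$gram_counts, collapse = "/")))
  invisible(x)
}

#' Score a word given its history
#'
#' Returns the natural-log stupid-backoff score of `word` following `history`
#' (earliest word first). The history is padded with sentence-start markers,
#' so an empty history scores the word as a sentence opener.
#'
#' @param model An `abbrex_lm`.
#' @param word A single word (lowercase).
#' @param history Character vector of preceding words.
#' @return A single numeric log score (`-Inf` for out-of-vocabulary words).
#' @export
lm_score <- function(model, word, history = character()) {
  stopifnot(inherits(model, "abbrex_lm"))
  h <- c(rep("<s>", model$order - 1L), tolower(history))
  h <- tail(h, model$order - 1L)
  log_alpha <- log(model$alpha)
  for (j in seq(length(h), 0L)) {
    key <- if (j > 0L) {
      paste(c(tail(h, j), word), collapse = " ")
    } else {
      word
    }
    val <- get0(key, envir = model$logp)
    if (!is.null(val)) {
      return(val + (length(h) - j) * log_alpha)
    }
  }
  -Inf
}

# Vectorized scoring of several candidate next words for one history:
# batched environment lookups per backoff order.
lm_next_scores <- function(model, history, candidates) {
  if (length(candidates) == 0L) return(numeric())
  h <- c(rep("<s>", model$order - 1L), history)
  h <- tail(h, model$order - 1L)
  log_alpha <- log(model$alpha)
  scores <- rep(NA_real_, length(candidates))
  for (j in seq(length(h), 0L)) {
    open <- is.na(scores)
    if (!any(open)) break
    keys <- if (j > 0L) {
      paste(paste(tail(h, j), collapse = " "), candidates[open])
    } else {
      candidates[open]
    }
    vals <- unlist(mget(keys, envir = model$logp, ifnotfound = NA_real_),
                   use.names = FALSE)
    hit <- !is.na(vals)
    scores[which(open)[hit]] <- vals[hit] + (length(h) - j) * log_alpha
  }
  scores[is.na(scores)] <- -Inf
  scores
}

# Vectorized score of a fixed right neighbour following each candidate word:
# score(right | ..., left, w) for every w in `candidates`.
lm_right_scores <- function(model, left, candidates, right) {
  if (length(candidates) == 0L) return(numeric())
  # history prefix shared by all candidates (padded, one slot kept for w)
  h_prefix <- tail(c(rep("<s>", model$order - 1L), left), model$order - 2L)
  hmax <- model$order - 1L
  log_alpha <- log(model$alpha)
  scores <- rep(NA_real_, length(candidates))
  for (j in seq(hmax, 1L)) {
    open <- is.na(scores)
    if (!any(open)) break
    pre <- if (j > 1L) paste(tail(h_prefix, j - 1L), collapse = " ") else ""
    keys <- if (nzchar(pre)) {
      paste(pre, candidates[open], right)
    } else {
      paste(candidates[open], right)
    }
    vals <- unlist(mget(keys, envir = model$logp, ifnotfound = NA_real_),
                   use.names = FALSE)
    hit <- !is.na(vals)
    scores[which(open)[hit]] <- vals[hit] + (hmax - j) * log_alpha
  }
  if (any(is.na(scores))) {
    uni <- get0(right, envir = model$logp) %||% -Inf
    scores[is.na(scores)] <- uni + hmax * log_alpha
  }
  scores
}

#' Write an n-gram model to an ARPA file
#'
#' Emits the model's conditional scores as log10 probabilities in the standard
#' ARPA layout (orders 1 and up, `\\data\\` header with n-gram counts). Backoff
#' weights are not written: this package applies a uniform stupid-backoff
#' discount instead, and [read_arpa()] likewise ignores any backoff fields.
#'
#' @param model An `abbrex_lm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arpa <- function(model, path) {
  stopifnot(inherits(model, "abbrex_lm"))
  keys <- ls(model$logp)
  orders <- lengths(strsplit(keys, " ", fixed = TRUE))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("\\data\\", con)
  for (k in seq_len(model$order)) {
    writeLines(sprintf("ngram %d=%d", k, sum(orders == k)), con)
  }
  for (k in seq_len(model$order)) {
    writeLines(c("", sprintf("\\%d-grams:", k)), con)
    ks <- sort(keys[orders == k])
    for (key in ks) {
      lp10 <- get(key, envir = model$logp) / log(10)
      writeLines(sprintf("%.7f\t%s", lp10, key), con)
    }
  }
  writeLines(c("", "\\end\\"), con)
  invisible(path)
}

#' Read an n-gram model from an ARPA file
#'
#' Reads log10 probabilities for n-grams of any order (1-5 are typical) into
#' an `abbrex_lm`. Backoff weight columns, if present, are ignored; scoring
#' applies the uniform stupid-backoff discount `alpha`.
#'
#' @param path Path to an ARPA file.
#' @param alpha Backoff discount applied at scoring time.
#' @return An `abbrex_lm`.
#' @export
read_arpa <- function(path, alpha = 0.4) {
  if (!file.exists(path)) {
    abort(sprintf("ARPA file '%s' does not exist", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  logp <- new.env(parent = emptyenv(), hash = TRUE)
  gram_counts <- integer()
  order <- 0L
  cur <- 0L
  vocab <- character()
  for (line in lines) {
    line <- trimws(line)
    if (!nzchar(line) || line == "\\data\\" || line == "\\end\\") next
    m <- regmatches(line, regexec("^\\\\([0-9]+)-grams:$", line))[[1]]
    if (length(m) == 2L) {
      cur <- as.integer(m[[2]])
      order <- max(order, cur)
      next
    }
    if (grepl("^ngram [0-9]+=[0-9]+$", line)) next
    if (cur == 0L) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      fields <- strsplit(line, "\\s+")[[1]]
      fields <- c(fields[[1]], paste(fields[-1], collapse = " "))
    }
    lp <- suppressWarnings(as.numeric(fields[[1]]))
    gram <- strsplit(fields[[2]], " ", fixed = TRUE)[[1]]
    # a third whitespace-separated field would be a backoff weight: drop it
    if (length(gram) > cur) gram <- gram[seq_len(cur)]
    if (is.na(lp) || length(gram) != cur) {
      abort(sprintf("malformed ARPA line: '%s'", line))
    }
    assign(paste(gram, collapse = " "), lp * log(10), envir = logp)
    if (length(gram_counts) < cur) gram_counts <- c(gram_counts, integer(cur - length(gram_counts)))
    gram_counts[[cur]] <- gram_counts[[cur]] + 1L
    if (cur == 1L && gram[[1]] != "<s>") vocab <- c(vocab, gram[[1]])
  }
  if (order == 0L) {
    abort(sprintf("'%s' contains no n-gram sections", path))
  }
  structure(
    list(order = order, alpha = alpha, vocab = sort(unique(vocab)),
         logp = logp, gram_counts = gram_counts),
    class = "abbrex_lm"
  )
}
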