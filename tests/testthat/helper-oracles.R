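# Independent brute-force oracle for constrained expansion: enumerate every
# vocabulary assignment consistent with the abbreviation, score each full
# phrase with scalar lm_score() calls plus the context bonus, and rank by
# (score desc, phrase asc). Deliberately shares no code with the beam search.
enum_expand <- function(model, abbrev, n_options, context = character(),
                        context_boost = 0.5) {
  vocab <- model$vocab
  skel <- consonant_skeleton(vocab)
  sets <- lapply(seq_along(abbrev$kind), function(i) {
    typed <- abbrev$typed[[i]]
    switch(abbrev$kind[[i]],
      initial = vocab[substr(vocab, 1, 1) == typed],
      full = vocab[vocab == typed],
      prefix = vocab[startsWith(vocab, typed)],
      consonant = vocab[startsWith(skel, typed)]
    )
  })
  if (any(lengths(sets) == 0)) return(character())
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(sets)), drop = FALSE]
  ctx_words <- if (length(context) > 0) {
    unique(unlist(strsplit(tolower(gsub("[,;:.!?]", "", context)), "\\s+")))
  } else {
    character()
  }
  scores <- vapply(seq_len(nrow(grid)), function(r) {
    w <- as.character(grid[r, ])
    s <- 0
    for (i in seq_along(w)) {
      s <- s + lm_score(model, w[[i]], w[seq_len(i - 1)]) +
        context_boost * (w[[i]] %in% ctx_words)
    }
    s
  }, numeric(1))
  phrases <- apply(grid, 1, paste, collapse = " ")
  head(phrases[order(-scores, phrases, method = "radix")], n_options)
}

# A tiny vocabulary with clustered initials, for randomized expansion cases.
toy_vocab_pool <- c(
  "the", "they", "that", "a", "at", "and", "i", "in", "it",
  "saw", "see", "so", "some", "bedroom", "backyard", "beach", "ball",
  "cat", "car", "coat", "dog", "door", "day", "play", "park", "pond",
  "we", "want", "was", "him", "her", "home"
)

random_expansion_case <- function(max_vocab = 30, max_words = 4) {
  vocab <- sample(toy_vocab_pool, sample(6:min(max_vocab, 20), 1))
  sentences <- replicate(
    10, paste(sample(vocab, sample(2:max_words, 1), replace = TRUE),
              collapse = " ")
  )
  model <- train_ngram(sentences, order = sample(1:3, 1))
  truth <- sample(model$vocab, sample(2:max_words, 1), replace = TRUE)
  context <- if (stats::runif(1) < 0.5) {
    paste(sample(model$vocab, 3), collapse = " ")
  } else {
    character()
  }
  list(model = model, truth = truth,
       abbrev = abbreviate_initials(paste(truth, collapse = " ")),
       context = context)
}

# Two-turn toy dialogue behind the fill-mask worked example.
fillmask_example_corpus <- function() {
  tibble::tibble(
    dialogue_id = "fm-example",
    turn = 1:2,
    speaker = c("A", "B"),
    text = c("Been sitting all day. Work was just one meeting after another.",
             "Oh, I'm sorry.")
  )
}
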