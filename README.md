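# abbrex

Simulation toolkit for **abbreviated text entry** in augmentative and
alternative communication (AAC). Users who type through eye trackers — for
example people living with ALS — pay a high motor cost per keystroke.
Abbreviation expansion (AE) reduces that cost: the user types a compressed
shorthand of the intended phrase and a predictive model proposes full-phrase
candidates. abbrex implements the computational machinery needed to study
this paradigm at desk scale:

* **The abbreviation algebra.** Four shorthand schemes over whitespace
  words: initials-only (`"I saw him play in the bedroom"` → `"ishpitb"`,
  with mid-sentence punctuation preserved and sentence-final punctuation
  dropped), fully spelled keywords (`"ishpit bedroom"`), prefix keywords
  (`"ishpit be"`) and consonant-skeleton keywords (`"ishpit bd"`, since the
  skeleton of *bedroom* is *bdrm*). Structured construction, rendering
  (compact display dialect and spaced serialization dialect), parsing and
  validation.
* **Predictors.** A pluggable contract with two backends: a stupid-backoff
  n-gram language model (ARPA read/write) decoded by constrained beam
  search with an additive log-score bonus for words from the prior dialogue
  turns, plus fill-mask word replacement and forward word
  completion/next-word prediction; and a fully configurable oracle for
  controlled experiments.
* **An ideal-user simulator.** Three recovery strategies (keyword spelling
  only; fill-mask when one incorrect word remains; fill-mask when at most
  two remain) over two expansion-model versions (full keywords only;
  incremental one-letter keyword prefixes), with motor-action ledgers and a
  forward-prediction baseline.
* **A training-data synthesizer** that turns dialogue corpora into
  context/shorthand/phrase and context/masked-phrase/word triplets.
* **A seeded synthetic dialogue generator** (six-turn, two-speaker
  dialogues from a template grammar with a content-word reuse knob) so that
  every experiment is reproducible without external data.

The central metric is the **keystroke-saving rate**

```
KSR = 1 - (motor actions used) / (characters of the reference phrase)
```

where motor actions broaden keystrokes to include every UI action (mode
entries, chip selections, option selections) and the denominator counts the
phrase's characters with interior spaces and mid-sentence punctuation,
excluding sentence-final punctuation. KSR is negative when assistance costs
more than plain typing.

## A worked example

```r
library(abbrex)

abbreviate_initials("I saw him play in the bedroom")
#> <abbreviation> ishpitb  [initial initial initial initial initial initial initial]

# seeded synthetic dialogues: the evaluation corpus and a disjoint training
# corpus for the n-gram predictor
corpus <- generate_dialogues(100, seed = 3)
head(corpus, 4)
#> # A tibble: 4 × 4
#>   dialogue_id  turn speaker text
#>   <chr>       <int> <chr>   <chr>
#> 1 dlg-0001        1 A       Have you seen my loft?
#> 2 dlg-0001        2 B       You saw our loft.
#> 3 dlg-0001        3 A       Did you made the loft?
#> 4 dlg-0001        4 B       Well, the loft was lovely.

train <- generate_dialogues(300, seed = 4)
lm <- train_ngram(corpus_sentences(train), order = 3)
pred <- ngram_predictor(lm)          # context boost 0.5 nats, beam width 16

expand_options(pred, abbreviate_initials("Do you like the bakery?"), n_options = 5)
#> # A tibble: 5 × 3
#>   phrase                    score  rank
#>   <chr>                     <dbl> <int>
#> 1 do you like the banjo     -7.90     1
#> 2 do you like the beach     -7.90     2
#> 3 do you like the birthday  -7.90     3
#> 4 do you like the backyard  -8.66     4
#> 5 do you like the bookstore -9.55     5

report <- run_simulation(corpus, pred, sim_config(strategy = "S2", seed = 1))
report
#> <abbrex_report> 600 turns | strategy S2 (V2) | 5 options | context on
#>   mean KSR 0.522 | single-call fraction 0.392

glance(run_baseline(corpus, lm))[, c("strategy", "mean_ksr", "n_turns")]
#> # A tibble: 1 × 3
#>   strategy mean_ksr n_turns
#>   <chr>       <dbl>   <int>
#> 1 BASELINE    0.593     600
```

Reading the numbers: with the intended phrase `"Do you like the bakery?"`
the initials-only expansion fails — five other b-nouns outrank *bakery* —
so the simulated user recovers by spelling (strategy S2 switches to
fill-mask once a single word is wrong). Across the 600 turns the
abbreviation interface saves 52.2% of motor actions and solves 39.2% of
turns with the single initials-only prediction call. The forward-prediction
baseline, which plays to the n-gram model's strength, saves 59.3% here:
with a desk-scale n-gram standing in for a large language model, absolute
orderings across predictors reflect predictor quality, not the interface
(see the methods vignette). A perfect predictor shows the interface's upper
bound:

```r
simulate_turn("I saw him playing in the bedroom", oracle_predictor(), sim_config())
#> <turn_outcome> 'I saw him playing in the bedroom'
#>   solved_by INITIALS_ONLY, 8 actions / 32 chars, KSR 0.750
```

Every result type has `tidy()`, `glance()` and `autoplot()` methods;
`sweep_n_options()` reruns a simulation across option counts and plots the
saturation curve.

## Command-line interface

A thin Rscript wrapper over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","abbrex.R",package="abbrex"))')" \
    gen-corpus --n 100 --seed 3 --out corpus.jsonl
# also: train-lm, simulate, baseline, sweep, make-data, abbreviate
```

Every output directory receives a `manifest.json` recording the command,
seed, effective configuration and input checksums.

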