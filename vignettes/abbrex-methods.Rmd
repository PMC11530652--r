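---
title: "Simulating abbreviated text entry: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating abbreviated text entry: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abbrex)
```

## The problem

People who type through an eye tracker — for example users living with ALS —
pay a high motor and temporal price per keystroke, and usually type below
10 words per minute. Abbreviation expansion (AE) attacks the keystroke count
directly: the user types a compressed shorthand of the intended phrase and a
predictive model proposes full-phrase candidates. abbrex implements the
computational side of one such paradigm end to end — the abbreviation
schemes, the predictors, an ideal-user simulator with motor-action
accounting, and a synthesizer of model-training triplets — so that interface
strategies can be compared quantitatively on seeded synthetic dialogues.

## The abbreviation algebra

A phrase is tokenized into whitespace-delimited words. Each word contributes
one *segment* to the abbreviation:

* **initial** — the word's initial letter, case-insensitively
  (`"I saw him play in the bedroom"` → `"ishpitb"`). A contracted word
  (`"you're"`) contributes only its initial. Mid-sentence punctuation
  attached to a word (by default `,` `;` `:`) is preserved in the shorthand;
  sentence-final punctuation (`.` `!` `?`) is dropped.
* **full keyword** — the word spelled out completely, embedded in the
  initials at its original position (`"ishpit bedroom"`).
* **prefix keyword** — two or more leading characters (`"ishpit be"`).
* **consonant keyword** — two or more leading characters of the word's
  consonant skeleton, which keeps the first letter and removes later vowels
  (`consonant_skeleton("bedroom")` is `"bdrm"`, giving `"ishpit bd"`).

Two string dialects exist. The *compact* dialect is the display form
(`"ishpit bedroom"`); it is ambiguous to parse, because `"saw"` could be a
keyword or three initials, so abbreviations are structured objects and only
the *spaced* dialect (`"i s h p i t bedroom"`, one space between segments) is
parseable. In the spaced dialect a multi-character token parses as a prefix
keyword; promotion to a full or consonant reading requires the reference
phrase (`validate_shorthand()`), which tries all three keyword
interpretations.

Deliberate conventions, where the scheme leaves room:

* Words are whitespace tokens; hyphenated tokens are single words.
* Matching is case-insensitive everywhere; committed text keeps the
  reference casing.
* Apostrophes are never emitted into initials-only shorthands, and keyword
  prefixes are tested against the raw word including its apostrophe.
* Digit-initial words (`"9am"`) are abbreviated by their first character and
  flagged; the fill-mask synthesizer never masks them.
* The punctuation sets are configurable through `punct_convention()`.

## Predictors

The predictor contract has two services: expand an abbreviation into ranked
phrases, and fill a masked word slot with ranked words constrained to an
initial letter. Two backends are provided.

**The n-gram backend** is a stupid-backoff model: the score of a word given a
history is its maximum-likelihood conditional frequency at the longest
observed order, discounted by a factor `alpha` (default 0.4, the conventional
value) once per backed-off order. Stupid backoff produces scores rather than
normalized probabilities — chosen for simplicity and exact reproducibility;
the language model is a test instrument here, not the contribution. Unigram
scores are exact relative frequencies and sum to one. Models read and write
a plain ARPA dialect (log10 probabilities; backoff-weight fields are ignored
because the discount is uniform).

Expansion is constrained beam search: one step per word position, candidates
at each position being the vocabulary words consistent with that segment,
hypotheses scored by summed n-gram scores. Conversational context enters as
an additive bonus of `context_boost` (default 0.5 natural-log units) for
every word present in the prior turns of the dialogue; setting the boost to
zero makes results provably independent of context, which is the "no
context" condition in the package's comparisons. Ties are broken
lexicographically at every ranking, so each result is reproducible
bit-for-bit, and the tests check the beam against an independent exhaustive
enumeration on small vocabularies. Ranked lists are computed once at a
generous depth and served as prefixes, so a request for fewer options is
always a prefix of the request for more — the property behind the
monotonicity results below. An abbreviation whose intended word is outside
the model vocabulary can never be solved by prediction; this is intentional
and exercises the full-spell fallback.

**The oracle backend** is a test instrument with fully controlled behaviour:
it reveals the true phrase at a configurable rank once the abbreviation
carries a configurable number of typed characters, and fills the other slots
with decoys that still satisfy the abbreviation. Near-miss decoys substitute
exactly `d` words with alternatives sharing the constraint (drawn from a
fixed internal lexicon, deterministically). The oracle makes hand-computed
action ledgers exact and lets each interface mechanism be isolated from
predictor quality.

## The ideal-user simulator

`simulate_turn()` executes the interaction state machine for a user who never
makes errors, never backtracks, and reads option lists for free:

1. Type the initials-only abbreviation (one keystroke per character,
   including preserved punctuation) and query the predictor. If the intended
   phrase is among the top *n* options, select it — one action — and stop.
2. Otherwise recover by keyword spelling. Under model version **V1** the
   leftmost incorrect word of the best-matching candidate is typed in full
   (the chip becomes an empty input box), with one prediction call per
   completed keyword; under **V2** one letter is appended at a time to the
   leftmost incorrect word, with a call after every keystroke, and the best
   candidate is re-evaluated after each call.
3. Strategy **S1** only ever spells. **S2** switches to fill-mask word
   replacement when exactly one incorrect word remains in the best candidate;
   **S2A** switches as soon as two or fewer remain, repairing slots left to
   right. A fill-mask failure falls back to typing that word in full, and
   keyword spelling is never re-entered after fill-mask begins.
4. If every position becomes fully spelled the phrase is committed directly
   (`FULL_SPELL`), so no turn can dead-end.

Motor actions use the broadened definition: keystrokes plus every UI action —
entering spell mode, selecting a chip, entering fill-mask mode, selecting the
word to replace, selecting phrase and word options, and (in manual-trigger
mode) each expansion trigger. Auto-triggered prediction calls cost no action.
The accounting choices that the interface description leaves open are all
individually visible in the ledger: the fill-mask mode entry is counted once
per turn (it models clicking the near-miss phrase), a chip selection is
counted whenever the spelling position changes, and the speaker-button
selection that commits a phrase is always counted.

The key metric is the keystroke-saving rate,

\[ \mathrm{KSR} = 1 - \frac{\text{motor actions used}}{\text{reference characters}}, \]

with the denominator being the characters of the reference phrase including
interior spaces and mid-sentence punctuation and excluding sentence-final
punctuation — the standard text-entry convention; `include_spaces = FALSE`
switches the convention. KSR is negative when assistance costs more than
plain typing. A turn solved by the single initials-only call contributes to
the *single-call fraction*, the second headline metric.

The forward-prediction baseline (`simulate_baseline_turn()`) models a
conventional predictive keyboard over the same n-gram model: the ideal user
types left to right and selects the intended word as soon as it appears among
the top-n completions or next-word predictions. A selection commits the word
plus one following space in a single action (commercial-keyboard behaviour;
the final word commits without a space); words carrying mid-sentence
punctuation have the mark and the following space typed literally. With a
model that never predicts, the baseline's actions equal the reference
character count exactly, so its KSR is zero by construction.

`project_time()` is declared plumbing: a linear projection of ledger counts,
call counts and options reviewed onto per-unit millisecond costs for what-if
decomposition. It fits no empirical timing model.

## The synthetic dialogue generator

Tests and the acceptance script run on seeded synthetic corpora, not on any
external dataset. `generate_dialogues()` emits six-turn, two-speaker
dialogues from a small template grammar — an opener question followed by
statements and follow-up questions — rather than from a language model, so
every test corpus is auditable. Content words (nouns) are drawn from a
built-in lexicon deliberately concentrated on a dozen initial letters
(roughly six in-vocabulary nouns per initial at the default vocabulary size
of 72), which is what makes initials-only expansion genuinely ambiguous at
five options. The `word_reuse_prob` knob (default 0.5, a realistic
mid-range for short topical dialogues) makes later turns reuse nouns from
earlier turns of the same dialogue; that reuse is the signal that
conversational context carries. Turns respect the ten-unit length limit
(words plus mid-sentence punctuation) that the simulator also enforces.

What the generator does *not* emulate: open vocabulary, topic drift,
disfluencies, typos, and the long-tail sentence structure of real dialogue.
Consequently, passing tests demonstrate the correctness of the accounting
and the *directions* of the contrasts (more options never hurt; context
strictly raises the single-call fraction; fill-mask recovery beats pure
spelling), not absolute savings on real conversations.

## What the desk-scale results do and do not reproduce

The interface this package simulates was designed around large fine-tuned
language models whose top-5 phrase accuracy is high; the n-gram backend here
is a structural stand-in, deliberately small. Two consequences are worth
stating plainly. First, absolute KSR values are far below what an accurate
phrase predictor yields, and the forward-prediction baseline — a task
n-grams are comparatively good at — can outperform abbreviation expansion
driven by the same n-gram model. Orderings *across predictors* are therefore
statements about predictor quality, not about the interface. Second, the
cost of premature fill-mask (the S2 versus S2A comparison) depends on how
often the expansion model would have fixed the remaining words cheaply; with
the weak n-gram expander, aggressive fill-mask can pay off. The test suite
therefore isolates that mechanism with the oracle: when the rank-1 candidate
is a two-word near-miss and one more appended letter would let expansion
succeed, S2A's mean KSR is measurably below S2's, which is the direction the
interface design cares about.

## Numerical choices and degenerate inputs

* Ranking ties everywhere: score descending, then lexicographic — no
  randomness in any predictor path.
* Scores are natural-log throughout; ARPA I/O converts to and from log10
  with seven decimals, round-tripping to 1e-6.
* Seeded functions (`generate_dialogues()`, the triplet synthesizers,
  `run_simulation()`) save and restore the global RNG state, so they are
  pure functions of their seed.
* Empty option lists (a constraint no vocabulary word satisfies) signal
  predictor failure; the simulator falls back to spelling. An empty
  filtered corpus, a zero option count, a prefix of length one, and a
  reference with no alphabetic word are validation errors.
* Problem sizes: the bundled checks simulate 600 turns (100 six-turn
  dialogues) per condition against an order-3 model trained on a disjoint
  300-dialogue corpus, and verify the beam search against exhaustive
  enumeration on 200 random problems with vocabularies of at most 30 words
  and phrases of at most 4 words. These sizes give stable means while
  keeping each full run in the order of half a minute.

## Known limitations

No typo tolerance (the shorthand must be exact); single-sentence turns;
Latin-script tokenization; no model of human reviewing cost, revision or
selection error — the simulator is an upper bound on motor savings by
construction. The triplet synthesizer reproduces the published data-layout
conventions (curly-brace context delimiters, spaced shorthands, initial-plus-
underscore masks) but the per-scheme mixing proportions of any particular
fine-tuning corpus are unknown; the defaults (one or two keywords per
variant, uniform positions and lengths) are exposed in `synthesis_config()`
rather than hard-coded.
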