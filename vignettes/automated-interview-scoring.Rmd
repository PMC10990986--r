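---
title: "Automated scoring of Autobiographical Interview narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated scoring of Autobiographical Interview narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aiscore)
```

## The measurement problem

The Autobiographical Interview is a widely used procedure for quantifying
episodic memory: participants narrate a remembered (or imagined) event, and
trained scorers segment the transcript into details, each classified as
*internal* — specific to the central event's time and place (happenings,
people, objects, perceptions, thoughts) — or *external* — semantic facts,
metacognitive comments, repetitions, or episodic content from other events.
Manual scoring is the bottleneck: it takes extensive training and roughly
half an hour per narrative. `aiscore` automates it.

Two modeling decisions make automation tractable:

1. **Words stand in for details.** Per narrative, the number of words
   falling in internal segments correlates near-perfectly with the number
   of internal details a human scorer counts (and likewise for external).
   The scorer therefore predicts internal and external *word counts* and
   never needs to segment sentences into individual details.
2. **Sentences are classified into four proportion classes.** Empirically,
   sentence-level internal proportions cluster at approximately 0%, 50%,
   75% and 100%; each sentence is assigned one of these four classes
   (`P0`, `P50`, `P75`, `P100`).

A narrative's score is then

$$\widehat{\mathrm{internal}} = \sum_{s \in \text{sentences}} f(c_s)\, w_s,
\qquad
\widehat{\mathrm{external}} = \sum_{s} \bigl(1 - f(c_s)\bigr)\, w_s,$$

where $w_s$ is the sentence's word count, $c_s$ its predicted class and
$f(\cdot) \in \{0, .5, .75, 1\}$ the class's representative fraction. Words
are conserved exactly: predicted internal + external = total words.

## Pipeline

Training/validation data are narratives with ordered internal/external span
annotations and manual detail counts (`annotated_corpus()`,
`read_annotations()`). Preparation proceeds:

1. **Prompt removal** (`strip_prompts()`): interviewer prompts, supplied by
   the user as literal strings, are excised. There is no built-in prompt
   lexicon — prompt wording is study-specific.
2. **Sentence splitting** (`split_sentences()`): rule-based boundaries at
   terminal punctuation (`.`, `!`, `?`, ellipsis), with an abbreviation
   list (`ai_abbreviations()`) and a single-initial rule blocking false
   splits. Text without terminal punctuation is *one* sentence — the
   splitter never invents boundaries, which is exactly why unpunctuated
   transcripts degrade scoring (see below).
3. **Span alignment** (`sentence_annotations()`): each sentence's true
   internal fraction is the share of its words lying in internal spans.
   A span crossing a sentence boundary donates its detail count to each
   side prorated by word overlap, rounded half-up; the annotations define
   spans while the filter below operates on sentences, and some join rule
   is needed — proration by words is the least arbitrary.
4. **Long-sentence filter** (`filter_long_sentences()`): training/validation
   sentences with *more than eight* manual details (strictly more; eight is
   kept) are removed — they are almost always multi-sentence stretches an
   unpunctuated transcript prevented the splitter from dividing. Validation
   detail counts are decremented by the removed details. The filter is a
   data-preparation step only: scoring new narratives never applies it.
5. **Labeling** (`bin_fraction()`): fractions map to the nearest class
   center; a midpoint tie (e.g. 0.25, 0.625) goes to the higher, more
   internal class. The tie direction is arbitrary in principle; fixing and
   testing one beats leaving it to floating-point accident. There is no
   25%-class, so external-heavy mixed sentences land on `P0` or `P50` by
   nearness — a consequence of the four-class scheme, not a defect to patch.
6. **Class balancing** (`balance_classes()`): every class is upsampled with
   replacement to the size of the largest class, in fixed label order from
   one seeded stream. Without balancing, a model can exploit the base rate
   of internal content instead of reading the sentence.

## The classifier backend

`train_classifier()` hides the model behind a backend interface: any
function from sentence text to four class probabilities can serve. The
shipped `"lightweight"` backbone uses token-count features and a
multinomial linear model with an L2 penalty, fit with `glmnet` (ridge,
`alpha = 0`). The `weight_decay` field of `train_config()` (default 0.01)
is used directly as the penalty $\lambda$ — for a linear model, weight
decay *is* L2 regularization. The backend is deterministic given the
config seed, trains in seconds on one CPU, and is the backend the test
suite pins.

The interface deliberately accommodates heavier backends — the natural
choice for production use on real narratives is a pretrained transformer
encoder with a linear classification head fine-tuned on the labeled
sentences (three epochs, training batch 16, evaluation batch 64, 500
warmup steps, the same 0.01 weight decay, accuracy as the training-time
criterion; those defaults are carried in `train_config()` for exactly that
purpose). No deep-learning stack is bundled: the scientific content here
is the labeling scheme, the balancing and the word-count aggregation, none
of which depend on the encoder.

Before fitting, a stratified 10% holdout is split off and the model's
accuracy on it is logged (`$eval_accuracy`); the training pool and
narrative ids are recorded in the model manifest so evaluation code can
prove fold isolation.

## Validation design

`quadrant_report()` computes the 2×2 of Pearson correlations between
{manual internal details, manual external details} and {predicted internal
words, predicted external words}. An accurate, non-confused scorer shows
high diagonal correlations (`r_int_int`, `r_ext_ext`) and near-zero
off-diagonal ones (`r_int_ext`: internal content misread as external;
`r_ext_int`: the converse). P-values are two-sided via the t transform
with $n-2$ degrees of freedom; sidedness is a convention we fix and
document. Correlations over constant vectors or fewer than three
narratives are reported as explicit `"undefined"` markers, never as 0 or
NaN.

`leave_one_dataset_out()` evaluates generalization across whole studies:
each dataset is held out in turn, preparation and training use only the
remaining datasets, and the held-out narratives are scored and reported —
per task subgroup where a dataset spans several tasks. Datasets scored
with a non-comparable procedure can be declared `protected`: they are
never trained on and are evaluated against a model trained on all
non-protected data (default) or against each fold's model; which mode ran
is recorded in the result. Both modes exist because either is defensible
and the choice should be explicit, not implicit.

The held-out sets receive the same long-sentence filter as the training
data, with their truth detail counts decremented accordingly — validation
counts must describe the text actually scored. The plain scoring path
(`score_corpus()`) filters nothing.

## The synthetic corpus

Real scored interview corpora are person-identifiable and not
redistributable, so every stage is exercised against a generator
(`generate_corpus()`) whose ground truth is known by construction:

- Sentences are composed from two *disjoint* template vocabularies — a
  past-tense/perceptual lexicon for internal content, a habitual/semantic
  one for external. Class separability is therefore controllable;
  textual realism is a non-goal.
- Per-sentence true fractions are exactly 0, 0.5, 0.75 or 1: pure
  sentences are one segment of $2w$ words, `P50` is $w + w$, `P75` is
  $3w + w$, with $w$ drawn from `words_per_segment` (default 3–8 words)
  and segment order randomized.
- Manual detail counts are generated as
  $\max(0, \mathrm{round}(0.4\,\text{words} + \mathcal N(0, \sigma)))$
  per segment. The rate 0.4 details/word matches the canonical scoring
  example ("he had a brown hat" = 5 words, 2 details). The noise
  $\sigma$ (`proxy_noise_sd`, default 1.3) was calibrated once so that
  narrative-level corr(details, words) falls inside the 0.86–0.98 band
  that manual scoring exhibits (a 12-seed sweep at $n = 200$ gave
  per-dataset internal $r \in [.93, .97]$ and external
  $r \in [.88, .95]$); it encodes the word-count proxy as the generative
  assumption, because the package's validity argument rests on it.
- The default corpus spans three datasets with different class mixes
  (`memories`, `simulation` — with young/old task subgroups — and
  `writing`), 100 narratives each at the default `n_narratives = 300`,
  4–10 sentences per narrative.
- `punctuation_dropout` deletes each sentence terminator with probability
  $p$ *as a final pass over an otherwise identical corpus*: two configs
  differing only in dropout share the same words, spans and detail
  counts, so degradation comparisons at the same seed are exact
  contrasts. `shuffle_labels()` permutes span categories corpus-wide for
  null-model constructions.

What passing tests on this corpus show — and what they do not: they show
the pipeline arithmetic is exact (oracle scoring reproduces annotated word
counts to machine equality), that training recovers separable structure,
and that the validation design detects both accuracy and its loss under
punctuation degradation. They do not show that any particular backend
reaches any particular accuracy on real interview transcripts, whose
lexical overlap between internal and external content is far larger than
the generator's.

## Numerical and design choices

- **Word** = whitespace-delimited token; punctuation stays attached,
  hyphens/em-dashes do not split. The only convention reproducible across
  implementations.
- Ellipsis (`...` or `…`) terminates a sentence, like `.`, `!`, `?`.
- Probability ties in `predict_class()` and midpoint ties in
  `bin_fraction()` both resolve toward the more internal class (one rule,
  applied twice).
- Detail proration rounds half *up* (0.5 → 1), not half-to-even.
- `NarrativeScore` conservation is exact in exact arithmetic because the
  class fractions (0, 0.5, 0.75, 1) are dyadic rationals; the invariant is
  still asserted at `1e-9 ×` total words to be robust to any future
  backend computing fractions in floating point.
- Degenerate inputs: empty text yields an empty sentence list (a signal,
  not an error); an empty narrative scores (0, 0, 0) with an `empty` flag
  and a warning; zero-variance correlations are `"undefined"`.
- Test and validation problem sizes (our choices for routine runs):
  oracle-equivalence at 100 narratives, conservation at 1,000,
  leave-one-dataset-out at 3 × 100 narratives, proxy validation at 200,
  null-model independence at 500 with constant narrative length. The
  constant-length null matters: with varying lengths, both predictions and
  label-shuffled truth scale with narrative length, and the shared factor
  alone induces correlation that has nothing to do with classification.

## Known limitations

- The rule-based splitter approximates, but is not, a full
  boundary-disambiguation system; its abbreviation list is editable and
  the backend pluggable.
- Unpunctuated transcripts are merged into long pseudo-sentences and
  scored coarsely — by design the package degrades (and its evaluation
  detects the degradation) rather than guessing boundaries. Transcribe
  with punctuation.
- Disfluent, "uninformative" speech is scored like any other content;
  removing it is upstream work.
- The lightweight backend is a bag-of-words model: adequate for the
  template corpus and for smoke-testing pipelines, not a substitute for a
  fine-tuned encoder on real data.
- Scores are word counts, not detail counts; studies needing per-detail
  subcategories (place, time, perceptual, ...) still require segmentation.

## A worked run

```{r example, eval = FALSE}
corpus <- generate_corpus(generator_config(n_narratives = 300, seed = 11))
result <- leave_one_dataset_out(corpus, train_config(seed = 11),
                                by_task = FALSE)
print(result)

pv <- proxy_validation(corpus)
pv$summary$internal
```
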