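---
title: "Metaphor-sentiment modelling of free text: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaphor-sentiment modelling of free text: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmtext)
```

## Overview

`msmtext` predicts binary mental-health status labels from free text in
three stages: token-level metaphor identification by best-fit-sense
selection over word embeddings, document-level feature extraction (five
metaphor features and ten sentiment features), and a small feedforward
classifier evaluated under stratified 10-fold cross-validation with
SMOTE rebalancing inside training folds. This vignette explains the
model and its assumptions, the parameters that matter, the numerical
choices, what the synthetic-data generators emulate, and the package's
known limitations.

## The metaphor identifier

The identifier rests on a distributional premise: a word used literally
means what its own embedding encodes, while a word used metaphorically
stands in for a different sense that fits its context better. For each
content word $d$ in a sentence:

1. **Candidate senses.** The candidate set contains $d$'s lemma, its
   single-word synonyms and direct hypernyms from a lexical ontology
   (union over the entry matching $d$'s coarse POS), and rule-based
   inflections of all of them. $d$ is always its own candidate, which
   makes the literal case well defined: if no other sense fits the
   context better, the best fit is $d$ itself and the similarity below
   is exactly 1.
2. **Best fit.** $w^\* = \arg\max_k \cos(v_k, v_{\text{context}})$,
   where $v_k$ is candidate $k$'s *input* vector and
   $v_{\text{context}}$ the mean input vector of the other
   in-vocabulary tokens of the sentence. The context window is the
   whole sentence by default (`window = 0`); a symmetric window is
   available but narrows the evidence.
3. **Decision.** The sense difference is
   $\cos(\text{out}(d), \text{out}(w^\*))$ over *output* vectors, and
   $d$ is metaphorical iff this value is strictly below the threshold
   (default **0.5**). Input vectors answer "what fits this context";
   output vectors answer "how alike are these two words as senses" —
   the two parameter matrices of a CBOW/Skip-Gram model play different
   roles, which is why the embedding store requires both.

Ties in the argmax break to the lexicographically smallest candidate so
annotation is deterministic. Out-of-vocabulary detected words, words
with no in-vocabulary context, and fully out-of-vocabulary candidate
sets are labelled `skipped`, reported separately, and counted as
literal by the feature extractor — features must be total functions of
a document. Auxiliary and modal verbs are excluded from detection by
default (`exclude_auxiliaries = TRUE`): they are content words by the
POS rule but their "senses" are grammatical, and flagging them mostly
adds noise.

A known failure mode is accepted as designed: fixed collocations can be
misflagged (an idiomatic word's context rarely matches its literal
sense). No collocation filter is applied by default because the method
is defined by its local decision rule; a `stop_lemmas` list exists for
users who want one.

The comparison is strict (`<` 0.5). The threshold is exposed because it
is the method's single most consequential dial: the set of metaphorical
tokens is monotone non-decreasing in it, which the test suite asserts
over a ten-value grid.

## Sentence sentiment and the feature sets

Sentence sentiment uses a strength lexicon (per word: positive strength
1..5, negative strength −1..−5) aggregated by maximum magnitude; the
overall score is the sum of the positive and negative components, so it
lies in [−4, 4] and 0 means neutral. This approximates the behaviour of
external sentiment-strength tools; for fidelity runs a backend reads
precomputed per-sentence scores instead (`score_document(scores = )`),
producing the same score type. Negation handling is off by default; an
optional flag mirrors the contribution of a strength word preceded
within two tokens by a negator.

Per document with sentence scores $S_1 \dots S_n$:

* $E = \frac{1}{n}\sum_i S_i$ (mean sentiment), and the fluctuation
  $F = \frac{1}{n-1}\sum_{i=2}^{n} |S_i - S_{i-1}|$. $F$ is defined as
  0 for single-sentence documents, where the sum is empty and the
  denominator vanishes. $F$ is deliberately order-sensitive; $E$ is
  not, and adding a constant to every score shifts $E$ by that constant
  and leaves $F$ unchanged (both tested properties).
* The five sentic means (pleasantness, attention, sensitivity,
  aptitude, polarity, each in [−1, 1]) average over lexicon-matched
  tokens only: out-of-lexicon words contribute nothing rather than
  diluting the mean toward zero. A document with no match gets 0 — the
  neutral point — for all five.
* The metaphor features: fraction of tokens labelled metaphorical,
  fraction of sentences containing at least one metaphor, and three
  sentiment-of-metaphor features where each metaphorical token inherits
  its sentence's overall score: the counts of metaphors in positive-
  and in negative-scored sentences (neutral sentences feed neither
  count) and the mean inherited score, 0 when the document has no
  metaphors. The counts are raw counts, not length-normalized, matching
  their definition as "numbers of" metaphors; the averaging is
  per-token rather than per-sentence-with-metaphor — both choices are
  recorded here because the definitions admit either reading.

The combined vector has a fixed, documented order
(`feature_names("all")`): the 5 metaphor features, then the 10-feature
sentiment block — sentic means, sentence fractions, $E$ and $F$.
Feature-set subsetting (`all` / `meta` / `sent`) supports the ablation
comparisons the classifier reports.

## Classifier, resampling and evaluation

**SMOTE.** The minority class is oversampled by drawing a minority
sample $x$, one of its $k = 5$ nearest minority neighbours $x_n$
(Euclidean distance on raw features), and $r \sim U(0,1)$. Canonical
mode interpolates, $x_{\text{new}} = x + r(x_n - x)$, so every
synthetic point lies on a segment between two minority points — a
brute-force membership check over all minority pairs is part of the
acceptance suite. A second mode, `as_printed`, implements the variant
$x_{\text{new}} = x + r(x - x_n)$ that some descriptions of the method
print; it extrapolates *away* from the neighbour. The discrepancy is
surfaced as an option rather than silently resolved; canonical
interpolation is the default. Resampling happens strictly inside each
training fold — test folds are never resampled, and per-fold test-set
fingerprints let the suite assert that adding SMOTE changes training
rows only.

**Network.** A four-layer fully connected network: input, two hidden
layers with output widths 100 and 50, and a 2-way softmax output. The
input and hidden layers use CReLU, $\text{CReLU}(z) = [\max(z,0),
\max(-z,0)]$, which doubles each layer's output width; the stated
widths are read as the linear layer's output before concatenation, so
with $p$ features the widths run
$p \to 2p \to 100 \to 200 \to 50 \to 100 \to 2$. Dropout 0.4 sits
between the two hidden layers; all weight matrices carry an L2 penalty
($\lambda = 10^{-4}$ by default). The exact wiring of activation to
layer widths is a design choice recorded here; the architecture's
sources state output dimensions but not the concatenation bookkeeping.

Unstated training hyperparameters were fixed once: Adam at learning
rate $10^{-3}$, batch size 16, at most 500 epochs, early stopping with
patience 20 on a 10% stratified validation split of the training data,
restoring the best weights. The monitored quantity is plain validation
cross-entropy, *excluding* the L2 term: the penalty decreases smoothly
for hundreds of epochs and would mask convergence of the fit itself. An
improvement must exceed `min_delta = 1e-4` to reset the patience
counter, since dropout makes the monitored loss noisy at the
$10^{-5}$ scale. Features are z-standardized inside `msm_train()`
(scaler stored, re-applied at prediction; zero-variance columns pass
through) because the feature blocks mix raw counts with fractions on
incompatible scales; in cross-validation the scaler is therefore fit on
the training fold only.

**Evaluation.** Stratified 10-fold cross-validation (plain k-fold on a
small imbalanced cohort risks single-class test folds, which the
implementation treats as an error); per-fold accuracy and F1 with sick
as the positive class, F1 defined as 0 when precision and recall are
both 0. The logistic-regression comparator is ridge-penalized
(`glmnet`, $\alpha = 0$, $\lambda = 0.01$) and the SVM comparator uses
an RBF kernel (`e1071` defaults); both receive the same per-fold
standardization and folds as the network.

## The synthetic-data generators

Real corpora for this problem are private or organizer-distributed, so
the package carries generators that emulate the *structure* the
pipeline depends on, at fixture scale.

**Planted embeddings.** A designated "context" axis carries the input
vectors of context and sentiment words; detected words sit nearly
orthogonal to it while their ontology synonym sits close to it, so the
best-fit search always selects the synonym. In output space each
detected/synonym pair is planted at a cosine of $0.5 - m - 0.05$
(metaphor-source words) or $0.5 + m + 0.05$ (literal words) for margin
$m$ (default 0.3), and the generator verifies every planted cosine by
direct computation at generation time, failing on infeasible geometry
(dimension below 6 or margin outside (0, 0.5)). Words without ontology
entries fall back to singleton candidate sets and are therefore always
literal — which is exactly how context and sentiment words are kept
out of the way.

**Cohorts.** Documents are template-built from the planted vocabulary:
each sentence holds context-word slots, two detected-word slots that
draw a metaphor-source word with the class's metaphor rate, and — when
the sentence's target sentiment score is nonzero — one strength word
that realizes that integer score exactly. Per-sentence target scores
are drawn from a normal around the class mean (sd 1.2) and rounded
into [−4, 4]. The default cohort is 29 sick / 127 healthy (the
prevalence of the least common condition in a 156-author cohort, so
imbalance handling is exercised realistically), 8–12 sentences per
document, metaphor rates 0.10 vs 0.02 and mean sentiment −1 vs +1. The
generated text is a token stream, not natural language: the pipeline
only consumes tokens, so linguistic realism is not required for
correctness testing — but for the same reason, passing on synthetic
cohorts demonstrates the machinery, not performance on real writing.

**Problem sizes used by the test and acceptance runs** (chosen once as
a balance between statistical resolution and desk-scale runtime, and
fixed): identification and recovery checks use 20 + 20 documents; the
full-effect classification runs use the default 29/127 cohort over 10
seeds; the metaphor-rate dose–response runs hold sentiment neutral in
both classes (isolating the metaphor dial) and use 25/50 cohorts at
sick rates 0.02/0.06/0.10 with 10 replicates each; the null
calibration uses 300 balanced samples of label-independent features
over 20 seeds, where mean CV accuracy must stay near chance.

## Corpus handling and resources

Tokenization, sentence splitting, coarse POS tagging and lemmatization
are deterministic and rule-based: a regex word/punctuation tokenizer, a
punctuation splitter with a small abbreviation list, closed-class word
lists plus suffix heuristics mapping to five coarse tags (noun, verb,
adjective, adverb, other), and suffix-stripping lemmas keyed on the
coarse tag. Content words are exactly the four open classes. A
user-supplied POS lexicon overrides the heuristics — the synthetic
generator emits one, so tagging is exact on synthetic corpora. No
claim is made that token counts match any external tokenizer; the
pipeline's definitions are stated in terms of its own tokenization.

Per-user writing histories (user id, timestamp, title, body) merge
chronologically into one document per user, with titles prepended and
every part terminated with a period to protect sentence splitting.
Lexicons load from CSV (strength: `word,pos_strength,neg_strength`;
sentic: `word` plus the five dimensions), embeddings from word2vec
text format (one file per matrix), and the ontology from a JSON
fixture `{word: {pos: {synonyms: [...], hypernyms: [...]}}}` — a full
lexical database exported to that shape plugs in unchanged. Duplicate
lexicon rows resolve last-wins with a warning; out-of-range values are
load errors with row numbers.

## Limitations

* Multiword expressions are not handled: multiword ontology candidates
  are dropped, and multiword metaphors cannot be detected.
* The identifier conflates novel and conventional metaphor and is
  blind to fixed collocations (see above).
* The rule-based tagger and lemmatizer are crude on real English;
  on real corpora a user should supply a POS lexicon or accept tagging
  noise in the content-word inventory.
* Sentence-sentiment scoring is a lexical approximation of external
  strength-scoring tools (no idioms, emoticons, boosters); the
  precomputed-score backend exists precisely so external scores can be
  substituted.
* All empirical claims in the package's tests are about synthetic
  corpora with planted structure; nothing here certifies predictive
  performance on real clinical text.
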