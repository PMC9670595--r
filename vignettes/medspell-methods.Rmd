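---
title: "Context-aware typo correction for medical text: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware typo correction for medical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medspell)
```

This vignette explains the models behind `medspell`, the parameters that
matter, what the synthetic corpora do and do not emulate, and the design
choices made where more than one reasonable option existed. Every number
shown here is computed by the chunk that prints it.

## The correction model

A token is a *non-word error* when it is absent from the word-frequency
dictionary. Correction proceeds in three steps.

**1. Candidate generation.** The dictionary maps words to corpus counts;
words rarer than `min_count` (default 20, with a count of exactly 20
retained) are excluded, as are numbers, symbols, and single characters,
because they generate pathological candidate sets. Candidates for a query
are all dictionary words within restricted Damerau–Levenshtein (optimal
string alignment) distance `max_distance` of it. We use the *restricted*
variant — insertions, deletions, substitutions, and adjacent transpositions,
each costing 1 — because swapped adjacent letters are one of the four
injected error types; plain Levenshtein would price a transposition at 2 and
systematically demote transposed candidates. Lookup uses a delete-only
neighborhood index: each dictionary word precomputes every string reachable
by at most `max_distance` deletions, and a query is answered by intersecting
its own deletion variants with that map. The intersection overgenerates for
substitutions and transpositions at distance 2, so every survivor is
verified with the exact distance before it becomes a candidate. The
equivalence of this fast path with a brute-force scan over the dictionary is
property-tested.

`max_distance` defaults to 2: every injected error is a single operation
(distance 1), and a cap of 2 tolerates one additional pre-existing
irregularity in the token.

**2. Scoring.** Candidates are ranked by the convex combination

$$\mathrm{FinalScore} = \lambda\,\mathrm{FrequencyScore}
  + (1-\lambda)\,\mathrm{ContextSensitiveScore}.$$

Both terms are normalized over the candidate set so they live on the same
$[0,1]$ scale: `FrequencyScore` is the candidate's dictionary count divided
by the summed counts of all candidates, and `ContextSensitiveScore` is the
context backend's probability of the candidate at the masked slot,
renormalized over the candidate set (softmax of the raw log-scores). The
renormalization choice matters — a raw masked-slot probability and a
relative frequency are not commensurate, and the convex combination is only
meaningful if its two terms are. Ranking ties are broken by smaller edit
distance, then larger raw count, then lexicographic order, so output is
fully deterministic.

$\lambda$ defaults to 0.5, a neutral prior between the two information
sources; it is exposed everywhere. At $\lambda = 1$ the ranking provably
reduces to frequency ordering and at $\lambda = 0$ to the context backend's
ordering (both are asserted in the tests).

**3. Substitution.** By default only out-of-vocabulary tokens are examined
(`oov_only = TRUE`): the experiments inject non-word errors, and re-ranking
valid words risks false alarms that precision pays for. Every token is
scored against the *original* corrupted sentence, never against earlier
corrections, so results do not depend on processing order. The chosen
candidate inherits the original token's capitalization pattern (initial
capital, all-caps).

## The context backend

The reference scorer of the method is a pre-trained transformer masked
language model with a dense softmax head. Shipping or pre-training one is
out of scope for an offline package, so the scorer is a *contract*:
`score_candidates(scorer, tokens, target_index, candidates)` must return one
finite probability per candidate, summing to one, depending only on its
inputs. Two backends implement it:

* **Bidirectional interpolated n-gram backend (default, trained in-repo).**
  The raw score of candidate $c$ at slot $i$ is the mean of a left-to-right
  and a right-to-left n-gram log-probability, approximating the MLM's
  bidirectional conditioning. Each direction averages the additively
  smoothed conditionals of orders $1..n$ (default order 3, smoothing 0.01).
  The interpolation is load-bearing: a short query sentence rarely repeats a
  training trigram context exactly, and without back-off every candidate
  would collapse onto the same smoothed floor. Additive smoothing guarantees
  finite scores for unseen words — the classical scarcity problem of count
  models. The backend serializes to a TSV counts file and reloads exactly.
* **Transformer MLM backend (optional).** `transformer_mlm_scorer()` wires a
  user-supplied scoring function over external pre-trained weights into the
  same contract; without one it raises a classed
  `medspell_backend_unavailable` error. A multi-subword candidate should be
  scored by masking one slot per subword piece and averaging the per-slot
  log-probabilities, a length normalization that avoids penalizing longer
  candidates.

The same pluggable pattern is used for the NER tagger: the in-repo baseline
is an HMM (additively smoothed transitions and emissions, a word-shape
back-off for unseen tokens, Viterbi decoding hard-constrained to valid BIO
transitions), and a fine-tuned transformer can stand behind the same predict
contract, with its hyper-parameter defaults (`fine_tune_config()`: learning
rate 3e-5, 3 epochs, maximum sequence length 178, batch size 16, Adam,
softmax) recorded but never exercised offline. `label_probabilities()`
exposes the forward–backward per-token posteriors; each row is a softmax
distribution over the scheme's labels.

## The typo-injection model

Words are corrupted through their two-way splits. A word of $n$ characters
has $n+1$ splits; the two with an empty side are excluded, leaving $n-1$
eligible:

```{r}
eligible_splits("random")
```

One eligible split is drawn and one of four operators applied — INSERT a
random ASCII letter between the halves, DELETE the first character of the
right half, REPLACE it with a random *different* letter, or TRANSPOSE the
first two characters of the right half:

```{r}
c(DELETE = apply_error("rand", "om", "DELETE"),
  TRANSPOSE = apply_error("rand", "om", "TRANSPOSE"),
  INSERT = apply_error("rand", "om", "INSERT", letter = "c"),
  REPLACE = apply_error("rand", "om", "REPLACE", letter = "c"))
```

Every corruption is therefore a true change at edit distance exactly 1
(asserted property-wise against the distance function). Two edge cases
needed decisions the split rule alone does not settle:

* A transposition of two *equal* adjacent characters would be a no-change;
  such splits are never drawn, and `apply_error()` rejects them.
* A two-letter word's only eligible split leaves a single character on the
  right, so it can never host a transposition. When corpus corruption
  balances the four error types (counts within one of each other, exact
  quarters when the total divides by 4), TRANSPOSE assignments are swapped
  onto tokens that can host one rather than redrawn, which preserves the
  type quota exactly; a corpus with no such token raises a capacity error.

Corruption targets alphabetic tokens of length ≥ 2, at most one typo per
token; the request is either an absolute count or a rate (fraction of
eligible tokens), since experiments are reported both ways. All randomness
flows through R's RNG, so `set.seed()` makes runs byte-identical, and every
change is logged in a provenance record (position, operator, split point,
original and corrupted form) that downstream evaluation keys on.

## Evaluation semantics

**Correction** is scored per token against the clean corpus. A corrupted
token restored to its original is a true positive; one left wrong is a false
negative; a *wrong change* — a typo fixed to the wrong word, or a clean
token edited — is a false positive (a mis-fix counts as both fn and fp).
This is the only reading under which support equals the injected-typo count
while precision and recall can still differ: precision is penalized by wrong
fixes, recall tracks restoration. `tp + fn = support` is invariant.

**NER** uses exact-span, exact-type entity matching — the strictest common
convention — with micro-averaged F1 pooled over entities, per-type
breakdowns, and token accuracy reported alongside. Gold files are validated
strictly (a dangling `I-X` is an error); predictions are repaired
(`I-X` promoted to `B-X`), the standard asymmetry: model output should never
crash an evaluation, gold errors should fail loudly. The evaluator is
property-tested against an independently written chunk evaluator on random
label sequences.

**The sweep** converts each rate into a balanced error budget over the test
corpus, tags the corrupted tokens, corrects, and tags again; each rate is
deterministically re-seeded from the sweep seed.

## Synthetic corpora: what they emulate, and what they do not

Real pathology records are restricted data, and the public disease-mention
corpus is a download; the package therefore generates its own test beds.

`generate_spr_corpus()` emulates the *structure* of surgical pathology
result lines: `Organ, Location, OperationName : HistologicDiagnosis, size`,
with gold BIO tags under a scheme whose entity types are ORGAN, LOCATION,
OPNAME, HISTOLOGIC DIAGNOSIS, and TUMOR_SIZE. The vocabulary tables ship as
a small TSV of clinically plausible lung-pathology terms; entity lengths are
short (≤ 3 tokens), matching the observation that short entities dominate
such records and are the most typo-fragile. The tag scheme has no
`I-TUMOR_SIZE`, so a size span must be one token; the generator accordingly
emits sizes unspaced (`2.1×1.3×1cm`, or occasionally `1.2cm` followed by
`IN GREATEST DIMENSION`), which is also how such measurements commonly
appear in practice. Both the `×` and ASCII `x` dialects and integer and
one-decimal dimensions are emitted, exercising the parser's tolerance;
`extract_max_dimension()` accepts spaced and unspaced forms, requires the
`cm` unit unless all three dimensions are present, and returns the maximum.

`generate_prose_corpus()` emits template sentences over a closed vocabulary
with deliberate collocations. A few words (e.g. "lung", "right", "node")
are *globally rarer* than a spelling neighbor at distance 1 ("long",
"night", "code") yet fully determined by their local context. This is the
regime the combined score exists for: a frequency-only ranker reliably
prefers the frequent neighbor, and the context term reverses it. The margin
between the combined and frequency-only restoration F1 on these fixtures is
therefore structural, not a seed accident.

What the fixtures do **not** show: robustness to real clinical spelling
variation (abbreviations, hyphenation, section headers, OCR noise),
real-word errors, spacing errors, or performance at realistic dictionary
scale (millions of words). Passing tests demonstrate the mechanics and the
qualitative directions — correction recovers entity F1, context beats
frequency where context disambiguates — not absolute real-data scores.

## Numerical choices and degenerate inputs

* Softmax subtracts the maximum before exponentiation; probability vectors
  sum to 1 within 1e-9 everywhere they are asserted.
* Precision, recall, and F1 use the 0-convention when their denominators
  vanish (a system that changes nothing has precision 0, not NaN).
* Empty corpora, empty candidate sets, unknown labels, misaligned corpora,
  and over-budget corruption requests raise immediate, located errors; empty
  *inputs* that are meaningful (empty sentence, no-match query) return empty
  values instead.
* Dictionary serialization sorts by descending count then lexicographic, so
  identical dictionaries are byte-identical on disk.

## Problem sizes

The shipped experiments run on one CPU in well under two minutes total: the
context-vs-frequency comparison trains on 600 template sentences and
corrupts 150 test sentences at a 15% rate; the NER sweep trains tagger,
dictionary, and language model on 200 synthetic pathology lines and sweeps
rates {0.05, 0.10, 0.15} over 120 held-out lines; the candidate-generation
equivalence check covers 100 random dictionary/query instances. These sizes
give stable margins on the pinned seeds while keeping the full suite fast.

## Known limitations

* The n-gram backend is a desk-scale approximation of a masked language
  model; with a rich context on both sides it discriminates well, but it
  cannot model long-range or semantic constraints.
* Only non-word errors are corrected; real-word (context-sensitive) errors
  and spacing errors pass through by design.
* The HMM tagger's unseen-token back-off is a single word-shape feature; it
  is adequate for template corpora and deliberately simple. On real text a
  fine-tuned transformer behind the same contract is the intended tagger.
* `corrupt_corpus()` does not prevent a corruption from colliding with a
  real dictionary word (e.g. REPLACE turning "lung" into "long"); such
  real-word collisions are invisible to an OOV-triggered corrector and are
  recorded in the provenance records for analysis.
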