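---
title: "Methods: Markov sequence learning, scoring and strategy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov sequence learning, scoring and strategy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predstat)
```

This vignette documents the models implemented in `predstat`, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open — in the spirit of a methods section a
reviewer could audit.

## Stochastic sources

A `MarkovSource` is a *k*-th order Markov chain over a small alphabet: the
target `s(i)` is drawn from a distribution conditioned on the context
`(s(i-1), ..., s(i-k))`. Order 0 is memory-less. Two canonical sources
define the two training conditions:

* **Level 0** — occurrence probabilities `0.18, 0.72, 0.05, 0.05` for
  `A–D`. Two symbols dominate (one strongly), two are rare.
* **Level 1** — each context allows exactly two targets, with
  probabilities `0.8` and `0.2`. The texture of conditional uncertainty
  therefore matches Level 0 (two viable continuations, one favored) while
  the *memory order* differs — the manipulation of interest.

The Level-1 transition matrix is not uniquely determined by the published
design description (only one row and the row constraints are stated), so
the package fixes a canonical default, `canonicalLevel1Table()`:
`A→B/C, B→C/D, C→D/A, D→A/B`, each `0.8/0.2`. This is the simplest matrix
satisfying every stated constraint — two allowed targets per context, the
`A→B` example, and equal marginal symbol probabilities (its stationary
distribution is exactly uniform, verified against a linear-solve oracle in
the tests). Any other row-stochastic matrix can be supplied.

### Information-theoretic summary

`summarizeSource()` reports, in bits (log base 2 throughout):

* marginal entropy `H(m)` of the stationary symbol distribution,
* entropy rate `h = Σ_c π(c) H(target | c)` with stationary context
  weights,
* predictive complexity `C = H(m) − h`, the average reduction in
  uncertainty about the next symbol gained by knowing the past.

For any order-0 source `C = 0` identically (the package returns an exact
zero rather than a rounding residue). For the canonical Level-1 source
`H(m) = 2` bits (the 4-symbol maximum), `h = H(0.8, 0.2) ≈ 0.7219` bits,
so `C ≈ 1.28` bits.

Stationary distributions are computed by power iteration on the lazy chain
`(P + I)/2` — same fixed point, aperiodic by construction, so the
iteration converges even for periodic chains such as a deterministic
cycle — to a `1e-10` max-norm tolerance. A chain with more than one closed
communicating class has no unique stationary distribution; the package
raises an error naming the offending state sets rather than silently
picking one.

### Sequence generation and selection

`generateSequence()` draws the initial context from the stationary context
distribution (unless supplied), so sequences are marginally stationary
from their first symbol; the initial context conditions the first draw but
is not part of the output. Generation is bit-reproducible for a fixed
seed (Mersenne-Twister, seeded locally without disturbing the caller's
RNG stream).

`selectSequences()` reproduces the stimulus-screening step: by default
10,000 candidates of 672 symbols per level, ranked by the KL divergence of
each candidate's empirical table from the source, keeping the 50 lowest.
Ties are broken by generation index so the result is a deterministic
function of the seed. Divergences are empirical-from-source,
`Σ P_emp log2(P_emp / Q)`, with per-context terms weighted by the
**empirical** context frequencies of the sequence. The published formulas
leave open whether context terms are weighted empirically or by the
source-stationary probabilities; empirical weighting is the default here
because it makes the statistic a property of the realized sequence alone
(and the two coincide as sequences grow long), with stationary weighting
available via `weights = "stationary"`. The conventions `0·log 0 = 0` and
"empirical mass where the source has none ⇒ flagged `+Inf`" apply to every
divergence in the package.

`sequenceEntropyRate()` applies the same per-sequence philosophy: the
"stationary distribution of contexts" is taken as the within-sequence
context frequency, so each sequence gets its own entropy-rate value (as
needed when the entropy rate serves as a per-sequence covariate).

## Trial and block design

`partitionBlock()` cuts one 672-symbol sequence into 56 trials — 8 trials
at each context length 8–14, in seeded shuffled order — consuming the
stream left-to-right without gaps; each trial's following symbol is the
hidden target. The arithmetic `8 × Σ(ℓ+1), ℓ = 8..14 = 672` closes
exactly, which is why the chain is modeled as running *continuously*
across trials within a block (a restart-per-trial design would not
reproduce the 672-symbol bookkeeping). Partitioning is lossless:
concatenating context + target over trials reproduces the input sequence,
a property the tests assert.

`buildTrainingSession()` draws block sequences from the selected pool
without replacement within a session (5 blocks/session);
`buildScanningRun()` builds the scanning layout (5 structured + 5 random
blocks in counterbalanced order, 2 trials per block, 10-symbol contexts).
Presentation timing (300 ms stimulus, 500 ms ISI, 2 s response window) is
out of scope: no real-time presentation is implemented.

## Synthetic responders

`ResponderModel` defines, per trial (in this order): a null response with
probability `nullRate`; a uniform lapse with probability `lapse`;
otherwise the policy — `uniform`, `matcher` (samples the source
conditional for the trial's trailing-k context), `maximizer` (modal
target, alphabet-order tie-break), or `mixture` (plays an asymptotic
policy with a per-block scheduled weight, else guesses uniformly).
`learningSchedule()` provides the saturating time course
`w(b) = ceiling − (ceiling − floor)·exp(−rate·b)`.

The default cohort (`defaultCohort()`) has 20 members: 12 learners (lapse
∈ {0, 0.1, 0.2} × asymptotic policy ∈ {matcher, maximizer} × rate ∈
{0.2, 0.5}), 6 pure non-learning matchers/maximizers at the same lapses,
and 2 uniform guessers. The null-response rate is 2% throughout — a
realistic omission rate for a 2-s response window. These agents emulate
the *statistics* of responding (context-conditional choice distributions
and their drift across blocks). They do not emulate reaction times,
feedback-driven updating (the paradigm has no trial-by-trial feedback),
sequential dependencies between successive choices, or attention lapses
that correlate across trials — so passing recovery tests shows the
estimators work on drifting multinomial responders, not that human data
are this well-behaved.

## Scoring

Per block and context, `AbDist = Σ_t |R(t|c) − Q(t|c)| ∈ [0, 2]` (the L1
distance; its half-complement `PI(c) = 1 − AbDist(c)/2` is the overlap of
the two distributions), and `PI = Σ_c π(c)·PI(c)` with stationary context
weights. Conventions:

* The reference distribution defaults to the **source model** conditionals
  rather than the block's realized targets. This choice is anchored by the
  uniform-guessing baselines: a 0.25-each responder scores exactly
  `PI_rand = 0.53` against Level 0 and `0.45` against Level 1 under the
  model reference. (The Level-1 baseline also fixes the interpretation of
  "equal probability per context": uniform over all four symbols, not
  over the two allowed targets — the latter would give 0.70.) The realized
  targets remain available via `reference = "empirical"`.
* Contexts with no non-null responses in a block take the random-guess PI
  for that context, keeping the weighted mean defined on 56-trial blocks.
* Null responses are excluded from all distribution estimates and counted
  separately — except in `accuracy()`, the proportion of correctly
  predicted trials, where they count as incorrect.

## Strategy analysis

Two baseline models per source: `matching` (the source table) and
`maximization` (point mass on each context's modal target). Both, and the
empirical response table, are floored at `epsilon` and renormalized;
response tables additionally fill never-observed contexts with the uniform
row. The per-block **strategy choice** is
`ΔKL = KL(R‖M_matching) − KL(R‖M_maximization)` with stationary context
weights (empirical weights optional): negative toward matching, positive
toward maximization. Because the `R·log R` terms cancel in the
difference, `ΔKL` is linear in `R` — handy both for reasoning about
expected values and for the exact zero-crossing constructed in the tests.

**Choice of the smoothing floor.** Smoothing is a modeling necessity, not
a detail: the unsmoothed maximization model assigns zero probability to
every non-modal target, so any responder who ever deviates from the mode
would sit at infinite divergence. The package defaults to
`epsilon = 0.05`. The floor acts as the maximization model's tolerance
for off-mode responses, so it should sit at the scale of the off-mode
response rate actually expected of an imperfect maximizer — a responder
with lapse rate λ emits each non-modal symbol at rate ≈ λ/4, i.e. 0.05 at
λ = 0.2, the top of the cohort's lapse range. A much smaller floor (e.g.
0.01) makes the maximization model so spiky that, on the Level-0 source,
an expected-value calculation classifies a maximizer with 20% lapse as a
matcher (`ΔKL < 0`) — the statistic would stop measuring the intended
construct at realistic noise levels. `epsilon` is exposed on every
strategy function for sensitivity analyses.

**Strategy index.** The index integrates (trapezoid over block index) the
responder's strategy curve and subtracts the integral of the
exact-matching baseline curve — the constant `ΔKL` of a responder whose
response model *is* the smoothed matching model. The published verbal
definition subtracts in the opposite order from its stated sign
interpretation ("negative indicates matching"); the package defaults to
`participant − matching-baseline`, which makes the index positive toward
maximization, consistent with that interpretation, and offers
`convention = "matching-minus-participant"` for the literal reading.

## Pipeline and reproducibility

`runConfig()`/`runExperiment()` execute the whole protocol: per level,
sequence selection → 4 training sessions × 5 blocks × 56 trials (1120
trials/level, inside the protocol's 840–1400 range; 3–5 sessions are
accepted) → cohort simulation → PI, accuracy, strategy curves and indices,
all written as TSV plus a JSON manifest. Every stage seed is derived from
the master seed by a counter scheme recorded in the manifest, so any
single stage can be reproduced in isolation; re-running a config
reproduces all tables byte-identically (the log file carries the wall
clock and is the one non-deterministic output). `summarizeRun()` reads a
run directory back and reports learning curves, strategy curves and the
matcher/maximizer separation; optional plots are written as PDF.

## Numerical choices and degenerate inputs

* Log base 2 everywhere; entropies and divergences in bits.
* `0·log 0 = 0`; support violations return a flagged `+Inf` rather than
  an error, except where a sequence contains symbols outside the alphabet
  (an error).
* Stationary distributions: lazy power iteration, tolerance `1e-10`,
  validated against a direct linear solve; reducible chains error with
  the offending states named.
* Maximizer and modal-target ties break by alphabet order (the canonical
  sources have unique modes); `strict = TRUE` turns ties into errors.
* Order-0 sources use a single empty-string context; all internal lookups
  are positional because R's character indexing cannot address an
  empty-string dimname.
* Degenerate inputs rejected with explicit messages: non-normalized
  probability rows, sequences shorter than the order, partition length
  mismatches (both totals reported), pools smaller than the session's
  block count, empty response sets, single-block strategy curves.

## Problem sizes in the test suite

The tests exercise the full default protocol where the property under
test depends on it (cohort sign recovery runs all 20 responders over
4 sessions × 5 blocks × 56 trials on both levels), and scale the
incidental dimensions down (candidate pools of 60–200 sequences rather
than 10,000) since pool screening quality is orthogonal to the properties
being tested; convergence properties use n = 10,000 symbols/trials with
3-standard-deviation binomial tolerances. The full-size selection
(10,000 × 672) remains the default of `selectSequences()` and
`runConfig()`.

## Known limitations

* Only the generic machinery supports orders k ≥ 2; the canonical designs
  are orders 0 and 1, and no variable-order or hidden-Markov models are
  provided.
* The strategy statistics inherit the arbitrariness of the smoothing
  floor; comparisons across datasets should hold `epsilon` fixed.
* Learning-curve *fitting* (e.g. least-squares saturating fits for
  display) is not implemented; curves are reported per block.
* Everything here concerns behavioral statistics; no neuroimaging
  quantities are computed.
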