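---
title: "Methods: resampling, forced-choice and minced-oath analyses of profanity sound patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resampling, forced-choice and minced-oath analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweardar)
```

This vignette documents the statistical machinery of `sweardar`: the
models, their assumptions, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## Segment coding

All analyses operate on ASJP transcriptions: ASCII strings with one symbol
per segment class (41 symbols; 34 consonants, 7 vowels `i e E 3 a u o`).
`tokenize_asjp()` splits a string into segments; whitespace and
punctuation separate the words of a phrase and yield no tokens, so a
phrase simply contributes the segments of all its words. Symbols are
case-sensitive (`s` = /s/, `S` = /ʃ/).

ASJP modifier characters are rare in practice and absent from the word
material these analyses target, so the default mode simply strips them.
Two alternatives are provided for robustness with real ASJP exports: in
`join` mode a trailing `~` (or `$`) merges the preceding two (three)
symbols into one multi-segment token, which is then classified by its
first symbol; `strict` mode refuses modifiers and unknown symbols
outright, which makes it the right mode for validating curated inputs.

The classification table maps each symbol to one of eight mutually
exclusive classes: the six consonant groups under test — plosives
`b d g p t k`, affricates `c C j`, approximants `l L w y r`, sibilant
fricatives `s z S Z`, non-sibilant fricatives `f v 8 x h X`, nasals
`m n N 5` — plus vowels and a catch-all `other` (the remaining ASJP
consonants, e.g. clicks and the dental fricative code `T`, which belong to
none of the six groups). The table never fails: unknown symbols classify
as `other` with a warning, so a stray character cannot silently shift a
group count.

Vowels count toward a word's total phoneme count. The source material for
the resampling analysis never specifies a vowel inventory, so the standard
seven ASJP vowel codes are used; whether the difference statistic's
denominator includes vowels is nevertheless exposed
(`denominator = "all"` vs `"consonants"`) because the choice rescales the
statistic.

## The resampling null

For one language, let the target (swear-word) lexicon contain $N$
phonemes in total, $n_t(g)$ of them in consonant group $g$, and let the
control lexicon (a Swadesh-style basic-vocabulary list) supply a pool of
phoneme tokens. Each of `n_sims` (default 1,000) simulations draws $N$
phonemes from the pool and records

$$d_{s}(g) = \mathrm{scale} \cdot \frac{n_t(g) - n_{s}(g)}{N},$$

with `scale = 100` by default so $d$ reads as "phonemes per 100": a value
of $-3$ means the group appears three fewer times per 100 phonemes in the
swear words than in a typical control sample. Under the default
with-replacement sampling, $n_s(g) \sim \mathrm{Binomial}(N, f_g)$ with
$f_g$ the pool frequency, so
$\mathbb{E}[d(g)] = \mathrm{scale}\,(n_t(g)/N - f_g)$ — an identity the
test suite checks against the closed form. Sampling without replacement
is available and requires the pool to be at least as large as $N$.

Two readings of "sampling phonemes from the control list" are possible:
drawing individual phoneme tokens from the pooled list (used here, as the
literal reading) or drawing whole words until $N$ phonemes accumulate.
Token-level sampling gives the exact binomial null above; word-level
sampling would inflate the variance slightly through word-length
clustering.

Per-group inference pools languages with an intercept-only linear mixed
model $d \sim 1 + (1\,|\,\mathrm{language})$, fitted by REML with
Satterthwaite degrees of freedom (`lmerTest`). The random intercept
absorbs stable cross-language differences in how strongly a group is
over- or under-used; observations within a language are exchangeable
simulations, so the residual term captures pure Monte-Carlo noise. With a
single language the model is not identified and the function degrades to
the exact equivalent in that case, a one-sample t-test; with zero
variance (every $d$ identical) it returns the constant with `se = 0` and
a degeneracy flag rather than erroring. A distribution-free companion,
`empirical_quantile_p()`, reports per-language two-sided empirical tail
probabilities floored at $2/\texttt{n\_sims}$.

The alpha policy reflects a planned-comparison design: one group
(plosives, the group prior literature points to) is judged at
$\alpha = 0.05$ and the remaining five at the fixed Bonferroni level
$0.05/5 = 0.01$. The level is stored as the constant 0.01 rather than
recomputed so the reported policy matches the printed one exactly.

## The forced-choice pipeline

Trial tables carry one row per 2AFC trial. The participant rules are
applied first, then the trial rules, and both are idempotent:

* attention: error fraction on attention-check trials strictly greater
  than 25% (a participant with no checks cannot be judged by this rule;
  this is logged);
* premature: responded before the second audio file ended on 10% *or
  more* of trials (inclusive, as worded);
* slow: among a participant's no-replay trials, 10% or more exceed three
  times the median no-replay reaction time. The median is per-participant
  by default — each participant's tempo is their own baseline — with a
  global variant behind `rt_median_scope = "global"`;
* runs: any run of ≥ 10 identical responses, implemented but **off by
  default**. `run_exclusion_probability()` justifies the default: an
  exact dynamic program over (current response, current run length)
  states shows an attentive coin-flipping responder produces such a run
  in 88 trials with probability 0.0758, far too high for an exclusion
  rule. The DP treats each trial as an iid choice of the first option
  with probability `p`; the probability is exact to double precision and
  the suite cross-checks it against large Monte-Carlo simulations.

Trial-level exclusions then drop premature trials and no-replay trials
slower than three times the no-replay median.

Selection of the affricate variant (coded 1, vs 0 for the approximant
variant) is modelled as
$\mathrm{logit}\,P(y=1) = \beta + u_p + u_i$, with crossed random
intercepts $u_p \sim N(0, \sigma_p^2)$ for participants and
$u_i \sim N(0, \sigma_i^2)$ for items, fitted with `lme4::glmer` (Laplace
approximation; the method string is recorded in the fit). Complete
separation returns a flagged infinite estimate instead of an error, and
singular fits are flagged as boundary. `implied_proportion()` converts
$\beta$ to the percentage scale via the inverse logit — `100 * plogis(beta)`
— which is a model-implied proportion for the average participant and
item; the pipeline also reports the raw pooled proportion, which differs
slightly because averaging over random effects is not the same as setting
them to zero.

## The minced-oath test

Each pair contributes the difference `minced − original` in approximant
count. Counts come from the transcriptions, so rhoticity is an input
decision: a non-rhotic (British-style) transcription of *darn* has no
approximant, a rhotic one has one. Originals are counted once per pair —
a source word with several minced variants appears with multiplicity —
because the test is over pairs.

The Wilcoxon signed-rank test uses the Pratt method for zeros: absolute
differences are ranked *including* zeros (midranks for ties), then the
zero ranks are discarded and $W^+$, $W^-$ are the rank sums of positive
and negative differences. The reported $W$ is by default
$\min(W^+, W^-)$, the common reporting convention; both one-sided sums
are always returned, and the plain zero-discarding variant is available
as `zero_method = "wilcox"` (it provably differs on inputs with zeros).
For 15 or fewer nonzero differences the two-sided p-value is exact, by
full enumeration of the $2^m$ sign assignments of the nonzero ranks
($p = 2\min\{P(W^+ \le w^+), P(W^+ \ge w^+)\}$, capped at 1); beyond that
a normal approximation with the standard zero- and tie-adjusted mean and
variance is used, which reproduces the common scientific-computing
implementations of the Pratt approximation to machine precision. A known
limitation: count data with heavy ties (many $|d| = 1$) make the rank-sum
distribution lumpy, so the exact and approximate p-values can disagree by
up to about 0.1 at moderate $n$ — the package therefore prefers the exact
path whenever enumeration is feasible, and all-zero inputs return a
flagged degenerate result ($W = 0$, $p = 1$).

## The synthetic-data generator

The generator exists so that each stage has inputs with known ground
truth. It emulates the *statistical* structure of the real data, not its
linguistics:

* **Lexicons.** Words are strings of 2–8 segments (truncated geometric
  length, matching the short CV-style items of the experimental stimuli),
  each segment drawn iid from a class-frequency vector (default: 45%
  vowels, plosives the most common consonant group, affricates the
  rarest) and then a uniform symbol within its class. Depletion
  multiplies the target set's frequency for one group (default
  approximants) by $\delta$ and renormalizes: $\delta = 1$ is the null,
  $\delta = 0$ removes the group. The iid-segment design is a deliberate
  simplification — it makes generated class frequencies converge exactly
  to the spec vector (a law-of-large-numbers property the tests check) at
  the cost of all phonotactic realism: no CV alternation, no sonority
  sequencing, no cross-language typological correlation. Passing tests
  therefore demonstrate the *inference machinery* recovers planted
  frequency structure, not that real lexicons behave like the generator.
* **Trials.** Defaults mirror the experiment's scale: 215 participants
  across six native-language groups, 40 experimental items, 40 fillers
  and 8 attention checks (88 trials each), true $\beta = 0.52$ and random
  intercept standard deviations of 0.5. Contamination is planted
  deterministically so exclusions can be validated exactly: a fixed
  number of participants (7.5% by default) miss exactly half their
  attention checks, and a further 2.5% respond prematurely on 20% of
  trials; attentive participants answer all checks correctly and respond
  prematurely at a 0.3% per-trial base rate. Reaction times are
  log-normal (median 1.5 s, $\sigma_{\log} = 0.4$), which incidentally
  yields a realistic ~1% rate of over-slow trials.
* **Oath pairs.** Originals are generated words; the minced variant
  differs by exactly one segment substitution, which with probability
  `insertion_prob` (default 0.6 over 67 pairs) is an approximant.

All generators are pure functions of their spec: the seed lives in the
spec, per-language streams are derived deterministically from language
identifiers, and repeated calls are byte-identical.

## Numerical choices and problem sizes

Monte-Carlo checks in the test suite use a fixed seed throughout. The
suite validates the run-probability DP against $10^6$ simulated
88-trial sequences (and a grid of smaller designs at $10^5$), the type-I
error of the corrected resampling decision over 500 replicate pipelines
of 1,000 simulations each, planted-depletion recovery over 100
replicates, and GLMM parameter recovery at the full 215 × 40 design over
100 replicates; these sizes give binomial standard errors a few times
smaller than the effects being checked while keeping the default test run
to a few minutes. GLMM convergence follows `lme4` defaults; the
mixed-model estimation method is always recorded in the returned fit so
downstream reports can state it.

## Known limitations

* The mixed model pools at the language level only; random slopes,
  language covariates and cross-group joint modelling are out of scope.
* The generator's phonotactics are deliberately naive (see above).
* Exact Wilcoxon enumeration is capped at 25 nonzero differences
  ($2^{25}$ assignments); beyond the default threshold of 15 the normal
  approximation is used.
* Grapheme-to-phoneme conversion is out of scope: transcriptions are
  inputs, and encode decisions such as rhoticity.
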