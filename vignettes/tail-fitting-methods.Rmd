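---
title: "Fitting Zipf's law to word and lemma frequencies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitting Zipf's law to word and lemma frequencies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zipflemma)
```

## The scientific question

Zipf's law for word frequencies can be stated in its frequency form: the
probability that a type (a distinct word form or lemma) occurs exactly $n$
times in a text follows

$$f(n) = \frac{n^{-\gamma}}{\zeta(\gamma, a)}, \qquad n \ge a,$$

with exponent $\gamma$ (near 2 for natural text), a low-frequency cutoff $a$
below which the law does not hold, and the Hurwitz zeta function
$\zeta(\gamma, a) = \sum_{k \ge a} k^{-\gamma}$ as normalization. The
rank-frequency form $n(r) \propto r^{-\alpha}$ is equivalent on the tail,
with $\gamma = 1 + 1/\alpha$.

The package exists to ask how this law behaves under *lemmatization*:
replacing every word form by its dictionary headword (houses, housed,
house → *house*) collapses whole inflectional paradigms onto single types
and reshapes the entire frequency distribution. The empirical questions are
whether the power-law tail survives, and whether its two parameters —
$\gamma$ and $a$ — are preserved. `zipflemma` implements the full analysis
pipeline: corpus ingestion and unit definitions, the tail fitter, frequency
spectra with finite-size rescaling, a cross-text statistical battery over
paired (word, lemma) parameters, and a synthetic-corpus generator that makes
the whole pipeline testable without access to any copyrighted novel.

## The tail fitter

Fitting a discrete power-law tail means choosing $a$ as well as estimating
$\gamma$; the two-step procedure in `fit_powerlaw_tail()` is:

1. **Candidate cutoffs** are laid on a geometric grid with 10 points per
   decade (`cutoff_grid()`): successive values multiply by
   $10^{1/10} \approx 1.26$ and non-integers are rounded up. Rounding up
   guarantees $a \ge 1$ and reads "the next integer" in the direction of an
   increasing scan.
2. **For each cutoff**, the exponent is fitted by maximum likelihood on the
   counts with $n \ge a$ (`fit_exponent()`): the log-likelihood
   $-\gamma \sum_i \ln n_i - N_a \ln \zeta(\gamma, a)$ is maximized
   numerically over $\gamma \in (1 + 10^{-6}, 10]$ to a tolerance of
   $10^{-6}$. The interval covers every exponent plausibly reported for
   heavy-tailed count data with a wide margin.
3. **Goodness of fit** (`gof_tail()`) uses the Kolmogorov–Smirnov distance
   between the empirical CDF and the fitted model CDF on the tail.
   Its null distribution is obtained from Monte-Carlo replicas drawn from
   the *fitted* model; crucially, each replica is re-fitted by maximum
   likelihood before its KS distance is computed, so the simulated data
   undergo the same estimation step as the real data. Skipping the re-fit
   systematically inflates p-values. The p-value is the fraction of replicas
   with a KS distance at least as large as the empirical one (ties count
   toward the p-value: the conservative convention). The standard deviation
   $\sigma$ of the re-fitted exponents is the reported uncertainty of
   $\hat\gamma$.
4. **Selection**: the chosen cutoff is the smallest one whose p-value
   exceeds 0.20 — the widest range on which the power law is not rejected.
   If no cutoff is accepted the result is an explicit "no power-law tail
   found" object, not an error. A fit is flagged `zipf_valid` when the
   accepted tail spans at least two decades ($n_m / a \ge 100$).

The defaults (10 grid points per decade, 1000 Monte-Carlo replicas,
acceptance threshold $p > 0.20$) are the standard operating point for this
family of methods; all three are arguments.

One design question is whether each Monte-Carlo replica should re-run the
*entire* cutoff scan rather than just the exponent fit at the candidate
cutoff. The two-step structure of the procedure (fit $\gamma$ at fixed
$a$, then judge that fixed-$a$ fit) implies the latter, which is what
`gof_tail()` does; re-scanning inside every replica would also raise the
cost of a scan by two orders of magnitude. The same convention is used for
$\sigma$: it quantifies uncertainty in $\hat\gamma$ *given* the selected
$a$, and therefore understates the total uncertainty, since cutoff selection
itself is data-driven. This caveat applies equally to the downstream
comparisons.

`fit_truncated_head()` addresses the complementary regime: some lemma
distributions show a second, shallower power law between $n = 1$ and a
maximum frequency. It fixes the lower end and scans truncation points $b$
downward from the maximum observed frequency, returning the largest
accepted truncated fit.

### Numerical choices

* $\zeta(\gamma, a)$ is computed by Euler–Maclaurin summation (25 direct
  terms, Bernoulli corrections through $B_{12}$), accurate beyond 10
  significant digits over the whole search interval.
* Sampling from the discrete law (`rpowerlaw()`) inverts a precomputed CDF
  table covering all but $10^{-9}$ of the mass, capped at $2^{16}$ entries;
  the rare draws beyond the table are inverted through the continuous tail
  approximation $\zeta(\gamma, x) \approx x^{1-\gamma}/(\gamma - 1)$, whose
  error at the table end is negligible relative to Monte-Carlo noise at the
  sample sizes involved. All randomness flows through R's RNG, so a single
  seed makes every fit, test and simulation bit-reproducible.
* The KS distance is evaluated on the full integer support when the range is
  small, and at the observed values and the points just before them (where
  the discrepancy of a step function against an increasing CDF is extremal)
  when the range is large.
* Degenerate inputs fail loudly: fewer than two in-range counts, or all
  counts equal, are errors at the single-fit level; inside a cutoff scan
  such cutoffs are skipped.

## Frequency spectra and rescaling

`frequency_spectrum()` keeps the spectrum over raw integer $n$ — the fitter
consumes raw counts, and binning is purely presentational.
`rescale_spectrum()` applies the moment rescaling

$$x = n \langle n \rangle / \langle n^2 \rangle, \qquad
  y = f(n) \langle n^2 \rangle^2 / \langle n \rangle^3,$$

a pure shift in log-log coordinates that removes the leading sample-size
dependence; spectra of distributions sharing a tail exponent then collapse
onto a common curve. `collapse_distance()` quantifies the collapse as the
mean absolute $\log_{10}$ difference of binned densities over the top
shared decades (5 bins per decade; within each bin the point masses are
summed and divided by the bin width, which keeps sparsely occupied tail
bins unbiased).

A practical warning: the upper decades of an empirical spectrum are the
extreme-value region. At vocabulary sizes of a few thousand types, only
tens of types occupy the top 1.5 decades, so even a perfect collapse
carries Poisson noise of a few tenths in this distance. Simulation of
same-exponent pairs at $V = 2000$–$8000$ puts typical values at 0.1–0.4;
the tests assert at that empirically calibrated scale. The distance is a
diagnostic for gross exponent mismatch, not a precision statistic.

## The cross-text battery

Given per-text paired parameters (word vs lemma; exponents or cutoffs),
`compare_texts()` runs the hypotheses battery:

* **Identical distribution within a text** — the exact coin-flipping test
  (`coin_flip_test()`): under the null, swapping the word and lemma value
  inside any text is immaterial, so all $2^N$ swap configurations are
  enumerated and $|\bar x - \bar y|$ is referred to its exact permutation
  distribution. The identity configuration always counts, so $p \ge 2^{-N}$.
* **Paired t** (`paired_t()`), $t = \bar d \sqrt{M} / s_d$ with the unbiased
  $s_d$, optionally after removing the pair with the largest $|d|$ (the
  outlier treatment). Because outlier removal distorts the null, the
  p-value comes from simulation (`simulated_t_pvalue()`): independent
  zero-mean normals with a common standard deviation, subjected to the same
  removal rule. With no removal this reproduces the closed-form Student-t
  tail, which the tests verify. The common-variance null is an
  approximation — the per-text $\sigma$'s differ — so these p-values are
  read as indicative.
* **Mean independence** — $E[x \mid y] = y$ implies the ratio $x/y$ is mean
  independent of $y$, which requires uncorrelation; Pearson and Spearman
  correlations of the ratio-vs-value forms are tested by permutation
  (`cor_perm_test()`): reshuffling one variable, two-sided by $|\rho|$,
  exhaustive over all $N!$ permutations when $N \le 9$ and seeded sampling
  (default $10^5$) otherwise. Complementarily,
  `mean_independence_regression()` fits OLS and tests slope $= 1$ and
  intercept $= 0$ with classical $N - 2$ d.f. standard errors.
* **Error propagation** — `sigma_diff()` combines the per-text fit
  uncertainties as $\sigma_d = \sqrt{\sigma_w^2 + \sigma_l^2}$, valid under
  independence of the two fits; the within-text covariance of the word and
  lemma estimates cannot be estimated from a single sample per text, so
  $\sigma_d$ is an upper bound on precision, not a substitute for the
  ensemble tests.

No multiple-testing correction is applied to the primary p-values;
Bonferroni and Šidák columns are emitted alongside so the reader can apply
either. The bundled `ten_novels()` table of published tail parameters for
ten classic novels makes the whole battery reproducible to the printed
precision, and the test suite asserts exactly that.

## The synthetic-corpus generator

`synthetic_spec()` fixes the generating conditions; the defaults are the
study conditions the pipeline is validated under: lemma frequencies iid
from the discrete power law with $\gamma = 2$, $a = 1$ — the classical
Zipf operating point — and $V = 5000$ lemma types, which yields tails
spanning three decades, comparable to a long novel's lemma table.

Words are derived from lemmas by a broken-stick rule: a lemma of frequency
$n \ge 2$ splits into two word forms with frequencies $(m, n - m)$, $m$
uniform on $\{1, \ldots, n-1\}$. The discrete uniform is taken over the
interior so that both word forms actually exist; hapax lemmas are
indivisible and stay whole. Under this rule the word-frequency distribution
retains the lemma-tail exponent — the property that makes word/lemma
exponent comparisons non-trivial — and the package verifies this
empirically (the supporting analytical derivation is not reproduced here).
A `broken_stick_k` variant splits recursively, always breaking the largest
remaining part, and an `ambiguity_rate` links a stated fraction of word
types to a second lemma in the association map without moving any counts,
emulating forms like English *found* that belong to two paradigms.

`write_corpus()` realizes the counts as a shuffled token-per-line stream;
every pipeline statistic is order-invariant, so the shuffle is purely
cosmetic, and re-reading the file reproduces the tables exactly — the
round-trip is asserted in the tests.

What the generator does *not* emulate: real morphology (the placeholder tag
column carries no information), the empirically wide distribution of words
per lemma (verb paradigms in Romance or Finnic languages can exceed 50
forms; the 2-way split caps it at 2), sentence structure, lemmatization
errors, and vocabulary-growth (Heaps-law) effects. Consequently, passing
tests demonstrate that the *estimators* are calibrated and that the
pipeline is faithful, not that real texts satisfy the model; with real
corpora the fitted window, dictionary coverage and tagging errors all
matter, and the low-frequency end of lemma distributions is known to be
the most error-prone region.

## Validation scales

The test-suite simulations are sized to exercise each claim at desk scale:
parameter-recovery coverage uses $N = 2000$ counts per fit with $\sigma$
from 40 Monte-Carlo re-fits and 100 replicas per $(\gamma, a)$ condition;
goodness-of-fit calibration uses $N = 500$ and 200 replicas per dataset;
broken-stick exponent preservation uses $V = 5000$ lemmas over 20 seeded
replicas; full cutoff scans in examples use 60–100 Monte-Carlo replicas
per cutoff. The estimator itself defaults to 1000 replicas, the operating
point intended for real analyses.

## Known limitations

* $\sigma$ conditions on the selected cutoff; total exponent uncertainty is
  larger by an amount that is hard to quantify.
* The simulated paired-t null pools variances across texts.
* The coin-flip test is exact but limited to $N \le 25$ texts by
  enumeration; beyond that, subsample or use the Monte-Carlo sign-flip
  approach shown in the tests.
* Lemmatization itself is out of scope: the package consumes the
  token-per-line output of external taggers and never attempts
  morphological analysis. The naive whitespace tokenizer is gated behind an
  explicit flag and intended only for demos.
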