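# zipflemma

Zipf's law tail fitting for word-form and lemma frequency distributions.

`zipflemma` is an R toolkit for quantitative-linguistics (and, more broadly,
heavy-tailed count-data) analyses that ask whether a power-law frequency
distribution survives a re-aggregation of its types — the canonical case
being *lemmatization*, where the word forms of a text (houses, housed,
house) are collapsed onto their dictionary headword (*house*). It is aimed
at corpus linguists and complex-systems researchers who need a calibrated,
reproducible version of the standard tail-fitting machinery rather than a
by-eye log-log fit.

## The model and method

For the frequency form of Zipf's law, the probability that a type occurs
exactly *n* times is

    f(n) = n^(-gamma) / zeta(gamma, a),   n >= a,

with exponent gamma (near 2 for natural text), a low-frequency cutoff *a*,
and the Hurwitz zeta function as normalization. The rank-frequency form
n(r) ∝ r^(-alpha) is related by gamma = 1 + 1/alpha. The package:

* fits gamma by Hurwitz-zeta maximum likelihood for a given cutoff;
* judges each candidate cutoff by a Monte-Carlo Kolmogorov–Smirnov
  goodness-of-fit in which every simulated replica is re-fitted before its
  KS distance is computed (skipping the re-fit inflates p-values);
* selects the smallest cutoff with p > 0.20 on a geometric grid of 10
  points per decade, and flags fits whose tail spans at least two decades;
* compares word vs lemma parameters across texts with an exact sign-flip
  ("coin-flipping") test, outlier-aware paired t tests with simulated
  nulls, permutation correlation tests, and mean-independence regressions;
* generates seeded synthetic corpora (power-law lemma frequencies, uniform
  broken-stick word splitting, optional lemma ambiguity) so the entire
  pipeline can be validated without any copyrighted text.

## Worked example

Generate a synthetic corpus, count both unit types, and fit both tails:

```r
library(zipflemma)

spec <- synthetic_spec(gamma = 2, a = 1, V_lemmas = 5000,
                       splitting = "broken_stick_2", seed = 42)
sim  <- simulate_corpus(spec, path = tempfile(fileext = ".tsv"))

toks   <- read_corpus(sim$path)
lemmas <- count_types(toks, "lemma")
glance(lemmas)
#> # A tibble: 1 × 7
#>   unit      L     V   n_m    V1 mean_n mean_n2
#>   <chr> <int> <int> <int> <int>  <dbl>   <dbl>
#> 1 lemma 32302  5000  4705  3051   6.46   9523.

fit_powerlaw_tail(count_types(toks, "word"), n_sims = 200, seed = 1)
#> <tail_fit> discrete power law on n >= 2
#>   gamma = 1.9619 +- 0.0257  (KS = 0.0159, p = 0.215, N_a = 1734, n_m = 3360)
#>   Zipf validity (two decades): TRUE

fit_powerlaw_tail(lemmas, n_sims = 200, seed = 2)
#> <tail_fit> discrete power law on n >= 1
#>   gamma = 2.0110 +- 0.0147  (KS = 0.0034, p = 0.835, N_a = 5000, n_m = 4705)
#>   Zipf validity (two decades): TRUE
```

Both fits recover the generating exponent (gamma = 2) within uncertainty,
and the broken-stick word table keeps the lemma exponent — the invariance
the word/lemma comparison revolves around.

The cross-text battery runs on a per-text parameter table; the bundled
`ten_novels()` table of published tail parameters for ten long novels in
four languages reproduces the reference analysis:

```r
cmp <- compare_texts(ten_novels(), seed = 3)
cmp$tests[cmp$tests$parameter == "a", c("test", "n_removed", "statistic", "p_value")]
#>   test      n_removed statistic p_value
#> 1 paired_t          0     -3.18  0.0123
#> 2 paired_t          1     -3.09  0.0192
#> 3 coin_flip         0     16.9   0.0156
#> 4 coin_flip         1     13.2   0.0312
```

The word and lemma cutoffs differ significantly however they are tested
(the lemma cutoff is systematically larger — lemmatization shrinks the
range of validity of Zipf's law), while the same battery applied to the
exponents finds only a marginal difference once one outlier text is
removed. The regressions make the cutoff asymmetry explicit:

```r
cmp$regressions[3:4, c("model", "slope", "se_slope", "intercept", "se_intercept")]
#>   model      slope se_slope intercept se_intercept
#> 1 E[a_w|a_l] 1.01    0.103      -17.5         7.80
#> 2 E[a_l|a_w] 0.912   0.0932      20.0         6.27
```

Slopes compatible with 1 but a significantly positive intercept for
E[a_l | a_w]: lemma cutoffs sit above word cutoffs by an additive offset.

A command-line front end wrapping the same functions ships in
`inst/cli/zipflemma.R` with subcommands `count`, `fit`, `compare`,
`simulate` and `spectrum`.

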