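---
title: "Scoring the IAT: the algorithm family, its evaluation, and the design choices behind iatkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the IAT: the algorithm family, its evaluation, and the design choices behind iatkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatkit)
```

## The problem

An Implicit Association Test session yields, per subject, two blocks of
reaction times and error flags — one for the *compatible* category–key
pairing and one for the *incompatible* pairing (classically 60 trials each:
20 practice + 40 test). The implicit preference is inferred from how much
slower (and more error-prone) the incompatible block is. Reaction-time
distributions are heavy-tailed, contaminated by fast guesses and lapses,
and heteroscedastic across subjects, so the mapping from raw trials to a
score involves consequential choices. `iatkit` treats that mapping as a
four-parameter design space and provides the machinery to measure, rank and
statistically compare the options.

## The four parameters

**Parameter 1 — extreme-latency treatment** (per critical block; the 10 s
ceiling is always applied first, to correct and error trials alike):

| option | rule |
|---|---|
| `none` | baseline |
| `fixed_trim` | drop latencies < 400 ms |
| `fixed_winsor` | recode < 300 ms to 300 ms and > 3000 ms to 3000 ms |
| `stat_trim` | remove the k = ⌊0.10·n⌋ fastest and k slowest latencies |
| `stat_winsor` | replace those 2k values by the most extreme retained order statistics |
| `stat_inverse_trim` | remove the k latencies immediately below and above the median |

The fixed cutoffs encode task-level theory (sub-300 ms responses cannot
reflect full processing; multi-second responses reflect distraction); the
statistical cutoffs adapt to each block's empirical distribution. Inverse
trimming deliberately deletes the centre instead of the tails — the
interference effect may live in the tails — but is, by the same token, not
robust.

**Parameter 2 — error treatment**: `ignore` (pool correct and error
latencies before Parameter 1), `exclude` (drop errors), `separate`
(Parameter 1 applied independently to the correct and error subsets, both
kept), `recode_2sd` / `recode_600` (replace each error latency by the
block's treated-correct mean + 2·SD or + 600 ms). The recode penalties
re-inject the speed–accuracy trade-off into the latency metric; with a
built-in-penalty procedure the recorded error latency already contains the
correction time, which is why `ignore` means something different across the
two IAT procedures.

**Parameter 3 — score formula**: with treated blocks \(C\) (compatible) and
\(I\) (incompatible),

- D: \((\bar I - \bar C)/SD_{C\cup I}\) — an individualized effect size;
  the inclusive SD damps general-speed differences.
- G: pooled fractional ranks \((r-0.5)/N\) with midranks, mapped through
  \(\Phi^{-1}\); score = difference of block means of these Gaussian ranks.
  Exactly invariant under any strictly increasing latency transform.
- WPR: \((q_{.90}(I) - q_{.90}(C))/SD_{C\cup I}\) — scores from the slow
  tail only (worst-performance rule).
- Mini-differences: all \(|I|\times|C|\) pairwise differences
  \(I_i - C_j\) (3600 for 60-trial blocks), mean divided by SD, with
  variants that trim/winsorize/inverse-trim the *difference* distribution
  with the same 10% statistical operators.

Simple mean, median and log-mean differences are deliberately not included;
they are consistently dominated by D-type scores and have dropped out of
practice.

**Parameter 4** — either pool all critical trials (`no_distinction`) or run
the entire pipeline separately on practice and test subsets and average the
two scores (`distinction`, which implicitly up-weights the rarer practice
trials).

The cross gives 420 algorithms. When Parameter 1 is distribution-free
(`none`, `fixed_trim`, `fixed_winsor`), `ignore` and `separate` are
provably identical — applying a fixed rule to a pooled set or to its parts
yields the same multiset — so deduplication keeps the `ignore`-coded spec
as canonical representative and leaves 378 unique algorithms. Presets
encode the conventional scores (`D2`, `D5`, `D6`: fixed trimming, the three
error options, D formula, distinction) and their improved variants
(statistical winsorizing + no distinction, changing nothing else).

### Conventions pinned here (the literature leaves them open)

- **k per tail** is ⌊p·n⌋ on the vector the operator sees: deterministic,
  no fractional removal.
- **Inverse trimming** sorts ascending and removes the k retained values at
  indices adjacent to the centre (both central positions for even n; the
  median itself is kept for odd n); ties broken by sort stability.
- **Winsorizing replacement** is the most extreme retained order statistic
  (standard winsorizing).
- **Order of composition**: the recode baselines (mean + 2SD / + 600) are
  computed on the *post-treatment* correct latencies of the block, and
  recoded values are not re-subjected to the latency treatment. This
  mirrors the D-score tradition in which extreme-latency handling precedes
  error replacement; the alternative order is defensible and the choice is
  isolated in `apply_error_treatment()`.
- **SD** is everywhere the sample (n−1) standard deviation.
- **WPR quantile**: linear interpolation between order statistics
  (`stats::quantile` type 7).
- **G fractional ranks**: \((r - 0.5)/N\) with midranks; pinned in one
  function (`score_g`) so an alternative convention is a one-line change.
- **Minimum data rule**: a block (or phase subset) must retain ≥ 2 scored
  latencies after all treatments, otherwise the cell is missing with a
  coded reason rather than a fragile number.
- **`G_standard` preset**: the G is scored on untrimmed pooled trials
  (`none`, `ignore`, `G`, `no_distinction`); being rank-based it is largely
  insensitive to tail treatment, which is the point of using it.

## Psychometric evaluation and rank composition

Per algorithm and dataset the package computes: split-half reliability
(odd/even by within-block presentation order, full pipeline on each half,
Pearson r, Spearman–Brown 2r/(1+r) clamped to [−1, 1]); test–retest
correlation across sessions; and Pearson validity correlations with
direct, indirect and behavioral criterion measures (pairwise deletion,
criteria pre-oriented so higher = stronger target-consistent preference,
behavioral criteria constituting predictive validity). The odd/even split
and the Spearman–Brown correction are explicit choices — alternating trials
share block context, which makes this split mildly optimistic relative to
random splits; the scheme is isolated so alternates can be added.

Indicators are converted to rank scores within dataset and indicator
(midranks on ties, highest rank = best), averaged within property, and
composed: overall validity is the unweighted mean of the direct, indirect
and predictive rank scores (absent properties drop out of the mean), and
the reliability composite averages the available reliability properties.
Ranking makes the downstream comparison invariant to any monotone
recalibration of an indicator.

## The rank-based inferential layer

Comparisons of parameter options use algorithm × dataset units and
rank-based robust methods throughout (midranks everywhere):

- `bdm_two_way()` computes the ANOVA-type statistic for both main effects
  and the interaction of a crossed two-way layout: global midranks, cell
  relative effects \(\hat p_i = (\bar R_i - 0.5)/N\), projection hypothesis
  matrices, and Box-approximated fractional degrees of freedom
  \(\hat f = \mathrm{tr}(TV)^2/\mathrm{tr}(TVTV)\),
  \(\hat f_0 = \mathrm{tr}(TV)^2 / \sum_i (T_{ii}V_{ii})^2/(n_i-1)\), with
  \(V = N\,\mathrm{diag}(\hat\sigma_i^2/n_i)\) estimated from within-cell
  rank variances. The statistic is referenced to \(F(\hat f, \hat f_0)\).
  The cell-size-weighted mean of the relative effects is exactly 0.5 by
  construction — a built-in self-check. The reported
  \(\eta_p^2 = f_1 F/(f_1 F + f_2)\) is an approximation derived from the
  ATS and labeled as such in output.
- `tukey_relative_contrasts()` reports all pairwise differences of group
  relative effects with simultaneous two-sided CIs. The equicoordinate
  critical value comes from the estimated joint normal distribution of the
  contrast statistics (`mvtnorm::qmvnorm` on their correlation matrix),
  with Bonferroni as fallback; the single-step adjusted p-values use the
  same joint distribution. Large-sample normal quantiles are used rather
  than t approximations; the Monte Carlo coverage checks in the test suite
  bear this out at the group sizes the package targets.
- `patel_hoel()` tests a 2×2 interaction on the dominance scale:
  \(\Delta = \hat P(A_1 < A_2 \mid B = b_1) - \hat P(A_1 < A_2 \mid B =
  b_2)\) with midrank (ties-half) estimates, per-level Brunner–Munzel
  placement variances, and a normal CI.
- `build_tgraph()` turns significant contrasts into a winner→loser
  digraph and applies transitive reduction (an edge is omitted when its
  endpoints are connected by an indirect path), preserving reachability
  exactly; a significance cycle — impossible for contrasts derived from a
  common relative-effect ordering — is rejected as an input error.

## The synthetic-data generator

`generate_iat()` emulates the study conditions the scoring comparison
assumes: 20 practice + 40 test trials per pairing (60 per critical block),
ex-Gaussian latencies (μ = 600, σ = 100, τ = 150 ms — typical
classification-task values), a per-subject general-speed offset
(SD 100 ms), and a latent preference θ ~ N(0, 1) that shifts the
incompatible/compatible gap by 150·θ ms split ± half across pairings and
moves the per-trial error probability (base .05, slope .04 per unit θ in
the incompatible direction, clamped to [.01, .5]) — so errors carry
preference signal and error-discarding treatments lose information, as in
real IATs. Contamination injects 2% fast guesses (100–300 ms) and 1%
lapses (3–9.5 s). Built-in mode adds a positive correction time
(300 ms + Exp(mean 300 ms)) to error latencies, making error trials slower
than correct ones within every block. Criterion measures are
loading·θ + noise with loadings .5 / .35 / .25 for direct / indirect /
behavioral; session 2 redraws trial noise around a θ attenuated by a
stability coefficient (default .8). All defaults are fixture choices fixed
once, not empirical claims.

What the generator does *not* model: recoding/faking strategies, block-order
effects, stimulus-level crossed random effects, practice-driven speedup
within blocks, and subject-level slow-responder exclusions. Passing tests
therefore show the pipeline's internal correctness and calibration under a
realistic RT family, not that any option ordering generalizes to real data.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to the
smallest designs that make each check meaningful: ATS type-I calibration
uses a 3×2 layout with 15 observations per cell and 2000 null replicates;
simultaneous-CI coverage uses 3 groups of 15 and 800 replicates;
latent-preference recovery uses 30 replicates of 200 subjects × 240 trials.
Degenerate inputs (empty blocks, zero pooled SD, fewer than 2 treated
correct latencies for a recode baseline, n < 2k for trimming) produce coded
missing values, never silent numbers. All randomness flows through
explicit seeds.

## Known limitations

- The contrast variance uses the diagonal (Brunner-type) approximation of
  the relative-effect covariance; cross-covariances induced by pooled
  ranking are ignored, which the coverage simulations show to be mildly
  liberal (~94% observed for 95% nominal at n = 15/group).
- η²ₚ for the ATS has no canonical definition; the conversion used here is
  a labeled approximation.
- The odd/even split-half scheme is one of several defensible splits.
- Rank tables feeding `bdm_two_way()` treat algorithm × dataset units as
  independent, as the rank-composition design intends; dependence among
  algorithms sharing a dataset is not modeled.
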