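# iatkit

Scoring algorithms and robust comparison machinery for the Implicit
Association Test (IAT).

The IAT infers implicit preferences from the latency difference between two
"critical" block pairings: classifying with a category–key assignment that
is *compatible* with one's association versus the *incompatible* assignment.
How that raw performance is turned into a score is a free choice with real
psychometric consequences. `iatkit` implements the full combinatorial family
of scoring algorithms spanned by four parameters, plus the machinery needed
to decide, on any dataset, which options win:

1. **Extreme-latency treatment** (6 options): none; fixed-value trimming
   (drop < 400 ms); fixed-value winsorizing (recode to 300/3000 ms); 10%
   statistical trimming; 10% statistical winsorizing; 10% inverse trimming
   (remove values adjacent to the median). Latencies above 10 s are always
   discarded first.
2. **Error treatment** (5 options): ignore, exclude, recode to the correct
   mean + 2 SD, treat correct/error latencies separately, recode to the
   correct mean + 600 ms.
3. **Score formula** (7 options): the D score
   `D = (mean_incompatible − mean_compatible) / SD_pooled`; the Gaussian-rank
   G score (difference of mean normal quantiles of pooled fractional ranks);
   the worst-performance rule `WPR = (q90_incompatible − q90_compatible) /
   SD_pooled`; and mini-differences — all pairwise incompatible-minus-
   compatible trial differences, averaged and standardized, optionally
   trimmed/winsorized/inverse-trimmed (60-trial blocks give 3600 difference
   indicators).
4. **Practice/test distinction** (2 options): pool the critical trials, or
   score the practice and test subsets separately and average.

Crossing everything gives **420 algorithms**; merging the provably identical
ignore/separate twins under distribution-free latency treatments leaves
**378 unique** ones. Named presets cover the conventional `D2`, `D5`, `D6`
(fixed trimming, distinction) and their improved variants (statistical
winsorizing, no distinction), plus a standard G.

To compare options, the package computes psychometric indicators per
algorithm (odd/even split-half reliability with Spearman–Brown correction,
test–retest correlation, convergent validity with direct and indirect
measures, predictive validity), converts them to per-dataset rank scores
(midranks, highest rank = best), and feeds the composites to a rank-based
inferential layer: two-way ANOVA-type statistics with Box-approximated
fractional degrees of freedom, Tukey-type nonparametric contrasts on
relative effects with simultaneous confidence intervals, the Patel–Hoel
2×2 interaction test, and T-graphs (significant-outperformance digraphs
after transitive reduction). A seeded ex-Gaussian simulator generates IAT
sessions with a latent preference, error signal, contamination, built-in
penalty behaviour, retest sessions, and correlated criterion panels.

## Worked example

```r
library(iatkit)

d <- generate_iat(synth_config(n_subjects = 50, seed = 42))
scores <- score_table(d$trials, list(preset("D2"), preset("D2_improved")))
head(scores, 3)
#>   subject P1.2-P2.1-P3.1-P4.2 P1.5-P2.1-P3.1-P4.1
#> 1    S001           0.1779976           1.0065099
#> 2    S002          -0.1834082          -0.6305097
#> 3    S003          -0.2174287           0.1693636
```

Each column is one algorithm (canonical id `P1.x-P2.y-P3.z-P4.w`); positive
scores mean slower responding in the incompatible pairing, in pooled-SD
units. Evaluating and comparing:

```r
ind <- rbind(validity_correlations(scores, d$criteria),
             reliability_indicators(d$trials, list(preset("D2"), preset("D2_improved"))))
rank_and_compose(ind)
#>             algorithm  dataset ... reliability overall_validity
#> 1 P1.2-P2.1-P3.1-P4.2 dataset1 ...           1              1.5
#> 2 P1.5-P2.1-P3.1-P4.1 dataset1 ...           2              1.5
```

Here the improved D2 earns the higher reliability rank (on one small
simulated dataset the validity composite happens to tie). On rank
tables spanning many algorithms and datasets, `bdm_two_way()`,
`tukey_relative_contrasts()`, `patel_hoel()` and `build_tgraph()` test which
options of a parameter significantly outperform which.

A command-line interface wraps the same functions
(`simulate`, `score`, `evaluate`, `compare`, `enumerate`, `presets`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "iatkit.R", package = "iatkit"))')" \
  score --input trials.csv --algorithms preset:D2,preset:D6 --out scores.csv
```

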