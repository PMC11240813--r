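# herdrank

Social dominance hierarchy in group-housed growing pigs, and what it does to
feeding behaviour, growth and the faecal microbiota — as one tested,
reproducible R pipeline.

Commercial pigs form stable-ish dominance hierarchies that gate access to
electronic feeders. `herdrank` implements the full analysis chain used to
study this: a paired food-competition test scored into a per-animal ranking,
per-pen hierarchy classes, feature extraction from feeder event logs with
pen-relative normalization, linear and random-intercept models for the
growth and behaviour contrasts, hierarchy-change accounting, and a
differential-network microbial biomarker analysis on genus-level 16S count
tables. A synthetic-cohort generator with planted effects makes every stage
testable without animal data.

## The methods in brief

**Ranking score.** Every pair of pen mates meets once in a two-stage food
competition (a round-robin: 7 days x 4 disjoint pairs = 28 bouts for a pen
of 8, scheduled by the circle method). A decisive bout adds +1 to the
winner's *Dominant* tally and -0.5 to the loser's; the *Dominant Confirmed*
tally receives the same only when the winner also displaces the loser in the
confirmation stage; draws are neutral and non-evaluable bouts are excluded.
With per-animal means D and C over counted bouts,

    ranking score = D / 2 + C

and within each pen of 8 the top 2 are *dominant*, the bottom 2
*submissive*, the middle 4 *intermediate*.

**Feeding behaviour.** From raw feeder sessions (animal, timestamp,
duration, intake) the package derives per animal-day: intake (g), visits,
total and median session duration, feed rate (g/s), and time in six 4-h
slots anchored at 02:00 (slot 3 is exactly 10:00-13:59), sessions split
pro-rata at slot boundaries. Each metric also has a pen-relative version
(value / same-day pen median, mixing-aware). Phase summaries are medians
over days (means for slot metrics).

**Inference.** Dominant-vs-submissive contrasts by OLS with treatment
coding; repeated weights by a single-random-intercept model fitted with
profiled REML (fixed-effect t-tests on residual df); hierarchy-change counts
by Pearson chi-square.

**Microbiome.** Genus counts are rarefied (31,731 reads) for Shannon alpha
and Bray-Curtis/Whittaker beta diversity. Biomarkers come from a
differential-network analysis: SparCC basis correlations per condition
(dominant / subordinate / pooled), modules by topological-overlap
clustering, and a per-genus transition score

    NMSS_i = sum_{j in Neighbors_A(i)} |dD_ij| - sum_{l in Neighbors_B(i)} |dD_il|

contrasting how node i's mean shortest-path distances to its neighbouring
modules change between each condition network and the pooled network
(min-max normalized to [0, 1]). A genus is a biomarker iff its score is
>= 0.25 and its BH-adjusted rank-sum p-value is < 0.05; the panel is
evaluated by stratified 5-fold cross-validated AUC of a ridge-stabilized
logistic classifier.

## Worked example

```r
library(herdrank)
report <- run_pipeline(cohort_config(seed = 11))
print(report)
```

```
herdrank run report
  class counts by phase:
phase dominant intermediate submissive
    1       16           32         16
    2       16           32         16
    3       16           32         16
  phase-3 biomarkers: Holdemanella, Acetitomaculum, Peptococcus, Oliverpabstia, Faecalibacterium
  panel AUC: 1
```

The per-phase class counts show the 2/4/2 split in all 8 pens. The feeding
contrasts (submissive minus dominant, dominant as reference):

```r
report$feeding_contrasts[1:5, ]
#>   phase       metric  estimate       se        p  n
#> 1     2     intake_g -222.9091 106.2043 4.70e-02 32
#> 2     3     intake_g -467.6012 114.2901 4.48e-04 32
#> 3     2 rel_intake_g   -0.0849   0.0378 3.26e-02 32
#> 4     3 rel_intake_g   -0.1335   0.0326 3.07e-04 32
#> 7     3    slot3_pct    4.3551   0.7958 1.46e-05 32
```

Submissive animals eat ~223 g/day less in phase 2 and ~468 g/day less in
phase 3 (8.5% and 13.4% in pen-relative terms), and spend 4.4 percentage
points more of their feeding time in the 10:00-13:59 window — the planted
effect pattern, recovered with the expected significance ordering. All five
planted genera are called with correct directions and the panel separates
the classes perfectly under cross-validation.

`run_pipeline(cfg, out_dir = "...")` additionally writes every intermediate
table (animals, bouts, hierarchy, weights, feeder events, daily summaries,
phase metrics, abundance TSV, biomarkers) plus a JSON report.

A minimal CLI wraps the same calls:

```sh
Rscript inst/cli/herdrank.R run --seed 1 --out my_run
Rscript inst/cli/herdrank.R replicate --seed 1 -n 20
```

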