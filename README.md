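# neep

Calibrated minimum-p-value survival screening for gene- and
splice-variant-level expression, with downstream prediction of
isoform-specific protein-interaction rewiring and mutational-signature
validation — for computational biologists analysing bulk RNA-seq
cohorts with clinical follow-up (and for anyone who needs a
statistically valid "optimal cutpoint" survival screen).

## The method

For each expression feature, patients are ranked by abundance and the
two-group logrank test is evaluated at every split between *low* and
*high* expression inside a percentile threshold range: low-group sizes
$k = \lfloor ls \rfloor, \dots, \lfloor hs \rfloor$ for $s$ patients
(defaults $l = 0.15$, $h = 0.85$).  The smallest p-value over the sweep
is retained.  Minimum p-values are anti-conservative — under the null
they are left-skewed, not uniform — so they are calibrated against a
single shared Monte-Carlo null: random patient permutations are swept
over the same threshold range and the empirical null distribution of
minimum p-values is built once per cohort (**NEEP**, null empirically
estimated p-values).  A feature's calibrated p-value is the null
quantile of its observed minimum p; Benjamini–Hochberg adjustment is
applied across features and q < 0.1 is called significant.  Effect
sizes are the O/E hazard ratio $(O_H/E_H)/(O_L/E_L)$ and group
mortality $1 - S_{KM}$ at 1/2/5 years.  The scan's exact null support
size is $\sum_{i=\lfloor ls\rfloor}^{\lfloor hs\rfloor}\binom{s}{i}$
(`null_size()`), and `plan_null()` sizes the simulation so adjacent
sorted p-values are distinct with chosen probability.

Downstream, `build_mgg()` constructs multi-granularity graphs —
*variant–domain–domain–variant* paths linking a survival-significant,
protein-coding isoform to potential interaction partners through
structurally supported domain–domain interactions — after classifying
each significant isoform's **gained** domains (present in it, absent
from all insignificant isoforms of its gene) and **ghost** domains
(present in an insignificant isoform, absent from it).  A
mutational-signature stage builds 96-context substitution profiles from
caller-consensus SNVs, refits signature contributions by non-negative
least squares, and compares expression-split patient groups with
Mood's median test.

Synthetic-data generators (`simulate_cohort()`,
`simulate_expression()`, `simulate_interactome()`,
`simulate_mutations()`) produce fixtures with recorded ground truth for
every stage.

## Worked example

```r
library(neep)

cohort <- simulate_cohort(200, event_rate_target = 0.4, seed = 7)
sim <- simulate_expression(cohort, n_null = 60,
                           planted = data.frame(hr = rep(2.5, 3),
                                                split_fraction = 0.4),
                           seed = 8)
elig <- filter_eligible(sim$matrix, l = 0.15)
res <- run_neep(elig$matrix, sim$cohort, N = 10000, seed = 9)
head(res[, c("feature_id", "k_star", "min_p", "neep_p", "q_value",
             "significant", "hazard_ratio")])
#>   feature_id k_star    min_p neep_p q_value significant hazard_ratio
#> 1     F00003     82 5.58e-09 0.0001  0.0063        TRUE        3.721
#> 2     F00002     69 4.56e-06 0.0009  0.0205        TRUE        2.942
#> 3     F00045     95 6.29e-06 0.0010  0.0205        TRUE        0.432
#> 4     F00001     83 1.68e-05 0.0013  0.0205        TRUE        2.485
sum(res$significant)
#> [1] 4
```

Three features (F00001–F00003) carry a planted hazard-ratio-2.5 effect
at a 0.4 split; all three are recovered with `k_star` near the planted
split of 80 patients and hazard ratios near the planted value (the
fourth call, F00045, is a false positive — at FDR 0.1 a few are
expected).  `neep_p` is the calibrated p-value: rerunning with a
different null seed changes `q_value` slightly but never the feature
ordering, because only the null calibration — not the minimum p — is
stochastic.

Command-line wrappers over the same functions live in `inst/cli/neep.R`
(`run`, `null`, `robustness`, `mgg`, `simulate` subcommands).

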