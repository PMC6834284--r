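---
title: "Calibrated minimum-p-value survival screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated minimum-p-value survival screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(neep)
```

## The problem

Given a cohort of cancer patients with right-censored survival
(`days_to_death` for observed deaths, `days_to_last_followup` for
censored exits) and a TPM abundance matrix over tens of thousands of
genes or splice variants, we want to find the features whose expression
level separates patients into groups with different survival.
Non-parametric survival analysis needs an expression threshold to split
the cohort; any single threshold is arbitrary and notoriously unstable.
Scanning many thresholds and keeping the *smallest* logrank p-value
removes the arbitrariness but breaks the p-value: the minimum of many
correlated tests is strongly anti-conservative, so raw minimum p-values
are left-skewed under the null and cannot be fed into multiple-testing
control.

The package calibrates the minimum p-value empirically (NEEP — null
empirically estimated p-values): the null distribution of the minimum p
is estimated once per cohort by Monte Carlo, every feature's observed
minimum p is converted to its null quantile, and Benjamini–Hochberg
adjustment is applied to the calibrated values.

## The screen, step by step

**Threshold scan.** Patients are sorted by ascending feature abundance,
ties broken by patient id (a fixed, deterministic rule; under the null
any tie-break is exchangeable with the permutations used for the null).
For every low-group size $k$ in $\lfloor l s\rfloor, \dots, \lfloor h
s\rfloor$ (with $s$ patients and percentile thresholds $l = 0.15$,
$h = 0.85$ by default) the two-group logrank test compares the $k$
lowest-expressing patients against the rest.  The thresholds are
realized as rank counts, not interpolated quantiles, so the scan's
support is exactly the binomial-coefficient sum computed by
`null_size()`:

$$\mathrm{size\ of\ null} \;=\; \sum_{i=\lfloor ls\rfloor}^{\lfloor
hs\rfloor} \binom{s}{i}.$$

The logrank statistic at each split uses the standard
observed-minus-expected form with the hypergeometric variance
$V_j = n_{1j} n_{2j} d_j (n_j - d_j) / (n_j^2(n_j-1))$ at each distinct
death time, referred to $\chi^2_1$.  Censored observations tied with
deaths at $t$ count as at risk at $t$ (the usual convention; no rule is
forced by the data).  A sweep is computed incrementally — moving one
patient from the high to the low group updates the at-risk tallies in
place — so a full scan costs $O(\sum_i m_i)$ instead of $s$ independent
logrank evaluations; this is implemented in compiled code, as is usual
for survival packages, and makes nulls of $10^5$–$10^6$ draws routine.

**Shared Monte-Carlo null.** Only patient ranks enter the scan, so the
null distribution of the minimum p is a property of the clinical data
alone and one null serves every feature.  `build_null()` draws one
uniform random permutation per simulation, sweeps all allowed $k$
within it (not an independent permutation per $k$), and records the
minimum p.  For small cohorts ($s \le 9$) `enumerate_null()` computes
the same distribution exactly by enumerating all $s!$ orderings; the
sampled null is tested against this exact CDF.

**Empirical p-values.** With $r$ null values at or below the observed
minimum p, the default estimator is $(r+1)/(N+1)$ — the standard
permutation-test form, which can never return zero and therefore keeps
BH adjustment well defined.  The plain fraction $r/N$ is available as
`mode = "fraction"` (zeros reported as $1/N$ and flagged).  Both are
monotone in the minimum p, so the feature ranking is identical to the
raw minimum-p ranking and does not depend on the null realization; only
the significance calls do.

**Null size planning.** Calibrated p-values are uniform under the null,
so the probability that two adjacent sorted p-values differ is
approximately $1 - m/N$ for $m$ tested features.  `plan_null()` returns
the exact product $N = \text{multiplier} \times m$ and that
probability; a multiplier of 10 gives 90% adjacent distinctness.

**Effect sizes.** At the optimal split the package reports the
observed/expected hazard-ratio estimator
$(O_H/E_H)/(O_L/E_L)$ — deliberately not a Cox fit, since the screen's
point is to avoid the proportional-hazards and censoring-independence
assumptions of Cox regression — plus group mortality $1 - S_{KM}$ at 1,
2 and 5 years (365/730/1825 days, configurable; no day convention is
canonical).  When a group has zero observed deaths, 0.5 is added to all
four tallies and the value is flagged.

**Eligibility.** A feature enters the screen only if the fraction of
patients expressing it (TPM strictly $> 0$; the natural reading given
zero-inflated expression) is at least $1 - l$; otherwise the low group
of every allowed split is dominated by ties at zero.  Constant features
are dropped as degenerate even when fully nonzero: every split of a
constant feature yields identical groups, so no minimum-p value is
defined for them.

**Robustness.** `robustness_simulation()` removes a fraction of
patients at random, re-runs the scan and compares feature *ranks* (not
p-values, which shrink with sample size) via Spearman correlation
against the full-data ranks.  At fraction 0 the procedure reproduces
the observed ranks exactly.

**Power planning.** `logrank_power_group_size()` exposes the Schoenfeld
approximation for the events needed by a logrank test at a given
allocation fraction — a planning heuristic for choosing $l$, clearly
approximate, and used nowhere in the screen itself.  Whether its alpha
should be one- or two-sided depends on the user's intent; the helper
takes alpha as given and defaults to one-sided.

## Multi-granularity graphs

Survival-significant isoforms are mechanistically interpreted by
integrating three granularities: gene-level protein–protein
interactions (BioGRID TAB2/TAB3 dialects, filtered to physical
interactions with both interactors human), structurally supported
domain–domain interactions (3did flat file or two-column TSV,
symmetric, self-pairs allowed), and per-isoform Pfam domain assignments
(HMMER3 `--domtblout` from hmmscan or hmmsearch, independent per-domain
E-value $\le$ 0.01 by default — HMMER's own defaults do not impose a
post-hoc cutoff, so one must be chosen here; accession versions
stripped).

Within a gene with at least two isoforms, a **ghost** domain is present
in at least one survival-insignificant isoform but absent from the
significant one (a potential lost interaction); a **gained** domain is
present in the significant isoform and absent from *all* insignificant
isoforms (a potential gained interaction).  The any/all asymmetry is
the literal reading of the definitions; both are implemented with one
union-based set algebra, and the two sets are provably disjoint.  When
several isoforms of one gene are significant, classification is against
the truly insignificant residue only.

`build_mgg()` applies a five-stage cascade with logged, monotonically
non-increasing candidate counts: expand gene pairs to ordered variant
pairs; require the left variant significant *and* protein-coding
(partner significance is deliberately not required); require a
catalogued DDI between a left domain (present or ghost) and a domain
present on the partner; require that supporting left domain to be
gained or ghost; require the left gene multi-isoform.  Each surviving
(significant variant, domain, domain, partner variant) combination is
one emitted path.  A gained-domain path is not additionally restricted
to partner domains absent from other isoform pairings — nothing in the
definitions forces that, so the more inclusive reading is used.

## Mutational-signature validation

Somatic SNV calls from several callers are intersected
(`intersect_callers()`: a record must be reported by every required
caller), binned into the 96 substitution-in-trinucleotide-context
classes of the COSMIC convention (purine-reference records
reverse-complemented to the pyrimidine strand), and refit against a
96 × K signature matrix by non-negative least squares.  Group
comparisons use Mood's median test: values equal to the pooled median
count as "not above" (the convention must be fixed somewhere; this one
keeps small tied tables deterministic), chi-square without continuity
correction on the 2 × 2 table, and the exact hypergeometric test
whenever an expected cell drops below 5.  Smoking-style confounders
dispatch by declared kind to Welch's t-test, the Wilcoxon rank-sum
test, or the two-sample proportion test.  Signature enrichment across
features uses the exact one-sided binomial tail; its background
probability is a required user parameter, as no canonical background
exists.

The repository ships a *synthetic* signature fixture
(`inst/extdata/synthetic_signatures_96.tsv`, built by
`synthetic_signatures()`): five distributions, each concentrating 80%
of its mass on a private block of classes with 20% spread uniformly.
Real signature definitions in the same layout drop in unchanged.

## What the generators emulate — and what they do not

`simulate_cohort()` draws exponential survival with uniform censoring —
the simplest model satisfying the proportional-hazards alternative the
logrank test targets.  Defaults: baseline hazard $\log 2 / 730$ per day
(two-year median survival, typical of an aggressive carcinoma cohort)
and, when a target event fraction is given, the censoring horizon
solved from the closed form $P(\text{event}) = 1 - (1 -
e^{-\lambda c})/(\lambda c)$.

`simulate_expression()` couples expression to survival through a
planted *binary* designation — a fraction of patients is marked "high",
their survival times are regenerated with the hazard multiplied by the
planted ratio, and their abundance draws are shifted (log-normal,
mean-log shift 2.0, sd-log 0.6: clear but imperfect separation, so rank
recovery of the split is non-trivial).  This matches the dichotomized
hypothesis the screen tests; it does *not* model dose–response
expression effects, library-size or count noise, correlated features,
or informative censoring.  Passing tests therefore demonstrate
calibration and power under the screen's own model class, not
robustness to everything real RNA-seq does.

`simulate_interactome()` plants gained/ghost paths over dedicated gene
pairs with role-disjoint accession ranges, so the expected path set is
exact and collision-free by construction; background DDIs live on a
reserved vocabulary never assigned to isoforms.  Real interactomes are
denser and noisier; the fixture tests cascade correctness, not
discovery yield.  `simulate_mutations()` draws per-patient multinomial
profiles from signature mixtures and emulates caller discordance with
independent record dropout — unbiased across contexts, unlike real
caller disagreement which is variant-class dependent.

## Numerical choices and degenerate inputs

* Zero logrank variance (one group exhausted at the only death times)
  yields p = 1 with a degenerate flag rather than NaN.
* Minimum-p ties across $k$ resolve to the smallest $k$; abundance ties
  resolve by patient id under a stable sort.  Results are bit-identical
  for a fixed seed; all randomness flows from one seeded generator per
  entry point.
* `null_size()` needs exact integers far beyond $2^{53}$ (a 432-patient
  cohort gives a 131-digit count), so it carries an addition-only
  big-integer Pascal row in base $10^{15}$ and returns a digit string
  when a double cannot represent the value exactly.
* The incremental sweep accumulates the variance term in floating
  point; agreement with from-scratch evaluation is tested to $10^{-9}$
  and with the reference `survival::survdiff` to $10^{-8}$.
* Zero mutation profiles refit to the zero vector without invoking the
  solver; profiles inside the nonnegative column span refit with zero
  residual.

## Problem sizes used by the test-suite and acceptance script

Chosen to exercise every property at desk scale: calibration on 200
null features with 120 patients and a 20,000-draw null; exact-null
comparison at $s = 8$ (40,320 enumerated orderings vs 100,000 draws);
power on 20 planted features (hazard ratio 3 at an even split) among
480 nulls with 300 patients; robustness over 20 resampling rounds at 5%
removal; signature recovery on 30 patients × 5,000 mutations with 5%
caller dropout; Mood's test level over 2,000 null repetitions; logrank
cross-validation on 1,000 random cohorts of 10–50 patients.

## Known limitations

* The screen tests a single dichotomized expression effect; graded or
  non-monotone effects, covariate adjustment and stratified or weighted
  logrank variants are out of scope.
* Analytic minimum-p corrections (Lausen–Schumacher style) are not
  implemented; the empirical null replaces them.
* The MGG stage predicts *potential* interaction changes: domain
  presence plus a structurally supported DDI is evidence, not proof,
  and protein–DNA/RNA/ligand interactions are not considered.
* Mood's median test discards magnitude information by design; with
  heavy zero-inflation in signature contributions this is a feature
  (robustness), but it costs power against location shifts that do not
  cross the pooled median.
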