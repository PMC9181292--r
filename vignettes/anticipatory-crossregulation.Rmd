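---
title: "Scoring anticipatory carbon-source cross-regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring anticipatory carbon-source cross-regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anticipatr)
```

## The scientific question

Carbon sources in the mammalian intestine are not uniformly distributed:
some sugars are abundant near the anterior end, others towards the distal
end. A bacterium that repeatedly transits this ordered landscape could, in
principle, learn the order: while growing on a sugar found upstream it
could already induce the catabolic genes for a sugar it will meet
downstream. This *anticipatory* response is distinguished from two
alternatives. A *homeostatic* response co-regulates the catabolic genes of
sugars whose spatial concentration patterns are similar (the sugars
co-occur, so inducing or repressing their genes together is simple
housekeeping). A *random* response induces the genes of an upstream sugar
while growing on a downstream one — an induction with no anticipatory
rationale.

`anticipatr` turns this idea into a testable pipeline: smooth literature
gradient profiles onto a common grid, derive an **expected** signed
cross-regulation map over ordered sugar pairs, call a **measured** signed
map from expression data, and score the agreement per category. Companion
calculators cover the wet-lab statistics that accompany such a study:
competition-assay fitness loss, maximum specific growth rate, ΔΔCt fold
changes, and reporter-screen filtering.

## Gradient profiles

Literature tables report abundance against position in heterogeneous units
and with uneven sampling. `normalize_profile()` maps both axes affinely
onto $[0,1]$ (duplicate positions are averaged first — published tables
sometimes repeat sampling sites). `loess_smooth()` then fits a locally
weighted linear regression (tricube weights, degree 1) and evaluates it at
`grid_size` evenly spaced points including both endpoints.

Parameters that matter:

* **`span`** (default 0.5): the fraction of points entering each local
  fit. Published gradient figures do not state their smoothing bandwidth,
  so the default is the common middle-ground choice; it is exposed in
  `pipeline_config()` and recorded in every report. Spans leaving fewer
  than two points per local fit are rejected.
* **`grid_size`** (default 1000): the evaluation grid; 1000 points
  reproduce the resolution used for published smoothed gradients.

Fitted values are *not* clipped to $[0,1]$: a degree-1 local fit may
slightly overshoot near steep flanks, and every downstream operation
tolerates this. The exact (`surface = "direct"`) Loess solution is used so
each grid value equals the weighted least-squares solution at that point;
the test suite checks this against an independent brute-force tricube
solver.

Profile geometry is summarized by `peak_position()` (argmax, ties broken
towards the anterior end; a flat profile warns and returns 0) and
`profile_similarity()` (Pearson correlation on the shared grid — the
simplest operationalization of "similar pattern"; the measure is kept
behind a single function so it can be swapped).

## The expectation rule

`classify_pair(a, b)` asks: growing on `a`, what should happen to the
catabolic genes of `b`? Two thresholds make the implicit decision rule
explicit (`expectation_thresholds()`):

1. similarity $\ge \rho_{\text{homeo}}$ (default 0.7) → **homeostatic**,
   expected sign $+1$;
2. otherwise $\mathrm{peak}(b) - \mathrm{peak}(a) \ge \delta_{\text{peak}}$
   (default 0.2) → **anticipatory**, expected $+1$;
3. otherwise $\mathrm{peak}(a) - \mathrm{peak}(b) \ge \delta_{\text{peak}}$
   → **random candidate**, expected $0$ (a measured induction here is a
   random response);
4. otherwise → homeostatic with expected $0$ (dissimilar but too close to
   order).

Similarity is evaluated before peak ordering, so the homeostatic label is
symmetric in the pair, and anticipatory/random-candidate are mutually
converse. Neither threshold has a published value; both defaults were
fixed once (0.7 is a conventional "strong correlation" cutoff; 0.2 is one
fifth of the normalized gut length) and are stamped into every report for
provenance. Curated knowledge can pin individual cells through the
`overrides` argument, taking precedence over the rule.

The default homeostatic expectation is co-*induction* ($+1$). Because
homeostasis really only demands that the two directions move together,
`compare_maps(homeostatic_match = "same_sign")` offers the alternative
reading: a homeostatic cell matches when its measured sign is non-zero and
equal to the reverse cell's sign.

## Measured relations

`call_relation_from_deg()` reduces a differential-expression table to one
signed relation per (treatment, target) pair: restrict to the target's
catabolic gene set, keep genes with adjusted $p <$ `alpha` (default 0.05)
and $|\log_2 \mathrm{FC}| \ge$ `lfc_min` (default 1), and take the majority
sign; no significant gene or an exact tie gives 0 — the conservative call.
Tables lacking an adjusted-p column are corrected by Benjamini–Hochberg
across the supplied table, keeping the DEG caller itself out of scope
while remaining self-sufficient. Set genes absent from a table count as
not significant (with a message): an uncalled gene is no evidence.

The qPCR route mirrors this: `ddct_fold_change()` implements
$2^{-\Delta\Delta C_t}$ against a constitutive reference transcript
(typically *ihfB*), and `relation_from_rtpcr()` votes per-gene folds
against thresholds of 2 (induced) and 0.5 (repressed).

## Concordance scoring

`compare_maps()` computes, per expected category, the percentage of
measured cells whose sign equals the expected sign. Unmeasured (`NA`)
cells never enter a denominator. Headline percentages are rounded half
away from zero; raw values are always retained in the machine output.

Symmetry is counted per *response*: a sugar pair regulating each other in
both directions is one symmetric response; a one-way non-zero cell is one
asymmetric response; silent pairs are not counted. This is the only
counting convention under which a printed split such as "16 responses,
69% asymmetric / 31% symmetric" decomposes into integers (11 one-way
cells + 5 mutual pairs); counting each direction of a mutual pair
separately would force the symmetric count to be even.
`symmetric_induction_fraction()` reports the share of symmetric pairs that
are mutual *inductions* (both $+1$); mixed-sign mutual pairs count in the
denominator only. `cross_platform_agreement()` compares two measured maps
(e.g. transcriptome versus RT-PCR calls) over cells measured on both.

## Wet-lab statistics

* **Competition fitness** (`fitness_loss()`): with blue = wild type
  (lacZ$^+$) and white = deletion mutant, $x$ and $y$ the blue/white CFU
  ratios at $t=0$ and $t=12$ h, the mutant's percentage loss is
  $100\,(y-x)/x$ — scale-invariant in the counts, positive when the
  mutant loses ground. Replicates are summarized as mean ± SE
  (`summarize_fitness()`); group comparisons use Welch's $t$ by default
  (`two_sample_t()`), since equal variances are not guaranteed between
  strains.
* **Growth kinetics** (`mu_max()`): the steepest slope of $\ln(\mathrm{OD})$
  over a sliding window of 5 consecutive readings (1 h at 15-min
  sampling), restricted to readings above `od_floor = 0.01` to keep
  blank-level noise out of the log; floored at 0. A caveat worth knowing:
  because the estimator takes a *maximum* over many windows, measurement
  noise biases it upward, not downward — replicate averaging does not
  remove this bias, so noisy plates should use wider windows.
  `pick_optimal_concentration()` picks the concentration with the highest
  mean rate, ties to the lower concentration (higher concentrations exert
  metabolic pressure).
* **Reporter screen** (`screen_positives()`, `top_k()`): OD-normalized GFP
  fold change per colony, positives strictly above a threshold, ranked
  descending with identifier tie-breaks. The phrase "a >1-fold increase"
  is genuinely ambiguous between ratio $>1$ and ratio $>2$; the default
  threshold of 2 takes the stricter reading (an increase of 100%), and
  `fold_threshold = 1` selects the other. Reports record the threshold
  used.
* **Flow cytometry** (`gate_and_summarize()`): a "tight" scatter gate is
  the interquartile box (0.25–0.75 sample quantiles, configurable) on
  forward and side scatter jointly; the median FL1 of gated events is
  reported, robust to the long tails of reporter distributions.
  `fold_repression()` is the plain treated/control ratio of gated medians
  (values $<1$ under repression), with an `invert` flag for the
  reciprocal.

## The synthetic-data module

Every input the pipeline reads can be generated with planted ground truth
(`gen_*` functions; `synthetic_scenario()` bundles a full study). Noise
models are the standard minimal choice per measurement type: Gaussian on
gradient values and $\log_2$ fold changes, Poisson on CFU counts,
lognormal on fluorescence and scatter. Each generator is a pure function
of its parameters and seed.

The default seven-source panel places planted gradient peaks in three
spatial clusters — anterior (lactose 0.06, galactose 0.10), mid (glucose
0.44, fructose 0.48) and distal (trehalose 0.82, oleic acid 0.86, maltose
0.90) — with bump width 0.15, 25 sampled positions per source and value
noise sd 0.05. The clustered layout keeps every pair far from the
classification boundaries (within-cluster similarity $\ge 0.92$,
between-cluster peak separation $\ge 0.34$), so the planted map is
identifiable from the generator's own sampled tables: a zero-noise
scenario reproduces it exactly, and cellwise flips at rate $\varepsilon$
degrade per-category agreement to $100(1-\varepsilon)$ on average. The
competition generator grows the wild-type/mutant ratio by $1/(1-d)$, so
the loss statistic has the closed-form expectation $100\,d/(1-d)$ used in
the recovery tests.

What the generator does **not** emulate: read-level RNA-Seq (it starts at
the DEG-table level, matching the pipeline's entry point), plate spatial
effects, fluorescence spillover, cross-regulation between gene *sets*
(each set's planted sign is independent), or literature heterogeneity
beyond irregular sampling and additive noise. Passing tests on synthetic
data therefore demonstrate correctness of the arithmetic and
identifiability under the stated noise models — not that any particular
organism behaves this way.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest sizes chosen to exercise
the estimators where their behavior is interesting: 25-point profiles
smoothed to 1000 grid points, DEG tables of a few hundred null genes,
competition counts around 500 CFU per class with 4 replicates over 20
seeds, 200-seed Monte-Carlo recoveries, 455-colony plates and
20000-event flow samples. Degenerate inputs have defined behavior rather
than silent answers: flat profiles warn and return peak 0, constant
profiles refuse a correlation, empty significant sets call 0, both-ways
zero-variance $t$-tests return $p = 1$ (equal means) or 0 by stated
convention, and zero white-colony counts are an error rather than an
infinite ratio.

## Limitations

The expectation rule is an explicit reconstruction of reasoning that is
usually left implicit; its two thresholds are package choices, not
measured quantities, and analyses should report them (every serialized
report does). Category percentages on real data inherit the ambiguity of
what counts as a "random" pair — here it is a pre-declared category of
ordered pairs (the converse of anticipatory), not a post-hoc label.
Finally, the published headline percentages for real intestinal data
cannot be regenerated from first principles without the underlying
expression tables; the package validates the arithmetic on printed worked
examples and on synthetic data with known truth instead.
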