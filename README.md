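# anticipatr

Tools for testing whether a gut bacterium *anticipates* its next carbon
source. Several sugars have reproducible spatial concentration gradients
along the mammalian intestine; a cell growing on a sugar abundant
upstream can gain a head start by pre-inducing the catabolic genes of a
sugar abundant downstream. `anticipatr` implements the full analysis for
researchers studying such cross-regulation in *E. coli* or similar
organisms: from literature-style gradient tables and
differential-expression results to a per-category concordance score, plus
the wet-lab statistics that accompany this kind of study (competition
fitness, growth rates, qPCR fold changes, reporter screens).

## The model

Each carbon source's concentration-versus-position profile is min–max
normalized on both axes and Loess-smoothed (tricube weights, degree 1,
default span 0.5) onto 1000 evenly spaced grid points on [0, 1]
(0 = anterior). Every ordered pair of sources (a → b: growing on *a*,
what happens to *b*'s catabolic genes?) is then classified:

| condition (applied in order)            | category          | expected sign |
|-----------------------------------------|-------------------|---------------|
| cor(a, b) ≥ ρ (default 0.7)             | homeostatic       | +1            |
| peak(b) − peak(a) ≥ δ (default 0.2)     | anticipatory      | +1            |
| peak(a) − peak(b) ≥ δ                   | random candidate  | 0             |
| otherwise                               | homeostatic       | 0             |

The measured map is called from one DEG table per treatment sugar: the
majority sign of the target's catabolic genes passing adjusted p < 0.05
and |log2FC| ≥ 1 (ties and empty sets → 0), or from ΔΔCt qPCR fold
changes (2^(−ΔΔCt) against a constitutive reference). Concordance is the
percentage of measured cells matching the expected sign, per category,
with unmeasured cells excluded; symmetry statistics count one-way cells
and mutually regulating pairs. A seeded synthetic-data module generates
every input with planted ground truth.

## Worked example

Smooth the packaged seven-source panel (a synthetic stand-in emulating
literature gradients) and build the expected map:

```r
library(anticipatr)

raw <- read_profiles(system.file("extdata",
        "intestinal_gradients_synthetic.csv", package = "anticipatr"))
profiles <- smooth_profiles(raw)          # span 0.5, 1000 grid points
round(sapply(profiles, peak_position), 3)
#>   D-lactose D-galactose   D-glucose  D-fructose D-trehalose  Oleic acid
#>       0.000       0.000       0.461       0.473       0.756       0.990
#>   D-maltose
#>       1.000

map <- build_expected_map(profiles)
head(as.data.frame(map), 3)
#>        from          to expected_sign     category
#> 1 D-lactose D-galactose             1  homeostatic
#> 2 D-lactose   D-glucose             1 anticipatory
#> 3 D-lactose  D-fructose             1 anticipatory
```

Lactose and galactose peak anteriorly and share a pattern (homeostatic);
lactose → glucose runs down the gradient, so anticipation (+1) is
expected. Running a complete synthetic study end to end:

```r
dir <- tempfile()
simulate_scenario(synthetic_scenario(seed = 20), dir)
run_pipeline(dir)
#> Pipeline result: 7 profiles, 42 expected-map cells
#> Concordance between expected and measured cross-regulation
#>   anticipatory      16/16 match  (100%)
#>   homeostatic       10/10 match  (100%)
#>   random_candidate  16/16 match  (100%)
#> Fitness loss: mean 19.1% (SE 5.58, n = 4)
```

The DEG tables were planted from the expected map, so every category
agrees perfectly; the fitness block reflects the scenario's planted 15%
competitive deficit (expected loss 100·d/(1−d) ≈ 17.6%). The same
statistics are available piecewise, e.g. for a competition assay:

```r
cc <- gen_competition_counts(d = 0.15, n0 = 500, replicates = 4, seed = 1)
loss <- fitness_loss(cc$blue_t0, cc$white_t0, cc$blue_t12, cc$white_t12)
round(loss, 2)
#> [1] 12.25 13.82 11.46 16.08
summarize_fitness(loss)   # mean 13.4, SE 1.02
```

See `vignette("anticipatory-crossregulation")` for the model's
assumptions, threshold choices and limitations.

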