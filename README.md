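# stemcycle

Quantitative analysis of stem- and progenitor-cell proliferation from
single-cell expression data and cumulative S-phase labeling experiments.

Studies of adult neurogenesis routinely need three desk analyses that sit
between standard toolkits:

1. **Pseudotime expression trends with a stage cutoff.** Given a cells x
   genes CPM matrix and a per-cell pseudotime (from an upstream trajectory
   inference), each gene's relative expression
   `log2(CPM+1) / max(log2(CPM+1))` is smoothed by local polynomial
   regression (loess, degree 2) with a 95% pointwise band. The trajectory
   is segmented into early (T1) and late (T2) stages at the **rightmost
   stationary point** of a stage-marker trend (e.g. the onset of *Tbr2*
   increase), and per-gene positive-cell frequencies are compared between
   stages with Fisher's exact test (probability-mass two-sided p;
   cross-product odds ratio).
2. **Cell-cycle scoring.** Per-cell G1/S and G2/M scores are the summed
   expression of Tirosh-style phase marker genes, divided by the
   across-cell median; cells with `max(norm_g1s, norm_g2m) >= 2` are
   called cycling, and cycling status is associated with a marker gene's
   positivity (percentages, odds ratio, Fisher p).
3. **Cumulative-labeling kinetics.** A cumulative EdU timecourse
   `LI(t) = GF (Ts + t) / Tc` (rise) plateauing at the growth fraction GF
   is fitted as two independent least-squares lines (rise + horizontal
   plateau, SSE-optimal split). The fit yields `Tc = GF/m`, `Ts = b/m`,
   `Li0 = b = GF Ts / Tc`, and the lines intersect at `t* = Tc − Ts`.

Seeded synthetic generators (`simulate_trajectory()`,
`simulate_labeling()`, `simulate_cycling_population()`) produce inputs
with the statistical structure each stage assumes, so the whole pipeline
is testable without any external download. A stereological helper
(`estimate_total_count()`) scales per-section immunopositive counts to a
whole-structure estimate (sum x 12 for a 1-in-12 section series), and
`run_pipeline()` drives everything deterministically from one JSON/YAML
configuration.

## Worked example

Cycling-versus-positivity association from a published 2x2 table
(18 marker-positive cells, 1 cycling; 82 negative, 20 cycling):

```r
library(stemcycle)
tab <- matrix(c(1, 20, 17, 62), 2, 2,
              dimnames = list(c("positive", "negative"),
                              c("cycling", "noncycling")))
percent_cycling(tab)
#> positive negative
#>      5.6     24.4
fisher_exact(tab)
#> Fisher's exact test on a 2x2 table
#>          cycling noncycling
#> positive       1         17
#> negative      20         62
#> odds ratio (cross-product): 0.1824
#> p-value (two-sided): 0.1098
```

Marker-positive cells cycle at 5.6% versus 24.4% in negative cells — a
cross-product odds ratio of 0.18, i.e. the odds of cycling are about
five-fold lower in positive cells.

Cell-cycle kinetics from a published rise line (`y = 0.6133 t + 7.996`)
and the time its plateau is reached (13.47 h):

```r
kinetics_from_lines(slope = 0.6133, intercept = 7.996, plateau_time = 13.47)
#> Cell-cycle kinetics from cumulative labeling
#>   growth fraction GF = 16.26 %
#>   cell-cycle length Tc = 26.51 h
#>   S-phase length Ts = 13.04 h
#>   initial labeling index Li0 = 7.996 %  (= GF Ts / Tc)
```

So ~16% of the population is cycling, with a ~26.5 h cell cycle of which
~13 h is S phase. The same numbers can be recovered from raw timecourse
data:

```r
tc <- simulate_labeling(kinetics_sim_spec(GF = 16.3, Tc = 26.5, Ts = 13,
                                          cells_per_sample = 2000), seed = 1)
fit <- fit_two_segment(tc)
fit
#> Two-segment cumulative-labeling fit
#>   rise:    LI = 7.611 + 0.6348 t  (R^2 = 0.888, n = 14)
#>   plateau: LI = 16.21 (growth fraction, n = 10)
#>   intersection t* = 13.55 h;  pooled SSE = 14.22
derive_kinetics(fit)
#> Cell-cycle kinetics from cumulative labeling
#>   growth fraction GF = 16.21 %
#>   cell-cycle length Tc = 25.54 h
#>   S-phase length Ts = 11.99 h
#>   initial labeling index Li0 = 7.611 %  (= GF Ts / Tc)
```

Stereological scaling of per-section counts (4 sections, 1-in-12 series):

```r
estimate_total_count(c(34, 41, 28, 37))
#> [1] 1680
```

See the methods vignette (`vignettes/stemcycle-methods.Rmd`) for the
models, parameter defaults, numerical conventions and known limitations,
including the precision attainable for Tc and Ts at realistic per-sample
cell counts.

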