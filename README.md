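# landsec

Composite-index evaluation of **land ecological security** and diagnosis of
its obstacle factors, for regional sustainability analysts working with
DPSIR-style indicator panels (n indicators observed over m years).

Land ecological security asks whether a region's land system can keep
delivering its ecological services under developmental pressure. landsec
implements the standard combined subjective–objective weighting pipeline:

1. **Normalization** — polarity-aware min–max ("range transformation"):
   positive indicators `Y = (x − min)/(max − min)`, negative indicators
   `Y = (max − x)/(max − min)`, per indicator across years, so 1 is always
   the most secure observed state.
2. **Improved AHP (subjective weights)** — expert pairwise comparisons on a
   three-level scale (`G_ij ∈ {0,1,2}`, reciprocity `G_ij + G_ji = 2`) are
   projected onto a consistent additive scale via the optimal transfer
   matrix `B_ij = (r_i − r_j)/n` (row sums `r` of `T = G − 1`), exponentiated
   into a perfectly consistent judgment matrix `Q = exp(B)`, and solved by
   normalized geometric row means (exact principal eigenvector; closed form
   `w_i ∝ exp(r_i/n)`). Layer and within-layer weights compose into totals
   `M_i`. No consistency ratio needed.
3. **Entropy method (objective weights)** — within-indicator year shares
   `P_ij = Y_ij / Σ_j Y_ij`, entropies `E_i = −(1/ln m) Σ_j P_ij ln P_ij`,
   weights `W_i = (1 − E_i)/(n − Σ E)`: the more an indicator varies, the
   more it weighs.
4. **Composite index** — combined weights `A_i = (M_i + W_i)/2`, per-year
   security value `T_j = Σ_i Y_ij A_i ∈ [0, 1]`, five DPSIR layer subscores
   summing exactly to `T_j`, and grades I (best) to V (worst) on the bins
   V ≤ 0.35 < IV ≤ 0.55 < III ≤ 0.65 < II ≤ 0.85 < I (boundaries take the
   lower grade).
5. **Obstacle diagnosis** — obstacle degrees
   `F_ij = (1 − Y_ij) A_i / Σ_k (1 − Y_kj) A_k`, per-year top-k rankings and
   cross-year frequency of the limiting factors.

The package bundles the **Xingtai city case (2006–2017, 24 indicators)** as
plain-text fixtures — indicator metadata with safety tendencies, the six
expert 0/1/2 comparison matrices, reference entropy weights, the composite
series and the per-year top-5 obstacle rankings — plus a seeded synthetic
panel generator (`simulate_panel()`, `ranking_comparison()`) standing in for
the non-redistributable raw panel.

## Worked example

```r
library(landsec)

xt <- xingtai_case()                      # bundled case-study inputs
iw <- iahp_weights(xt$comparisons)        # subjective weights from 0/1/2 matrices
round_half_up(iw$criterion, 4)
#>      D      P      S      I      R
#> 0.0774 0.3834 0.1411 0.2570 0.1411
```

Pressure (0.3834) and Impact (0.2570) dominate the criterion layer. Within
layers, the report composes displayed columns consistently (`M = BL × BP`):

```r
head(iw$report, 5)
#>   code layer     BL     BP      M
#> 1  D_1     D 0.0774 0.4484 0.0347
#> 2  D_2     D 0.0774 0.3213 0.0249
#> 3  D_3     D 0.0774 0.2302 0.0178
#> 4  P_1     P 0.3834 0.0520 0.0199
#> 5  P_2     P 0.3834 0.1102 0.0423
```

Averaging with the case's entropy weights gives the combined weights; the
environmental-investment indicator I_3 ends up heaviest:

```r
A <- combine_weights(iw$total[names(xt$entropy_weights)], xt$entropy_weights)
round_half_up(A[c("I_3", "P_5", "P_4")], 4)
#>    I_3    P_5    P_4
#> 0.0996 0.0777 0.0633
```

Grading the case's composite series and counting the published top-5
obstacle lists:

```r
table(classify_security(xt$security_series$T))
#> II IV  V
#>  1  7  4
head(obstacle_frequency(xt$obstacle_top5), 4)
#>   code count   pct
#> 1  P_3     1  8.33
#> 2  P_4     6 50.00
#> 3  P_5    11 91.67
#> 4  P_7     2 16.67
```

So 4 of the 12 years sit in the worst grade V, 7 in IV and only the final
year reaches II, and pesticide usage (P_5) appears among the top five
obstacles in 11 of 12 years (91.67%).

The full pipeline on a synthetic panel (the raw case panel is not
distributed):

```r
panel <- simulate_panel(panel_spec(seed = 42))
res <- evaluate_security(panel, xt$comparisons,
                         entropy_weights = xt$entropy_weights)
res$series$table[c(1, 6, 12), ]
#>    year    T    D    P    S    I    R grade
#> 1  2006 0.46 0.06 0.21 0.07 0.10 0.02    IV
#> 6  2011 0.52 0.04 0.18 0.12 0.12 0.06    IV
#> 12 2017 0.50 0.03 0.12 0.16 0.06 0.12    IV
```

`T` is the composite security value, the five middle columns its layer
subscores (they sum to `T`), and `grade` its class. File-based runs
(`run_pipeline()`) write `weights.csv`, `series.csv`, `obstacles.csv`,
`obstacle_frequency.csv` and a markdown report; `inst/cli/landsec.R` wraps
the same functions as a command-line tool with `simulate`, `validate` and
`run` subcommands.

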