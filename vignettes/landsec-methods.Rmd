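---
title: "Evaluating land ecological security: models and methods in landsec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating land ecological security: models and methods in landsec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsec)
```

## The assessment problem

Land ecological security asks whether a region's land system can keep
supplying its ecological services under the pressure of economic and
demographic development. landsec operationalizes the question as a
composite-index assessment over a DPSIR indicator system: indicators are
grouped into **D**riving force, **P**ressure, **S**tate, **I**mpact and
**R**esponse layers, observed as an $n \times m$ panel $X_{ij}$ ($n$
indicators, $m$ years), and aggregated into one security value per year. The
bundled Xingtai city case uses $n = 24$ indicators (layers D:3, P:8, S:7,
I:3, R:3) over 2006–2017.

The pipeline has five stages, each exposed as ordinary functions:

1. polarity-aware min–max normalization (`normalize_panel()`);
2. subjective weights from expert 0/1/2 comparisons via an improved AHP
   (`iahp_weights()`);
3. objective weights from information entropy (`panel_entropy_weights()`);
4. combination, composite index and grading (`combine_weights()`,
   `security_index()`);
5. obstacle-degree diagnosis (`obstacle_diagnosis()`).

## Normalization

Each indicator carries a polarity ("safety tendency"): for positive
indicators larger raw values mean more security, for negative ones less.
Range transformation maps both onto $[0, 1]$ with 1 always the most secure
observed state:

$$Y_{ij} = \frac{X_{ij} - \min_j X_{ij}}{\max_j X_{ij} - \min_j X_{ij}}
\quad\text{(positive)},\qquad
Y_{ij} = \frac{\max_j X_{ij} - X_{ij}}{\max_j X_{ij} - \min_j X_{ij}}
\quad\text{(negative)}.$$

The min and max are taken over the supplied years only — there is no external
reference window, so every indicator attains both 0 and 1 somewhere in the
series, and adding a year can change all of an indicator's scores. This makes
$Y$ (and everything downstream) a *relative* within-window measure, which is
the intended semantics of the method; cross-study comparisons of $T_j$ levels
are correspondingly weak (see Limitations).

A constant indicator row has no defined range transform. The default is a
loud error; `constant_rows = "fill"` substitutes a neutral 0.5 (configurable)
with a warning, which then flows through entropy weighting as a
zero-information indicator.

## Improved AHP on a three-level scale

Experts compare elements pairwise on three levels: $G_{ij} = 0$ (i less
important than j), 1 (equal), 2 (more important), with reciprocity
$G_{ij} + G_{ji} = 2$ and unit diagonal. Relative to Saaty's 1–9 scale this
is coarser but far easier to elicit consistently, and it needs no consistency
ratio: the construction below is self-regulating.

Let $T = G - 1$ (entries $-1/0/+1$, antisymmetric) with row sums
$r_i = \sum_k T_{ik}$. The **optimal transfer matrix**

$$B_{ij} = \frac{1}{n}\sum_k (T_{ik} + T_{kj}) = \frac{r_i - r_j}{n}$$

is the additively consistent least-squares approximation of $T$ (the second
equality uses the antisymmetry of $T$, whose column sums are $-r$). The
**judgment matrix** $Q_{ij} = \exp(B_{ij})$ is then a perfectly consistent
positive reciprocal matrix, so its principal eigenvector is exactly the
vector of normalized geometric row means computed by the product square
method (`layer_weights()`); the principal eigenvalue equals $n$ and is never
computed. The whole chain collapses to the closed form

$$w_i = \frac{e^{r_i/n}}{\sum_k e^{r_k/n}},$$

which the test suite uses as an independent oracle, alongside a brute-force
power iteration on $Q$.

One reading note: the transfer formula is sometimes written directly in
terms of $G$ rather than $G - 1$. The two differ by a constant that does not
cancel in $B$'s pairwise form. landsec defines $T = G - 1$; with that
definition the two printed forms of $B$ coincide and the chain reproduces
every published weight of the Xingtai case to all four printed decimals,
which settles the ambiguity empirically.

Ordinal intransitivity in $G$ (i beats j beats k beats i) is legal — the
row-sum projection simply averages it away — so validation warns rather than
fails, matching the method's "no consistency test" design.

Hierarchical composition multiplies each indicator's within-layer weight by
its layer's criterion weight: $M_i = BL_i \times BP_{ij}$. With exact inputs
$\sum_i M_i = 1$, so no renormalization is applied.

### Reporting convention for rounded weight tables

All computation uses full precision. Reports round weights to 4 decimals,
half away from zero (`round_half_up()`), and the displayed total column is
composed from the *displayed* factors:
$M^{rep}_i = \mathrm{rd}_4(\mathrm{rd}_4(BL_i)\cdot \mathrm{rd}_4(BP_{ij}))$.
This keeps the printed table internally consistent — a reader multiplying two
displayed values reproduces the displayed total — and it is the convention
the Xingtai reference tables themselves follow (composing unrounded factors
and then rounding disagrees with four of their 24 printed totals by one unit
in the last digit; composing displayed factors matches all 24).

A related caveat applies to any published *combined* weight table: averages
that land exactly on a half unit of the last printed digit (e.g.
$(0.0249 + 0.0388)/2 = 0.03185$) are sensitive to digits the publication no
longer carries, so recomputations from rounded columns can differ by one
final-digit unit in either direction. landsec always reports such averages
at half a unit's agreement or better; its own outputs are computed from full
precision throughout.

## Entropy weighting

Objective weights come from how much each indicator's normalized values vary
across years. Shares are formed within each indicator across years,
$P_{ij} = Y_{ij} / \sum_j Y_{ij}$, giving the entropy

$$E_i = -\frac{1}{\ln m}\sum_j P_{ij}\ln P_{ij}, \qquad 0\ln 0 := 0,$$

so $E_i \in [0, 1]$, with 1 for an indicator spread uniformly over years and
0 for one concentrated in a single year. (Normalizing across indicators
within a year instead would not be bounded by $\ln m$; the within-indicator
reading is the only one consistent with $K = 1/\ln m$.) Weights invert
entropy:

$$W_i = \frac{1 - E_i}{n - \sum_k E_k},$$

summing to 1, with $W_i = 0$ exactly when $E_i = 1$. An all-uniform panel
(every $E_i = 1$) carries no information and is an error. All-zero normalized
rows — only possible for constant-filled indicators — are assigned $E_i = 1$,
hence zero weight, with a warning. Natural logarithms throughout.

Because the case's raw panel is not distributed, `xingtai_case()` carries the
case's entropy weights as *data* (`code,weight` CSV, also accepted by
`run_pipeline()` as an alternative input), while the comparison matrices are
carried as true inputs from which the subjective weights are recomputed.

## Combination, composite index and grades

Combined weights average the two unit-sum vectors, $A_i = (M_i + W_i)/2$.
Single-indicator security values are $H_{ij} = Y_{ij} A_i$; the composite is
$T_j = \sum_i H_{ij} \in [0, 1]$, and layer subscores are sums of $H_{ij}$
over each layer's indicators, so the five subscores add exactly to $T_j$.

Grades discretize $T_j$ into five classes, best to worst I–V, on lower-open,
upper-closed bins:

| grade | bin |
|---|---|
| I | $T > 0.85$ |
| II | $0.65 < T \le 0.85$ |
| III | $0.55 < T \le 0.65$ |
| IV | $0.35 < T \le 0.55$ |
| V | $T \le 0.35$ |

Boundary values take the lower (less secure) grade — a deliberate
precautionary choice: 0.35 is grade V. Reference grade tables occasionally
misprint the grade-I row as $T < 0.85$; only $T > 0.85$ is consistent with
the other four bins, and that is what `grade_scale()` implements (bins and
labels are configurable). `security_index()` grades full-precision $T_j$ by
default; `grade_on_rounded = TRUE` grades the 2-decimal reported values
instead, which is what published series graded on their printed values
require.

## Obstacle diagnosis

Which factors hold security back, and by how much? Three ingredients: the
factor contribution (identified with the combined weight $A_i$), the index
deviation $N_{ij} = 1 - Y_{ij}$, and the obstacle degree

$$F_{ij} = \frac{N_{ij} A_i}{\sum_k N_{kj} A_k},$$

each indicator's share of year $j$'s total weighted shortfall. Columns sum
to 1; $F_{ij} = 0$ wherever the indicator is at its ideal; uniform deviations
reduce $F$ to the weights themselves. A year with zero total deviation
(perfect security) has no defined profile and is reported all-zero with a
warning. `top_obstacles()` ranks the top $k$ (default 5) per year; exact
ties — which real panels essentially never produce — are broken
deterministically by DPSIR layer order then numeric code index, and flagged.
`obstacle_frequency()` counts top-$k$ appearances across years; counts always
total $k \times$ years. Percentages are reported to 2 decimals, half away
from zero; internals stay unrounded. Criterion-layer obstacle shares are
exposed as sums over member indicators (`$layer_obstacles`), nothing more.

## The synthetic panel generator

The raw Xingtai panel is not redistributable, so `simulate_panel()` generates
structurally matched stand-ins for testing every stage:
$X_{ij} = b_i + s_i (j - 1) + \varepsilon_{ij}$,
$\varepsilon_{ij} \sim N(0, \sigma_i^2)$, with R's Mersenne–Twister generator
seeded from the spec (bit-reproducible; the caller's RNG state is restored).
Defaults mirror the case: 24 indicators in layers D:3/P:8/S:7/I:3/R:3, years
2006–2017, and the case's mix of 16 positive / 8 negative polarities.
Baselines are drawn once per spec from $U(50, 150)$, slopes from $U(-8, 8)$
per year — over eleven steps a typical trend then spans a substantial
fraction of its baseline, like real development indicators — and the noise
standard deviation is 5, visible jitter that does not drown the trend. Noise
is Gaussian and serially independent: downstream stages consume only
within-row min–max ranks of a short series, so autocorrelation, units,
heteroscedasticity and realistic indicator magnitudes are deliberately *not*
emulated. Passing tests on synthetic panels therefore demonstrate the
pipeline's mathematics (bounds, sums, orderings, invariances), not domain
validity of any particular real-world series.

`ranking_comparison()` closes the loop for the subjective side: it inverts
the 0/1/2 semantics, turning a known importance ranking into a comparison
matrix, so tests can assert that the IAHP recovers the intended order
exactly — which the closed form above guarantees, since group rank determines
$r_i$ monotonically.

## Numerical choices and degenerate inputs

* Half-away-from-zero rounding for all reported values (weights 4 dp, index
  2 dp, obstacle percentages 2 dp); internal values never rounded.
* Weight vectors are checked to sum to 1 within $10^{-10}$ when exact
  ($5\times 10^{-3}$ when built from published 4-dp columns).
* Constant panel rows: error by default, 0.5-fill opt-in; the fill value
  propagates to zero entropy weight.
* $m < 2$ years, all-maximum-entropy panels, perfect-security years,
  reciprocity violations and out-of-range scale values are all hard errors
  or loud warnings naming the offending indicator, cell or year.
* End-to-end file runs are deterministic: identical inputs produce
  byte-identical CSVs and report.

The test suite exercises the pipeline at the case's native size (24
indicators, 12 years), with property checks on a few hundred randomly
generated comparison matrices (orders 3–12) and panels; the full suite runs
in a few seconds.

## Limitations

* $T_j$ is window-relative: values are not comparable across different year
  windows or regions without a shared normalization reference.
* The composite is a weighted linear aggregate; substitutability between
  indicators is assumed, and no interaction or threshold effects are
  modelled.
* Expert comparisons enter as a single aggregated 0/1/2 matrix per layer;
  multi-expert aggregation happens before landsec.
* Entropy weights inherit any artefact of the normalization window (an
  indicator with one outlier year gets concentrated shares, low entropy and
  a large weight).
* The grade scale is a convention, not an estimated quantity; alternative
  bin definitions change grades but nothing upstream of them.
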