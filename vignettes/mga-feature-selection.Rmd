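---
title: "Grid-structured GA feature selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-structured GA feature selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MGAselect)
```

MGAselect is a feature-selection toolkit for labelled sample-by-feature
matrices of the kind produced by expression profiling: thousands of
correlated features, tens to a few hundred samples, two to five often
imbalanced classes, and occasional missing measurements. This vignette is
the package's own account of the methods it implements, the parameters
that matter, and the choices made where the design was genuinely open.

## The data model

A `LabeledDataset` holds a numeric matrix (samples in rows, features in
columns, `NA` for missing entries) and a factor of class labels. Labels
are opaque categories and are never coerced to numbers. Standardization
(`standardizeDataset()`) is feature-wise centering and scaling by the
*population* standard deviation computed over observed entries; the
population formula (divide by N) is the convention of the nearest-neighbour
imputation literature, and since every use of standardization here is
paired with its exact affine inverse, any consistent convention would do.
Constant features get a floored standard deviation of 1e-8 so that their
standardized values are zero rather than undefined.

`stratifiedSplit()` partitions samples while preserving class proportions:
each class contributes `floor(fraction * classSize)` training samples, and
the remaining slots up to `round(fraction * N)` go to classes by decreasing
fractional part (ties by label order). The rule is exact, deterministic per
seed, and keeps at least one sample of every class on each side.

## The KNN classifier

Classification is by plurality vote among the k nearest training samples.
Two metrics are provided: the Chebyshev distance
$L_\infty(x, y) = \max_l |x_l - y_l|$ and the weighted Minkowski family
$L_p(x, y) = \left(\sum_l |w_l x_l - w_l y_l|^p\right)^{1/p}, \quad p \ge 1,$
with weights applied inside the absolute difference so that per-feature
weights reshape the geometry rather than merely rescaling votes. Three
deterministic tie rules make every prediction reproducible: neighbour
ties at equal distance keep the lower training index; vote ties go to the
tied class whose nearest member is closest; any remaining tie goes to the
lexicographically smallest label. Odd k avoids binary vote ties in the
first place, which is why `scanK()` defaults to the odd grid 1, 3, ..., 15;
the package default k = 7 is a robust operating point for data of this
shape, and `scanK()` exists precisely so users can check it on their own
data. Missing entries are rejected by every classifier entry point —
impute first, classify second — because the distance formulas assume
complete vectors.

## KNN imputation

Imputation works in standardized coordinates. The similarity between two
rows is the taxicab (L1) distance averaged over their *co-observed*
coordinates:
$d(x_i, x_j) = \frac{\sum_n Z_{in} Z_{jn} |x^*_{in} - x^*_{jn}|}{\sum_n Z_{in} Z_{jn}},$
where $Z$ marks observed entries. Averaging (rather than summing) keeps
rows with few shared coordinates comparable to rows with many; a pair
sharing no coordinate has undefined distance and ranks after all defined
ones. Each incomplete row takes its k nearest rows with defined distance
as the adjacent set and estimates every missing standardized value as a
weighted average over the neighbours that observe that feature, with
inverse-distance weights
$\beta_j = \frac{1/(d_j + \varepsilon)}{\sum_{j'} 1/(d_{j'} + \varepsilon)}, \quad \varepsilon = 10^{-8}.$
The functional form of the weights is the package's choice (closer
neighbours count more; the epsilon keeps exact duplicates finite); weights
are re-normalised over the neighbours eligible for each feature so the
estimate is always a proper convex combination, and when no neighbour in
the set observes the feature, the nearest eligible donor outside the set
is used. Estimates are mapped back through the affine inverse
$\hat{x}_{in} = \hat{x}^*_{in}\sigma_n + \mu_n$, and observed entries are
returned bit-identical. Only this single-pass scheme is implemented;
iterative refinement (e.g. re-imputing from imputed values to convergence,
or pursuit-style updates) is out of scope.

## Chi-square relevance filtering

Each feature is discretized — by default a median split into two levels,
configurable to quantile bins — and cross-tabulated against the classes.
The general statistic is the goodness-of-fit form
$\chi^2 = \sum_i (f_i - n p_i)^2 / (n p_i)$ with independence-expected
proportions from the marginals; for a 2x2 table this reduces to
$\chi^2 = \frac{n(ad - bc)^2}{(a+c)(b+d)(a+b)(c+d)},$
with df = 1. No continuity correction is applied by default (the `yates`
flag exposes the corrected variant for comparison); p-values come from the
upper tail of the chi-square distribution, never from table lookup. A
larger statistic means a stronger feature-class association, so features
are ranked by decreasing statistic, ties keeping input order. The median
split is a deliberate, recorded choice: it is scale-free, robust to
outliers, and gives balanced marginals; its cost is discreteness — under
the null the p-value distribution is discrete (exactly 1 on balanced
tables), which is why threshold selection uses p ≤ alpha. No
multiple-testing correction is applied by default (selection at raw 0.05
is the filter's documented behaviour); Benjamini-Hochberg is available via
`adjust = "BH"`.

## The matrix-structured GA

The population lives on an R x C grid (default 5 x 5, 25 individuals).
Each generation:

1. the best individual of every row is marked (first occurrence on ties)
   and copied onto the row's main-diagonal slot;
2. every non-diagonal cell is recombined, with probability
   `crossoverRate`, with its row's diagonal individual — the diagonal
   mediates all mixing, which is what "diagonally dominant" means here;
3. each offspring gene mutates with probability `mutationRate`
   (bit flips in binary mode; clipped Gaussian perturbations with
   sigma = 10% of the bound width in continuous mode);
4. changed cells are re-evaluated.

Diagonal slots are never crossed or mutated, so the global best survives
every generation unchanged and best-so-far fitness is monotone — an
invariant the tests assert on every problem and seed. Crossover in
continuous mode is an arithmetic blend with a single uniform alpha per
offspring; as the grid converges, blends interpolate ever more finely,
which is why a 5 x 5 grid reaches ~1e-9 on the 2-D sphere within 200
generations. The pairing rule (always the row's diagonal) is the package's
reading of diagonal dominance; a non-square grid has no main diagonal, so
the row-best cell takes the diagonal's role and a warning is emitted.
Termination is a fixed generation count, optionally shortened by an
absolute fitness tolerance. Default rates (crossover 0.9, mutation 0.1)
are conventional GA settings; both are exposed.

## GA-KNN wrapper selection

A chromosome is a per-feature weight vector in [0, 1]; decoding keeps the
features whose weight strictly exceeds a threshold, and the surviving
weights double as Minkowski distance weights during fitness evaluation —
weighting affects the geometry, not just membership. Fitness is KNN
accuracy on an internal stratified 70/30 validation split (a single seeded
split, not cross-validation: one accuracy per individual keeps the fitness
landscape fixed within a generation); the engine minimizes 1 - accuracy so
the optimizer needs one convention. An empty decode scores zero fitness
rather than raising an error, so evolution simply abandons such
chromosomes.

Five encodings are provided, every rule below being a recorded package
choice since only the scheme names are standard:

| scheme   | weights                  | initialisation        | decode threshold |
|----------|--------------------------|-----------------------|------------------|
| binary   | {0, 1}                   | Bernoulli(0.5)        | 0.5 (fixed)      |
| decimal  | {0, 0.1, ..., 1.0}       | uniform on the grid   | 0.5              |
| real     | [0, 1]                   | uniform               | 0.5              |
| gaussian | [0, 1]                   | N(0.5, 0.2) clipped   | 0.5              |
| adaptive | [0, 1]                   | uniform               | mean weight of the current best individual, updated per generation |

Because the adaptive threshold moves, the reported result is the best
(chromosome, threshold) pair *ever evaluated*, which also makes the
accuracy history non-decreasing by construction for every scheme.

A caveat the package's own tests document: when the planted signal is
highly redundant (many correlated informative columns), validation
accuracy saturates at 1.0 for essentially every chromosome, the fitness
surface is flat, and the selected subset is then arbitrary among
equally-perfect ones — wrapper selection can rank *sets* only as finely as
the validation accuracy can distinguish them. The chi-square filter does
not share this ceiling and is the right tool for per-feature attribution
in that regime.

## GP feature construction

Constructed features are binary arithmetic expression trees over a
terminal set of feature indices, with operators {+, -, x, /} and ephemeral
random constants (uniform in [-1, 1], 10% of leaf draws). Division is
protected — x/y = 1 when |y| < 1e-9 — and any non-finite intermediate
(overflow in deep products) is also replaced by 1, so evaluation is total
and finite on every real input; the suite verifies this on 1e5 random
programs. Initialisation is ramped half-and-half between depths 2 and 6;
the hard depth cap is 19, and offspring violating it are rejected in
favour of their parent.

Selection is by tournament (championship) of size 7 with elitism of 1.
The configured operator rates — crossover 1.0, reproduction 0.2, mutation
0.2 — sum to more than one, so they are applied as a per-offspring
categorical choice with probabilities proportional to the three rates;
that is the only normalisation that uses all three numbers. A tree's
fitness is the KNN validation accuracy with the tree's output appended as
one extra column, standardized by training-set statistics; at validation
time the same training-derived statistics are applied to the test set, so
nothing leaks. Constructed features *augment* the originals rather than
replace them (replacement is a caller-side subset operation). Repeated
runs (`constructMulti()`) return the per-run winners with duplicates by
serialized expression removed.

## Synthetic data: what it emulates and what it does not

The generator plants three feature kinds: informative features
(class-conditional Gaussians whose class centers sit `effectSize` standard
deviations apart, center order permuted per feature), redundant features
(a randomly chosen informative source plus N(0, 0.3) noise, correlation
about 0.97), and pure noise. Class weights may be imbalanced; presets
named after common public expression-dataset shapes (e.g. 1800 features x
70 samples x 3 classes) reproduce shapes, never content. Missingness is
MCAR only, with a re-draw guarantee that every row and feature keeps at
least one observed entry. The interaction generator places two features in
{-1, +1} clusters (jitter 0.35), labels by the sign of their product plus
N(0, 0.1), and adds 14 standard-Gaussian noise features — sized so that a
plain KNN on the raw columns sits near 0.7 accuracy, leaving both the
degradation and its repair by a multiplicative constructed feature
measurable. A separate low-rank generator (rank 2 plus N(0, 0.1) noise,
200 x 50 by default) provides the structure under which nearest-neighbour
imputation demonstrably beats column-mean filling.

What passing tests on these generators do *not* show: real expression data
have batch and array effects, heavy-tailed noise, and missingness that is
usually not MCAR; none of these are modelled, so results here bound
behaviour under clean conditions only.

## The experiment protocol

`runExperiment()` repeats (default 50 times): a fresh seeded stratified
70/30 split, then the stage order impute -> chi-square filter -> GA-KNN
selection -> GP construction -> KNN evaluation, each stage optional. The
summary reports mean accuracy, maximum accuracy and mean selected-feature
count over completed repeats; per-repeat seeds are derived from the master
seed by a counter and recorded, together with all stage parameters, in an
optional JSON log. Stage failures mark the repeat failed rather than
aborting the run. Imputation runs once, before splitting, because MCAR
missingness carries no label information.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately scaled study
sizes chosen as the smallest at which each claim is statistically crisp:
planted-recovery and ranking checks on 60 x 200 matrices (10 informative
at 2-SD separation, 20 redundant), imputation on the 200 x 50 rank-2
generator at 10% missingness, interaction recovery with GP population 200
over 20 generations and 3 construction runs, optimizer checks on the 2-D
sphere with the default 5 x 5 grid over 200 generations. Numerical floors:
standard deviations at 1e-8, neighbour-weight epsilon 1e-8, protected
division at |y| < 1e-9, optimizer tolerance (when enabled) 1e-8. All
randomness flows from explicit integer seeds; child seeds are derived
arithmetically and kept inside R's 32-bit integer range.

## Known limitations

- Wrapper selection inherits the validation-accuracy ceiling discussed
  above; on saturated problems prefer the filter, or enlarge the
  validation split.
- Brute-force distance computation is quadratic in samples; adequate at
  the few-hundred-sample scale this package targets, with no tree-based
  acceleration.
- The imputation scheme is single-pass; heavily missing rows fall back to
  few or single donors.
- The chi-square filter sees only marginal association; purely
  interactive features (the XOR structure) are invisible to it by design —
  that is exactly the gap the construction module fills.
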