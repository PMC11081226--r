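# MGAselect

Feature selection for high-dimensional, low-sample-count labelled
matrices — the shape of bulk and single-cell expression data: thousands
of correlated features, tens to a few hundred samples, two to five often
imbalanced classes, occasional missing measurements.

The package combines four ingredients around a k-nearest-neighbour
classifier:

- **A matrix-structured genetic algorithm (MGA).** The population sits on
  an R×C grid; each generation the best individual of every row is copied
  onto the row's main-diagonal slot, and every other cell recombines with
  its row's diagonal individual before mutating ("diagonally dominant"
  selection). Diagonal slots are never perturbed, so the best-so-far
  fitness is monotone by construction. The engine minimizes arbitrary
  continuous or binary objectives (`mgaMinimize()`, with `sphere`,
  `rastrigin` and `rosenbrock` benchmarks built in).
- **GA-KNN wrapper selection** (`selectFeaturesGA()`): per-feature weight
  chromosomes under five encodings (binary, decimal, real, gaussian,
  adaptive) are evolved on the grid; a chromosome's fitness is the KNN
  validation accuracy under the weighted Minkowski distance
  `L_p(x, y) = (Σ_l |w_l x_l − w_l y_l|^p)^(1/p)`, with the decoded
  weights acting as distance weights. The Chebyshev distance
  `L_∞(x, y) = max_l |x_l − y_l|` is also available.
- **Chi-square relevance filtering** (`rankFeaturesChi2()`): features are
  median-split, cross-tabulated against the classes, and scored with
  `χ² = Σ_i (f_i − n p_i)²/(n p_i)`, which for a 2×2 table reduces to
  `χ² = n(ad − bc)² / [(a+c)(b+d)(a+b)(c+d)]`, df = 1, no continuity
  correction.
- **KNN missing-value imputation** (`imputeKNN()`): neighbours ranked by
  the taxicab distance averaged over co-observed standardized
  coordinates, missing values estimated as inverse-distance-weighted
  donor averages, then mapped back through the affine inverse of the
  standardization.
- **GP feature construction** (`constructFeature()`, `constructMulti()`):
  arithmetic expression trees (`+ − × ÷`, protected division) over a
  selected feature subset, evolved by tournament selection and subtree
  crossover/mutation, scored by the KNN accuracy with the tree output
  appended as one standardized extra column.

Seeded synthetic-data generators with planted ground truth
(`makeSyntheticDataset()`, `makeXorDataset()`, `makeLowRankDataset()`,
`syntheticPreset()`) make every claim testable without any download, and
`runExperiment()` runs the repeated-split protocol (default 50 repeats of
a stratified 70/30 split) over the pipeline impute → filter → select →
construct → evaluate.

## Worked example

```r
library(MGAselect)

# simulate an expression-like matrix: 60 samples, 200 features,
# 10 informative + 20 redundant, 3 classes
gen <- makeSyntheticDataset(nSamples = 60, nFeatures = 200,
                            nInformative = 10, nRedundant = 20, seed = 7)
ds <- gen$dataset
ds
#> LabeledDataset: 60 samples x 200 features
#> classes: c1 (22), c2 (20), c3 (18)

# chi-square filter: rank features against the labels
head(rankFeaturesChi2(ds), 3)
#>   feature index statistic df      p.value
#> 1      f2     2  42.22222  2 6.785173e-10
#> 2     f25    25  42.22222  2 6.785173e-10
#> 3      f7     7  38.18182  2 5.115917e-09

# GA-KNN wrapper selection, binary encoding, 5x5 grid, 40 generations
res <- selectFeaturesGA(ds, "binary",
                        mgaConfig(rows = 5, cols = 5, generations = 40),
                        seed = 1)
res
#> GA-KNN selection (binary encoding)
#>   features: 200 -> 115
#>   validation accuracy: 1.0000 -> 1.0000

# 2x2 chi-square worked example: feature present/absent vs benign/malignant
str(chi2TwoByTwo(105, 95, 120, 180))
#> List of 3
#>  $ statistic: num 7.58
#>  $ df       : int 1
#>  $ p.value  : num 0.00592
```

The ranking puts planted features (`f2`, `f25`, `f7` are informative or
redundant copies) at the top with p-values around 1e-9, far below any
noise feature. The wrapper keeps 115 of 200 features at unchanged
validation accuracy — on this strongly redundant simulation the accuracy
ceiling is reached by many subsets, a regime discussed in the methods
vignette. The 2×2 table (105, 95 / 120, 180) gives χ² ≈ 7.576 at df 1,
p ≈ 0.006: feature and class are associated at the 0.05 level.

## Command-line interface

A thin CLI over the same functions lives at `inst/cli/mgaselect.R`:

```sh
Rscript inst/cli/mgaselect.R simulate --preset colon-like --seed 1 --out data.csv
Rscript inst/cli/mgaselect.R impute   --in data.csv --out imputed.csv --k 7
Rscript inst/cli/mgaselect.R filter   --in data.csv --top 100 --out ranked.tsv
Rscript inst/cli/mgaselect.R select   --in data.csv --scheme adaptive --gens 40 --out result.json
Rscript inst/cli/mgaselect.R benchmark --fn sphere --dims 2 --gens 200 --out history.csv
```

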