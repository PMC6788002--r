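# patsim

Patient similarity and personalized predictive modeling for electronic
medical record (EMR) cohorts.

Clinical decision support often wants a prediction for *this* patient,
not a population average.  `patsim` implements a multi-dimensional
patient-similarity measure over routine EMR features — age, sex, a panel
of continuous laboratory values, and ICD-10 diagnosis sets — and uses it
to build *personalized* classifiers: for each index patient, a model
(k-nearest neighbors, logistic regression, or random forest) is trained
on only the top-K most similar patients from the training pool, then
applied to that patient.  An evaluation harness compares this
similarity-based training-sample selection against random selection of
the same size.  The package is aimed at biostatisticians and informatics
researchers studying cohort-retrieval-based prediction; it ships with a
synthetic diabetes case–control cohort generator so everything runs
without any patient data.

## The similarity measure

Feature-level similarities, each in [0, 1]:

- age: FS_A(i,j) = min(Age_i, Age_j) / max(Age_i, Age_j)
- sex: FS_S(i,j) = 1 if same sex, else 0
- labs: items z-scored with training-pool statistics;
  d_lab(i,j) = Euclidean distance, min–max normalized per query over the
  pool, FS_L = 1 − d′
- diagnoses, two schemes:
  - ICD-10 hierarchical: single codes score
    S(x,y) = level(NCA(x,y)) / 4 on the truncated 4-level hierarchy
    (E10.9 vs E11.9: NCA = E1 at level 2, S = 2/4 = 0.5); code *sets*
    are compared by averaging the pairwise distances d = 1 − S of the
    codes private to each set over the union (FS_D1)
  - CCS cosine: diagnosis sets collapsed onto the 259 Clinical
    Classifications Software categories; FS_D2 = cosine of the 0/1
    category vectors

Patient similarity is the weighted sum

    PS(i,j) = w1·FS_D + w2·FS_L + w3·FS_A + w4·FS_S,
    w = (0.4, 0.4, 0.1, 0.1) by default, Σw = 1.

## Worked example

```r
library(patsim)

## synthetic diabetes case-control cohort: 150 DM / 150 non-DM
x  <- generate_cohort(synthetic_config(n_per_class = 150), seed = 7)
sp <- holdout_split(x, train_per_class = 100, test_per_class = 25, seed = 7)

q <- sp$test[3]                       # an index patient (true DM case)
prof <- similarity_profile(q, sp$train, scheme = "ccs")
head(as.data.frame(prof), 5)
#>       id    ps  fs_d  fs_l  fs_a fs_s
#> 1 p00039 0.857 0.707 0.967 0.874    1
#> 2 p00100 0.834 0.913 0.768 0.618    1
#> 3 p00082 0.761 0.816 0.862 0.899    0
#> 4 p00040 0.755 0.730 0.725 0.725    1
#> 5 p00096 0.744 0.500 0.918 0.764    1

personalized_predict(q, sp$train, k = 60, model_spec("rf"), seed = 11)
#> [1] 0.82
```

The profile ranks the 200-patient training pool by PS; the five most
similar patients here are all DM cases (the diagnosis, lab, and age
components all contribute), and the random forest trained on the
query's 60 nearest neighbors gives this true case a 0.82 predicted
probability of diabetes.

Comparing selection strategies across training-subset sizes:

```r
res <- sweep_training_size(sp$train, sp$test, k_grid = c(20, 60, 200),
                           algorithms = c("knn", "rf"), schemes = "ccs",
                           replicates = 2, seed = 7)
agg <- aggregate(auc ~ algorithm + mode + k, res, mean)
print(agg[order(agg$algorithm, agg$k, agg$mode), ],
      digits = 3, row.names = FALSE)
#>  algorithm    mode   k   auc
#>        knn  random  20 0.500
#>        knn similar  20 0.967
#>        knn  random  60 0.608
#>        knn similar  60 0.983
#>        knn  random 200 0.816
#>        knn similar 200 0.816
#>         rf  random  20 0.735
#>         rf similar  20 0.961
#>         rf  random  60 0.784
#>         rf similar  60 0.938
#>         rf  random 200 0.900
#>         rf similar 200 0.900
```

At small K the personalized (`similar`) models clearly outperform
models trained on random subsets of the same size; at K = pool size
(200) the two coincide exactly — with the whole pool selected there is
nothing left for similarity to choose, and the personalized model
degenerates into the traditional one.  `compare_curves()` (Mann–Whitney
with Bonferroni adjustment) and `fit_trend()` (cubic AUC-vs-K trend)
summarize such sweeps statistically.

A command-line wrapper is installed at `exec/patsim`
(`patsim simulate|similarity|predict|evaluate`).

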