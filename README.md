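# raacpred

Binary protein-family classification with **reduced amino acid cluster
(RAAC)** encodings, built for families — such as the 2-oxoglutarate/Fe(II)-
dependent oxygenases — whose signature is the physicochemical character of a
conserved catalytic core rather than overall sequence similarity.

The pipeline: rewrite each protein over a reduced alphabet that merges
physicochemically similar residues (the 18 nested type-33 schemes, sizes
2–19, ship with the package); represent it by its k-mer composition
(dimension *s*ᵏ, *k* ≤ 3, frequencies *dᵢ = nᵢ / Σnᵢ* over the *L − k + 1*
overlapping windows); rank features by the one-way ANOVA F statistic
(between-class over pooled within-class mean square); prune with incremental
feature selection (IFS); and classify with an RBF-kernel SVM, grid-searched
over 2⁻⁵ < C < 2¹⁵ and 2⁻¹⁵ < γ < 2³ and evaluated by stratified 10-fold
cross-validation with Sn, Sp, F1, Acc, MCC and ROC/AUC. A seeded synthetic
generator plants a conserved `H-x-D … H` metal-binding-style motif on a
polar-biased background, so the whole pipeline runs and is tested without
any external corpus.

## Worked example

```r
library(raacpred)

# a small synthetic two-class set: positives carry the motif on a
# polar-tilted background, negatives are background only
sim <- simulate_dataset(sim_config(n_pos = 40, n_neg = 40,
                                   length_range = c(250L, 350L), seed = 41))

scheme <- raac_type33()[["15"]]      # type 33, 15 groups
cfg <- svm_config(cost_exponents = c(0, 4, 8),
                  gamma_exponents = c(-6, -2, 2), folds = 5, seed = 19)

pipe <- train_pipeline(sim$pos_fasta, sim$neg_fasta, scheme, k = 1,
                       config = cfg, ifs_step = 3)
pipe
#> <raac_pipeline>
#>   features: 15 encoded; 15 used
#>   IFS best dimension: 15
#>   pooled CV: acc 0.9750, mcc 0.9512, auc 0.9956
```

So on this draw the 15 single-letter composition features of the reduced
alphabet separate the two classes almost perfectly: 78 of 80 sequences are
called correctly out-of-fold (two false positives, specificity 0.95) and
the ranking places essentially all mass on the polar/hydrophobic split.
The IFS curve, ROC curve and scheme-scan heat map all have `autoplot()`
methods, and fitted objects have broom-style `tidy()` / `glance()` methods:

```r
glance(pipe$model)
#> # A tibble: 1 x 13
#>   n_features  cost gamma    tp    tn    fp    fn    sn    sp    f1   acc   mcc
#>        <int> <dbl> <dbl> <int> <int> <int> <int> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1         15    16     4    40    38     2     0     1  0.95 0.976 0.975 0.951
#> # with one more column: auc <dbl>

predict(pipe$model, c(query = "MSTHADKLMHEESTANDGHKLV"))
#> # A tibble: 1 x 5
#>   sample_id  pred score probability note
#>   <chr>     <int> <dbl>       <dbl> <chr>
#> 1 query         1  3.29       1.000 <NA>
```

`scan_schemes()` reproduces the scheme-space survey (all shipped sizes ×
k values) on your own data, and `inst/cli/raacpred.R` exposes
`simulate / encode / scan / select / train / predict / evaluate`
subcommands for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","raacpred.R",package="raacpred"))')" \
  simulate --n-pos 50 --n-neg 50 --seed 3 --out data/
```

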