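# pastaclass

Identification of pre-cooked pasta products in different physical states
(frozen vs. thawed) from Vis–SWIR reflectance spectra (350–2500 nm, 1 nm
grid, 2151 variables), for spectroscopists and chemometricians evaluating
deep-learning classifiers against classical baselines.

At its core is a hybrid **CNN–LSTM** classifier: a modified 1-D AlexNet
(five convolutions (64,11,4), (64,5,1), (92,3,1), (92,3,1), (64,3,1);
batch normalization before the first three; no pooling; ReLU throughout)
extracts local spectral features, and an LSTM (hidden size 10, dropout
0.3) reads the resulting sequence of 64-channel vectors along the reduced
spectral axis to capture position information. The LSTM cell follows the
standard gate equations, with A = [h, x]:

    C̃ = tanh(Wc·A + bc)            candidate memory
    f = σ(Wf·A + bf)               forget gate
    i = σ(Wi·A + bi)               update gate
    o = σ(Wo·A + bo)               output gate
    C = f ∗ C_prev + i ∗ C̃         memory cell
    h = o ∗ tanh(C)                hidden output

Around it: per-wavelength standardization S = (x − μ)/σ, PCA feature
extraction X = T·Pᵀ + E (default k = 100 scores), a deterministic
systematic 7:3 train/test split stratified by product class, evaluation by
accuracy / precision / recall / F1 (positive class = Pennette72 = 1,
macro-averaged), classical baselines (KNN, decision tree, naive Bayes,
SVM), and a seeded synthetic Vis–SWIR generator that emulates the
two-product × two-state × six-sample × fifty-replicate study design. All
forward/backward passes (conv, batch norm, pooling, dense, dropout, LSTM)
and the Adam optimizer are implemented natively in R and verified against
finite-difference gradients in the test suite.

## Worked example

```r
library(pastaclass)

ds <- generate_dataset(generator_config(seed = 1))
print(ds)
#> <spectra_dataset> 1200 spectra x 2151 wavelengths (350-2500 nm @ 1 nm)
#>      state
#> class frozen thawed
#>     0    300    300
#>     1    300    300

th <- subset_by_state(ds, "thawed")
parts <- systematic_split(th)         # deterministic 7:3 -> 420 / 180

std <- fit_standardizer(parts$train)
pca <- fit_pca(apply_standardizer(parts$train, std), k = 100)
train_ft <- apply_pca(apply_standardizer(parts$train, std), pca)
test_ft  <- apply_pca(apply_standardizer(parts$test, std), pca)

model <- build_cnn_lstm(input_len = 100)
print(model)
#> <spectral_model:cnn_lstm> input_len=100, untrained, 85560 parameters

model <- train_classifier(model, train_ft,
                          cfg = train_config(epochs = 100, seed = 1,
                                             converge_stop = TRUE))
nrow(model$log)                        # epochs actually run
#> 41

pred <- predict(model, test_ft)
aggregate_metrics(per_class_metrics(feature_labels(test_ft), pred))
#> accuracy 1.0000 | precision 1.0000 | recall 1.0000 | F1 1.0000
```

The 1200 generated spectra reproduce the study shape (600 per state, 2151
variables); the systematic split gives exactly 420 training and 180 test
spectra per state; and on the thawed subset — where the two products
differ by a reflectance offset above 1300 nm — the hybrid classifies every
held-out spectrum correctly. The frozen subset, where the class offset is
near zero and replicate variability is higher, is harder; accuracies there
typically land a few points lower, and the plain LSTM (fed raw PCA scores)
trails both convolutional models.

The full model × preprocessing × state comparison grid is one call:

```r
grid <- run_benchmark(ds,
                      models = c("knn", "dt", "nb", "svm",
                                 "cnn", "lstm", "cnn_lstm"),
                      processings = c("raw", "standardization", "pca"),
                      cfg = train_config(epochs = 100, converge_stop = TRUE))
```

A thin command-line front end with `simulate`, `run` and `benchmark`
subcommands is installed at `inst/cli/pastaclass`.

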