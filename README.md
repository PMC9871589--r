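# epcog

Individual-level classification of early psychosis (EP) versus healthy
controls (HC) from structural MRI, with simultaneous estimation of six
MCCB-style cognition dimensions, via a multi-task 3D convolutional
network — plus everything needed to study the approach without access to
restricted clinical data.

`epcog` is aimed at psychiatric-neuroimaging methodologists who want to
probe *whether and when auxiliary cognitive estimation helps structural
MRI classification*: it implements the full pipeline (tissue-probability
input handling, cognitive score imputation/binning/standardization, the
multi-task network and its training recipe, stratified cross-validation,
classical machine-learning baselines, and volumetric GradCam/GradCam++
saliency) together with a calibrated synthetic cohort generator so every
stage runs end-to-end on phantom data.

## The model

A 3D convolutional encoder reads an H x W x D x 2 array of gray- and
white-matter probability maps (channel order fixed; a lone tissue map is
replicated). Each block is conv(3³, stride 1, pad 1) → batch norm → ReLU
→ 2× max-pool; global average pooling yields one feature vector per
subject, consumed by up to three independent MLP subbranches:

* **EP** — diagnosis logits, trained with cross-entropy
  L<sub>CE</sub> = −Σᵢ sᵢ log ŝᵢ;
* **CLC** — cognitive-level classes (equal-width n-category binning per
  dimension), one n-way softmax per dimension, mean cross-entropy;
* **CLR** — cognitive regression in standardized units, squared-error
  loss L<sub>MSE</sub> = ‖g − ĝ‖²₂.

The training objective is the unweighted sum
L = L<sub>CE-SZ</sub> + L<sub>CE-C</sub> + L<sub>MSE</sub> + L<sub>reg</sub>,
optimized end-to-end with Adam (starting learning rate 1e-4, decay 0.7
every 60 epochs, weight decay 0.02, batch size 10, 300 epochs, random
flip/rotation augmentation; all configurable, with the published
hyperparameter grid available through `grid_search()`).

Evaluation uses stratified five-fold cross-validation (diagnosis ×
gender strata; fold sizes {16, 16, 15, 15, 15} at n = 77) reporting
accuracy, F1, specificity, AUC, MAE and R² as mean ± SD over folds, with
all preprocessing fitted per training split.

## Worked example

Simulate a phantom cohort with the published group structure, train the
diagnosis head, cross-validate, and inspect cohort statistics:

```r
library(epcog)

cfg <- simulation_config(n_hc = 50, n_ep = 50, dims = c(24, 24, 24),
                         effect_size = 3, seed = 42)
coh <- simulate_cohort(cfg)

summary_tbl <- cohort_summary(coh)
mc <- model_config(c(24, 24, 24), conv_channels = c(8, 16, 32),
                   heads = "EP")
tc <- train_config(learning_rate = 1e-3, batch_size = 10, epochs = 30,
                   augmentation = TRUE, weight_decay = 0.02, seed = 1)
cv <- cross_validate(coh, mc, tc, k = 5, seed = 42)
cv
glance(cv)
```

On this strong-effect phantom (a 3-noise-SD gray-matter reduction
implanted in one template region) the run prints:

```
<epcog_cv  5 folds>
  acc      0.980 +/- 0.027
  auc      0.992 +/- 0.018
  f1       0.979 +/- 0.029
  spe      1.000 +/- 0.000
```

meaning the implanted diagnosis effect is recovered almost perfectly:
mean five-fold accuracy 0.98, AUC 0.99, specificity 1.0. The same
pipeline on a null phantom (`effect_size = 0`, zero cognition loadings)
stays inside the binomial 95% band around 0.5 — the procedure does not
manufacture signal. Saliency maps for any subject come from
`gradcam(fit, volume, target = list(head = "EP", class = 2))` and export
to NIfTI with `export_saliency()`.

A command-line wrapper over the same functions ships in
`inst/cli/epcog` (`simulate`, `train`, `crossval`, `baseline`,
`saliency`, `summary`), driven by a YAML run config; every run writes a
`manifest.json` with the config echo, seed and package version so
artifacts are reproducible from the manifest alone.

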