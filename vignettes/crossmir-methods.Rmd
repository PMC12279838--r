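---
title: "Cross-omics prediction of miRNA expression: models and methods"
author: "crossmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-omics prediction of miRNA expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmir)
```

# The problem

Paired transcriptome studies that profile both mRNA and miRNA expression in
the same samples are rare, while mRNA-only datasets are abundant. `crossmir`
asks whether the miRNA layer can be predicted from the mRNA layer: it trains
multi-output regression models (a deep feed-forward network, or one LASSO
model per miRNA) that map an mRNA expression profile to a miRNA expression
profile, and evaluates the predictions on two levels:

* **sample level** — the Pearson correlation between the predicted and the
  true miRNA profile of each sample;
* **differential-expression (DEA) level** — the Pearson correlation of
  log2 fold changes, and of raw p-values, computed by a moderated t-test on
  the true versus the predicted miRNA matrix.

The distinction matters. Sample-level correlations are dominated by the
between-feature spread of baseline expression and can be high even for a
model that predicts little beyond feature means; the DEA-level correlations
measure whether the *disease signal* survives the cross-omics mapping.

# Preprocessing

Input matrices are features × samples with a declared scale
(`counts`, `log_intensity`, `compressed`).

* **Quantile normalization** forces all samples onto the common reference
  distribution given by the row means of the column-sorted matrix. Ties
  within a column receive the mean of the reference quantiles their rank
  positions span — a deterministic convention chosen over rank
  interpolation; the two agree everywhere except at ties of three or more.
* **Log-CPM transform** for count data:
  `log2((count + 0.5)/(libsize + 1) * 1e6)`. Precision weights are not
  computed — the downstream models are unweighted, so the transform serves
  purely as a variance-stabilizing normalization ahead of quantile
  normalization.
* **[0,1] compression.** Before modelling, every matrix is linearly mapped
  to the unit interval using its *global* minimum and maximum (one pair per
  matrix, not per feature). Global scaling preserves the relative
  expression levels across features; per-feature scaling (available via
  `fitCompression(..., perFeature = TRUE)`) would equalize all features and
  amplify noise in flat ones. In cross-study mode the training matrix's
  parameters are reused on the test matrix — the model was trained on that
  scale — and out-of-range test values are clipped to [0,1] with a logged
  count.
* **Low-expression filter** (off by default): drops the
  `floor(fraction * n)` features with the lowest mean expression, ties
  resolved in input order. It is exposed because it sometimes helps, but it
  showed only situational benefit, hence the conservative default.

All downstream analysis — training, prediction and the DEA — runs on the
compressed scale. The "log2FC" of the DEA is therefore a group-mean
difference of linearly rescaled log intensities. This is deliberate:
predicted data only exist on the compressed scale, and every concordance
metric is a Pearson correlation, which is invariant under a common linear
rescaling, so the choice does not affect the reported r values.

# Data augmentation

Small cohorts (3–10 samples per group) are enlarged by appending
whole-cohort copies perturbed with i.i.d. Gaussian noise of standard
deviation 0.01 on the compressed scale, until each condition group holds at
least 100 samples. Design choices:

* the size target applies **per group** (both groups are augmented, and
  separate-condition models need enough samples each); a cohort-total mode
  exists (`perGroup = FALSE`);
* the original samples are **kept** — discarding real data from a
  ten-sample study is indefensible;
* noise is added after compression, where a fixed standard deviation is
  meaningful across datasets;
* values pushed marginally outside [0,1] are left as-is, preserving the
  noise distribution;
* paired mRNA/miRNA samples receive independent noise but remain paired
  under a shared new sample ID, and the whole procedure is a deterministic
  function of its seed.

With a 10-sample group the procedure appends exactly 9 noisy copies,
reaching exactly 100 samples.

# The neural network

A feed-forward multi-output regression network maps the full mRNA profile
to the full miRNA profile:

* input width = number of mRNA features; four hidden dense layers of
  1024, 512, 256 and 128 units; each hidden layer is followed by batch
  normalization, ReLU, and dropout at rate 0.4; linear dense output of
  width = number of miRNAs;
* loss: mean squared error, plus an L2 penalty `l2Coeff * sum(W^2)` on the
  hidden-layer kernels (`l2Coeff` defaults to 1e-4 and is configurable —
  the penalty strength is a free parameter of the architecture);
* optimizer: Adam at learning rate 0.001, reduced by a factor 0.5 when the
  validation loss has not improved for 5 epochs (floor 1e-6);
* at most 150 epochs, batch size 32, no early stopping;
* the last 20% of the seeded sample shuffle forms the validation set.

The training loop is implemented in compiled code (RcppArmadillo) with all
randomness — Glorot-uniform initialization, per-epoch shuffling, dropout
masks — drawn from R's RNG, so a seed makes training bit-reproducible and
single-threaded runs are deterministic. Numerical conventions: batch
normalization uses the biased batch variance with epsilon 1e-3 and running
statistics with momentum 0.99 (used at inference); Adam uses
beta1 = 0.9, beta2 = 0.999, epsilon 1e-7; dropout is "inverted" (activations
scaled by 1/keep at training time). Analytic gradients are verified against
central finite differences in the test suite.

Open choices resolved here: the plateau schedule monitors the validation
loss (the quantity the schedule exists to protect); batch normalization
sits between the dense layer and its activation, reading "after each dense
layer" literally; the L2 penalty applies to the hidden-layer kernels, with
the output layer left unpenalized.

# Per-miRNA LASSO

For each miRNA, an individual linear model with an L1 penalty is fitted on
all mRNAs, minimizing on the standardized predictor scale

$$\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 + \lambda\lVert\beta\rVert_1 .$$

The penalty path is generated automatically:
$\lambda_{max} = \max_j |\langle x_j, y\rangle|/n$ (at which every
coefficient is exactly zero), followed by 100 log-equispaced values down to
$\lambda_{max}/100$. No cross-validation is used — with 6–12 real samples
it would be meaningless; instead predictions are evaluated at two fixed
path points: the **minimal** λ (last path entry; small training error,
strong overfitting risk) and the **10th largest** λ (1-based index 10;
stronger regularization, more generalizable). The solver is cyclic
coordinate descent with soft-thresholding, warm starts along the path, and
covariance (Gram-matrix) updates so the Gram matrix of the standardized
predictors is computed once and shared across all per-miRNA fits;
convergence is declared when the largest coefficient change in a cycle
falls below 1e-7. Standardization uses the population (1/n) standard
deviation; coefficients are reported on the original predictor scale.
Constant predictors are excluded (coefficient zero); miRNAs with a constant
response are skipped and predicted at their training mean. The tests check
the Karush–Kuhn–Tucker conditions at every path point and compare the
attained objective against an accelerated proximal-gradient solver and
against an independent package implementation.

LASSO models are fitted separately per condition by default; a joint fit
over both conditions requires an explicit override
(`allowJointLasso = TRUE`). The override exists because joint fitting is
the configuration in which the DEA-level signal must travel through the
mRNA data (see *Interpreting the two evaluation levels* below).

# Moderated t-test

Differential expression between the diseased and control groups uses an
empirical-Bayes moderated t-statistic. Per feature $g$:
$\mathrm{logFC}_g$ is the diseased-minus-control mean difference on the
analysis scale; the pooled residual variance $s_g^2$ has
$d_g = n_1 + n_2 - 2$ degrees of freedom. The prior
$(d_0, s_0^2)$ is estimated by the method of moments on
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ by monotone root-finding
(bisection-bracketed `uniroot`), with $d_0 = \infty$ when the right-hand
side is non-positive; then
$s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$. The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields
$t_g = \mathrm{logFC}_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ with two-sided
p-values from $t_{d_g + d_0}$. **No multiple-testing adjustment is applied
anywhere** — the object of study is the correlation between the p-value
vectors of true and predicted data, not individual significance calls.
Forcing $d_0 = 0$ recovers the ordinary pooled two-sample t-test exactly,
which the tests verify, along with agreement with an independently coded
moment-estimator oracle and with an established reference implementation.

# Evaluation and interpretation

`samplewiseCorrelation` correlates true and predicted profiles per sample;
`deaConcordance` correlates the logFC vectors and the **raw** p-value
vectors (a `-log10` option exists behind a flag; raw is the default because
near-null p-values are the quantity of interest, not their tail
magnification). Features with undefined statistics are dropped pairwise and
counted. All correlations are invariant under positive affine transforms of
either argument, which is what makes the compressed analysis scale
innocuous.

For interpretation, `firstLayerMeanWeights` reports, per mRNA input, the
mean *absolute* weight forwarding it to the first hidden layer (signed
means of near-symmetric weight distributions cancel and would rank noise;
a signed mode exists). `tfEnrichment` takes the top `ceiling(0.05 * n)`
inputs by that weight (ties broken by input order) and compares the
transcription-factor proportion in the top set against the background
proportion; under random weights the top-set proportion is an unbiased
estimator of the background, which the tests confirm by simulation.

# The synthetic study generator

Real paired GEO studies cannot ship with a package, so validation runs on a
linear-Gaussian simulator of a two-group paired study on the log-intensity
scale:

$$\mathrm{miRNA}_{gs} = \mu_g + \delta\,\mathrm{sign}_g\,[g \in DE][s \in
\mathrm{diseased}] + \varepsilon,\qquad
\mathrm{mRNA}_{ms} = b_m - \beta \sum_{g:\,m \in T(g)}
(\mathrm{miRNA}_{gs} - \mu_g) + \eta.$$

Defaults define the study conditions used throughout the tests: 300
miRNAs, 2000 mRNAs, 5 + 5 samples (the typical design of the motivating
infection studies; a 3 + 5 variant mirrors the smallest), 20 targets per
miRNA with overlapping target sets, repression strength β = 0.4, 20% of
miRNAs differentially expressed with log-scale effect δ = 1 and random
sign, noise SDs 0.3 (mRNA) and 0.2 (miRNA), baselines uniform on [4, 12]
log2 units — the dynamic range of a typical normalized microarray.
Repression acts on *centered* miRNA values so baselines do not shift mRNA
means. Passing an existing truth object re-draws samples under the same
structure (baselines, target map, DE set): two such draws emulate two
independent studies of the same disease, the scenario behind the
cross-study evaluations.

What the simulator does *not* emulate: count overdispersion, batch
effects, platform differences between studies, nonlinear or saturating
regulation, and correlated noise. Passing the recovery tests therefore
shows that the pipeline is a faithful implementation whose models recover
a linear-Gaussian repression signal at realistic sizes and noise — it does
not certify performance on any particular real dataset.

# Interpreting the two evaluation levels

Two structural facts are worth stating because they shape which settings
are meaningful to compare:

* With **separate-condition models**, each model's intercept (or learned
  output bias) absorbs its condition's mean miRNA profile. Predicted fold
  changes then reflect the training group difference even if the mRNA
  input carried no signal. Within-data, that is precisely why separate
  training recovers fold changes so well; across studies, it means the
  DEA-level evaluation is only a genuine test of cross-omics transfer for
  **joint** models, where the group difference must travel through the
  mRNA data.
* The cross-study acceptance checks therefore run a *joint* LASSO (via the
  explicit override) at the 10th-largest λ, and include a negative
  control: a test draw with β = 0 (mRNA decoupled from miRNA). Sample-level
  correlations stay high there — baselines still dominate — while the
  fold-change correlation collapses toward zero. That dissociation between
  a strong sample level and an absent DEA level is the qualitative
  signature the evaluation framework is designed to expose.

# Problem sizes and determinism

The test suite and the acceptance script run the full network (four hidden
layers, 150 epochs) on the simulator defaults — 2000 mRNAs → 300 miRNAs,
two networks per run for separate conditions, three seeds — and the
cross-study LASSO block over five seeds; lighter unit tests use reduced
layer widths and epoch counts where only contracts, not recovery, are
checked. Every stochastic stage (simulation, augmentation, training)
derives its seed deterministically from a single master seed, and reruns
with the same seed are bit-identical.

# Known limitations

* The compressed analysis scale makes absolute fold-change magnitudes
  non-comparable across datasets; only correlations are.
* Cross-study feature matching is a case-insensitive exact ID
  intersection; probe-to-gene harmonization across platforms is out of
  scope and must happen upstream.
* The network trainer is single-threaded by design (reproducibility);
  very large input layers will train slowly.
* The moderated t-test supports the two-group equal-variance design only —
  no covariates, no robust hyperparameter estimation.
* LASSO is Gaussian/identity only; no elastic-net mixing, no
  cross-validated λ.
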