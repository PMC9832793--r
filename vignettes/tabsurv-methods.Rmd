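---
title: "Survival prediction on heterogeneous tabular cohorts: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival prediction on heterogeneous tabular cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabsurv)
```

## The problem

Population ageing cohorts follow thousands of subjects for a decade or more,
recording a wide mix of continuous measurements (cognitive scores, gait
speed, blood pressure, BMI) and binary indicators (comorbidities, lifestyle,
disability items) at baseline, and observing a clinical event — here, the
template is incident neurodegenerative disease — under heavy right
censoring: most subjects never experience the event inside the follow-up
window, and some drop out for unknown reasons. The modelling question is
whether flexible risk scores (neural networks) can out-discriminate the
classical penalized Cox toolkit on this kind of tabular, incomplete,
censoring-dominated data.

`tabsurv` implements a five-model comparison framework end to end: an
elastic-net Cox model (`coxen`), a stability-selected Cox model pooled over
multiple imputations (`coxsf`), and three neural networks — feedforward,
densely connected, and a TabTransformer variant — all trained with the same
censoring-aware loss, plus the preprocessing, chained-equations imputation,
nested cross-validation and time-dependent evaluation machinery around them.

## The shared loss: Breslow partial likelihood

All risk models map a feature row $x$ to a scalar log-risk $h(x)$; under
proportional hazards the hazard is $\lambda_0(t)\,e^{h(x)}$. The networks
are trained by minimizing the negative log of the Breslow-approximation
partial likelihood,

$$
L(h) = -\sum_{i:\ \delta_i = 1}\Big[\,h_i - \log\!\!\sum_{j:\ t_j \ge t_i}
e^{h_j}\Big],
$$

where tied event times share the full risk set. The loss depends on $h$ only
through differences, so it is invariant to a constant shift of all
log-risks — the network's output has no identifiable intercept, exactly like
the Cox linear predictor. `breslow_neg_log_pl()` computes $L$ with
log-sum-exp stabilization, and by default divides by the number of events so
the optimizer's step size does not depend on batch size; both modes are
tested against a naive risk-set enumeration oracle. The analytic gradient
(`breslow_loss_grad()`) is validated against central finite differences.

The Cox baselines use the same Breslow convention (`ties = "breslow"` in the
underlying fit), so penalized, unpenalized and network models all optimize
the same objective family and their scores are directly comparable.

## The three networks

* **Feedforward** — four hidden layers of 32 SELU units, each followed at
  train time by dropout (rate 0.2) and additive Gaussian noise, and a single
  linear output node for the log-risk.
* **DenseNet-style** — a four-layer dense block: layer $\ell$ sees the input
  concatenated with all previous layers' outputs and emits 8 new features
  (the growth rate); the final concatenation feeds the linear Cox node.
* **TabTransformer** — every binary feature gets a learned per-level
  embedding of dimension 64 tied to the column's identity; the token
  sequence passes through six transformer layers (eight-head self-attention,
  feed-forward sublayer, residual connections, layer normalization).
  Contextual embeddings are flattened and concatenated with layer-normalized
  continuous features, then fed through a small MLP head (one hidden layer
  of 32 SELU units, mirroring the other models) into the linear Cox node.

Optimization is Adam at learning rate $10^{-4}$ by default, with global
gradient-norm clipping (at 5) and a two-epoch linear learning-rate warmup —
standard stabilizers for attention stacks that also keep the smaller
networks' early steps well behaved. Choices the
architecture descriptions leave open, decided here once: the Gaussian-noise
standard deviation defaults to 0.1 (a common regularization default — the
single most uncertain constant in the reimplementation); no batch or layer
normalization inside the dense block; continuous features bypass the
transformer stack (the original TabTransformer convention) with a learned
layer norm; no separate column embedding is added, because the per-column
embedding tables already encode column identity — this is what makes the
model exactly permutation-equivariant over tokens, a property the test
suite asserts.

Two batch modes exist. `"full"` computes the exact partial likelihood (risk
sets over the whole training set) once per epoch. `"risk-set-batched"`
repartitions the subjects into random batches each epoch and forms risk
sets within each batch — the standard stochastic approximation for Cox
losses; it buys several optimizer steps per epoch and bounds the attention
memory. In batched mode the recorded training-loss
curve is the running mean of batch losses; validation loss is always the
exact evaluation-mode loss.

The networks run on a small reverse-mode tape over dense matrices, with the
attention stack, SELU and layer normalization as compiled kernels; every
architecture's parameter gradients are checked against finite differences in
the test suite.

## Preprocessing

Categorical predictors are dichotomized to 0/1. Skewed positive predictors
use a base-2 logarithmic transform; the literal form $y = \log_2 x + 1$ is
the default, with $y = \log_2(x+1)$ available as `variant = "shifted"`
because the literal form is undefined at zero — which of the two a given
analysis intends cannot be settled in general, so both are explicit.
Min-max normalization statistics are computed on training rows only and
applied unchanged to test rows, which are deliberately **not** clipped: the
map is affine, and clipping would silently distort both Cox and network
inputs. Multicollinearity is pruned by iteratively removing the feature with
the largest variance inflation factor while any VIF exceeds 10 (largest
first, column order breaking exact ties — the removal order is otherwise
arbitrary and fixing it makes the report replayable). Proportional hazards
are checked per covariate with scaled Schoenfeld residuals against a
Kaplan-Meier time transform.

## Missing data

Missingness in ageing cohorts ranges from under 1% to a third of a variable,
and complete-case analysis under a missing-at-random mechanism is biased,
so imputation is part of the pipeline, not an afterthought:

* `quickpred()` builds the predictor matrix: a candidate predicts an
  incomplete target if either the value correlation or the
  missingness-indicator correlation reaches 0.1 (the canonical default),
  subject to a usable-cases floor; outcome columns and key confounders are
  forced in. The outcome is a predictor but is never imputed.
* `choose_m()` sets the number of imputations from the maximum missingness
  percentage, rounded up to the next ten (33.5% → 40) — the round-up rule
  is a reverse-engineered formalization of "at least as many imputations as
  the percentage of missing data", and is configurable.
* `mice_impute()` runs chained equations: predictive mean matching with 5
  donors for continuous targets (imputed values stay inside the observed
  support), logistic-model draws for binary targets, both with approximate
  posterior draws of the regression coefficients so the imputations are
  proper. Observed cells are never altered — asserted bit-for-bit in tests.
* `imputation_bias_check()` compares pooled imputed-cell means with observed
  means; at most 5% relative bias is acceptable.
* `rubin_pool()` pools per-imputation estimates ($\bar Q$, within-variance
  $W$, between-variance $B$, total $T = W + (1+1/m)B$) with Barnard-Rubin
  degrees of freedom; `wald_compare_pooled()` implements the multi-parameter
  $D_1$ statistic for nested pooled models. Per-variable imputation models
  beyond the pmm/logistic pair, and multilevel or passive imputation, are
  out of scope.

## The two Cox procedures

`coxen` tunes $(\alpha, \lambda)$ by twice-repeated 5-fold cross-validated
partial-likelihood deviance, averaged over the imputed datasets, and fits
the elastic-net Cox model at the optimum. "Selected" always means a
coefficient that is exactly nonzero.

`coxsf` is a two-level stability selection: within each imputed dataset, ten
training sets (2 x 5-fold) are drawn, the elastic net is fitted on each, and
a feature passes the dataset if selected in at least 8 of 10; features are
then ranked by how many of the $m$ imputed datasets they pass. Nested
candidate lists at consensus thresholds are compared with the pooled Wald
test, and the final list's coefficients are pooled with Rubin's rules into
hazard ratios with 95% CIs. The "lowest p-value" choice rule is
implemented as stated — among candidates whose extra variables test
significant, take the smallest p — with a conventional forward sequential
mode behind a flag, because the literal rule is unconventional enough that
users may prefer the standard procedure. Whether $\lambda$ should be
re-tuned inside every split is left open by the procedure's description; the
default fixes the globally tuned value (re-tuning is exposed), which keeps
the selection frequencies comparable across splits.

## Evaluation

Discrimination uses Uno's inverse-probability-of-censoring-weighted
concordance, which unlike Harrell's C does not depend on the study-specific
censoring distribution: comparable pairs are weighted by
$\hat G(t_i-)^{-2}$ with $\hat G$ the Kaplan-Meier estimator of censoring.
Without censoring the two estimators coincide exactly — asserted in tests.
The truncation time defaults to the 95th percentile of observed times; the
censoring KM is estimated on the evaluation sample by default (a training
sample can be designated instead — the choice is reported, not hidden).

Time-dependent metrics use the cumulative-case / dynamic-control definition
at horizons of 4, 6, 8, 10 and 12 years: cases have events by $t$, controls
are event-free beyond $t$, and censoring is handled with the Kaplan-Meier
estimator of the survivalROC family (conditional KM within marker strata).
In the censoring-free limit this reduces *exactly* to the binary ROC of the
label $[T \le t]$, which is the acceptance oracle. Sensitivity and
specificity require a cutoff; no cutoff policy is inherent to the metric,
so the package's default derives the Youden-optimal cutoff on the training
split and applies it to test data, and every report row records the policy
used. Balanced accuracy is $(\mathrm{Se}+\mathrm{Sp})/2$ by definition and
the identity is asserted exactly everywhere.

Confidence intervals are percentile bootstrap over subjects (100
replications at study scale); model differences are assessed by one-way
ANOVA over per-imputed-dataset Uno's C values followed by Tukey's HSD. The
comparison operates over imputed datasets (the alternative — over bootstrap
replicates — is noted but not used, since replicate values of one model are
not exchangeable across models).

## The synthetic cohort generator

Because the motivating cohort is registration-gated, every stage is
exercised on a seeded synthetic stand-in with the same statistical shape.
Event times follow a Weibull-Cox model, $T^* = \big(-\log U / (\lambda_0
e^{x\beta})\big)^{1/k}$ — any proportional-hazards generator would do;
Weibull has a closed-form inverse. The `make_elsa_like()` preset fixes the
study conditions: 5,433 subjects by default; 91 features (31 continuous,
equicorrelated at 0.2; 60 binary at prevalence 0.3); 8 features with
nonzero log hazard ratios, $|\beta| \in \{0.3, 0.7\}$ with mixed signs
(mirroring an eight-predictor selected model); $\lambda_0$ calibrated by
monotone bisection so that 13% of subjects experience the event under 12
years of administrative censoring; exponential dropout at 0.06/year chosen
so the median observed follow-up lands at 10 years; observation times
rounded **up** to the next biennial wave (detection happens at the next
visit, and rounding up can never create a zero follow-up time); and
missingness rates spread over [0, 0.335] under a missing-at-random
mechanism driven logistically by the first continuous feature — the
simplest mechanism that actually biases complete-case analysis and thus
justifies the imputation stage. The driver feature itself stays fully
observed.

What the generator does *not* emulate: real variable semantics (hearing,
gait, depression scores), nonlinear or interacting effects, informative
censoring, and measurement error. Passing tests on this generator therefore
demonstrate the machinery's correctness and the procedures' operating
characteristics under proportional hazards — not clinical performance on
any real cohort.

## Problem sizes and numerical choices

Defaults are the study-scale values (40 imputations, 20 chained-equation
iterations, 300-epoch training at learning rate $10^{-4}$, 100 bootstrap
replications). The `scale = "desk"` preset in `experiment_config()` is the
package's single-workstation configuration and is what the test suite and
the acceptance script exercise: 2,000 subjects, $m = 5$ imputations, 50
bootstrap replications, one evaluated split per imputed dataset, 60 epochs
for the feedforward and dense networks and 20 for the transformer at
learning rate $10^{-2}$ (a few hundred full-batch Adam steps at $10^{-4}$
cannot move the parameters materially; the higher rate reaches the same
optimum family in far fewer steps on these smooth losses), and a slimmer
transformer (2 layers, embedding 32, 4 heads, risk-set batches of 320). The
full-size architectures remain the defaults of `network_spec()` and their
geometry is shape-tested; the desk preset only changes how long and how
large the *demonstration* runs are.

Other numerical decisions: Newton/coordinate convergence thresholds follow
the underlying `survival` and `glmnet` implementations with tightened
tolerances ($10^{-12}$); exact collinearity reports VIF as `+Inf` rather
than a capped number; constant min-max training columns map to 0; the
event-rate calibration reuses one fixed uniform sample across bisection
steps, making the bisected function exactly monotone; degenerate bootstrap
resamples (no events) are skipped and counted, and more than 50% degeneracy
is an error rather than a silent CI.

## Known limitations

* The imputation engine covers pmm and logistic draws only — adequate for
  the cohort shape emulated here, not a general `mice` replacement.
* The risk-set-batched loss is biased relative to the exact partial
  likelihood (risk sets are truncated at batch boundaries); full-batch mode
  exists precisely so the bias can be measured on any given dataset.
* Tukey comparison assumes per-dataset metric values are exchangeable
  across models; with few imputed datasets the test is coarse.
* The desk-scale transformer is a faithful but reduced instance; conclusions
  about the full-size architecture's relative ranking require the full-scale
  configuration and corresponding compute.
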