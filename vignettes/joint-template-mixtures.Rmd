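---
title: "Joint mixture modelling and registration of cell populations across samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint mixture modelling and registration of cell populations across samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jcmix)
```

## The problem

A flow cytometry experiment rarely produces one sample.  A batch — a time
course, a patient cohort, a set of stimulation conditions — produces many,
and the scientific questions are comparative: is population 3 larger after
stimulation, did its phosphorylation signal shift, does this patient's
sample resemble class A or class B?  Answering any of these requires knowing
*which* cluster in sample k corresponds to *which* cluster in every other
sample.  Clustering each sample separately and matching the pieces
afterwards is fragile when inter-sample variation is high; `jcmix` instead
fits the whole batch with a single two-level model in which the
correspondence is part of the model, not a post-processing step.

## The model

At the lower level, each sample is a g-component finite mixture.  Component
densities are either the multivariate t,

$$f_h(y) = \frac{\Gamma\{(\nu_h+p)/2\}}
  {\Gamma(\nu_h/2)\,(\pi\nu_h)^{p/2}\,|\Sigma_h|^{1/2}}
  \left\{1 + d(y;\mu_h,\Sigma_h)/\nu_h\right\}^{-(\nu_h+p)/2},$$

with $d$ the Mahalanobis squared distance, or the unrestricted (Sahu-form)
skew t obtained from the latent construction
$y = \mu_h + \Delta_h |u_0| + u_1$, where $w \sim
\mathrm{Gamma}(\nu_h/2, \nu_h/2)$ and $(u_0, u_1)$ are zero-mean normal with
block-diagonal covariance $(I_p/w,\ \Sigma_h/w)$, $\Delta_h$ a diagonal
matrix of skewness parameters.  Its density is

$$f_h(y) = 2^p\, t_p(y;\mu_h,\Omega_h,\nu_h)\,
  T_p\!\left(q_h(y)\,s_h(y);\,0,\,\Lambda_h,\,\nu_h+p\right),$$

with $\Omega_h = \Sigma_h + \Delta_h^2$,
$q_h(y) = \Delta_h\Omega_h^{-1}(y-\mu_h)$,
$s_h(y) = \{(\nu_h+p)/(\nu_h+d_{\Omega_h}(y))\}^{1/2}$ and
$\Lambda_h = I - \Delta_h\Omega_h^{-1}\Delta_h$.  Heavy tails (small
$\nu$) absorb outliers and debris; the skewness captures the asymmetric,
tail-connected subpopulations typical of marker intensity data.

At the upper level, the batch shares a *template* mixture.  Sample k does
not carry free component means: its mean for component h and marker i is

$$\mu_{hik} = a_{hik}\,\mu_{hi} + b_{hik}, \qquad
  a_{hik} \sim N(1, \sigma_a^2), \quad b_{hik} \sim N(0, \sigma_b^2),$$

a random-effects model (REM) in which each sample is an affine (scale +
shift) instance of the template.  Scale matrices, skewness and degrees of
freedom are template-level; mixing proportions are sample-specific, with the
template proportions defined as their cell-count-weighted mean.  Because
every sample indexes the same template components, label h means the same
population everywhere — the registration is intrinsic.  The REM variances
$\sigma_a^2, \sigma_b^2$ are estimated, and quantify the batch's
inter-sample variation.

## Fitting

`stmix()` fits one sample by EM.  The t-family E and M steps are the
classical weighted updates; the degrees of freedom solve the digamma score
equation, bracketed on $[0.5, 400]$ (a fit at 400 is reported as
effectively Gaussian, since $\nu$ is unidentifiable near Gaussianity).  The
skew-t E-step requires the conditional moments
$E[w \mid y]$, $E[wu \mid y]$, $E[wuu^\top \mid y]$ of the latent
positive vector; writing the t as a gamma mixture of normals, each
truncated-normal boundary term integrates to a lower-dimensional t
distribution function with shifted degrees of freedom, giving closed forms
in terms of $T_{p-1}$ and $T_{p-2}$.  These formulas are verified in the
test suite against Monte-Carlo sampling and against direct 2-D quadrature
of the latent joint density.  The skew-t degrees of freedom are refined by
a bracketed search on the observed log-likelihood (an ECME step, so the
monotonicity guarantee is preserved).

`jcm()` fits the batch by expectation/conditional maximization:

1. initialize the template with `stmix()` on a balanced pooled subsample
   (at most 5000 cells per sample), transforms at identity;
2. E-step per sample under its transformed template;
3. CM-1: template locations by generalized least squares across all
   samples (each sample contributes through its own $a, b$), then scale,
   skewness and degrees of freedom from pooled weighted residuals;
4. CM-2: each sample's $(a_{h\cdot}, b_{h\cdot})$ by an exact closed-form
   ridge (MAP) solve under the REM prior, jointly across markers so the
   scale-matrix correlations are respected, and the sample proportions from
   the responsibilities;
5. CM-3: $\sigma_a^2 = \overline{(a-1)^2}$, $\sigma_b^2 = \overline{b^2}$
   (maximum likelihood given the effects), floored at $10^{-8}$.

**What is monotone.**  With MAP updates of the effects and ML updates of
their variances, the quantity that provably never decreases is the
*penalized* objective — observed log-likelihood plus the REM log-prior of
$(a, b)$.  The observed log-likelihood alone can decrease slightly when the
variances shrink.  `jcm()` records both (`objective_trace`,
`loglik_trace`) and uses the penalized one for convergence; every fit in
the test suite checks it to a $10^{-6}$ relative tolerance.  When the
variances are frozen at zero the prior is degenerate, the transforms stay
at identity, and the objective is exactly the log-likelihood; with a single
sample this reproduces the plain mixture fit — the model's single-sample
reduction, which the tests verify to $10^{-6}$ relative log-likelihood.

**Identifiability of a and b.**  For a fixed (h, i, k) the likelihood
constrains only the scalar $a\mu + b$; the two effects are separated by
their priors alone.  A shift on a component with a large mean is therefore
attributed mostly to $a$ under equal prior variances.  This is intended REM
behaviour, not an estimation failure; when translations are the scientific
quantity of interest, fit with `translation_only = TRUE` (fixes $a = 1$) or
choose prior variances reflecting which effect is believed small.

## Numerical choices

* **Multivariate t distribution functions.**  The skew-t density and E-step
  need $T_p$ at fractional degrees of freedom.  For $p = 2$ the package
  integrates the closed-form derivative of $T_2$ with respect to the
  correlation (Plackett-type identity) after the $r = \sin\theta$
  substitution, on dyadically graded panels that resolve the boundary layer
  arising when the two arguments nearly coincide; accuracy is ~$10^{-11}$
  and the evaluation is vectorized over cells.  $p = 3$ reduces to an
  adaptive 1-D integral over the conditioned first coordinate; $p \ge 4$
  mixes randomized quasi-Monte-Carlo normal probabilities over the gamma
  weight with a locally fixed seed, so results are deterministic and the
  error estimate is reported.  Near-exact CDFs are what make the EM traces
  monotone at the $10^{-8}$ tolerance the tests demand.
* **Uncorrelated is not independent.**  $T_p$ with identity scale does not
  factor into univariate CDFs (the coordinates share the gamma weight);
  tests check values against an independent deterministic reference, not a
  product rule.
* **Degenerate scales.**  Scale matrices are symmetrized and, if a Cholesky
  factorization fails, regularized once by adding
  $\varepsilon\,\mathrm{tr}(\Sigma)/p$ to the diagonal
  ($\varepsilon = 10^{-8}$); M-step covariances carry a $10^{-10}$-scale
  ridge.  A component claiming fewer than `min_cluster_fraction` of the
  cells (default 0.5%) signals a collapse; the driver restarts that run
  once from a fresh initialization and abandons it on a second collapse.
* **Initialization.**  k-means on a capped subsample provides locations,
  scales and proportions.  For the skew-t family, $\delta = 0$ is nearly a
  stationary point of the EM map, so the skewness starts from each
  cluster's marginal sample skewness — and because a hard partition
  truncates inter-cluster tails and can flip that sign, each component's
  sign is chosen greedily by the observed mixture likelihood, followed by a
  short burn-in comparison of the global sign flip (emEM-style).  Strongly
  overlapping skewed components can still converge to a symmetric local
  optimum; multiple starts (`n_starts`) are the remedy, and recovery
  guarantees in the tests use separated templates.
* **Ties.**  Cell labels take the smallest component index at exactly equal
  posteriors; BIC ties go to the smaller model order;
  classification ties go to the lexicographically smallest class id.

## The synthetic-batch generator

`default_template()` and `simulate_batch()` generate the exact world the
model assumes: a known template, per-sample effects $a \sim N(1,\sigma_a^2)$
truncated to positive values, $b \sim N(0,\sigma_b^2)$, optional Dirichlet
jitter of the proportions, and cells drawn through the latent construction,
with all ground truth (transforms and per-cell template labels) returned.
Defaults mirror a well-behaved surface-marker panel on a transformed scale:
components separated by four standard-deviation units per dimension,
unit-scale matrices with mild random anisotropy, degrees of freedom in
4–15, translation SD 0.3 for a visibly mis-registered batch.  What the
generator does *not* emulate: compensation artifacts, saturation, debris
and doublets, non-affine distortions, or marker-specific transforms.
Passing the recovery suite therefore demonstrates correctness of the
estimator under its own assumptions — not robustness to everything a real
instrument can produce.

A statistical limit worth knowing: the template mean is identified only
through the m translation effects, so no estimator can localize it better
than $\sigma_b/\sqrt{m}$ per entry (0.15 for $m = 4$, $\sigma_b = 0.3$).
Recovery expectations for small batches must be read against that floor;
the package's recovery suite states its problem sizes (m of 4 and 8, 2000
cells per sample, three markers, three populations, ten seeds) and the
m = 4, high-variation cell sits essentially on the floor.

## Evaluation tools

`misclassification_rate()` scores labels against a reference by optimal
assignment on the confusion matrix — exactly the minimum over label
permutations, with outlier label 0 always an error and surplus predicted
clusters unmatched.  `f_measure()` is the size-weighted best-match harmonic
mean of precision and recall.  `kl_divergence_mc()` estimates the
Kullback–Leibler divergence between two fitted mixtures by Monte Carlo with
a reported standard error.  `classify_sample()` registers a query sample
against each class template and scores by transform-adjusted mean
log-likelihood per cell (deterministic default) or symmetric Monte-Carlo KL.
The package ships the published per-sample benchmark MCR table for the
flowCAP-I DLBCL 16-sample batch (`dlbcl_benchmark()`); aggregating it
reproduces the printed summary figures, which the acceptance checks use as
exact targets.

## Marginal overlays

With a diagonal skewness matrix and the shared gamma weight, coordinate i
of the skew-t construction involves only $(u_{0i}, u_{1i}, w)$ — exactly
the univariate construction with parameters
$(\mu_i, \Sigma_{ii}, \delta_i, \nu)$.  Marker-wise marginals are therefore
exact univariate skew-t mixtures, and `overlay_density_data()` needs no
projection approximation.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` fit: 20 randomized t mixtures
(600 cells) and 20 randomized skew-t mixtures (250–300 cells, 1–2 markers)
for monotonicity; batches of m in {4, 8} samples of 2000 three-marker cells
over ten (tests) or five (script) seeds for recovery; 200 random label
instances for the assignment/permutation equivalence; and 40 simulated
samples for classification.  These sizes were chosen so the entire suite
exercises every code path at meaningful statistical resolution while
remaining comfortable to run on a laptop.

## Known limitations

* Skew-t fitting cost grows steeply with dimension: $p \le 2$ is fast
  (vectorized bivariate CDFs), $p = 3$ workable for density evaluation but
  slow for large-n fitting, $p \ge 4$ practical only for density queries.
  The t family has closed-form steps and scales to typical panel sizes.
* The REM covers means and proportions only; scale/skew/dof are assumed
  batch-invariant.  Rotational or shear misalignment is outside the model.
* Strongly overlapping skewed components can defeat any initialization;
  BIC order selection inherits the usual sensitivity to such optima.
* FCS support is deliberately narrow: 3.0/3.1 float list mode, no
  compensation or transformation on read (`run_cli()` offers an optional
  arcsinh as an explicit preprocessing flag).
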