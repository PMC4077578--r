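# jcmix

Joint mixture modelling and registration of cell populations across a
batch of flow cytometry samples.

## What problem this solves, and for whom

Automated gating methods can find cell populations in a *single* sample,
but most experiments produce a *batch* — patients, replicates, time points,
stimulation conditions — and the scientific questions are comparative.
Comparing populations across samples requires knowing which cluster in one
sample corresponds to which cluster in every other one, in the face of
sample-to-sample shifts and rescalings of marker intensities.  `jcmix` is
for analysts of cytometry (or any cells-by-features single-cell) data who
need that correspondence to be reliable and quantified, not reconstructed
post hoc.

The package fits all samples of a batch *simultaneously*: each sample is a
finite mixture of multivariate t or unrestricted (Sahu-form) skew-t
distributions, and a batch-level random-effects model ties the samples to a
shared **template**.  Component h of sample k has mean

    mu_hik  =  a_hik * mu_hi + b_hik,
    a_hik ~ N(1, sigma_a^2),   b_hik ~ N(0, sigma_b^2),

so every sample is an affine (scale + shift) instance of the template,
populations are **registered** by construction (label h means the same
population in every sample), the variances quantify the batch's
inter-sample variation, and new samples can be classified by how well a
class template explains them after registration.

## A worked example

Simulate a batch with known ground truth (a 3-population, 3-marker template
with translation effects of SD 0.3 per sample), fit the joint model, and
check the registration against the truth:

```r
library(jcmix)

tpl <- default_template(p = 3, g = 3, family = "t", separation = 4,
                        seed = 101)
sim <- simulate_batch(tpl, m = 4, n_per_sample = 1500,
                      sigma_a = 0, sigma_b = 0.3, seed = 7)

fit <- jcm(sim$batch, g = 3, family = "t", seed = 1, n_starts = 2)
fit
#> <jcm>: 3-component t template over 4 samples (3 markers)
#>   loglik -34412.818 | BIC 69191.016 | 23 iterations (converged)
#>   REM variances: sigma_a2 = 0.00646, sigma_b2 = 1e-08

summary(fit)
#> Per-sample fit and transform magnitude:
#>   sample    n loglik mean_abs_a1 mean_abs_b
#> 1  sim01 1500  -8617     0.06395  4.025e-08
#> 2  sim02 1500  -8588     0.05839  3.428e-08
#> 3  sim03 1500  -8616     0.07811  4.777e-08
#> 4  sim04 1500  -8593     0.05170  3.500e-08

mcr <- sapply(seq_along(sim$labels), function(k)
  misclassification_rate(fit$per_sample[[k]]$labels, sim$labels[[k]]))
mcr
#> 0.000667 0.000667 0.000667 0.001333
```

Reading the output: the fitted labels agree with the generating labels for
99.9% of cells in every sample — the populations are registered.  The
simulated mis-registration is real (`mean_abs_a1` ~ 0.06 per sample), but
note it has been attributed to the scaling effects `a` rather than the
translations `b`: for any one component and marker the likelihood
constrains only `a*mu + b`, so the split between the two effects is decided
by their priors.  The transformed means — the identified quantities — are
recovered; use `translation_only = TRUE` if shifts themselves are the
quantity of interest.  `export_feature_matrix(fit)` turns the fit into a
features-by-samples table (`pi.1`, `mu.1.M1`, `a.1.M1`, ...) ready for any
downstream statistics, and `plot(fit, marker = "M2")` overlays each
sample's marginal density on the template's.

Other entry points: `stmix()` fits one sample (with BIC order selection
when `g` is a vector), `estimate_transform()` registers a new sample
against a frozen template, `classify_sample()` assigns a sample to the
best-explaining class template, `read_fcs()` / `read_marker_csv()` ingest
data, and `run_cli()` (or `inst/cli/jcm-cli.R`) drives the
simulate/fit/evaluate/classify/plotdata pipeline from a shell.

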