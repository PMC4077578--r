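# Synthetic batches with the exact generative structure the joint model
# assumes: a known template plus per-sample random effects, with full ground
# truth emitted alongside the data.

#' Construct a well-separated synthetic template
#'
#' Component means are placed sequentially at random in a growing cube,
#' accepting a location only if its distance to every earlier mean is at
#' least `separation * sqrt(p)`; scales are identity plus a random SPD
#' jitter; degrees of freedom are drawn in `[4, 15]`; skewness is zero for
#' the t family and uniform in `[-2, 2]` for the skew-t family; proportions
#' are uniform.
#'
#' @param p dimension (number of markers).
#' @param g number of components.
#' @param family `"t"` or `"skew-t"`.
#' @param separation minimum pairwise mean distance in units of `sqrt(p)`.
#' @param seed integer seed.
#' @return a [mixture_model()].
#' @export
default_template <- function(p, g, family = c("t", "skew-t"),
                             separation = 4, seed = 1L) {
  family <- match.arg(family)
  stopifnot(p >= 1L, g >= 1L)
  with_local_seed(child_seed(seed, 11L), function() {
    mind <- separation * sqrt(p)
    mu <- matrix(0, g, p)
    half <- mind                      # half-width of the sampling cube
    h <- 1L
    tries <- 0L
    while (h <= g) {
      cand <- runif(p, -half, half)
      ok <- h == 1L ||
        min(sqrt(rowSums((mu[seq_len(h - 1L), , drop = FALSE] -
                            rep(cand, each = h - 1L))^2))) >= mind
      if (ok) {
        mu[h, ] <- cand
        h <- h + 1L
        tries <- 0L
      } else {
        tries <- tries + 1L
        if (tries > 200L) { half <- half * 1.3; tries <- 0L }
      }
    }
    sg <- lapply(seq_len(g), function(i) {
      G <- matrix(rnorm(p * p, sd = 0.15), p, p)
      S <- diag(p) + crossprod(G)
      (S + t(S)) / 2
    })
    delta <- if (family == "skew-t") matrix(runif(g * p, -2, 2), g, p)
             else matrix(0, g, p)
    mixture_model(pi = rep(1 / g, g), mu = mu, sigma = sg, delta = delta,
                  nu = runif(g, 4, 15), family = family,
                  marker_names = paste0("M", seq_len(p)))
  })
}

#' Simulate a batch of samples from a template with random effects
#'
#' For sample k and component h draws scaling effects
#' `a ~ N(1, sigma_a^2)` truncated to positive values and translations
#' `b ~ N(0, sigma_b^2)` per marker, sample-specific proportions from a
#' Dirichlet with concentration `concentration * pi` (infinite concentration
#' keeps the template proportions exactly), and cells from the transformed
#' template via the latent construction.  Ground-truth transforms and
#' per-cell template component labels are returned alongside the data.
#'
#' @param template a [mixture_model()].
#' @param m number of samples.
#' @param n_per_sample cells per sample (scalar or length-m vector).
#' @param sigma_a,sigma_b random-effect standard deviations (>= 0).
#' @param concentration Dirichlet concentration for proportion jitter
#'   (`Inf` = fixed proportions).
#' @param seed integer seed; the generator is fully reproducible.
#' @param class_id batch identifier.
#' @return list with `batch` (a [sample_batch()]), `transforms` (true
#'   per-sample `a`, `b`, `pi`), `labels` (per-sample integer vectors of
#'   true template components), and `template`.
#' @export
simulate_batch <- function(template, m, n_per_sample = 1000L,
                           sigma_a = 0, sigma_b = 0.3,
                           concentration = Inf, seed = 1L,
                           class_id = "simbatch") {
  stopifnot(m >= 1L, sigma_a >= 0, sigma_b >= 0)
  g <- template$g; p <- template$p
  n_per_sample <- rep_len(as.integer(n_per_sample), m)
  samples <- vector("list", m)
  transforms <- vector("list", m)
  labels <- vector("list", m)
  for (k in seq_len(m)) {
    sd_k <- child_seed(seed, 1000L + k)
    tr <- with_local_seed(sd_k, function() {
      a <- matrix(1, g, p); b <- matrix(0, g, p)
      if (sigma_a > 0) {
        a <- matrix(rnorm(g * p, 1, sigma_a), g, p)
        while (any(a <= 0))                       # truncate to (0, Inf)
          a[a <= 0] <- rnorm(sum(a <= 0), 1, sigma_a)
      }
      if (sigma_b > 0) b <- matrix(rnorm(g * p, 0, sigma_b), g, p)
      pi_k <- if (is.finite(concentration)) {
        x <- rgamma(g, shape = concentration * template$pi)
        if (sum(x) <= 0) template$pi else x / sum(x)
      } else template$pi
      list(a = a, b = b, pi = pi_k)
    })
    mod_k <- sample_model_from_template(template, tr)
    draw <- rmixture(n_per_sample[k], mod_k, seed = child_seed(seed, 2000L + k))
    samples[[k]] <- marker_sample(draw$y, template$marker_names,
                                  sample_id = sprintf("sim%02d", k),
                                  class_label = class_id)
    transforms[[k]] <- tr
    labels[[k]] <- draw$component
  }
  list(batch = sample_batch(samples, class_id = class_id),
       transforms = transforms, labels = labels, template = template)
}
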