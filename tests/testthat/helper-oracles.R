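# Independent oracles used across tests. These deliberately re-derive results
# by brute force / closed form, not via the package's own code paths.

# Exact Wilcoxon signed-rank: enumerate all 2^n sign assignments over the
# observed midranks; two-sided p = P(|W - E[W]| >= |w_obs - E[W]|).
wilcoxon_exact_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 14)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ew <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  list(W = w_obs,
       p = mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9))
}

# White-noise NPS closed form: sigma^2 * pixel_area.
white_nps_oracle <- function(sigma, pixel_size) sigma^2 * pixel_size^2

# Naive two-pass summary for dose records.
naive_summary_oracle <- function(x) {
  c(mean = sum(x) / length(x),
    sd = sqrt(sum((x - sum(x) / length(x))^2) / (length(x) - 1)),
    min = min(x), max = max(x))
}

# iid Gaussian noise ensemble around an arbitrary base image.
make_white_ensemble <- function(n = 64, n_slice = 10, n_rep = 5, sigma = 10,
                                pixel_size = 0.429, base = 0, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(n * n * n_slice * n_rep, mean = base, sd = sigma),
                 dim = c(n, n, n_slice, n_rep))
  })
  noise_ensemble(arr, pixel_size)
}

# Average the power maps of all slices of an ensemble.
mean_power_map <- function(ens) {
  n_slice <- dim(ens$images)[3]
  maps <- lapply(seq_len(n_slice), function(s) ensemble_power_map(ens, s))
  vals <- Reduce(`+`, lapply(maps, function(m) m$values)) / n_slice
  out <- maps[[1]]
  out$values <- vals
  out
}

# Noise variance of an ensemble relative to a known noiseless base.
ensemble_noise_var <- function(ens, base_stack) {
  d <- dim(ens$images)
  base <- array(base_stack, dim = d)
  var(as.vector(ens$images - base))
}
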