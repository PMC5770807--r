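# Small fixture builders used across test files.

tiny_config <- function(n_subjects = 2, n_regions = 4, vertices_per_region = 5,
                        n_trials = 50, noise_sd = 1, effects = list(),
                        seed = 101, ...) {
  simulation_config(n_subjects = n_subjects, n_regions = n_regions,
                    vertices_per_region = vertices_per_region,
                    n_trials_per_condition = n_trials, noise_sd = noise_sd,
                    effects = effects, seed = seed, ...)
}

# component scores for one condition: 3 x T x n, gaussian around per-component
# means
fake_scores <- function(n, T = 11, mean = c(0, 0, 0), sd = 1, seed = 1) {
  withr::with_seed(seed, {
    arr <- array(rnorm(3 * T * n, sd = sd), dim = c(3, T, n))
    arr + array(rep(mean, T * n), dim = c(3, T, n))
  })
}

# one subject's components at a given size, from a null simulation
null_components <- function(n_regions = 2, n_trials = 50, seed = 5) {
  cfg <- tiny_config(n_subjects = 1, n_regions = n_regions, n_trials = n_trials,
                     seed = seed)
  parc <- build_synthetic_parcellation(n_regions, 5, seed = cfg$seed)
  sub <- simulate_subject(cfg, 1, parc)
  extract_region_components(sub$epochs, parc)
}

# brute-force Spearman with average ranks, written independently of stats::cor
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# brute-force Benjamini-Hochberg step-up: returns logical rejections
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}
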