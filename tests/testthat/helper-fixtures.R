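# Shared fixtures: small designs used across test files.

scatter_off <- list(rayleigh1 = c(0, 5), rayleigh2 = c(0, 5), raman = c(0, 5))

# default two-analyte design with noise and scatter disabled
noiseless_design <- function(n_samples = 21, seed = 9, n_spiked_pairs = 0) {
  simulation_design(n_samples = n_samples, noise_sd = 0, scatter = scatter_off,
                    n_spiked_pairs = n_spiked_pairs, seed = seed)
}

# single-analyte design (analyte A only)
single_analyte_design <- function(seed = 2) {
  simulation_design(analytes = default_analytes()[1],
                    concentration_ranges = list(A = c(0.002, 1.020)),
                    n_samples = 5, noise_sd = 0, scatter = scatter_off,
                    seed = seed)
}

# m x p design whose centered columns are orthonormal under the 1/m inner
# product, so the lasso has the closed-form soft-thresholding solution
orthonormal_design <- function(m, p, seed = 7) {
  set.seed(seed)
  M <- scale(matrix(rnorm(m * p), m, p), center = TRUE, scale = FALSE)
  sqrt(m) * qr.Q(qr(M))
}
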