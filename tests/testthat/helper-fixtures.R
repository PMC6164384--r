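# Shared fixtures, all generated in code under fixed seeds.

# two well-separated Gaussian blobs in p dimensions
make_blobs <- function(n_per = 50, p = 5, sep = 10, sd = 0.1, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(stats::rnorm(n_per * p, 0, sd), n_per, p),
    matrix(stats::rnorm(n_per * p, 0, sd), n_per, p) + sep / sqrt(p))
  rownames(X) <- sprintf("b%03d", seq_len(2 * n_per))
  list(X = X,
       labels = factor(rep(c("blob1", "blob2"), each = n_per)))
}

default_schemes <- function() {
  list(h = make_scheme("1H", 0.1), c = make_scheme("13C", 0.5))
}

# small two-class spectra world for fast tests
small_spectra_sim <- function(n = 15, seed = 42) {
  gen_spectra(spectra_sim_config(n_active = n, n_inactive = n, seed = seed))
}
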