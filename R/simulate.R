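# Seeded synthetic-data generators.
#
# gen_spectra() emulates a two-class collection of crude-extract peak
# lists: a small set of "informative" bins is occupied with higher
# probability in actives than inactives, on top of sparse background
# occupancy.  gen_regression() emulates descriptor tables with a sparse
# linear signal mapping to pIC50.  Neither attempts realistic metabolomes
# or NMR lineshapes; they provide exact ground truth (bin identities,
# supports, effect sizes) for testing the pipelines.

#' Configuration for the two-class spectra generator
#'
#' Defaults state the simulated world used throughout the test-suite:
#' 60 active + 60 inactive samples, eight informative bins (five 1H, three
#' 13C, spread over aliphatic/oxygenated/aromatic regions), occupancy
#' probabilities 0.9 (informative bin, active sample), 0.2 (informative
#' bin, inactive sample) and 0.05 (any other bin, either class), on the
#' 0.1 ppm 1H + 0.5 ppm 13C joint scheme (520 descriptors).
#'
#' @param n_active,n_inactive Sample counts per class.
#' @param scheme_h,scheme_c Binning schemes; default 0.1 ppm 1H, 0.5 ppm
#'   13C.
#' @param informative_bins Data frame with columns `nucleus` and `bin`
#'   (per-nucleus bin index); `NULL` selects the 8 default bins.
#' @param p_informative_active,p_informative_inactive Occupancy
#'   probability of each informative bin in active / inactive samples
#'   (must satisfy active > inactive for a learnable signal).
#' @param p_background Per-bin occupancy probability of all other bins.
#' @param peaks_per_sample Mean count of additional uniform background
#'   peaks (Poisson); default 0 (background is fully described by
#'   `p_background`).
#' @param shift_jitter Standard deviation (ppm) of optional Gaussian
#'   jitter added after uniform in-bin placement; default 0, so bin
#'   identity is exact ground truth.  Positive values stress bin-edge
#'   effects.
#' @param seed Integer seed; required.
#' @return A `spectra_sim_config` list.
#' @export
spectra_sim_config <- function(n_active = 60, n_inactive = 60,
                               scheme_h = make_scheme("1H", 0.1),
                               scheme_c = make_scheme("13C", 0.5),
                               informative_bins = NULL,
                               p_informative_active = 0.9,
                               p_informative_inactive = 0.2,
                               p_background = 0.05,
                               peaks_per_sample = 0,
                               shift_jitter = 0,
                               seed = 1L) {
  if (is.null(informative_bins)) {
    # aliphatic CH3/CH2, O/N-CH, vinylic and aromatic 1H; oxygenated,
    # aliphatic and aromatic 13C
    informative_bins <- data.frame(
      nucleus = c(rep("1H", 5), rep("13C", 3)),
      bin = c(bin_index(scheme_h, c(0.95, 1.35, 3.45, 5.15, 7.25)),
              bin_index(scheme_c, c(25.3, 75.2, 128.4))))
  }
  probs <- c(p_informative_active, p_informative_inactive, p_background)
  stopifnot(all(probs >= 0), all(probs <= 1))
  if (p_informative_active <= p_informative_inactive) {
    stop("p_informative_active must exceed p_informative_inactive ",
         "for a learnable signal", call. = FALSE)
  }
  n_bins <- c(scheme_h$n_bins, scheme_c$n_bins)[
    match(informative_bins$nucleus, c("1H", "13C"))]
  if (any(informative_bins$bin < 1 | informative_bins$bin > n_bins)) {
    stop("informative bin index outside its scheme", call. = FALSE)
  }
  structure(list(
    n_active = n_active, n_inactive = n_inactive,
    scheme_h = scheme_h, scheme_c = scheme_c,
    informative_bins = informative_bins,
    p_informative_active = p_informative_active,
    p_informative_inactive = p_informative_inactive,
    p_background = p_background,
    peaks_per_sample = peaks_per_sample,
    shift_jitter = shift_jitter,
    seed = as.integer(seed)), class = "spectra_sim_config")
}

.bin_lo <- function(scheme, k) scheme$origin + (k - 1) * scheme$width

# one uniformly-placed peak inside each of the given bins, with optional
# Gaussian cross-bin jitter
.peaks_in_bins <- function(scheme, bins, jitter) {
  if (!length(bins)) return(numeric())
  s <- .bin_lo(scheme, bins) + stats::runif(length(bins)) * scheme$width
  if (jitter > 0) s <- s + stats::rnorm(length(bins), sd = jitter)
  pmin(pmax(s, scheme$span_lo), scheme$span_hi - 1e-9)
}

#' Generate a two-class collection of synthetic peak lists
#'
#' For each sample, every informative bin is occupied (one peak at a
#' uniform position within the bin) with its class-specific probability;
#' every remaining bin is occupied with probability `p_background`;
#' optional extra background peaks fall uniformly over the scheme span.
#' Deterministic for a fixed `seed`.
#'
#' @param config A [spectra_sim_config()].
#' @return List with `peaklists` (list of [peak_list()]), `labels`
#'   (factor, levels `moderate-active-to-active`, `inactive`) and
#'   `config`.
#' @examples
#' sim <- gen_spectra(spectra_sim_config(n_active = 5, n_inactive = 5, seed = 1))
#' table(sim$labels)
#' @export
gen_spectra <- function(config) {
  stopifnot(inherits(config, "spectra_sim_config"))
  set.seed(config$seed)
  n <- config$n_active + config$n_inactive
  active <- rep(c(TRUE, FALSE), c(config$n_active, config$n_inactive))
  ids <- sprintf("sim_%03d_%s", seq_len(n), ifelse(active, "act", "inact"))

  schemes <- list("1H" = config$scheme_h, "13C" = config$scheme_c)
  info <- split(config$informative_bins$bin, config$informative_bins$nucleus)
  peaklists <- vector("list", n)
  for (i in seq_len(n)) {
    p_info <- if (active[i]) config$p_informative_active else
      config$p_informative_inactive
    nuc <- character(); sh <- numeric()
    for (nm in names(schemes)) {
      sc <- schemes[[nm]]
      ib <- info[[nm]]
      if (is.null(ib)) ib <- integer()
      occ_info <- ib[stats::runif(length(ib)) < p_info]
      bg_pool <- setdiff(seq_len(sc$n_bins), ib)
      occ_bg <- bg_pool[stats::runif(length(bg_pool)) < config$p_background]
      s <- c(.peaks_in_bins(sc, occ_info, config$shift_jitter),
             .peaks_in_bins(sc, occ_bg, config$shift_jitter))
      if (config$peaks_per_sample > 0) {
        m <- stats::rpois(1, config$peaks_per_sample)
        s <- c(s, stats::runif(m, sc$span_lo, sc$span_hi))
      }
      nuc <- c(nuc, rep(nm, length(s))); sh <- c(sh, s)
    }
    inten <- stats::rlnorm(length(sh), meanlog = 0, sdlog = 0.5)
    peaklists[[i]] <- peak_list(ids[i], nuc, sh, inten)
  }
  labels <- factor(ifelse(active, "moderate-active-to-active", "inactive"),
                   levels = c("moderate-active-to-active", "inactive"))
  list(peaklists = peaklists, labels = labels, config = config)
}

#' Joint descriptor indices of the planted informative bins
#'
#' @param config A [spectra_sim_config()].
#' @return Integer vector of joint (1H-then-13C) descriptor indices.
#' @export
informative_joint_indices <- function(config) {
  stopifnot(inherits(config, "spectra_sim_config"))
  ib <- config$informative_bins
  ifelse(ib$nucleus == "1H", ib$bin, ib$bin + config$scheme_h$n_bins)
}

#' Configuration for the sparse-linear regression generator
#'
#' Defaults: n = 500 samples, p = 100 descriptors of which 10 carry
#' signal, effect sizes alternating +/- 0.8, Gaussian noise sd 0.5 pIC50
#' units around an intercept of 5 (a realistic assay spread around the
#' hit-to-lead threshold), binary descriptors (fingerprint bits with 30%
#' on-rate).
#'
#' @param n,p Sample and descriptor counts.
#' @param k_informative Number of signal-carrying descriptors (the first
#'   `k` columns).
#' @param beta Effect sizes (recycled to length `k_informative`).
#' @param intercept Baseline pIC50.
#' @param noise_sd Gaussian noise standard deviation (pIC50 units).
#' @param binary_features Bernoulli(0.3) descriptors if `TRUE`, standard
#'   normal otherwise.
#' @param seed Integer seed; required.
#' @return A `regression_sim_config` list.
#' @export
regression_sim_config <- function(n = 500, p = 100, k_informative = 10,
                                  beta = c(0.8, -0.8), intercept = 5,
                                  noise_sd = 0.5, binary_features = TRUE,
                                  seed = 1L) {
  stopifnot(k_informative <= p, noise_sd >= 0, n >= 1, p >= 1)
  structure(list(n = n, p = p, k_informative = k_informative,
                 beta = rep_len(beta, k_informative), intercept = intercept,
                 noise_sd = noise_sd, binary_features = binary_features,
                 seed = as.integer(seed)), class = "regression_sim_config")
}

#' Generate a descriptor table with a sparse linear pIC50 signal
#'
#' `y = intercept + X[, 1:k] %*% beta + N(0, noise_sd)`.  Deterministic
#' for a fixed seed.
#'
#' @param config A [regression_sim_config()].
#' @return List with `X` (n x p matrix, columns `D0001`...), `y` (pIC50
#'   targets), `support` (informative column indices), `beta`, `config`.
#' @export
gen_regression <- function(config) {
  stopifnot(inherits(config, "regression_sim_config"))
  set.seed(config$seed)
  X <- if (config$binary_features) {
    matrix(stats::rbinom(config$n * config$p, 1, 0.3),
           config$n, config$p)
  } else {
    matrix(stats::rnorm(config$n * config$p), config$n, config$p)
  }
  dimnames(X) <- list(sprintf("mol_%04d", seq_len(config$n)),
                      sprintf("D%04d", seq_len(config$p)))
  support <- seq_len(config$k_informative)
  y <- config$intercept +
    as.numeric(X[, support, drop = FALSE] %*% config$beta) +
    stats::rnorm(config$n, sd = config$noise_sd)
  list(X = X, y = y, support = support, beta = config$beta, config = config)
}
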