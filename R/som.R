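# Kohonen self-organizing map: competitive training, chemistry-aware
# train/test partitioning, response patterns and the average-SOM-distance
# (ASD) applicability domain.

.grid_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols),
        col = rep(seq_len(cols), times = rows))
}

# squared grid distances between all neuron pairs (planar or toroidal)
.grid_dist2 <- function(rows, cols, topology) {
  g <- .grid_coords(rows, cols)
  dr <- abs(outer(g[, 1], g[, 1], "-"))
  dc <- abs(outer(g[, 2], g[, 2], "-"))
  if (topology == "toroidal") {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  dr^2 + dc^2
}

#' Default SOM grid side for n samples
#'
#' `ceiling(sqrt(5 * sqrt(n)))` per side — the usual "about 5*sqrt(n)
#' neurons" rule of thumb.
#'
#' @param n Number of training samples.
#' @return Integer side length (at least 2).
#' @export
som_grid_side <- function(n) max(2L, as.integer(ceiling(sqrt(5 * sqrt(n)))))

#' Train a Kohonen self-organizing map
#'
#' Online competitive learning: per presented sample the best-matching
#' unit (BMU, minimal Euclidean distance, ties to the lowest neuron
#' index) and its grid neighbourhood move toward the sample.  Gaussian
#' neighbourhood on a rectangular grid (toroidal by default); learning
#' rate and radius decay linearly over the run.
#'
#' @param X Numeric sample matrix (rows = samples).
#' @param rows,cols Grid dimensions; default `som_grid_side(nrow(X))`
#'   each.
#' @param epochs Full passes over the data; default 100.
#' @param alpha Initial and final learning rate; default `c(0.5, 0.01)`.
#' @param radius Initial and final neighbourhood radius (grid units);
#'   default `c(max(rows, cols)/2, 1)`.
#' @param topology `"toroidal"` (default) or `"planar"`.
#' @param seed Integer seed (mandatory: initialization and presentation
#'   order are random).
#' @return A `som_model`: centroid matrix (`rows*cols` x p, row-major
#'   grid order), grid geometry and training parameters.
#' @export
som_train <- function(X, rows = NULL, cols = NULL, epochs = 100,
                      alpha = c(0.5, 0.01), radius = NULL,
                      topology = c("toroidal", "planar"), seed) {
  topology <- match.arg(topology)
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty training matrix", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite values in X", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (is.null(rows)) rows <- som_grid_side(n)
  if (is.null(cols)) cols <- som_grid_side(n)
  n_neurons <- rows * cols
  if (n_neurons < 2) stop("grid must have at least 2 neurons", call. = FALSE)
  if (is.null(radius)) radius <- c(max(rows, cols) / 2, 1)
  if (epochs < 1) stop("need at least one epoch", call. = FALSE)

  set.seed(seed)
  # init: uniform within per-dimension data range
  rng_lo <- apply(X, 2, min); rng_hi <- apply(X, 2, max)
  W <- matrix(stats::runif(n_neurons * p), n_neurons, p)
  W <- sweep(sweep(W, 2, rng_hi - rng_lo, "*"), 2, rng_lo, "+")

  gd2 <- .grid_dist2(rows, cols, topology)
  total_steps <- epochs * n
  step <- 0L
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      frac <- step / max(1L, total_steps - 1L)
      a <- alpha[1] + (alpha[2] - alpha[1]) * frac
      sig <- radius[1] + (radius[2] - radius[1]) * frac
      x <- X[i, ]
      d2 <- rowSums(sweep(W, 2, x)^2)
      bmu <- which.min(d2)  # first minimum: lowest-index tie rule
      h <- exp(-gd2[, bmu] / (2 * sig^2))
      W <- W + (a * h) * sweep(-W, 2, x, "+")
      step <- step + 1L
    }
  }
  structure(list(rows = rows, cols = cols, centroids = W,
                 topology = topology, p = p,
                 train_params = list(epochs = epochs, alpha = alpha,
                                     radius = radius, seed = seed),
                 trained = TRUE),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d %s grid, %d-dim centroids (%d epochs, seed %d)\n",
              x$rows, x$cols, x$topology, x$p,
              x$train_params$epochs, x$train_params$seed))
  invisible(x)
}

.check_som_x <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != model$p) {
    stop("dimension mismatch: model expects ", model$p, " features",
         call. = FALSE)
  }
  X
}

# samples x neurons Euclidean distances
.som_dist <- function(model, X) {
  W <- model$centroids
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) - 2 * X %*% t(W) +
    outer(rep(1, nrow(X)), rowSums(W^2))
  sqrt(pmax(d2, 0))
}

#' Map samples to their winning neuron
#'
#' @param model A trained [som_train()] model.
#' @param X Sample matrix (or a single vector).
#' @return Integer vector of winning neuron indices (argmin Euclidean
#'   distance, ties to the lowest index).
#' @export
som_map <- function(model, X) {
  stopifnot(inherits(model, "som_model"))
  X <- .check_som_x(model, X)
  D <- .som_dist(model, X)
  apply(D, 1, which.min)
}

#' Mean quantization error
#'
#' Mean distance of samples to their winning centroid; decreases with
#' training.
#'
#' @inheritParams som_map
#' @return Non-negative scalar.
#' @export
som_quantization_error <- function(model, X) {
  stopifnot(inherits(model, "som_model"))
  X <- .check_som_x(model, X)
  mean(apply(.som_dist(model, X), 1, min))
}

#' SOM-based stratified train/test partition
#'
#' Test samples are drawn only from occupied neurons, cycling over the
#' occupied neurons of each stratum (lowest neuron index first, random
#' sample order within a neuron under `seed`) so the test set spreads
#' across the map.  Per-stratum test counts are `round(test_fraction *
#' n_stratum)`, hence within one sample of proportional allocation.
#'
#' @param model A trained SOM.
#' @param X Sample matrix; row names (or indices) become sample ids.
#' @param strata Category per sample (activity class, sample type, ...);
#'   a single stratum is allowed.
#' @param test_fraction Fraction of each stratum assigned to the test
#'   set, in (0, 1).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test` (disjoint,
#'   exhaustive) and the winning `neurons` per sample.
#' @export
som_partition <- function(model, X, strata, test_fraction, seed) {
  stopifnot(inherits(model, "som_model"))
  X <- .check_som_x(model, X)
  n <- nrow(X)
  strata <- as.factor(rep_len(strata, n))
  if (any(is.na(strata))) stop("strata must be defined for all samples",
                               call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  neurons <- som_map(model, X)

  set.seed(seed)
  test <- character()
  for (s in levels(strata)) {
    idx <- which(strata == s)
    n_test <- round(test_fraction * length(idx))
    if (n_test == 0) next
    # queue per occupied neuron, randomized within, visited round-robin
    by_neuron <- split(idx, neurons[idx])
    by_neuron <- lapply(by_neuron, function(v) v[sample.int(length(v))])
    picked <- integer()
    while (length(picked) < n_test) {
      for (k in seq_along(by_neuron)) {
        if (length(picked) >= n_test) break
        q <- by_neuron[[k]]
        if (!length(q)) next
        picked <- c(picked, q[1])
        by_neuron[[k]] <- q[-1]
      }
    }
    test <- c(test, ids[picked])
  }
  list(train = setdiff(ids, test), test = test,
       neurons = stats::setNames(neurons, ids))
}

#' SOM response pattern of a sample
#'
#' The vector of Euclidean distances `d(x, n_i)` to every neuron
#' centroid, min-max normalized to `[0, 1]` within the vector (0 at the
#' best-matching unit, 1 at the farthest neuron).  Used as the
#' similarity representation behind the ASD applicability domain.
#'
#' @param model A trained SOM.
#' @param X A sample vector or matrix.
#' @return Matrix (samples x neurons) of normalized patterns.
#' @export
response_pattern <- function(model, X) {
  stopifnot(inherits(model, "som_model"))
  X <- .check_som_x(model, X)
  D <- .som_dist(model, X)
  lo <- apply(D, 1, min); hi <- apply(D, 1, max)
  if (any(hi - lo < 1e-12)) {
    stop("degenerate response pattern: all centroids equidistant",
         call. = FALSE)
  }
  (D - lo) / (hi - lo)
}

#' Average SOM distance (ASD) to a training set
#'
#' Mean Euclidean distance between the query's response pattern and each
#' training response pattern, rescaled by `1/sqrt(n_neurons)` so values
#' lie in `[0, 1]` (patterns live in the unit hypercube).  Small ASD
#' means the query responds to the map like the training set does —
#' i.e. it falls inside the applicability domain.
#'
#' @param model A trained SOM.
#' @param x Query sample vector (or one-row matrix).
#' @param training_patterns Matrix of training response patterns from
#'   [response_pattern()] (rows = training samples).
#' @return ASD value in `[0, 1]`.
#' @export
asd <- function(model, x, training_patterns) {
  stopifnot(inherits(model, "som_model"))
  training_patterns <- as.matrix(training_patterns)
  if (!nrow(training_patterns)) stop("empty training set", call. = FALSE)
  px <- response_pattern(model, x)
  if (nrow(px) != 1L) stop("asd takes a single query sample", call. = FALSE)
  d <- sqrt(rowSums(sweep(training_patterns, 2, px[1, ])^2))
  mean(d) / sqrt(ncol(training_patterns))
}

#' Applicability-domain membership
#'
#' Strict comparison: inside the domain iff `asd_value < threshold`.
#' The default threshold 0.421 was calibrated on a structural-cluster
#' SOM of a 5875-molecule fingerprint training set; with a different
#' map, descriptor set or normalization it should be recalibrated
#' (e.g. to a high quantile of training-vs-training ASD).
#'
#' @param asd_value ASD value(s), non-negative.
#' @param threshold Cutoff in (0, 1); default 0.421.
#' @return Logical vector.
#' @examples
#' in_domain(c(0.420, 0.421))  # TRUE FALSE
#' @export
in_domain <- function(asd_value, threshold = 0.421) {
  stopifnot(all(asd_value >= 0), threshold > 0, threshold < 1)
  asd_value < threshold
}

#' Ward clustering of a fingerprint matrix
#'
#' Agglomerative Ward clustering (Ward's minimum-variance criterion on
#' Euclidean distances, `ward.D2`) cut at `k` clusters; used to define
#' structural classes / scaffold types.
#'
#' @param X Numeric (typically binary fingerprint) matrix.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @return Integer cluster assignment per sample.
#' @export
cluster_ward <- function(X, k) {
  X <- as.matrix(X)
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(X)) stop("k exceeds the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Serialize a SOM model to JSON
#'
#' @param model A `som_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_som_json <- function(model, path) {
  stopifnot(inherits(model, "som_model"))
  obj <- list(format = "nmrqsar-som", version = 1L,
              rows = model$rows, cols = model$cols, p = model$p,
              topology = model$topology,
              train_params = model$train_params,
              centroids = as.numeric(t(model$centroids)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a SOM model from JSON
#'
#' @param path Path written by [write_som_json()].
#' @return A `som_model`.
#' @export
read_som_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nmrqsar-som")) {
    stop("not a SOM model file", call. = FALSE)
  }
  W <- matrix(obj$centroids, nrow = obj$rows * obj$cols, ncol = obj$p,
              byrow = TRUE)
  structure(list(rows = obj$rows, cols = obj$cols, centroids = W,
                 topology = obj$topology, p = obj$p,
                 train_params = obj$train_params, trained = TRUE),
            class = "som_model")
}

#' Write a partition to CSV
#'
#' Two columns: `sample_id`, `split` (`train`/`test`).
#'
#' @param partition Result of [som_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  df <- rbind(data.frame(sample_id = partition$train, split = "train"),
              data.frame(sample_id = partition$test, split = "test"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
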