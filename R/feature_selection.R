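# Descriptor-subset selection: CFS merit and searches, M5-style stepwise
# elimination with AIC stopping, top-N by importance.

#' CFS merit of a feature subset
#'
#' Hall's correlation-based feature-selection merit
#' `k * mean|r_cf| / sqrt(k + k*(k-1) * mean|r_ff|)` over a subset of k
#' features, where `r_cf` are feature-target and `r_ff` feature-feature
#' correlations.  Absolute values are used throughout; `k = 1` reduces to
#' `|r_cf|`.
#'
#' @param subset Integer indices of the subset (non-empty).
#' @param r_cf Numeric vector of feature-target correlations (all
#'   features).
#' @param r_ff Feature-feature correlation matrix.
#' @return The merit (non-negative scalar).
#' @examples
#' cfs_merit(1:2, c(0.5, 0.5), diag(2))  # 2*0.5/sqrt(2) = 0.7071
#' @export
cfs_merit <- function(subset, r_cf, r_ff) {
  subset <- as.integer(subset)
  if (!length(subset)) stop("subset must be non-empty", call. = FALSE)
  stopifnot(all(subset >= 1), all(subset <= length(r_cf)),
            !anyDuplicated(subset))
  k <- length(subset)
  rcf_bar <- mean(abs(r_cf[subset]))
  if (k == 1L) return(rcf_bar)
  ff <- abs(r_ff[subset, subset])
  rff_bar <- mean(ff[upper.tri(ff)])
  k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
}

# correlations with NA (constant columns) treated as 0 association
.cfs_correlations <- function(X, y) {
  if (is.factor(y)) y <- as.numeric(y == levels(y)[1])
  if (stats::sd(y) == 0) stop("constant target", call. = FALSE)
  r_cf <- suppressWarnings(as.numeric(stats::cor(X, y)))
  r_cf[is.na(r_cf)] <- 0
  r_ff <- suppressWarnings(stats::cor(X))
  r_ff[is.na(r_ff)] <- 0
  diag(r_ff) <- 1
  list(r_cf = r_cf, r_ff = r_ff)
}

#' Search for the maximal-merit CFS subset
#'
#' Strategies:
#' * `"best_first"` (reference): forward best-first search with
#'   backtracking over an OPEN list; terminates after `max_stale`
#'   consecutive node expansions that fail to improve the best merit.
#' * `"greedy_stepwise"`: plain forward selection, stops at the first
#'   non-improving addition (equivalently best-first without
#'   backtracking, the "linear forward selection" variant).
#' * `"exhaustive"`: all non-empty subsets; exact oracle, allowed for at
#'   most 20 features.
#'
#' For a binary factor target the point-biserial correlation (Pearson on
#' a 0/1 encoding) is used.
#'
#' @param X Numeric feature matrix (>= 2 columns).
#' @param y Numeric target or binary factor.
#' @param strategy Search strategy.
#' @param max_stale Best-first stale-expansion cutoff; default 5.
#' @return A `selection_result`: list with `selected` (integer indices,
#'   empty if no subset beats merit 0), `merit`, `trace` (data.frame of
#'   visited best merits), `strategy`.
#' @export
cfs_search <- function(X, y,
                       strategy = c("best_first", "greedy_stepwise",
                                    "exhaustive"),
                       max_stale = 5) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need at least two features", call. = FALSE)
  cors <- .cfs_correlations(X, y)
  merit_of <- function(s) cfs_merit(s, cors$r_cf, cors$r_ff)

  key <- function(s) paste0("k", paste(sort(s), collapse = ","))
  best <- integer(); best_merit <- 0
  trace <- list()
  note <- function(step, s, m) {
    trace[[length(trace) + 1L]] <<- data.frame(
      step = step, size = length(s), merit = m)
  }

  if (strategy == "exhaustive") {
    if (p > 20) stop("exhaustive search limited to 20 features", call. = FALSE)
    step <- 0L
    for (k in seq_len(p)) {
      combos <- utils::combn(p, k)
      for (j in seq_len(ncol(combos))) {
        s <- combos[, j]
        m <- merit_of(s)
        step <- step + 1L
        if (m > best_merit + 1e-12) {
          best <- s; best_merit <- m; note(step, s, m)
        }
      }
    }
  } else if (strategy == "greedy_stepwise") {
    current <- integer(); step <- 0L
    repeat {
      cand <- setdiff(seq_len(p), current)
      if (!length(cand)) break
      merits <- vapply(cand, function(j) merit_of(c(current, j)), numeric(1))
      jbest <- which.max(merits)  # first max: lowest index tie-break
      step <- step + 1L
      if (merits[jbest] <= best_merit + 1e-12) break
      current <- c(current, cand[jbest])
      best <- current; best_merit <- merits[jbest]
      note(step, current, best_merit)
    }
  } else {
    # best-first: expand the best unexpanded subset; children add one
    # feature; stop after max_stale expansions without global improvement
    open_sets <- list(integer()); open_merits <- 0
    seen <- new.env(parent = emptyenv()); assign(key(integer()), TRUE, envir = seen)
    stale <- 0L; step <- 0L
    while (length(open_sets) && stale < max_stale) {
      i <- which.max(open_merits)
      s <- open_sets[[i]]
      open_sets <- open_sets[-i]; open_merits <- open_merits[-i]
      improved <- FALSE
      for (j in setdiff(seq_len(p), s)) {
        child <- sort(c(s, j))
        k <- key(child)
        if (exists(k, envir = seen, inherits = FALSE)) next
        assign(k, TRUE, envir = seen)
        m <- merit_of(child)
        open_sets[[length(open_sets) + 1L]] <- child
        open_merits <- c(open_merits, m)
        if (m > best_merit + 1e-12) {
          best <- child; best_merit <- m; improved <- TRUE
          step <- step + 1L
          note(step, child, m)
        }
      }
      stale <- if (improved) 0L else stale + 1L
    }
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), size = integer(), merit = numeric())
  structure(list(selected = sort(best), merit = best_merit,
                 trace = trace_df, strategy = strategy),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d feature(s) selected\n",
              x$strategy, length(x$selected)))
  invisible(x)
}

# least-squares fit (ridge fallback when the system is not full rank /
# underdetermined); returns coefficients (no intercept term in `b`), rss
.ls_fit <- function(X, y, ridge = 0) {
  n <- nrow(X); p <- ncol(X)
  Xc <- cbind(1, X)
  if (ridge > 0 || p + 1 >= n) {
    lambda <- max(ridge, 1e-8)
    A <- crossprod(Xc) + diag(c(0, rep(lambda, p)), p + 1)
    coefs <- solve(A, crossprod(Xc, y))
  } else {
    fit <- stats::lm.fit(Xc, y)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
  }
  resid <- y - Xc %*% coefs
  list(b = coefs[-1], intercept = coefs[1], rss = sum(resid^2))
}

# AIC for least squares with p features (+ intercept); a relative floor on
# RSS keeps the zero-noise case finite so that dropping spurious features
# still improves AIC by its 2-per-parameter penalty
.ls_aic <- function(rss, n, p, y_scale) {
  n * log(max(rss, 1e-12 * n * y_scale^2, 1e-300) / n) + 2 * (p + 1)
}

#' M5-style stepwise descriptor elimination with AIC stopping
#'
#' Fits a least-squares model on all features, then repeatedly removes
#' the feature with the smallest absolute standardized coefficient
#' (`b_j * sd(x_j) / sd(y)`) and refits, as long as the Akaike
#' information criterion `n*ln(RSS/n) + 2*(p+1)` improves; stops at the
#' first worsening step.  Constant columns are removed up front; if the
#' remaining system is underdetermined (p >= n) a small ridge penalty
#' stabilizes the fits.
#'
#' @param X Numeric feature matrix.
#' @param y Numeric target.
#' @param ridge Optional ridge penalty for the fallback; default
#'   automatic.
#' @return A `selection_result` with the surviving feature indices and
#'   the per-step AIC trace.
#' @export
m5_select <- function(X, y, ridge = 0) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n)
  usable <- which(apply(X, 2, stats::sd) > 0)
  if (length(usable) < 2) stop("fewer than two usable features", call. = FALSE)
  y_sd <- stats::sd(y)
  if (y_sd == 0) stop("constant target", call. = FALSE)

  current <- usable
  fit <- .ls_fit(X[, current, drop = FALSE], y, ridge)
  aic <- .ls_aic(fit$rss, n, length(current), y_sd)
  trace <- data.frame(step = 0L, size = length(current), aic = aic,
                      dropped = NA_integer_)
  while (length(current) > 1L) {
    std_b <- abs(fit$b) * apply(X[, current, drop = FALSE], 2, stats::sd) / y_sd
    drop_i <- which.min(std_b)  # lowest index on ties
    candidate <- current[-drop_i]
    fit_new <- .ls_fit(X[, candidate, drop = FALSE], y, ridge)
    aic_new <- .ls_aic(fit_new$rss, n, length(candidate), y_sd)
    if (aic_new >= aic) break
    trace <- rbind(trace, data.frame(step = nrow(trace), size = length(candidate),
                                     aic = aic_new, dropped = current[drop_i]))
    current <- candidate; fit <- fit_new; aic <- aic_new
  }
  structure(list(selected = current, merit = -aic, trace = trace,
                 strategy = "m5_aic"), class = "selection_result")
}

#' Top-N features by importance
#'
#' @param importances Numeric importance per feature (e.g. random-forest
#'   permutation importance).
#' @param n How many to keep (`1 <= n <= length(importances)`).
#' @return A `selection_result`; `selected` holds the indices of the `n`
#'   largest importances in decreasing order, ties broken by lower index.
#' @examples
#' rf_top_n(c(3, 1, 2), 2)$selected  # 1 3
#' @export
rf_top_n <- function(importances, n) {
  stopifnot(is.numeric(importances))
  n <- as.integer(n)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (n > length(importances)) {
    stop("n exceeds the number of features", call. = FALSE)
  }
  ord <- order(importances, -seq_along(importances), decreasing = TRUE)
  sel <- ord[seq_len(n)]
  structure(list(selected = sel, merit = importances[sel[n]],
                 trace = data.frame(step = seq_len(n), size = seq_len(n),
                                    merit = importances[sel]),
                 strategy = "rf_top_n"),
            class = "selection_result")
}

#' Write a selection result to CSV
#'
#' Columns: rank, index, name (if available), criterion value.
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @param names Optional descriptor names (full-length vector indexed by
#'   `sel$selected`).
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(sel, path, names = NULL) {
  stopifnot(inherits(sel, "selection_result"))
  idx <- sel$selected
  df <- data.frame(rank = seq_along(idx), index = idx,
                   name = if (is.null(names)) NA_character_ else names[idx],
                   criterion = sel$merit, strategy = sel$strategy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
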