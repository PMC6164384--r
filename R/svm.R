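# Support vector machines with RBF kernel, solved by SMO (maximal
# violating pair working-set selection) on the standard dual
#   min 1/2 a'Qa + p'a   s.t.  y'a = 0,  0 <= a_t <= C_t.
# C-SVC uses n dual variables; eps-SVR uses 2n (alpha, alpha*).

.rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) - 2 * A %*% t(B) +
    outer(rep(1, nrow(A)), rowSums(B^2))
  exp(-gamma * pmax(d2, 0))
}

# generic SMO solver; Q given implicitly as sgn %o% sgn * Kfull
.smo <- function(Kfull, sgn, pvec, C_up, eps = 1e-3, max_iter = 100000L) {
  m <- length(sgn)
  alpha <- numeric(m)
  G <- pvec  # gradient of the dual objective at alpha = 0
  Q_col <- function(t) sgn * sgn[t] * Kfull[, t]
  for (iter in seq_len(max_iter)) {
    crit <- -sgn * G
    up <- (sgn > 0 & alpha < C_up - 1e-12) | (sgn < 0 & alpha > 1e-12)
    low <- (sgn < 0 & alpha < C_up - 1e-12) | (sgn > 0 & alpha > 1e-12)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(crit[up])]
    j <- which(low)[which.min(crit[low])]
    if (crit[i] - crit[j] < eps) break

    Qi <- Q_col(i); Qj <- Q_col(j)
    ai_old <- alpha[i]; aj_old <- alpha[j]
    if (sgn[i] != sgn[j]) {
      quad <- Qi[i] + Qj[j] + 2 * Qi[j]   # = K_ii + K_jj - 2 K_ij
      quad <- max(quad, 1e-12)
      delta <- (-G[i] - G[j]) / quad
      diff <- alpha[i] - alpha[j]
      alpha[i] <- alpha[i] + delta
      alpha[j] <- alpha[j] + delta
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- diff }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- -diff }
      }
      if (diff > C_up[i] - C_up[j]) {
        if (alpha[i] > C_up[i]) { alpha[i] <- C_up[i]; alpha[j] <- C_up[i] - diff }
      } else {
        if (alpha[j] > C_up[j]) { alpha[j] <- C_up[j]; alpha[i] <- C_up[j] + diff }
      }
    } else {
      quad <- Qi[i] + Qj[j] - 2 * Qi[j]   # = K_ii + K_jj - 2 K_ij
      quad <- max(quad, 1e-12)
      delta <- (G[i] - G[j]) / quad
      ssum <- alpha[i] + alpha[j]
      alpha[i] <- alpha[i] - delta
      alpha[j] <- alpha[j] + delta
      if (ssum > C_up[i]) {
        if (alpha[i] > C_up[i]) { alpha[i] <- C_up[i]; alpha[j] <- ssum - C_up[i] }
      } else {
        if (alpha[j] < 0) { alpha[j] <- 0; alpha[i] <- ssum }
      }
      if (ssum > C_up[j]) {
        if (alpha[j] > C_up[j]) { alpha[j] <- C_up[j]; alpha[i] <- ssum - C_up[j] }
      } else {
        if (alpha[i] < 0) { alpha[i] <- 0; alpha[j] <- ssum }
      }
    }
    G <- G + Qi * (alpha[i] - ai_old) + Qj * (alpha[j] - aj_old)
  }
  # rho from free variables, else bound midpoint
  free <- alpha > 1e-12 & alpha < C_up - 1e-12
  yG <- sgn * G
  rho <- if (any(free)) {
    mean(yG[free])
  } else {
    ub <- suppressWarnings(min(yG[(sgn > 0 & alpha < C_up - 1e-12) |
                                    (sgn < 0 & alpha > 1e-12)]))
    lb <- suppressWarnings(max(yG[(sgn < 0 & alpha < C_up - 1e-12) |
                                    (sgn > 0 & alpha > 1e-12)]))
    (ub + lb) / 2
  }
  list(alpha = alpha, rho = rho)
}

# C-SVC; y in {-1, +1}; per-sample C (class weighting) supported
.svc_fit <- function(X, y_sign, C, gamma, class_C = NULL) {
  n <- nrow(X)
  Cv <- if (is.null(class_C)) rep(C, n) else class_C
  K <- .rbf_kernel(X, X, gamma)
  sol <- .smo(K, y_sign, rep(-1, n), Cv)
  sv <- which(sol$alpha > 1e-8)
  list(sv_x = X[sv, , drop = FALSE], sv_coef = sol$alpha[sv] * y_sign[sv],
       rho = sol$rho, gamma = gamma)
}

# eps-SVR: 2n variables (alpha then alpha*)
.svr_fit <- function(X, y, C, gamma, epsilon = 0.1) {
  n <- nrow(X)
  K <- .rbf_kernel(X, X, gamma)
  K2 <- rbind(cbind(K, K), cbind(K, K))  # |Q| pattern; signs via sgn
  sgn <- c(rep(1, n), rep(-1, n))
  pvec <- c(epsilon - y, epsilon + y)
  sol <- .smo(K2, sgn, pvec, rep(C, 2 * n))
  beta <- sol$alpha[1:n] - sol$alpha[(n + 1):(2 * n)]
  sv <- which(abs(beta) > 1e-8)
  list(sv_x = X[sv, , drop = FALSE], sv_coef = beta[sv],
       rho = sol$rho, gamma = gamma)
}

.svm_decision <- function(fit, X) {
  if (!nrow(fit$sv_x)) return(rep(-fit$rho, nrow(X)))
  K <- .rbf_kernel(X, fit$sv_x, fit$gamma)
  as.numeric(K %*% fit$sv_coef) - fit$rho
}
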