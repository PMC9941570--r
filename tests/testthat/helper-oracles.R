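# Independent reference implementations used as oracles.  These are
# deliberately written in plain R, directly transcribing the defining
# formulas, and share no code with the package internals.

# --- local-linear weights, one covariate -----------------------------------
oracle_weights_1d <- function(T, t, h, kernel = "gaussian") {
  K <- if (kernel == "gaussian") dnorm((T - t) / h) / h
       else ifelse(abs((T - t) / h) < 1, 0.75 * (1 - ((T - t) / h)^2), 0) / h
  b0 <- mean(K)
  b1 <- mean(K * (T - t))
  b2 <- mean(K * (T - t)^2)
  s0 <- b0 * b2 - b1^2
  K * (b2 - b1 * (T - t)) / s0
}

# --- local-linear weights, two covariates (product kernel) -----------------
oracle_weights_2d <- function(X, x, h, kernel = "gaussian") {
  n <- nrow(X)
  kf <- function(u) if (kernel == "gaussian") dnorm(u)
                    else ifelse(abs(u) < 1, 0.75 * (1 - u^2), 0)
  K <- (kf((X[, 1] - x[1]) / h[1]) / h[1]) *
       (kf((X[, 2] - x[2]) / h[2]) / h[2])
  D <- sweep(X, 2, x)
  b0 <- mean(K)
  b1 <- colMeans(K * D)
  b2 <- crossprod(D, K * D) / n
  b2inv <- solve(b2)
  denom <- b0 - drop(t(b1) %*% b2inv %*% b1)
  as.numeric(K * (1 - D %*% b2inv %*% b1) / denom)
}

# --- all set partitions of 1..m as membership vectors ----------------------
oracle_partitions <- function(m) {
  out <- list()
  recurse <- function(a, i) {
    if (i > m) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (lab in seq_len(max(a[seq_len(i - 1)], 0) + 1))
      recurse(c(a[seq_len(i - 1)], lab), i + 1)
  }
  recurse(integer(0), 1)
  out
}

# --- modularity by direct double sum ---------------------------------------
oracle_modularity <- function(A, memb) {
  s <- sum(A)
  if (s <= 0) return(0)
  d <- rowSums(A)
  Q <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(ncol(A)))
      if (memb[i] == memb[j]) Q <- Q + A[i, j] - d[i] * d[j] / s
  Q / s
}

oracle_max_modularity <- function(A) {
  best <- -Inf
  for (p in oracle_partitions(nrow(A))) {
    q <- oracle_modularity(A, p)
    if (q > best) best <- q
  }
  best
}

# --- global efficiency via Floyd-Warshall ----------------------------------
oracle_global_efficiency <- function(A, rule = "weight") {
  m <- nrow(A)
  L <- matrix(Inf, m, m)
  diag(L) <- 0
  pos <- A > 0
  L[pos] <- if (rule == "weight") A[pos] else 1 / A[pos]
  diag(L) <- 0
  for (k in seq_len(m))
    for (i in seq_len(m))
      for (j in seq_len(m))
        if (L[i, k] + L[k, j] < L[i, j]) L[i, j] <- L[i, k] + L[k, j]
  inv <- 1 / L
  diag(inv) <- 0
  inv[is.infinite(L)] <- 0
  sum(inv) / (m * (m - 1))
}

# --- projected-gradient minimizer of sum_i w_i ||C - C_i||_F^2 over PSD ----
oracle_projected_gradient <- function(mats, w, max_iter = 5000,
                                      tol = 1e-12) {
  m <- nrow(mats[[1]])
  W <- sum(w)
  Cw <- Reduce(`+`, Map(function(M, wi) M * wi, mats, as.list(w)))
  proj <- function(S) {
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(pmax(e$values, 0), m) %*% t(e$vectors)
  }
  C <- diag(m)
  eta <- 0.45 / W  # gradient is 2 (W C - Cw); step keeps contraction
  for (it in seq_len(max_iter)) {
    Cnew <- proj(C - eta * 2 * (W * C - Cw))
    if (max(abs(Cnew - C)) < tol) return(Cnew)
    C <- Cnew
  }
  C
}

# --- random weighted undirected graphs -------------------------------------
rand_adj <- function(m, density = 0.5, wmin = 0.1, wmax = 1) {
  A <- matrix(0, m, m)
  up <- upper.tri(A)
  nedge <- sum(up)
  w <- ifelse(runif(nedge) < density, runif(nedge, wmin, wmax), 0)
  A[up] <- w
  A + t(A)
}

# --- small synthetic cohorts for fast tests --------------------------------
quick_config <- function(n_children = 100, m_rois = 6, seed = 1, ...) {
  synthetic_config(n_children = n_children, m_rois = m_rois, seed = seed,
                   ...)
}

# configuration with identical generative law in every group (null);
# extra rho entries (e.g. a divergence boost) can be layered on top
null_config <- function(n_children = 400, m_rois = 6, seed = 1,
                        rho = list(), ...) {
  synthetic_config(n_children = n_children, m_rois = m_rois, seed = seed,
                   visits_pmf = c(1, rep(0, 7)), p_male = 0.5,
                   p_high_mated = 0.5,
                   rho = utils::modifyList(
                     list(mated_gain = 0, elc_gain = 0), rho), ...)
}
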