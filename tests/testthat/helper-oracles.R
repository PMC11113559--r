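# Independent oracles used across the suite. These deliberately take
# different computational routes than the package implementations.

# Exact non-negative least squares by exhaustive support enumeration:
# min over c >= 0 of || t(A) c - p ||. At the optimum the solution equals
# the unconstrained least-squares fit on its support, so scanning every
# support and keeping feasible fits attains the exact minimum.
nnls_enumerate <- function(A, p) {
  k <- nrow(A)
  best <- list(resid2 = sum(p^2), x = rep(0, k))
  for (sz in seq_len(k)) {
    for (S in utils::combn(k, sz, simplify = FALSE)) {
      M <- t(A[S, , drop = FALSE])
      x <- qr.coef(qr(M), p)
      if (any(is.na(x)) || any(x < -1e-12)) next
      r2 <- sum((p - M %*% x)^2)
      if (r2 < best$resid2 - 1e-12) {
        full <- rep(0, k)
        full[S] <- x
        best <- list(resid2 = r2, x = full)
      }
    }
  }
  best
}

# Exact two-sided Mann-Whitney p by enumerating all permutations of the
# pooled sample (factorial route, vs the package's combination route).
mw_permutation_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  N <- length(pooled)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  perms <- gtools_permutations(N)
  Us <- apply(perms, 1L, function(idx) {
    sum(rk[idx[seq_len(n1)]]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# All permutations of 1..n (small n only).
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(sub) + 1L):(i * nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = nrow(sub))
  }
  out
}

# Redundancy-analysis eigenvalues via an explicit hat matrix on centered
# (not standardized) explanatory variables; the constrained subspace is
# invariant to column scaling, so eigenvalues must agree.
rda_brute_eigen <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  Yhat <- H %*% Yc
  ev <- eigen(crossprod(Yhat) / (nrow(Yc) - 1), symmetric = TRUE)$values
  ev[ev > 1e-10 * max(ev)]
}

# Small noise-free cruise shared by several tests.
noise_free_cruise <- function(n_stations = 1L, seed = 42L) {
  generate_cruise(cruise_config(n_stations_per_regime = n_stations,
                                noise_cv = 0, seed = seed))
}

NAT_ABUND <- isotope_constants()$natural_abundance_atom_pct
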