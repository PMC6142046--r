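# Independent oracles and small fixtures used across the suite. These are
# deliberately written against first principles (direct summation, exact SSA,
# dense tensor algebra, exhaustive labeling), not by calling the package's
# own fast paths.

# quick, cheap configuration for simulator-level tests
quick_config <- function(horizon_min = 40, ...) {
  migration_config(grid = surface_grid(24, 12), horizon_min = horizon_min,
                   ...)
}

# exact SSA over a duration, plain R, independent of the package steppers
oracle_ssa <- function(x, k1, k2, k3, k4, F_nM, duration) {
  nu <- matrix(c(-1, 1, 0, 0,  1, -1, 0, 0,  0, 0, -1, 1,  0, 0, 1, -1),
               nrow = 4)
  t <- 0
  repeat {
    a <- c(k1 * F_nM * x[1], k2 * x[2], k3 * x[2] * x[3], k4 * x[4])
    a0 <- sum(a)
    if (a0 <= 0) break
    dt <- rexp(1, a0)
    if (t + dt > duration) break
    t <- t + dt
    j <- sample.int(4, 1, prob = a / a0)
    x <- x + nu[, j]
  }
  x
}

# dense direct-summation convolution with periodic alpha and reflective beta,
# O(n^2 k^2); oracle for the FFT path
oracle_convolve <- function(events, grid, kernel) {
  r <- attr(kernel, "radius")
  na <- grid$n_alpha
  nb <- grid$n_beta
  out <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (events[i, j] == 0) next
      for (di in -r:r) {
        ii <- ((i - 1 + di) %% na) + 1
        for (dj in -r:r) {
          jj <- j + dj
          # reflect at the beta poles (even extension)
          while (jj < 1 || jj > nb) {
            if (jj < 1) jj <- 1 - jj
            if (jj > nb) jj <- 2 * nb + 1 - jj
          }
          out[ii, jj] <- out[ii, jj] +
            events[i, j] * kernel[di + r + 1, dj + r + 1]
        }
      }
    }
  }
  out
}

# exhaustive component labeling by fixpoint label propagation (8-connectivity,
# alpha wrapped); returns labels normalized by first-occurrence order
oracle_label <- function(b) {
  na <- nrow(b)
  nb <- ncol(b)
  lab <- matrix(seq_along(b), na, nb)
  lab[!b] <- 0L
  repeat {
    changed <- FALSE
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        if (!b[i, j]) next
        for (di in -1:1) {
          ii <- ((i - 1 + di) %% na) + 1
          for (dj in -1:1) {
            jj <- j + dj
            if (jj < 1 || jj > nb) next
            if (b[ii, jj] && lab[ii, jj] < lab[i, j]) {
              lab[i, j] <- lab[ii, jj]
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  normalize_labels(lab)
}

# rename labels by first occurrence so two labelings can be compared directly
normalize_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  out <- lab
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# dense 9x9 tensor-algebra evaluation of the constrained-strain relation,
# assembled from first principles (isotropic C_ijkl, Eshelby components with
# minor symmetries)
oracle_constrained <- function(eps_f_voigt, E_I, nu_I, E_M, nu_M, aspect) {
  idx <- cbind(rep(1:3, each = 3), rep(1:3, times = 3))  # 9 (i,j) pairs
  iso_C <- function(E, nu) {
    lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
    mu <- E / (2 * (1 + nu))
    C <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
      C[i, j, k, l] <- lam * (i == j) * (k == l) +
        mu * ((i == k) * (j == l) + (i == l) * (j == k))
    }
    C
  }
  # Eshelby components from the package's closed form, expanded to the full
  # tensor with minor symmetries (the Voigt packing itself is what is being
  # cross-checked here)
  Sv <- eshelby_tensor(aspect, nu_M)
  S <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) S[i, i, j, j] <- Sv[i, j]
  sh <- list(c(2, 3, Sv[4, 4] / 2), c(1, 3, Sv[5, 5] / 2),
             c(1, 2, Sv[6, 6] / 2))
  for (p in sh) {
    i <- p[1]; j <- p[2]; v <- p[3]
    S[i, j, i, j] <- v; S[i, j, j, i] <- v
    S[j, i, i, j] <- v; S[j, i, j, i] <- v
  }
  to9 <- function(A4) {
    M <- matrix(0, 9, 9)
    for (p in 1:9) for (q in 1:9) {
      M[p, q] <- A4[idx[p, 1], idx[p, 2], idx[q, 1], idx[q, 2]]
    }
    M
  }
  eps_f <- matrix(0, 3, 3)
  eps_f[1, 1] <- eps_f_voigt[1]; eps_f[2, 2] <- eps_f_voigt[2]
  eps_f[3, 3] <- eps_f_voigt[3]
  eps_f[2, 3] <- eps_f[3, 2] <- eps_f_voigt[4] / 2
  eps_f[1, 3] <- eps_f[3, 1] <- eps_f_voigt[5] / 2
  eps_f[1, 2] <- eps_f[2, 1] <- eps_f_voigt[6] / 2
  C_I <- to9(iso_C(E_I, nu_I))
  C_M <- to9(iso_C(E_M, nu_M))
  S9 <- to9(S)
  # all operators preserve the 6-dim symmetric subspace (the full 9x9 of an
  # isotropic stiffness is rank-6), so solve there
  B <- matrix(0, 9, 6)
  sym_pairs <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (c6 in 1:6) {
    i <- sym_pairs[[c6]][1]; j <- sym_pairs[[c6]][2]
    m <- matrix(0, 3, 3)
    if (i == j) m[i, j] <- 1 else {
      m[i, j] <- 1 / sqrt(2); m[j, i] <- 1 / sqrt(2)
    }
    B[, c6] <- as.vector(m)
  }
  A6 <- t(B) %*% ((C_I - C_M) %*% S9 + C_M) %*% B
  rhs6 <- t(B) %*% (C_I %*% as.vector(eps_f))
  eps_c6 <- t(B) %*% S9 %*% B %*% solve(A6, rhs6)
  matrix(B %*% eps_c6, 3, 3)
}

# brute-force O(n^2) Pareto dominance oracle (maximize both)
oracle_pareto <- function(a, b) {
  n <- length(a)
  out <- logical(n)
  for (i in seq_len(n)) {
    dom <- FALSE
    for (k in seq_len(n)) {
      if (k == i) next
      if (a[k] >= a[i] && b[k] >= b[i] && (a[k] > a[i] || b[k] > b[i])) {
        dom <- TRUE
        break
      }
    }
    out[i] <- !dom
  }
  out
}
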