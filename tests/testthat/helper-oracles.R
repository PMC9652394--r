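# Independent numerical oracles used to validate the semi-analytic solvers.

# Radial finite-difference eigensolver for the scalar mode equation
#   u'' + u'/r - l^2 u / r^2 + k0^2 n(r)^2 u = beta^2 u
# on a staggered grid r_i = (i - 1/2) dr with zero boundary at R, symmetrized
# with the cylindrical measure.  n^2 is cell-averaged with the r dr weight
# (exact for piecewise-constant profiles), which restores smooth second-order
# convergence across the misaligned circular interfaces.  Returns bound-mode
# effective indices above n_outer + margin, descending.
fd_mode_neff <- function(stack, lambda, l, R = 8 * max(stack$radii),
                         dr = 0.004, margin = 0.003) {
  k0 <- 2 * pi / lambda
  n <- as.integer(round(R / dr))
  r <- (seq_len(n) - 0.5) * dr
  N2 <- function(x) { # integral of n(s)^2 s ds from 0 to x
    out <- numeric(length(x))
    lo <- 0
    bounds <- c(stack$radii, Inf)
    for (j in seq_along(stack$indices)) {
      hi <- bounds[j]
      seg <- pmax(pmin(x, hi), lo)
      out <- out + stack$indices[j]^2 * (seg^2 - lo^2) / 2
      lo <- hi
    }
    out
  }
  a <- r - dr / 2; b <- r + dr / 2
  n2 <- (N2(b) - N2(a)) / ((b^2 - a^2) / 2)
  main <- -(a + b) / (r * dr^2) - l^2 / r^2 + k0^2 * n2
  off <- b[-n] / (dr^2 * sqrt(r[-n] * r[-1]))
  A <- diag(main)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  neff <- sqrt(ev[ev > 0]) / k0
  n_out <- stack$indices[length(stack$indices)]
  sort(neff[neff > n_out + margin & neff < max(stack$indices) - 1e-6],
       decreasing = TRUE)
}

# Characteristic-matrix (u, u') reflectance/transmittance oracle for one
# layer between two semi-infinite media at fixed axial n_eff, scalar/TE.
# Solves the 2x2 boundary-value system directly; independent of the Airy
# two-interface formula used by the implementation.
charmat_rt <- function(lambda, t, n1, n2, n3, n_eff) {
  k0 <- 2 * pi / lambda
  k1 <- k0 * sqrt(as.complex(n1^2 - n_eff^2))
  k2 <- k0 * sqrt(as.complex(n2^2 - n_eff^2))
  k3 <- k0 * sqrt(as.complex(n3^2 - n_eff^2))
  d <- k2 * t
  cc <- cos(d); ss <- sin(d)
  # unknowns (r, tau):  tau = cc(1+r) + (ss/k2) i k1 (1-r)
  #                     i k3 tau = -k2 ss (1+r) + i k1 cc (1-r)
  A <- matrix(c(-cc + 1i * k1 * ss / k2, 1,
                k2 * ss + 1i * k1 * cc, 1i * k3), 2, 2, byrow = TRUE)
  bvec <- c(cc + 1i * k1 * ss / k2, 1i * k1 * cc - k2 * ss)
  sol <- solve(A, bvec)
  list(R = Mod(sol[1])^2, T = Re(k3) / Re(k1) * Mod(sol[2])^2)
}

# Session-level cache so expensive transmission spectra are computed once and
# shared across test files.
.na_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .na_cache))
    assign(key, force(expr), envir = .na_cache)
  get(key, envir = .na_cache)
}

coarse_grid <- function() default_grid("coarse")
coarse_wl <- function() default_lambda_nm("coarse")

# Randomized three-layer stacks: transfer-matrix roots vs the FD oracle.
# Returns one row per stack with the mode counts in the comparison window
# and the largest |n_eff| discrepancy among matched roots.
random_stack_comparison <- function(n_stacks = 10, seed = 42) {
  cached(sprintf("stackcmp_%d_%d", n_stacks, seed), {
    set.seed(seed)
    rows <- lapply(seq_len(n_stacks), function(i) {
      r1 <- runif(1, 0.25, 0.45)
      t2 <- runif(1, 0.1, 0.3)
      n_out <- runif(1, 1.32, 1.36)
      n_mid <- runif(1, 1.42, 1.47)
      n_in <- runif(1, 1.36, 1.40)
      lam <- runif(1, 0.4, 0.8)
      l <- sample(0:2, 1)
      st <- layer_stack(c(r1, r1 + t2), c(n_in, n_mid, n_out))
      tm <- find_modes(lam, st, l_max = l)
      tm <- tm$n_eff[tm$l == l]
      tm <- tm[tm > n_out + 0.003]     # clear of the oracle's wall margin
      fd <- fd_mode_neff(st, lam, l)
      k <- min(length(tm), length(fd))
      data.frame(stack = i, lambda = lam, l = l,
                 n_tm = length(tm), n_fd = length(fd),
                 max_err = if (k > 0) max(abs(tm[seq_len(k)] - fd[seq_len(k)]))
                           else 0)
    })
    do.call(rbind, rows)
  })
}
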