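# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the finite-difference solver discretises the
# diffusion equation directly, the convolution oracle writes out the
# ion-by-ion sums, and the grid search brute-forces the MIDA objective.

# 1-D steady-state diffusion with consumption confined to the monolayer:
# uniform grid over [0, x], Dirichlet c = c_interface at the surface, flux
# boundary D * dc/dz = J at z = 0. Solved as a linear system; if the
# demanded flux would pull the monolayer below critical_o2, the consistent
# regime pins c(0) = critical_o2 and the realised flux is whatever that
# Dirichlet problem carries.
fd_oxygen_oracle <- function(depth, D, c_interface, demand, critical_o2,
                             n = 401L) {
  k <- D * 1000  # fmol/mm^2/s per (uM/mm)
  dz <- depth / (n - 1L)
  solve_with_flux <- function(J) {
    A <- matrix(0, n, n)
    b <- numeric(n)
    A[1, 1] <- -1; A[1, 2] <- 1; b[1] <- J * dz / k     # one-sided flux BC
    for (i in 2:(n - 1L)) {
      A[i, i - 1L] <- 1; A[i, i] <- -2; A[i, i + 1L] <- 1
    }
    A[n, n] <- 1; b[n] <- c_interface
    solve(A, b)
  }
  c_demand <- solve_with_flux(demand)
  if (c_demand[1] >= critical_o2 - 1e-9) {
    list(realised_ocr = demand, profile = c_demand,
         z = seq(0, depth, length.out = n), limited = FALSE)
  } else {
    # pinned regime: linear profile between critical_o2 and c_interface
    A <- matrix(0, n, n)
    b <- numeric(n)
    A[1, 1] <- 1; b[1] <- critical_o2
    for (i in 2:(n - 1L)) {
      A[i, i - 1L] <- 1; A[i, i] <- -2; A[i, i + 1L] <- 1
    }
    A[n, n] <- 1; b[n] <- c_interface
    cc <- solve(A, b)
    flux <- k * (cc[2] - cc[1]) / dz
    list(realised_ocr = flux, profile = cc,
         z = seq(0, depth, length.out = n), limited = TRUE)
  }
}

# direct transcription of the five ion-by-ion convolution sums for window 5
convolve5_oracle <- function(mp, m) {
  c(
    mp[1] * m[1],
    mp[1] * m[2] + mp[2] * m[1],
    mp[1] * m[3] + mp[2] * m[2] + mp[3] * m[1],
    mp[1] * m[4] + mp[2] * m[3] + mp[3] * m[2] + mp[4] * m[1],
    mp[1] * m[5] + mp[2] * m[4] + mp[3] * m[3] + mp[4] * m[2] + mp[5] * m[1]
  )
}

# exact-factorial binomial term, independent of dbinom
binom_term_oracle <- function(x, N, p) {
  (factorial(N) / (factorial(x) * factorial(N - x))) * p^x * (1 - p)^(N - x)
}

# brute-force the MIDA objective on an (f, p) grid
mida_grid_sse <- function(obs_frac, natural, N, n_grid = 101L) {
  fs <- seq(0, 1, length.out = n_grid)
  ps <- seq(0, 0.99, length.out = n_grid)
  best <- Inf
  for (f in fs) {
    for (p in ps) {
      pred <- predict_observed(f, p, N, natural)$fractions
      sse <- sum((obs_frac - pred)^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# full polynomial-expansion natural envelope for C_a H_b O_c via R's own
# polynomial multiplication (untruncated), used to check natural_pattern
natural_poly_oracle <- function(nc, nh, no, window = 5L) {
  polymul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    }
    out
  }
  polypow <- function(a, n) {
    out <- 1
    for (i in seq_len(n)) out <- polymul(out, a)
    out
  }
  v <- polymul(
    polymul(polypow(c(0.9893, 0.0107), nc), polypow(c(0.999885, 0.000115), nh)),
    polypow(c(0.99757, 0.00038, 0.00205), no)
  )
  v[seq_len(window)]
}
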