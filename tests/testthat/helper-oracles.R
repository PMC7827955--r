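# Independent oracles used by the unit and acceptance tests. These are
# deliberately written from the defining formulas, not from package code.

# Fixed-step classical RK4 integration of dN/dt = r * N * (1 - N/K),
# vectorised over a set of parameter draws (one state per draw).
# Returns a matrix of N values: rows = draws, cols = checkpoints.
rk4_logistic <- function(r, K, N0, checkpoints, h = 0.005) {
  n <- max(length(r), length(K), length(N0))
  r <- rep_len(r, n); K <- rep_len(K, n); N <- rep_len(N0, n)
  f <- function(N) r * N * (1 - N / K)
  out <- matrix(NA_real_, n, length(checkpoints))
  t <- 0
  for (j in seq_along(checkpoints)) {
    target <- checkpoints[j]
    while (t < target - 1e-12) {
      step <- min(h, target - t)
      k1 <- f(N)
      k2 <- f(N + step / 2 * k1)
      k3 <- f(N + step / 2 * k2)
      k4 <- f(N + step * k3)
      N <- N + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[, j] <- N
  }
  out
}

# Closed-form viability written out by hand (logistic ratio composed with
# the Emax model), independent of simulate_mtt.
oracle_viability <- function(D, day, lambda, K, N0, Emax, IC50) {
  eps <- Emax * D / (D + IC50)
  r <- lambda * (1 - eps)
  Nt <- function(rr) N0 * K / (N0 + (K - N0) * exp(-rr * day))
  Nt(r) / Nt(lambda)
}

# Plain bisection for the dose at which the closed-form viability crosses
# 0.5; NA when it does not cross within the bracket.
oracle_ic50_bisect <- function(day, lambda, K, N0, Emax, IC50,
                               lo = 1e-8, hi = 1e8, tol = 1e-10) {
  f <- function(D) oracle_viability(D, day, lambda, K, N0, Emax, IC50) - 0.5
  if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo - 1 < tol) break
  }
  sqrt(lo * hi)
}

# Brute-force elementwise SSR re-summation.
oracle_ssr <- function(obs, pred) {
  total <- 0
  for (i in seq_along(obs)) total <- total + (obs[i] - pred[i])^2
  total
}

# Shared truth for recovery tests (the package's stated world).
truth_params <- function() growth_parameters(lambda = 0.5, K = 1e5, N0 = 1000)
truth_effect <- function() drug_effect(Emax = 0.9, IC50 = 0.002)
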