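# Independent brute-force oracles. These never call the package's own
# solvers/fitters, so they can vouch for them.

# linear interpolation between closest ranks (inclusive), by hand
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

# 1:1 equilibrium by bisection on g(x) = (N*M - x)(L - x) - K*x
oracle_one_site <- function(M_t, L_t, K_D, N = 1) {
  S <- N * M_t
  if (S == 0 || L_t == 0) return(0)
  g <- function(x) (S - x) * (L_t - x) - K_D * x
  lo <- 0
  hi <- min(S, L_t)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# competitive two-ligand equilibrium by nested bisection on the mass-action
# residuals: for a trial ML1, the inner bisection solves ML2 from its own
# balance, and the outer bisection drives the ML1 residual to zero. This
# never touches the package's free-site reduction.
oracle_racemic <- function(M_t, L1_t, L2_t, K_D1, K_D2, N = 1) {
  S <- N * M_t
  if (S == 0 || (L1_t == 0 && L2_t == 0)) return(c(0, 0))
  inner_x2 <- function(x1) {
    # root of (S - x1 - x2)(L2 - x2) - K2*x2 over [0, min(S - x1, L2)]
    hi <- min(S - x1, L2_t)
    if (hi <= 0) return(0)
    h <- function(x2) (S - x1 - x2) * (L2_t - x2) - K_D2 * x2
    lo <- 0
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (h(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  r1 <- function(x1) {
    x2 <- inner_x2(x1)
    (S - x1 - x2) * (L1_t - x1) - K_D1 * x1
  }
  lo <- 0
  hi <- min(S, L1_t)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (r1(mid) > 0) lo <- mid else hi <- mid
  }
  x1 <- (lo + hi) / 2
  c(x1, inner_x2(x1))
}

# Langmuir least squares by 2-D grid search with refinement
oracle_langmuir_grid <- function(conc, theta, n_grid = 61, n_ref = 12) {
  sse <- function(kd, tm) sum((tm * conc / (kd + conc) - theta)^2)
  lk <- log(c(1e-2, 1e5))
  tm_rng <- c(1e-3, 1.6)
  best <- c(NA, NA)
  for (lev in seq_len(n_ref)) {
    gk <- seq(lk[1], lk[2], length.out = n_grid)
    gt <- seq(tm_rng[1], tm_rng[2], length.out = n_grid)
    gr <- expand.grid(k = gk, t = gt)
    v <- mapply(function(k, t) sse(exp(k), t), gr$k, gr$t)
    i <- which.min(v)
    best <- c(gr$k[i], gr$t[i])
    wk <- diff(lk) / (n_grid - 1)
    wt <- diff(tm_rng) / (n_grid - 1)
    lk <- c(best[1] - 2 * wk, best[1] + 2 * wk)
    tm_rng <- c(max(1e-6, best[2] - 2 * wt), best[2] + 2 * wt)
  }
  list(K_D = exp(best[1]), theta_max = best[2],
       cell_kd = exp(best[1]) * (exp(diff(lk) / (n_grid - 1)) - 1),
       cell_tm = diff(tm_rng) / (n_grid - 1))
}
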