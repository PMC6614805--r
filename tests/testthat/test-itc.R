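ex_std <- itc_experiment(cell_conc = 20, syringe_conc = 350)

test_that("one-site equilibrium solver handles limits and matches bisection", {
  expect_equal(solve_equilibrium_one_site(20, 0, 1), 0)
  expect_equal(solve_equilibrium_one_site(0, 10, 1), 0)
  # stoichiometric limit: K_D -> 0 with ligand below saturation
  expect_equal(solve_equilibrium_one_site(20, 10, 1e-12), 10, tolerance = 1e-9)
  expect_error(solve_equilibrium_one_site(-1, 1, 1), "non-negative")

  ml <- solve_equilibrium_one_site(20, 10, 0.0465)
  expect_equal(ml, oracle_one_site(20, 10, 0.0465), tolerance = 1e-9)
})

test_that("one-site solver agrees with bisection on 100 random cases", {
  set.seed(101)
  for (i in 1:100) {
    M <- runif(1, 0.1, 100)
    L <- runif(1, 0, 300)
    K <- 10^runif(1, -3, 2)
    N <- runif(1, 0.5, 2)
    ml <- solve_equilibrium_one_site(M, L, K, N)
    orc <- oracle_one_site(M, L, K, N)
    expect_lt(abs(ml - orc) / max(orc, 1e-12), 1e-6)
    # mass conservation: bound never exceeds either total
    expect_lte(ml, min(N * M, L) + 1e-12)
  }
})

test_that("racemic solver reduces to one-site and splits symmetric ligands", {
  one <- solve_equilibrium_one_site(20, 10, 0.0465)
  two <- solve_equilibrium_racemic(20, 10, 0, 0.0465, 3.61)
  expect_equal(unname(two[1L]), one, tolerance = 1e-9)
  expect_equal(unname(two[2L]), 0)

  # identical affinities: total bound equals one-site on the summed ligand,
  # split in proportion to the totals
  sym <- solve_equilibrium_racemic(20, 6, 3, 0.5, 0.5)
  tot <- solve_equilibrium_one_site(20, 9, 0.5)
  expect_equal(unname(sum(sym)), tot, tolerance = 1e-9)
  expect_equal(unname(sym[1L] / sym[2L]), 2, tolerance = 1e-9)
})

test_that("racemic solver matches the grid-refinement oracle on 100 random cases", {
  set.seed(202)
  for (i in 1:100) {
    M <- runif(1, 1, 50)
    L1 <- runif(1, 0, 100)
    L2 <- runif(1, 0, 100)
    K1 <- 10^runif(1, -3, 2)
    K2 <- 10^runif(1, -3, 2)
    N <- runif(1, 0.5, 1.5)
    ml <- solve_equilibrium_racemic(M, L1, L2, K1, K2, N)
    orc <- oracle_racemic(M, L1, L2, K1, K2, N)
    scale <- max(orc, 1e-9)
    expect_lt(max(abs(ml - orc)) / scale, 1e-6)
    # mass-action residuals vanish to 1e-9 relative
    S <- N * M - sum(ml)
    r1 <- S * (L1 - ml[1L]) - K1 * ml[1L]
    r2 <- S * (L2 - ml[2L]) - K2 * ml[2L]
    expect_lt(abs(r1) / max(1, N * M * max(L1, 1)), 1e-9)
    expect_lt(abs(r2) / max(1, N * M * max(L2, 1)), 1e-9)
  }
})

test_that("simulated isotherms respect degenerate and conservation limits", {
  # zero enthalpy: every injection heat equals the baseline
  iso0 <- simulate_isotherm(one_site_params(1, 1, dH = 0, baseline = 2.5), ex_std)
  expect_equal(iso0$q_uJ, rep(2.5, 25))

  # saturating schedule: cumulative heat approaches N*M_t*V0*dH. Small
  # injections of a concentrated titrant saturate the sites at the first
  # shot, so almost no aptamer is expelled unbound by the overflow.
  ex_sat <- itc_experiment(cell_conc = 20, syringe_conc = 6000,
                           injection_volumes = rep(5, 20))
  ps <- one_site_params(N = 0.9, K_D = 1e-4, dH = -40)
  iso <- simulate_isotherm(ps, ex_sat)
  q_tot <- sum(iso$q_uJ)
  q_lim <- 1e-3 * 1400 * (-40) * 0.9 * 20   # uJ; complex formed from all sites
  expect_lt(abs(q_tot - q_lim) / abs(q_lim), 0.005)
})

test_that("total evolved heat accounts for every complex formed, by independent bookkeeping", {
  ps <- one_site_params(N = 0.92, K_D = 0.5, dH = -40, baseline = 3)
  iso <- simulate_isotherm(ps, ex_std)
  # independent ledger: bisection-oracle equilibria plus explicit tracking
  # of complex expelled by each overflow
  V0 <- 1400; M <- 20; X <- 0; prev <- 0; formed <- 0
  for (v in ex_std$injection_volumes) {
    f <- V0 / (V0 + v)
    M <- M * f
    X <- X * f + 350 * v / (V0 + v)
    b <- oracle_one_site(M, X, 0.5, 0.92)
    formed <- formed + (b - f * prev)
    prev <- b
  }
  expect_equal(sum(iso$q_uJ), 1e-3 * V0 * (-40) * formed + 25 * 3,
               tolerance = 1e-7)
})

test_that("racemic model collapses to one-site when enantiomers are identical", {
  rp <- racemic_params(N = 0.95, K_D_minus = 0.8, K_D_plus = 0.8,
                       dH_minus = -30, dH_plus = -30)
  op <- one_site_params(N = 0.95, K_D = 0.8, dH = -30)
  q_r <- simulate_isotherm(rp, ex_std)$q_uJ
  q_o <- simulate_isotherm(op, ex_std)$q_uJ
  expect_lt(max(abs(q_r - q_o)), 1e-9)

  # phi -> 1 limit: the minority component carries no material
  rp1 <- racemic_params(N = 0.95, K_D_minus = 0.8, K_D_plus = 3,
                        dH_minus = -30, dH_plus = -99,
                        fraction_minus = 1 - 1e-12)
  q_r1 <- simulate_isotherm(rp1, ex_std)$q_uJ
  expect_lt(max(abs(q_r1 - q_o)), 1e-6)
})

test_that("racemic isotherm at the enantiomer parameter pair is non-sigmoidal", {
  rp <- racemic_params(N = 0.92, K_D_minus = 0.0465, K_D_plus = 3.61,
                       dH_minus = -40, dH_plus = -25)
  q_rac <- simulate_isotherm(rp, ex_std)$q_uJ
  # matched one-site curve: same N, tight-binder K_D, same total heat scale
  q_one <- simulate_isotherm(one_site_params(0.92, 0.0465, -40), ex_std)$q_uJ
  # the sigmoidal one-site curve has a sharper transition than the blended
  # racemic curve once both are normalized to their total evolved heat
  step_one <- max(abs(diff(q_one / sum(q_one))))
  step_rac <- max(abs(diff(q_rac / sum(q_rac))))
  expect_lt(step_rac, step_one)
})

test_that("dilution correction subtracts constant offsets and is idempotent", {
  ps <- one_site_params(N = 0.92, K_D = 0.0465, dH = -40, baseline = 5)
  iso <- simulate_isotherm(ps, ex_std)

  flat <- iso
  flat$q_uJ <- rep(7, nrow(flat))
  corr <- correct_dilution(flat, "trailing_mean")
  expect_equal(corr$q_uJ, rep(0, nrow(flat)))

  once <- correct_dilution(iso, "trailing_mean")
  twice <- correct_dilution(once, "trailing_mean")
  expect_equal(twice$q_uJ, once$q_uJ, tolerance = 1e-12)

  expect_error(correct_dilution(iso, "trailing_mean", k = 25), "smaller")

  # fitted-constant method recovers a known 5 uJ offset on a saturating run
  ex_sat <- itc_experiment(cell_conc = 20, syringe_conc = 700,
                           injection_volumes = rep(10, 30))
  iso_sat <- simulate_isotherm(one_site_params(0.92, 0.0465, -40, baseline = 5),
                               ex_sat)
  corr_b <- correct_dilution(iso_sat, "fit_constant")
  expect_lt(abs(attr(corr_b, "baseline_estimate") - 5) / 5, 0.02)
})

test_that("noiseless one-site round trips recover all parameters", {
  grid <- expand.grid(K_D = c(0.0465, 0.5, 3.61), dH = c(-60, -40, -20))
  for (i in seq_len(nrow(grid))) {
    ps <- one_site_params(N = 0.92, K_D = grid$K_D[i], dH = grid$dH[i])
    fit <- fit_one_site(simulate_isotherm(ps, ex_std), ex_std)
    expect_lt(abs(fit$K_D - ps$K_D) / ps$K_D, 1e-6)
    expect_lt(abs(fit$N - ps$N) / ps$N, 1e-6)
    expect_lt(abs(fit$dH - ps$dH) / abs(ps$dH), 1e-6)
  }
  # the printed enantiomer parameter sets round-trip too
  f1 <- fit_one_site(simulate_isotherm(one_site_params(0.92, 0.0465, -40), ex_std), ex_std)
  expect_lt(abs(f1$K_D - 0.0465) / 0.0465, 1e-6)
  f2 <- fit_one_site(simulate_isotherm(one_site_params(0.95, 3.61, -40), ex_std), ex_std)
  expect_lt(abs(f2$K_D - 3.61) / 3.61, 1e-6)

  flat <- simulate_isotherm(one_site_params(1, 1, dH = 0), ex_std)
  expect_error(fit_one_site(flat, ex_std), "unidentifiable")
})

test_that("one-site fits tolerate 1% heat noise (median K_D within 10%)", {
  ps <- one_site_params(N = 0.92, K_D = 0.0465, dH = -40)
  qmax <- max(abs(simulate_isotherm(ps, ex_std)$q_uJ))
  kds <- vapply(1:100, function(seed) {
    iso <- simulate_isotherm(ps, ex_std, noise_sd = 0.01 * qmax, seed = seed)
    fit_one_site(iso, ex_std)$K_D
  }, numeric(1))
  expect_lt(abs(median(kds) - 0.0465) / 0.0465, 0.10)
})

test_that("noiseless racemic round trip recovers both affinities", {
  rp <- racemic_params(N = 0.92, K_D_minus = 0.0465, K_D_plus = 3.61,
                       dH_minus = -40, dH_plus = -25)
  iso <- simulate_isotherm(rp, ex_std)
  fit <- fit_racemic(iso, ex_std)
  expect_lt(abs(fit$K_D_minus - 0.0465) / 0.0465, 1e-4)
  expect_lt(abs(fit$K_D_plus - 3.61) / 3.61, 1e-4)
  expect_lt(abs(fit$N - 0.92) / 0.92, 1e-4)
  expect_lt(abs(fit$dH_minus - (-40)) / 40, 1e-4)
  expect_lt(abs(fit$dH_plus - (-25)) / 25, 1e-4)
})

test_that("racemic fit of a degenerate input reproduces the isotherm", {
  rp <- racemic_params(N = 0.95, K_D_minus = 0.8, K_D_plus = 0.8,
                       dH_minus = -30, dH_plus = -30)
  iso <- simulate_isotherm(rp, ex_std)
  fit <- suppressWarnings(fit_racemic(iso, ex_std))
  expect_lt(fit$sse, 1e-10)
})

test_that("near-degenerate affinities trigger the identifiability warning", {
  rp <- racemic_params(N = 0.95, K_D_minus = 0.5, K_D_plus = 1.0,
                       dH_minus = -30, dH_plus = -28)
  iso <- simulate_isotherm(rp, ex_std)
  expect_warning(fit_racemic(iso, ex_std), "unidentifiable")
})

test_that("racemic fits under 1% noise recover the minority affinity (median within 25%)", {
  rp <- racemic_params(N = 0.92, K_D_minus = 0.0465, K_D_plus = 3.61,
                       dH_minus = -40, dH_plus = -25)
  qmax <- max(abs(simulate_isotherm(rp, ex_std)$q_uJ))
  kds <- vapply(1:100, function(seed) {
    iso <- simulate_isotherm(rp, ex_std, noise_sd = 0.01 * qmax, seed = seed)
    suppressWarnings(fit_racemic(iso, ex_std))$K_D_plus
  }, numeric(1))
  expect_lt(abs(median(kds) - 3.61) / 3.61, 0.25)
})
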