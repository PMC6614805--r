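#' ITC experiment geometry
#'
#' Describes a titration: fixed-volume cell holding the aptamer (the
#' macromolecule), syringe holding the titrant, and an injection schedule.
#' The perfusion (overflow) convention is used throughout: each injection of
#' volume `v` dilutes all cell contents by `V0/(V0 + v)` while the injected
#' titrant enters at `syringe_conc * v/(V0 + v)`.
#'
#' @param cell_conc aptamer concentration in the cell, uM.
#' @param syringe_conc total titrant concentration in the syringe, uM.
#' @param injection_volumes per-injection volumes, uL (>= 5 injections).
#' @param cell_volume active cell volume V0, uL.
#' @param temperature K.
#' @return Object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_conc, syringe_conc,
                           injection_volumes = rep(10, 25),
                           cell_volume = 1400, temperature = 298.15) {
  stopifnot(cell_conc > 0, syringe_conc > 0, cell_volume > 0,
            temperature > 0, all(injection_volumes > 0))
  if (length(injection_volumes) < 5L)
    stop("need at least 5 injections")
  structure(
    list(cell_volume = cell_volume, cell_conc = cell_conc,
         syringe_conc = syringe_conc,
         injection_volumes = as.numeric(injection_volumes),
         temperature = temperature),
    class = "itc_experiment"
  )
}

#' Binding parameter sets for ITC models
#'
#' `one_site_params()` describes a single class of `N` identical,
#' independent sites per aptamer with one dissociation constant and molar
#' enthalpy. `racemic_params()` describes the competitive model for a
#' racemic (two-enantiomer) titrant: both enantiomers compete for the same
#' single class of `N` sites, each with its own `K_D` and `dH`; the syringe
#' contains a fraction `fraction_minus` of the (-) enantiomer (0.5 for a
#' racemate). `baseline` is a constant per-injection dilution-heat offset
#' in uJ.
#'
#' @param N sites per aptamer (dimensionless, > 0).
#' @param K_D,K_D_minus,K_D_plus dissociation constants, uM.
#' @param dH,dH_minus,dH_plus molar binding enthalpies, kJ/mol.
#' @param fraction_minus mole fraction of the (-) enantiomer in the
#'   titrant, in (0, 1).
#' @param baseline per-injection offset, uJ.
#' @return Object of class `one_site_params` or `racemic_params`.
#' @export
one_site_params <- function(N, K_D, dH, baseline = 0) {
  stopifnot(N > 0, K_D > 0)
  structure(list(N = N, K_D = K_D, dH = dH, baseline = baseline),
            class = "one_site_params")
}

#' @rdname one_site_params
#' @export
racemic_params <- function(N, K_D_minus, K_D_plus, dH_minus, dH_plus,
                           fraction_minus = 0.5, baseline = 0) {
  stopifnot(N > 0, K_D_minus > 0, K_D_plus > 0,
            fraction_minus > 0, fraction_minus < 1)
  structure(
    list(N = N, K_D_minus = K_D_minus, K_D_plus = K_D_plus,
         dH_minus = dH_minus, dH_plus = dH_plus,
         fraction_minus = fraction_minus, baseline = baseline),
    class = "racemic_params"
  )
}

#' One-site binding equilibrium
#'
#' Solves the 1:1 mass-action equilibrium for a single ligand binding a
#' single class of `N * M_t` sites: the bound concentration is the smaller
#' root of `x^2 - (N*M_t + L_t + K_D) x + N*M_t*L_t = 0`, evaluated in the
#' numerically stable form that avoids cancellation for small `K_D`.
#'
#' @param M_t total macromolecule (aptamer) concentration, uM.
#' @param L_t total ligand concentration, uM.
#' @param K_D dissociation constant, uM.
#' @param N sites per macromolecule.
#' @return Bound-complex concentration `[ML]` in uM, within
#'   `[0, min(N*M_t, L_t)]`.
#' @export
solve_equilibrium_one_site <- function(M_t, L_t, K_D, N = 1) {
  if (M_t < 0 || L_t < 0 || K_D < 0 || N < 0) stop("inputs must be non-negative")
  S <- N * M_t
  if (S == 0 || L_t == 0) return(0)
  b <- S + L_t + K_D
  disc <- b^2 - 4 * S * L_t
  disc <- max(disc, 0)
  # smaller quadratic root, stable form: 2ac / (b + sqrt(b^2 - 4ac))
  2 * S * L_t / (b + sqrt(disc))
}

#' Two-ligand competitive binding equilibrium
#'
#' Two ligand species (e.g. the two enantiomers of a chiral titrant)
#' compete for a single class of `N * M_t` sites. With free-site
#' concentration `S`, each bound species is
#' `[ML_j] = S * L_jt / (K_Dj + S)`, so the site balance
#' `S + sum_j S*L_jt/(K_Dj + S) = N*M_t` is monotone in `S` and is solved
#' by safeguarded bisection (`uniroot`) followed by Newton polishing until
#' both mass balances hold to 1e-9 relative.
#'
#' @param M_t total macromolecule concentration, uM.
#' @param L1_t,L2_t total concentrations of the two ligand species, uM.
#' @param K_D1,K_D2 their dissociation constants, uM.
#' @param N sites per macromolecule.
#' @return Numeric vector `c(ML1, ML2)` in uM.
#' @export
solve_equilibrium_racemic <- function(M_t, L1_t, L2_t, K_D1, K_D2, N = 1) {
  if (min(M_t, L1_t, L2_t, K_D1, K_D2, N) < 0)
    stop("inputs must be non-negative")
  Stot <- N * M_t
  if (Stot == 0 || (L1_t == 0 && L2_t == 0)) return(c(ML1 = 0, ML2 = 0))
  g <- function(S) S + S * L1_t / (K_D1 + S) + S * L2_t / (K_D2 + S) - Stot
  # g is strictly increasing; g(0) = -Stot < 0, g(Stot) >= 0
  S <- stats::uniroot(g, lower = 0, upper = Stot,
                      tol = .Machine$double.eps^0.75 * max(1, Stot))$root
  # Newton polish for tight mass conservation
  for (i in 1:50) {
    gp <- 1 + L1_t * K_D1 / (K_D1 + S)^2 + L2_t * K_D2 / (K_D2 + S)^2
    step <- g(S) / gp
    S_new <- S - step
    if (S_new < 0) S_new <- S / 2
    if (abs(S_new - S) <= 1e-15 * max(1, S)) { S <- S_new; break }
    S <- S_new
  }
  if (abs(g(S)) > 1e-9 * max(1, Stot))
    stop(sprintf("equilibrium solve did not converge: site-balance residual %.3g at S = %.6g uM",
                 g(S), S))
  c(ML1 = S * L1_t / (K_D1 + S), ML2 = S * L2_t / (K_D2 + S))
}

# Per-injection bound-species trajectory under the perfusion convention.
# Returns list(f, M, X (matrix n x nl), bound (matrix n x nl)) where f is
# the per-injection dilution factor and X/bound are totals in the cell.
.itc_trajectory <- function(exp, syringe_fractions, K_D, N) {
  V0 <- exp$cell_volume
  v <- exp$injection_volumes
  n <- length(v)
  nl <- length(K_D)
  f <- V0 / (V0 + v)
  M <- numeric(n)
  X <- matrix(0, n, nl)
  bound <- matrix(0, n, nl)
  M_prev <- exp$cell_conc
  X_prev <- numeric(nl)
  Xsyr <- exp$syringe_conc * syringe_fractions
  for (i in seq_len(n)) {
    M[i] <- M_prev * f[i]
    X[i, ] <- X_prev * f[i] + Xsyr * v[i] / (V0 + v[i])
    bound[i, ] <- if (nl == 1L) {
      solve_equilibrium_one_site(M[i], X[i, 1L], K_D, N)
    } else {
      solve_equilibrium_racemic(M[i], X[i, 1L], X[i, 2L], K_D[1L], K_D[2L], N)
    }
    M_prev <- M[i]
    X_prev <- X[i, ]
  }
  list(f = f, M = M, X = X, bound = bound)
}

# Design columns a_ij = 1e-3 * V0 * (bound_ij - f_i * bound_{i-1,j}), with
# f_i the perfusion dilution factor: the heat of injection i is
# q_i = sum_j dH_j * a_ij + baseline (uJ). Complex carried out of the cell
# by overflow released its heat when it formed, so only newly formed
# complex (relative to the diluted carry-over f_i * bound_{i-1}) heats the
# cell; at saturation bound_i = f_i * bound_{i-1} and the heat vanishes.
.itc_design <- function(exp, syringe_fractions, K_D, N) {
  tr <- .itc_trajectory(exp, syringe_fractions, K_D, N)
  n <- nrow(tr$bound)
  prev <- rbind(0, tr$bound[-n, , drop = FALSE])
  1e-3 * exp$cell_volume * (tr$bound - tr$f * prev)
}

#' Simulate an ITC isotherm
#'
#' Forward-simulates per-injection heats for a one-site or racemic
#' competitive parameter set under the perfusion dilution convention
#' (each injection dilutes all cell contents by `f_i = V0/(V0 + v_i)`
#' before re-equilibration). The heat of injection i is
#' `q_i = V0 * sum_j dH_j * ([ML_j]_i - f_i [ML_j]_{i-1}) + baseline`, in
#' uJ (concentrations uM, volumes uL, enthalpies kJ/mol): only complex
#' formed beyond the diluted carry-over releases heat, so a saturated run
#' has vanishing tail heats and the cumulative heat accounts for every
#' complex ever formed, including the portion later expelled by overflow.
#' Gaussian noise of standard deviation `noise_sd` uJ is added when
#' requested.
#'
#' @param params a [one_site_params()] or [racemic_params()] object.
#' @param exp an [itc_experiment()].
#' @param noise_sd Gaussian noise SD on each heat, uJ.
#' @param seed RNG seed used only when `noise_sd > 0`.
#' @return Object of class `isotherm`: data.frame with columns `injection`,
#'   `volume_ul`, `titrant_total_uM` (cumulative titrant in the cell),
#'   `q_uJ` and `ndh_kJ_mol` (heat normalized per mole of injectant).
#' @export
simulate_isotherm <- function(params, exp, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(exp, "itc_experiment"), noise_sd >= 0)
  if (inherits(params, "one_site_params")) {
    frac <- 1
    K_D <- params$K_D
    dH <- params$dH
  } else if (inherits(params, "racemic_params")) {
    frac <- c(params$fraction_minus, 1 - params$fraction_minus)
    K_D <- c(params$K_D_minus, params$K_D_plus)
    dH <- c(params$dH_minus, params$dH_plus)
  } else stop("params must be one_site_params or racemic_params")
  A <- .itc_design(exp, frac, K_D, params$N)
  q <- drop(A %*% dH) + params$baseline
  if (noise_sd > 0) {
    q <- q + .with_seed(seed, stats::rnorm(length(q), 0, noise_sd))
  }
  tr <- .itc_trajectory(exp, frac, K_D, params$N)
  v <- exp$injection_volumes
  structure(
    data.frame(
      injection = seq_along(v),
      volume_ul = v,
      titrant_total_uM = rowSums(tr$X),
      injectant_pmol = exp$syringe_conc * v,
      q_uJ = q,
      ndh_kJ_mol = q / (exp$syringe_conc * v) * 1e3
    ),
    class = c("isotherm", "data.frame"),
    corrected = FALSE
  )
}

#' Correct an isotherm for titrant dilution heat
#'
#' Two estimators of the constant dilution-heat offset: `"trailing_mean"`
#' subtracts the mean heat of the last `k` injections (appropriate when the
#' schedule saturates, so trailing heats are pure dilution);
#' `"fit_constant"` fits a geometric decay `b + a * r^i` to the trailing
#' half of the injections and subtracts the fitted asymptote `b`, which
#' tolerates residual binding heat in the tail.
#'
#' @param iso an `isotherm`.
#' @param method `"trailing_mean"` or `"fit_constant"`.
#' @param k number of trailing injections for `"trailing_mean"`.
#' @return The corrected isotherm; attributes `corrected = TRUE`,
#'   `correction_method`, `baseline_estimate` (uJ).
#' @export
correct_dilution <- function(iso, method = c("trailing_mean", "fit_constant"),
                             k = 3L) {
  stopifnot(inherits(iso, "isotherm"))
  method <- match.arg(method)
  q <- iso$q_uJ
  n <- length(q)
  if (method == "trailing_mean") {
    if (k >= n) stop("k must be smaller than the number of injections")
    b <- mean(q[(n - k + 1L):n])
  } else {
    m <- max(5L, n %/% 2L)
    idx <- (n - m + 1L):n
    qi <- q[idx]
    b0 <- qi[length(qi)]
    resid_fun <- function(par) par[1L] + par[2L] * exp(-exp(par[3L]) * seq_along(qi)) - qi
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(b0, qi[1L] - b0, log(0.5)), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    b <- if (is.null(fit)) mean(q[(n - 2L):n]) else fit$par[1L]
  }
  out <- iso
  out$q_uJ <- q - b
  if (!is.null(iso$injectant_pmol))
    out$ndh_kJ_mol <- out$q_uJ / iso$injectant_pmol * 1e3
  attr(out, "corrected") <- TRUE
  attr(out, "correction_method") <- method
  attr(out, "baseline_estimate") <- b
  out
}

# profile SSE for variable-projection ITC fits: given nonlinear parameters
# build the design, solve the linear (dH..., baseline) part exactly
.itc_profile <- function(q, exp, syringe_fractions, K_D, N, w) {
  A <- tryCatch(.itc_design(exp, syringe_fractions, K_D, N),
                error = function(e) NULL)
  if (is.null(A) || any(!is.finite(A))) return(NULL)
  X <- cbind(A, 1)
  sw <- sqrt(w)
  cf <- tryCatch(stats::lm.fit(X * sw, q * sw)$coefficients,
                 error = function(e) NULL)
  if (is.null(cf) || any(is.na(cf))) return(NULL)
  fitted <- drop(X %*% cf)
  list(coef = cf, sse = sum(w * (q - fitted)^2), fitted = fitted)
}

#' Fit the single-site ITC model
#'
#' Weighted least squares of per-injection heats against the one-site
#' Wiseman-type model. `dH` and `baseline` enter the heat linearly, so they
#' are profiled out exactly (variable projection) and only `(N, K_D)` are
#' optimized numerically, with deterministic multi-start over `K_D`
#' decades. Standard errors are asymptotic, from the numeric Jacobian over
#' all four parameters at the optimum.
#'
#' @param iso an `isotherm` (>= 5 injections spanning the transition).
#' @param exp the [itc_experiment()] that produced it.
#' @param weights optional per-injection weights (default equal).
#' @param drop_first drop injection 1 (common ITC practice); default keeps
#'   all injections.
#' @return Object of class `one_site_fit`: list with `N`, `K_D` (uM), `dH`
#'   (kJ/mol), `baseline` (uJ), `se` (named vector), `sse`, `n`, `fitted`,
#'   and `dG_kJ_mol` (= RT ln K_D, a derived convenience).
#' @export
fit_one_site <- function(iso, exp, weights = NULL, drop_first = FALSE) {
  stopifnot(inherits(iso, "isotherm"), inherits(exp, "itc_experiment"))
  q <- iso$q_uJ
  keep <- if (drop_first) -1L else seq_along(q)
  q <- q[keep]
  exp_fit <- exp
  exp_fit$injection_volumes <- exp$injection_volumes[keep]
  n <- length(q)
  if (n < 5L) stop("need at least 5 injections")
  if (stats::sd(q) < .Machine$double.eps^0.5 * max(1, abs(mean(q))))
    stop("unidentifiable: flat isotherm")
  w <- if (is.null(weights)) rep(1, n) else weights[keep]

  obj <- function(psi) {
    pr <- .itc_profile(q, exp_fit, 1, exp(psi[2L]), exp(psi[1L]), w)
    if (is.null(pr)) return(1e300)
    pr$sse
  }
  kd_starts <- exp$cell_conc * c(1e-3, 1e-2, 0.1, 1, 10)
  best <- NULL
  for (kd0 in kd_starts) {
    opt <- stats::nlminb(c(0, log(kd0)), obj,
                         control = list(rel.tol = 1e-15, x.tol = 1e-12,
                                        iter.max = 1000, eval.max = 2000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  psi <- best$par
  N <- exp(psi[1L]); K_D <- exp(psi[2L])
  pr <- .itc_profile(q, exp_fit, 1, K_D, N, w)
  dH <- pr$coef[1L]; baseline <- pr$coef[2L]

  full_resid <- function(par) {
    A <- .itc_design(exp_fit, 1, par[2L], par[1L])
    sqrt(w) * (drop(A %*% par[3L]) + par[4L] - q)
  }
  se <- .asymptotic_se(full_resid, c(N, K_D, dH, baseline), pr$sse, n)
  names(se) <- c("N", "K_D", "dH", "baseline")
  RT <- 8.314462618e-3 * exp$temperature  # kJ/mol
  structure(
    list(N = N, K_D = K_D, dH = dH, baseline = baseline,
         se = se, sse = pr$sse, n = n, fitted = pr$fitted,
         dG_kJ_mol = RT * log(K_D * 1e-6)),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat(sprintf("<one_site_fit> N = %.3f, K_D = %.4g uM, dH = %.3f kJ/mol, baseline = %.3g uJ (SSE %.3g, n %d)\n",
              x$N, x$K_D, x$dH, x$baseline, x$sse, x$n))
  invisible(x)
}

#' Fit the racemic competitive ITC model
#'
#' Fits the two-enantiomer competitive model: both enantiomers of a chiral
#' titrant compete for the same single class of `N` sites per aptamer, each
#' with its own `K_D` and `dH`. The enantiomer fraction `fraction_minus` is
#' fixed (0.5 for a racemate), not fitted. `dH_minus`, `dH_plus` and
#' `baseline` are profiled out linearly; `(N, K_D_minus, K_D_plus)` are
#' optimized with starts from a one-site pre-fit whose `K_D` is split by
#' +/- 1.5 decades. When `fraction_minus = 0.5` the two components are
#' exchangeable, so the result is reported with `K_D_minus <= K_D_plus`.
#'
#' @inheritParams fit_one_site
#' @param fraction_minus fixed mole fraction of the (-) enantiomer.
#' @return Object of class `racemic_fit`: list with `N`, `K_D_minus`,
#'   `K_D_plus` (uM), `dH_minus`, `dH_plus` (kJ/mol), `baseline`, `se`,
#'   `sse`, `n`, `fitted`.
#' @export
fit_racemic <- function(iso, exp, fraction_minus = 0.5, weights = NULL,
                        drop_first = FALSE) {
  stopifnot(inherits(iso, "isotherm"), inherits(exp, "itc_experiment"),
            fraction_minus > 0, fraction_minus < 1)
  q <- iso$q_uJ
  keep <- if (drop_first) -1L else seq_along(q)
  q <- q[keep]
  exp_fit <- exp
  exp_fit$injection_volumes <- exp$injection_volumes[keep]
  n <- length(q)
  if (n < 5L) stop("need at least 5 injections")
  if (stats::sd(q) < .Machine$double.eps^0.5 * max(1, abs(mean(q))))
    stop("unidentifiable: flat isotherm")
  w <- if (is.null(weights)) rep(1, n) else weights[keep]
  frac <- c(fraction_minus, 1 - fraction_minus)

  pre <- fit_one_site(iso, exp, weights = weights, drop_first = drop_first)
  kd_pre <- pre$K_D
  split <- 10^1.5
  starts <- list(
    c(log(pre$N), log(kd_pre / split), log(kd_pre * split)),
    c(log(pre$N), log(kd_pre / 10), log(kd_pre * 10)),
    c(log(pre$N), log(kd_pre), log(kd_pre * split^2)),
    c(log(pre$N), log(kd_pre / split^2), log(kd_pre))
  )
  obj <- function(psi) {
    pr <- .itc_profile(q, exp_fit, frac, exp(psi[2:3]), exp(psi[1L]), w)
    if (is.null(pr)) return(1e300)
    pr$sse
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, obj,
                         control = list(rel.tol = 1e-15, x.tol = 1e-12,
                                        iter.max = 2000, eval.max = 4000))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  psi <- best$par
  N <- exp(psi[1L]); K_D <- exp(psi[2:3])
  pr <- .itc_profile(q, exp_fit, frac, K_D, N, w)
  dH <- pr$coef[1:2]; baseline <- pr$coef[3L]
  if (fraction_minus == 0.5 && K_D[1L] > K_D[2L]) {
    K_D <- rev(K_D); dH <- rev(dH)
  }
  ratio <- max(K_D) / min(K_D)
  if (ratio < 5)
    warning(sprintf("K_D ratio %.2f < 5: enantiomer affinities may be unidentifiable",
                    ratio))
  full_resid <- function(par) {
    A <- .itc_design(exp_fit, frac, par[2:3], par[1L])
    sqrt(w) * (drop(A %*% par[4:5]) + par[6L] - q)
  }
  se <- .asymptotic_se(full_resid, c(N, K_D, dH, baseline), pr$sse, n)
  names(se) <- c("N", "K_D_minus", "K_D_plus", "dH_minus", "dH_plus", "baseline")
  structure(
    list(N = N, K_D_minus = K_D[1L], K_D_plus = K_D[2L],
         dH_minus = dH[1L], dH_plus = dH[2L], baseline = baseline,
         fraction_minus = fraction_minus,
         se = se, sse = pr$sse, n = n, fitted = pr$fitted),
    class = "racemic_fit"
  )
}

#' @export
print.racemic_fit <- function(x, ...) {
  cat(sprintf("<racemic_fit> N = %.3f; K_D = %.4g / %.4g uM; dH = %.2f / %.2f kJ/mol (SSE %.3g)\n",
              x$N, x$K_D_minus, x$K_D_plus, x$dH_minus, x$dH_plus, x$sse))
  invisible(x)
}

# asymptotic SEs from a residual function at the optimum
.asymptotic_se <- function(resid_fun, par, sse, n) {
  p <- length(par)
  if (n <= p) return(rep(NA_real_, p))
  J <- .num_jacobian(resid_fun, par)
  s2 <- sse / (n - p)
  cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, p))
  sqrt(pmax(diag(cv), 0))
}

# evaluate expr with a temporary RNG state when seed is non-NULL
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
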