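#' Gel-elution binding fraction
#'
#' The gel-elution assay immobilizes the library on beads, elutes with
#' target, and quantifies two gel bands: the supernatant band (target-eluted
#' strands, concentration `c_s`) and the formamide band (all remaining
#' strands, concentration `c_b`). The eluted fraction, in percent, is
#'
#' \deqn{\theta = 100 \cdot \frac{V_1 c_s}{V_2 c_s + V_3 c_b}}
#'
#' where `V1` is the solution volume before supernatant collection, `V2` the
#' collected supernatant volume and `V3` the volume after formamide
#' addition. The defaults (62, 40, 80 uL) are the assay's standard
#' geometry; `V1` already discounts the ~8 uL occupied by agarose beads.
#'
#' @param c_s,c_b band concentrations (same arbitrary units, >= 0, not both
#'   zero).
#' @param V1,V2,V3 assay volumes in uL.
#' @return Eluted fraction in percent. A value above 100% (possible when
#'   `c_b` is very small relative to the volume model) triggers a warning.
#' @export
elution_fraction <- function(c_s, c_b, V1 = 62, V2 = 40, V3 = 80) {
  stopifnot(V1 > 0, V2 > 0, V3 > 0)
  if (c_s < 0 || c_b < 0) stop("band concentrations must be non-negative")
  if (c_s == 0 && c_b == 0) stop("no signal in either gel fraction")
  theta <- 100 * V1 * c_s / (V2 * c_s + V3 * c_b)
  if (theta > 100)
    warning(sprintf(
      "elution fraction %.1f%% exceeds 100%%: volume model and band quantification are inconsistent",
      theta))
  theta
}

#' Langmuir saturation curve
#'
#' Single-site binding isotherm for the eluted fraction as a function of
#' target concentration: `theta(c) = theta_max * c / (K_D + c)`.
#'
#' @param conc target concentrations, uM.
#' @param K_D dissociation constant, uM.
#' @param theta_max maximal eluted fraction (dimensionless, on (0, 1]).
#' @return Eluted fraction (dimensionless) at each concentration.
#' @export
langmuir_theta <- function(conc, K_D, theta_max) {
  theta_max * conc / (K_D + conc)
}

#' Fit the Langmuir isotherm to elution data
#'
#' Least-squares fit of `theta(c) = theta_max * c/(K_D + c)` to eluted
#' fractions. Because enriched pools often saturate well below 100% elution
#' (only a subpopulation binds), `theta_max` is a free parameter by default;
#' set `fix_theta_max` to pin it (e.g. at 1).
#'
#' Initialization is deterministic multi-start: `K_D` starts at 0.1x, 1x and
#' 10x the median positive concentration, the best final sum of squares
#' wins. Standard errors are asymptotic (from the Jacobian at the optimum).
#'
#' @param conc target concentrations in uM; at least 3 distinct values
#'   including 0.
#' @param theta eluted fractions (dimensionless, i.e. percent / 100);
#'   values above 1 are tolerated up to 1.6 to accommodate volume-model
#'   mismatch flagged by [elution_fraction()].
#' @param fix_theta_max optional fixed value for `theta_max`.
#' @return An object of class `langmuir_fit`: list with `K_D` (uM),
#'   `theta_max`, `se_KD`, `se_theta_max`, `residual_sse`, `n`, `fitted`.
#' @export
fit_langmuir <- function(conc, theta, fix_theta_max = NULL) {
  stopifnot(length(conc) == length(theta), length(conc) >= 3L)
  if (length(unique(conc)) < 3L || !any(conc == 0))
    stop("need >= 3 distinct concentrations including 0")
  if (any(theta < 0) || any(theta > 1.6))
    stop("theta must lie in [0, 1.6] (fractions, not percent)")
  if (max(theta) - min(theta) < .Machine$double.eps^0.5)
    stop("unidentifiable: no curvature in the elution data")

  cpos <- conc[conc > 0]
  kd_starts <- stats::median(cpos) * c(0.1, 1, 10)
  fixed_tm <- !is.null(fix_theta_max)

  resid_fun <- function(par) {
    kd <- exp(par[[1L]])
    tm <- if (fixed_tm) fix_theta_max else par[[2L]]
    langmuir_theta(conc, kd, tm) - theta
  }
  best <- NULL
  for (kd0 in kd_starts) {
    start <- if (fixed_tm) c(log(kd0)) else c(log(kd0), max(theta))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("Langmuir fit failed from every start")
  par <- best$fit$par
  K_D <- exp(par[[1L]])
  theta_max <- if (fixed_tm) fix_theta_max else par[[2L]]

  # asymptotic covariance from the Jacobian in (log KD, theta_max) space
  n <- length(conc)
  p <- length(par)
  se <- rep(NA_real_, p)
  if (n > p) {
    J <- .num_jacobian(resid_fun, par)
    s2 <- best$sse / (n - p)
    cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  structure(
    list(K_D = K_D, theta_max = theta_max,
         se_KD = K_D * se[1L],      # delta method from log scale
         se_theta_max = if (fixed_tm) 0 else se[2L],
         residual_sse = best$sse, n = n,
         fitted = langmuir_theta(conc, K_D, theta_max)),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("<langmuir_fit> K_D = %.4g uM (se %.3g), theta_max = %.3f, SSE = %.3g (n = %d)\n",
              x$K_D, x$se_KD, x$theta_max, x$residual_sse, x$n))
  invisible(x)
}

#' Single-concentration elution profile across ligands
#'
#' Assembles the percent-elution screen used to assess cross-reactivity and
#' specificity: one eluted-fraction value per ligand at a common target
#' concentration, with buffer alone as the reference row. Input order is
#' preserved and values are passed through unchanged.
#'
#' @param ligand character vector of ligand labels (unique; typically
#'   includes `"buffer"`).
#' @param theta_pct percent elution per ligand.
#' @return data.frame with columns `ligand`, `theta_pct`, class
#'   `elution_profile`.
#' @export
elution_profile <- function(ligand, theta_pct) {
  stopifnot(length(ligand) == length(theta_pct))
  if (anyDuplicated(ligand))
    stop("duplicate ligand labels in elution profile")
  structure(
    data.frame(ligand = as.character(ligand), theta_pct = as.numeric(theta_pct),
               stringsAsFactors = FALSE),
    class = c("elution_profile", "data.frame")
  )
}

# central-difference numeric Jacobian of a residual function
.num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[[j]]))
    pp <- par; pp[[j]] <- pp[[j]] + h
    pm <- par; pm[[j]] <- pm[[j]] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}
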