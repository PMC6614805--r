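#' Colorimetric signal gain from two-wavelength absorbances
#'
#' The Cy7-displacement readout uses the absorbance ratio `R = A670/A775`:
#' aptamer-bound Cy7 monomer absorbs near 775 nm, and target-displaced,
#' dimerized dye absorbs near 670 nm, so displacement raises `R`. Signal
#' gain is the relative change of the ratio against the no-target blank:
#' `G = 100 * (R_sample - R_blank) / R_blank`, in percent. The absolute
#' form `G = R_sample - R_blank` is available via `relative = FALSE`.
#'
#' @param sample,blank numeric length-2 vectors `c(A670, A775)`; `A775`
#'   must be positive in both.
#' @param relative use the relative (percent) definition; otherwise the
#'   plain ratio difference is returned.
#' @return Signal gain (percent when `relative = TRUE`).
#' @export
signal_gain <- function(sample, blank, relative = TRUE) {
  stopifnot(length(sample) == 2L, length(blank) == 2L)
  if (sample[2L] <= 0 || blank[2L] <= 0)
    stop("A775 must be positive in both sample and blank")
  if (any(c(sample, blank) < 0)) stop("absorbances must be non-negative")
  r_s <- unname(sample[1L] / sample[2L])
  r_b <- unname(blank[1L] / blank[2L])
  if (relative) 100 * (r_s - r_b) / r_b else r_s - r_b
}

#' Cross-reactivity table relative to a reference target
#'
#' Cross-reactivity of a ligand is its signal gain as a percentage of the
#' reference target's gain: `CR = 100 * G_ligand / G_reference`. The
#' reference row is exactly 100% by construction.
#'
#' @param gains named numeric vector of signal gains (percent), one per
#'   ligand; names are ligand labels.
#' @param reference label of the reference target (must be present, with
#'   positive gain).
#' @return Object of class `cross_reactivity`: data.frame with columns
#'   `ligand`, `signal_gain_pct`, `cross_reactivity_pct`; attribute
#'   `reference`.
#' @export
cross_reactivity <- function(gains, reference) {
  stopifnot(is.numeric(gains), !is.null(names(gains)))
  if (anyDuplicated(names(gains))) stop("duplicate ligand labels")
  if (!reference %in% names(gains))
    stop(sprintf("reference ligand '%s' not present", reference))
  g_ref <- gains[[reference]]
  if (g_ref <= 0) stop("reference signal gain must be positive")
  structure(
    data.frame(ligand = names(gains),
               signal_gain_pct = as.numeric(gains),
               cross_reactivity_pct = 100 * as.numeric(gains) / g_ref,
               stringsAsFactors = FALSE),
    reference = reference,
    class = c("cross_reactivity", "data.frame")
  )
}

#' Exact 1:1 binding signal with ligand depletion
#'
#' Predicted readout for a titration of aptamer into a fixed dye
#' concentration, under the exact (quadratic) 1:1 isotherm: the bound-dye
#' fraction is `[AD]/D_t` with `[AD]` from the mass-action quadratic, and
#' the signal interpolates linearly between the free-dye and bound-dye
#' endpoints. At the micromolar dye concentrations used here, dye depletion
#' is substantial relative to `K_D`, so the hyperbolic (no-depletion)
#' approximation is biased; the quadratic form is the correct model.
#'
#' @param aptamer_conc total aptamer concentrations, uM.
#' @param K_D dye-aptamer dissociation constant, uM.
#' @param dye_conc total dye concentration, uM.
#' @param s_free,s_bound signal (e.g. A775) of fully free and fully bound
#'   dye.
#' @return Predicted signal at each aptamer concentration.
#' @export
dye_binding_signal <- function(aptamer_conc, K_D, dye_conc,
                               s_free = 0, s_bound = 1) {
  bound <- vapply(aptamer_conc, function(a)
    solve_equilibrium_one_site(M_t = dye_conc, L_t = a, K_D = K_D, N = 1),
    numeric(1))
  s_free + (s_bound - s_free) * bound / dye_conc
}

#' Fit the dye-aptamer affinity from a titration
#'
#' Fits the exact ligand-depletion isotherm of [dye_binding_signal()] to a
#' titration of aptamer into fixed dye, read out at 775 nm. The signal
#' endpoints enter linearly and are profiled out exactly; `K_D` alone is
#' optimized (log scale, deterministic multi-start). A fit whose `K_D`
#' standard error exceeds 50% of the estimate is flagged low-confidence.
#'
#' @param aptamer_conc total aptamer concentrations, uM (>= 5 values).
#' @param signal readout at each concentration (e.g. A775).
#' @param dye_conc total dye concentration, uM.
#' @return Object of class `dye_affinity_fit`: list with `K_D` (uM),
#'   `s_free`, `s_bound`, `se_KD`, `low_confidence`, `sse`, `n`, `fitted`.
#' @export
fit_dye_affinity <- function(aptamer_conc, signal, dye_conc) {
  stopifnot(length(aptamer_conc) == length(signal), dye_conc > 0)
  n <- length(signal)
  if (n < 5L) stop("need at least 5 aptamer concentrations")
  if (stats::sd(signal) < .Machine$double.eps^0.5 * max(1, abs(mean(signal))))
    stop("unidentifiable: flat response")

  profile <- function(log_kd) {
    frac <- dye_binding_signal(aptamer_conc, exp(log_kd), dye_conc,
                               s_free = 0, s_bound = 1)
    X <- cbind(1, frac)
    cf <- stats::lm.fit(X, signal)$coefficients
    fitted <- drop(X %*% cf)
    list(coef = cf, sse = sum((signal - fitted)^2), fitted = fitted)
  }
  obj <- function(log_kd) profile(log_kd)$sse
  starts <- log(stats::median(aptamer_conc[aptamer_conc > 0]) * c(0.03, 0.3, 1, 3, 30))
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, obj, control = list(rel.tol = 1e-15, x.tol = 1e-14))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  K_D <- exp(best$par)
  pr <- profile(best$par)
  resid_fun <- function(par) {
    frac <- dye_binding_signal(aptamer_conc, par[1L], dye_conc, 0, 1)
    par[2L] + par[3L] * frac - signal
  }
  se <- .asymptotic_se(resid_fun, c(K_D, pr$coef), pr$sse, n)
  structure(
    list(K_D = K_D, s_free = pr$coef[[1L]],
         s_bound = pr$coef[[1L]] + pr$coef[[2L]],
         se_KD = se[1L],
         low_confidence = is.na(se[1L]) || se[1L] > 0.5 * K_D,
         sse = pr$sse, n = n, fitted = pr$fitted),
    class = "dye_affinity_fit"
  )
}

#' @export
print.dye_affinity_fit <- function(x, ...) {
  cat(sprintf("<dye_affinity_fit> K_D = %.4g uM (se %.3g)%s\n", x$K_D, x$se_KD,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Calibration curve and limit of detection for the displacement assay
#'
#' Ordinary least squares of signal gain against analyte concentration
#' inside the stated linear range, with blank statistics from replicate
#' blank gains. The limit of detection is the concentration whose
#' predicted gain first reaches `blank_mean + 3 * blank_sd`, solved from
#' the fitted line: `lod = (blank_mean + 3*blank_sd - intercept)/slope`.
#' When the fitted intercept equals the blank mean (as for noiseless linear
#' data), this reduces to the familiar closed form `3 * blank_sd / slope`.
#' An alternative rule (`lod_rule = "lowest_tested"`) reports the lowest
#' measured concentration whose mean gain exceeds the blank by a one-sided
#' Welch t-test at `alpha = 0.01`.
#'
#' @param conc analyte concentrations, uM (one per gain measurement;
#'   replicates share a concentration).
#' @param gain signal gains (percent).
#' @param blank_gain replicate blank gains (>= 3 values) used for
#'   `blank_mean`/`blank_sd`.
#' @param linear_range length-2 numeric; points outside are excluded from
#'   the regression. Default spans the data.
#' @param lod_rule `"blank_3sd"` (default) or `"lowest_tested"`.
#' @return Object of class `calibration_fit`: list with `slope` (per uM),
#'   `intercept`, `linear_range`, `lod` (uM), `blank_mean`, `blank_sd`,
#'   `se_slope`, `r_squared`, `n`.
#' @export
fit_calibration <- function(conc, gain, blank_gain,
                            linear_range = range(conc),
                            lod_rule = c("blank_3sd", "lowest_tested")) {
  stopifnot(length(conc) == length(gain))
  lod_rule <- match.arg(lod_rule)
  if (length(blank_gain) < 3L)
    stop("cannot estimate blank SD: need >= 3 blank replicates")
  stopifnot(length(linear_range) == 2L, linear_range[1L] < linear_range[2L])
  in_range <- conc >= linear_range[1L] & conc <= linear_range[2L]
  if (sum(in_range) < 3L) stop("need >= 3 points inside the linear range")
  fit <- stats::lm(gain[in_range] ~ conc[in_range])
  cf <- stats::coef(fit)
  slope <- cf[[2L]]; intercept <- cf[[1L]]
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive and finite")
  blank_mean <- mean(blank_gain)
  blank_sd <- stats::sd(blank_gain)
  if (lod_rule == "blank_3sd") {
    lod <- (blank_mean + 3 * blank_sd - intercept) / slope
    if (lod <= 0) {
      # the fitted line at zero already exceeds the blank criterion
      # (curvature or offset); fall back to the blank-referenced form
      warning("fitted intercept exceeds blank_mean + 3*blank_sd; reporting the blank-referenced LOD 3*blank_sd/slope")
      lod <- 3 * blank_sd / slope
    }
  } else {
    cs <- sort(unique(conc[conc > 0]))
    lod <- NA_real_
    for (cc in cs) {
      g <- gain[conc == cc]
      p <- if (length(g) >= 2L) {
        stats::t.test(g, blank_gain, alternative = "greater")$p.value
      } else {
        # single replicate: z against blank spread
        stats::pnorm(g, blank_mean, blank_sd, lower.tail = FALSE)
      }
      if (p < 0.01) { lod <- cc; break }
    }
  }
  # noiseless calibrations are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  structure(
    list(slope = slope, intercept = intercept,
         linear_range = as.numeric(linear_range), lod = lod,
         blank_mean = blank_mean, blank_sd = blank_sd,
         se_slope = sm$coefficients[2L, 2L],
         r_squared = sm$r.squared, n = sum(in_range)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> gain = %.3f + %.3f * conc (R2 %.4f); LOD = %.4g uM\n",
              x$intercept, x$slope, x$r_squared, x$lod))
  invisible(x)
}
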