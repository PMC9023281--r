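#' Fraction bound from gel band intensities
#'
#' Standard gel-shift quantification: `f = bound / (bound + free)`. Vectors
#' recycle as usual. Lanes where both bands are zero give `NA`.
#'
#' @param bound_intensity,free_intensity Non-negative band intensities.
#' @return Fraction bound in \[0, 1\] (`NA` where both intensities are zero).
#' @examples
#' fraction_bound(c(1, 3, 0), c(1, 1, 0))
#' @export
fraction_bound <- function(bound_intensity, free_intensity) {
  if (any(bound_intensity < 0, na.rm = TRUE) ||
      any(free_intensity < 0, na.rm = TRUE))
    stop("band intensities must be non-negative")
  tot <- bound_intensity + free_intensity
  out <- ifelse(tot > 0, bound_intensity / tot, NA_real_)
  out
}

#' Fit a one-site hyperbolic binding isotherm
#'
#' Nonlinear least squares fit of `f = Bmax [P] / (Kd + [P])` to
#' replicate-averaged fraction-bound data. By default the fit is
#' unweighted: with the usual three replicates, per-point SEM estimates are
#' so noisy that 1/SEM^2 weighting measurably inflates the variance of the
#' fitted Kd (and SEM weighting is therefore opt-in via
#' `weighting = "sem"`, with an automatic unweighted fallback when any SEM
#' is zero). Initial values: `Kd` is the concentration whose mean response
#' is nearest half of the maximum, `Bmax` is the maximum mean. `Bmax` is
#' fit freely and reported.
#'
#' When the data do not constrain `Kd` from above -- specifically, when the
#' lower 95% confidence bound on `Kd` exceeds the maximum tested
#' concentration -- `Kd` is not reported as a point estimate: `censored` is
#' set and `kd_reported` carries the lower bound, to be read as
#' "Kd > kd_reported nM".
#'
#' @param concs Concentrations in nM (>= 4 distinct values).
#' @param f_replicates Matrix (length(concs) x replicates) or vector of
#'   fraction bound.
#' @param weighting `"none"` (default) or `"sem"` (weight replicate means
#'   by 1/SEM^2).
#' @return An object of class `binding_fit`: list with `kd_nM`, `kd_se`,
#'   `kd_ci95`, `bmax`, `bmax_se`, `censored`, `kd_reported`, `converged`,
#'   `n_replicates`, `residuals`, `data`.
#' @examples
#' concs <- c(0, 2^(0:9))
#' f <- concs / (39 + concs)
#' fit_hyperbolic(concs, f)$kd_nM
#' @export
fit_hyperbolic <- function(concs, f_replicates,
                           weighting = c("none", "sem")) {
  weighting <- match.arg(weighting)
  f_mat <- if (is.matrix(f_replicates)) f_replicates else
    matrix(f_replicates, ncol = 1)
  if (length(unique(concs)) < 4)
    stop("need at least 4 distinct concentrations")
  stopifnot(nrow(f_mat) == length(concs))
  nrep <- ncol(f_mat)
  fbar <- rowMeans(f_mat)
  sem <- if (nrep > 1) apply(f_mat, 1, stats::sd) / sqrt(nrep) else
    rep(0, length(concs))

  fail <- function() structure(list(
    kd_nM = NA_real_, kd_se = NA_real_, kd_ci95 = c(NA_real_, NA_real_),
    bmax = NA_real_, bmax_se = NA_real_, censored = FALSE,
    kd_reported = NA_real_, converged = FALSE, n_replicates = nrep,
    residuals = NULL, data = data.frame(conc_nM = concs, mean = fbar,
                                        sem = sem)), class = "binding_fit")

  # monotone-decreasing (or degenerate) response is not a binding isotherm
  ccor <- suppressWarnings(stats::cor(concs, fbar))
  if (!is.finite(ccor) || ccor < 0 || max(fbar) <= 0) return(fail())

  bmax0 <- max(fbar)
  kd0 <- concs[which.min(abs(fbar - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- stats::median(concs[concs > 0])
  w <- if (weighting == "sem" && all(sem > 0)) 1 / sem^2 else
    rep(1, length(concs))
  df <- data.frame(conc = concs, f = fbar)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nlsLM(f ~ bmax * conc / (kd + conc), data = df,
                        start = list(bmax = bmax0, kd = max(kd0, 1e-6)),
                        lower = c(1e-6, 1e-6), weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) return(fail())
  cf <- summary(fit)$coefficients
  kd <- cf["kd", "Estimate"]; kd_se <- cf["kd", "Std. Error"]
  ci <- kd + c(-1, 1) * stats::qt(0.975, df = length(concs) - 2) * kd_se
  censored <- is.finite(ci[1]) && ci[1] > max(concs)
  structure(list(
    kd_nM = kd, kd_se = kd_se, kd_ci95 = ci,
    bmax = cf["bmax", "Estimate"], bmax_se = cf["bmax", "Std. Error"],
    censored = censored,
    kd_reported = if (censored) ci[1] else kd,
    converged = TRUE, n_replicates = nrep,
    residuals = stats::resid(fit),
    data = data.frame(conc_nM = concs, mean = fbar, sem = sem)
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hyperbolic binding fit: FAILED\n")
  } else if (x$censored) {
    cat(sprintf("Hyperbolic binding fit: Kd > %.0f nM (unconstrained above;",
                x$kd_reported),
        sprintf("point estimate %.0f nM), Bmax = %.2f\n", x$kd_nM, x$bmax))
  } else {
    cat(sprintf("Hyperbolic binding fit: Kd = %.1f +/- %.1f nM, Bmax = %.2f +/- %.2f\n",
                x$kd_nM, x$kd_se, x$bmax, x$bmax_se))
  }
  invisible(x)
}

#' Fit a titration data frame (long format)
#'
#' Convenience wrapper around [fit_hyperbolic()] for the long-format output
#' of [simulate_titration()] or a titration CSV with columns `conc_nM`,
#' `replicate` and either `fraction_bound` or both `bound` and `free`.
#'
#' @param titration Long-format `data.frame`.
#' @return A `binding_fit`.
#' @export
fit_titration <- function(titration) {
  if (!"fraction_bound" %in% names(titration)) {
    titration$fraction_bound <- fraction_bound(titration$bound,
                                               titration$free)
  }
  concs <- sort(unique(titration$conc_nM))
  reps <- sort(unique(titration$replicate))
  f_mat <- vapply(reps, function(r) {
    sub <- titration[titration$replicate == r, ]
    sub$fraction_bound[match(concs, sub$conc_nM)]
  }, numeric(length(concs)))
  fit_hyperbolic(concs, matrix(f_mat, nrow = length(concs)))
}

#' Normalize a dissociation time course and estimate k_off
#'
#' Divides the treated series by the matched-time control series (the
#' condition without the challenge), then fits a single exponential
#' `exp(-k_off t)` to the normalized values. Time points where the control
#' is <= 0 are dropped.
#'
#' @param times_min Time points in minutes.
#' @param treated,control Bound fractions at `times_min` (replicate means).
#' @return A list: `data` (data.frame `time_min`, `normalized`),
#'   `k_off_per_min` (`NA` if the exponential fit fails), `dropped` (indices
#'   of removed points).
#' @examples
#' t <- 0:10
#' dissociation_timecourse(t, exp(-0.2 * t), rep(1, 11))$k_off_per_min
#' @export
dissociation_timecourse <- function(times_min, treated, control) {
  stopifnot(length(times_min) == length(treated),
            length(times_min) == length(control))
  bad <- which(!(control > 0))
  if (length(bad)) {
    message("dropping ", length(bad), " point(s) with control <= 0")
    times_min <- times_min[-bad]; treated <- treated[-bad]
    control <- control[-bad]
  }
  norm <- treated / control
  df <- data.frame(time_min = times_min, normalized = norm)
  k <- NA_real_
  pos <- norm > 0
  if (sum(pos) >= 3 && any(norm[pos] < 1)) {
    # log-linear start, refined by nonlinear LS on the natural scale
    k0 <- max(1e-6, -stats::coef(stats::lm(log(norm[pos]) ~
                                             times_min[pos]))[2])
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(normalized ~ exp(-k * time_min), data = df,
                          start = list(k = k0), lower = 0)),
      error = function(e) NULL)
    if (!is.null(fit)) k <- unname(stats::coef(fit)["k"])
  }
  list(data = df, k_off_per_min = k, dropped = bad)
}
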