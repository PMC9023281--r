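#' Define a molecule region of interest
#'
#' A molecule ROI is a horizontal band of the image: `width_px` rows centered
#' on the molecule's row, spanning the columns from the barrier (5' end, low
#' column index) to the anchor (3' end). The default width of 3 px accounts
#' for the diffraction-limited signal and transverse molecule motion.
#'
#' @param barrier_px Column of the 5' tether (barrier).
#' @param anchor_px Column of the 3' end (anchor/pedestal); must exceed
#'   `barrier_px`.
#' @param row_center_px Row of the molecule axis.
#' @param width_px Odd number of rows summed (default 3).
#' @param molecule_id Identifier used in messages and output tables.
#' @return An object of class `molecule_roi`.
#' @export
molecule_roi <- function(barrier_px, anchor_px, row_center_px, width_px = 3,
                         molecule_id = "mol1") {
  stopifnot(barrier_px < anchor_px, width_px %% 2 == 1, width_px >= 1)
  structure(list(barrier_px = as.integer(barrier_px),
                 anchor_px = as.integer(anchor_px),
                 row_center_px = as.integer(row_center_px),
                 width_px = as.integer(width_px),
                 molecule_id = molecule_id),
            class = "molecule_roi")
}

# ROI matching the simulated geometry of a kymo_stack
#' Default ROI for a simulated stack
#' @param stack A `kymo_stack`.
#' @param molecule_id Identifier for the molecule.
#' @return A [molecule_roi()] covering the simulated tethered span.
#' @export
roi_from_config <- function(stack, molecule_id = "mol1") {
  cfg <- stack$config
  molecule_roi(cfg$barrier_px, cfg$anchor_px, cfg$row_center,
               molecule_id = molecule_id)
}

#' Extract a background-subtracted intensity profile
#'
#' Sums pixel intensity across the ROI's rows for every column between the
#' barrier and the anchor, then subtracts the local background estimated as
#' the per-column median of rows at least 5 px outside the ROI band (scaled
#' to the number of summed rows). The background is recomputed per frame so
#' slow illumination drift cancels.
#'
#' @param stack A `kymo_stack` (or any list with 3-D channel arrays indexed
#'   `[frame, row, col]`).
#' @param roi A [molecule_roi()].
#' @param frame Frame index.
#' @param channel `"green"` or `"magenta"`.
#' @return Numeric vector of background-subtracted summed intensities, one
#'   per column, named by absolute column index.
#' @export
extract_profile <- function(stack, roi, frame, channel = "magenta") {
  img <- stack[[channel]][frame, , ]
  nr <- nrow(img)
  hw <- (roi$width_px - 1L) %/% 2L
  rows <- (roi$row_center_px - hw):(roi$row_center_px + hw)
  if (min(rows) < 1 || max(rows) > nr ||
      roi$barrier_px < 1 || roi$anchor_px > ncol(img))
    stop("ROI for molecule '", roi$molecule_id, "' touches the image edge")
  cols <- roi$barrier_px:roi$anchor_px
  sig <- colSums(img[rows, cols, drop = FALSE])

  bg_rows <- c(seq_len(max(0, min(rows) - 5L)),
               seq(min(nr + 1L, max(rows) + 5L), nr))
  bg_rows <- bg_rows[bg_rows >= 1 & bg_rows <= nr]
  if (length(bg_rows) == 0)
    stop("no background rows available for molecule '", roi$molecule_id, "'")
  bg <- apply(img[bg_rows, cols, drop = FALSE], 2, median)
  out <- sig - roi$width_px * bg
  names(out) <- cols
  out
}

# width between the outermost half-maximum crossings (linear interpolation)
half_max_width <- function(x, y, baseline = min(y)) {
  half <- baseline + (max(y) - baseline) / 2
  above <- y >= half
  if (!any(above)) return(0)
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 > 1) {
    x[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) *
      (x[i1] - x[i1 - 1])
  } else x[i1]
  right <- if (i2 < length(x)) {
    x[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) * (x[i2 + 1] - x[i2])
  } else x[i2]
  right - left
}

profile_fit <- function(model, center_px = NA_real_, fwhm_px = NA_real_,
                        amplitude = NA_real_, baseline = NA_real_,
                        sigma_px = NA_real_, edges_px = c(NA_real_, NA_real_),
                        r2 = NA_real_, resid_sd = NA_real_,
                        converged = FALSE, frame = NA_integer_) {
  structure(list(model = model, frame = frame, center_px = center_px,
                 fwhm_px = fwhm_px, amplitude = amplitude,
                 baseline = baseline, sigma_px = sigma_px,
                 edges_px = edges_px, r2 = r2, resid_sd = resid_sd,
                 converged = converged),
            class = "profile_fit")
}

#' Fit a Gaussian to an intensity profile
#'
#' Nonlinear least squares fit of
#' `y = baseline + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' with initial guesses: baseline = 10th percentile, amplitude = max -
#' baseline, center = argmax, sigma from the second moment of the
#' baseline-subtracted profile. The full width at half maximum is
#' `2 sqrt(2 ln 2) sigma`. A failed optimization or an amplitude below 3x the
#' residual SD yields `converged = FALSE`; this function never throws for
#' data reasons, so whole-movie loops need no error handling.
#'
#' @param profile Numeric vector (length >= 7); names, if present, are taken
#'   as absolute column positions.
#' @param frame Optional frame index stored in the result.
#' @return A `profile_fit` object (fields: `center_px`, `fwhm_px`,
#'   `amplitude`, `baseline`, `sigma_px`, `r2`, `converged`).
#' @examples
#' x <- 1:41
#' y <- 5 + 100 * exp(-(x - 21)^2 / (2 * 2^2))
#' fit_gaussian_profile(y)$fwhm_px   # 2 sqrt(2 ln 2) * 2 = 4.71
#' @export
fit_gaussian_profile <- function(profile, frame = NA_integer_) {
  n <- length(profile)
  if (n < 7) stop("profile must have at least 7 points")
  x <- if (!is.null(names(profile))) as.numeric(names(profile)) else
    seq_len(n)
  y <- as.numeric(profile)
  if (all(!is.finite(y)) || diff(range(y)) == 0)
    return(profile_fit("gaussian", frame = frame))

  b0 <- quantile(y, 0.1, names = FALSE)
  if (abs(b0) < 1e-8 * diff(range(y))) b0 <- 0   # snap numeric dust
  a0 <- max(y) - b0
  c0 <- x[which.max(y)]
  w <- pmax(y - b0, 0)
  s0 <- if (sum(w) > 0) sqrt(sum(w * (x - c0)^2) / sum(w)) else 2
  s0 <- min(max(s0, 0.8), (max(x) - min(x)) / 2)
  # second start: sigma from the direct half-maximum crossing width; for
  # plateau-topped peaks the second-moment start can fall into a narrow
  # local optimum, the crossing width starts near the broad one
  s0b <- half_max_width(x, y, b0) / (2 * sqrt(2 * log(2)))
  s0b <- min(max(s0b, 0.8), (max(x) - min(x)) / 2)

  one_fit <- function(s_init) tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ b + a * exp(-(x - m)^2 / (2 * s^2)),
      start = list(b = b0, a = a0, m = c0, s = s_init),
      lower = c(-Inf, 0, min(x), 0.3),
      upper = c(Inf, Inf, max(x), (max(x) - min(x))),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL)
  fits <- list(one_fit(s0))
  if (abs(s0b - s0) > 0.25) fits <- c(fits, list(one_fit(s0b)))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) {
    b0 <- min(y); a0 <- max(y) - min(y)
    fits <- Filter(Negate(is.null),
                   list(one_fit((s0 + s0b) / 2), one_fit(2)))
  }
  if (length(fits) == 0) return(profile_fit("gaussian", frame = frame))
  dev <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  fit <- fits[[which.min(dev)]]

  p <- stats::coef(fit)
  res <- stats::resid(fit)
  # a peak wider than the fit window (or an amplitude within noise) is a
  # baseline artifact, not a detection
  span <- max(x) - min(x)
  if (!all(is.finite(p)) || p[["a"]] < 3 * stats::sd(res) ||
      2 * sqrt(2 * log(2)) * p[["s"]] > 0.9 * span)
    return(profile_fit("gaussian", frame = frame))
  sst <- sum((y - mean(y))^2)
  profile_fit("gaussian",
              center_px = p[["m"]],
              fwhm_px = 2 * sqrt(2 * log(2)) * p[["s"]],
              amplitude = p[["a"]], baseline = p[["b"]],
              sigma_px = p[["s"]],
              r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
              resid_sd = stats::sd(res),
              converged = TRUE, frame = frame)
}

#' Fit a two-edge step (boxcar/Heaviside) model to an intensity profile
#'
#' Fits `y = baseline + amplitude * [left <= x <= right]` by exhaustive scan
#' over all integer edge pairs (the conditional least-squares amplitude and
#' baseline are closed-form for each pair), followed by sub-pixel refinement
#' of each edge by local quadratic interpolation of the SSE. The FWHM is the
#' edge separation. Used interchangeably with the Gaussian fit; the two
#' estimators agree downstream.
#'
#' @inheritParams fit_gaussian_profile
#' @return A `profile_fit` with `edges_px` (left, right) populated and
#'   `fwhm_px = right - left`.
#' @examples
#' y <- rep(c(0, 80, 0), c(15, 10, 16))
#' fit_heaviside_profile(y)$fwhm_px  # ~10
#' @export
fit_heaviside_profile <- function(profile, frame = NA_integer_) {
  n <- length(profile)
  if (n < 7) stop("profile must have at least 7 points")
  x <- if (!is.null(names(profile))) as.numeric(names(profile)) else
    seq_len(n)
  y <- as.numeric(profile)
  if (diff(range(y)) == 0) return(profile_fit("heaviside", frame = frame))

  cs <- cumsum(y); cs2 <- cumsum(y^2)
  tot <- cs[n]; tot2 <- cs2[n]
  sse <- matrix(Inf, n, n)
  for (l in 1:(n - 1)) {
    r <- (l):n                       # boxcar spans indices l..r inclusive
    s_in <- cs[r] - if (l > 1) cs[l - 1] else 0
    s2_in <- cs2[r] - if (l > 1) cs2[l - 1] else 0
    n_in <- r - l + 1
    n_out <- n - n_in
    s_out <- tot - s_in
    s2_out <- tot2 - s2_in
    sse_in <- s2_in - s_in^2 / n_in
    sse_out <- ifelse(n_out > 0, s2_out - s_out^2 / pmax(n_out, 1), 0)
    sse[l, r] <- sse_in + sse_out
  }
  best <- arrayInd(which.min(sse), dim(sse))
  l <- best[1]; r <- best[2]
  if (r - l + 1 >= n)  # "boxcar" covering everything is a flat model
    return(profile_fit("heaviside", frame = frame))

  n_in <- r - l + 1
  mean_in <- (cs[r] - if (l > 1) cs[l - 1] else 0) / n_in
  mean_out <- (tot - n_in * mean_in) / (n - n_in)
  amp <- mean_in - mean_out
  fitted <- ifelse(seq_len(n) >= l & seq_len(n) <= r, mean_in, mean_out)
  res <- y - fitted
  if (amp < 3 * stats::sd(res))
    return(profile_fit("heaviside", frame = frame))

  # sub-pixel edges: quadratic interpolation of SSE around the integer optimum
  refine <- function(vals) {
    # vals = SSE at (e-1, e, e+1); returns offset in (-0.5, 0.5)
    if (any(!is.finite(vals))) return(0)
    den <- vals[1] - 2 * vals[2] + vals[3]
    if (den <= 0) return(0)
    max(-0.5, min(0.5, 0.5 * (vals[1] - vals[3]) / den))
  }
  dl <- if (l > 1 && l < r) refine(c(sse[l - 1, r], sse[l, r], sse[l + 1, r]))
        else 0
  dr <- if (r < n && r > l) refine(c(sse[l, r - 1], sse[l, r], sse[l, r + 1]))
        else 0
  step <- if (n > 1) (x[n] - x[1]) / (n - 1) else 1
  left <- x[l] - 0.5 * step + dl * step
  right <- x[r] + 0.5 * step + dr * step
  sst <- sum((y - mean(y))^2)
  profile_fit("heaviside",
              center_px = (left + right) / 2,
              fwhm_px = right - left,
              amplitude = amp, baseline = mean_out,
              edges_px = c(left, right),
              r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
              resid_sd = stats::sd(res),
              converged = TRUE, frame = frame)
}
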