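#' Build a clearance trace: per-frame FWHM of the growing cleared region
#'
#' Runs the profile fit on every frame of a molecule's ROI and assembles the
#' FWHM time series that measures the extent of protein clearance. The RPA
#' assay reads the magenta channel (complementary-oligo gain in cleared
#' ssDNA); the RAD51 assay reads the green channel (RPA-GFP influx). The fit
#' window is re-centered each frame on the previous frame's fitted center
#' with width `max(21 px, 3 x previous FWHM)`, so the ROI tracks the extent
#' of the clearance; frames whose fit does not converge are carried as
#' missing values.
#'
#' @param stack A `kymo_stack`.
#' @param roi A [molecule_roi()]; defaults to the simulated geometry.
#' @param channel Channel to analyze; default `"magenta"` for `"rpa"`-mode
#'   stacks and `"green"` for `"rad51"`-mode stacks.
#' @param model `"gaussian"` or `"heaviside"` profile model.
#' @param calibrate Convert fitted FWHM to a calibrated cleared extent by
#'   inverting the blurred-tophat response of the fit model (see
#'   [extent_calibration()]); requires a PSF width.
#' @param psf_sigma_px PSF sigma used for the calibration; defaults to the
#'   simulated stack's configured value, else 1.3 px.
#' @return A `data.frame` of class `clearance_trace` with columns `frame`,
#'   `time_s`, `model`, `center_px`, `fwhm_px`, `fwhm_nt` (as fitted),
#'   `extent_px`, `extent_nt` (calibrated cleared extent; equal to the FWHM
#'   columns when `calibrate = FALSE`), `r2`, `converged`, and attributes
#'   `molecule_id`, `channel`, `usable` (FALSE when more than half the
#'   frames failed to converge) and `edges_px` (two-column matrix, Heaviside
#'   model only).
#' @examples
#' cfg <- sim_config(n_frames = 12, span_px = 60, molecule_length_knt = 25)
#' pop <- motor_population(63, c(28, 117), 3.9, c(2.7, 5.1), 1)
#' stk <- render_kymograph(sample_motors(pop, cfg, seed = 3), cfg, seed = 3)
#' tr <- build_trace(stk)
#' head(tr)
#' @export
build_trace <- function(stack, roi = roi_from_config(stack), channel = NULL,
                        model = c("gaussian", "heaviside"),
                        calibrate = TRUE, psf_sigma_px = NULL) {
  model <- match.arg(model)
  if (is.null(psf_sigma_px))
    psf_sigma_px <- if (!is.null(stack$config)) stack$config$psf_sigma_px
      else 1.3
  calib <- if (calibrate) extent_calibration(psf_sigma_px, model) else
    identity
  if (is.null(channel))
    channel <- if (identical(stack$mode, "rad51")) "green" else "magenta"
  if (!channel %in% stack$channels)
    stop("channel '", channel, "' not present in stack")
  fitfun <- if (model == "gaussian") fit_gaussian_profile else
    fit_heaviside_profile
  nf <- dim(stack[[channel]])[1]
  dt <- stack$frame_interval_s
  npp <- stack$nt_per_px

  prev_center <- NA_real_
  prev_fwhm <- NA_real_
  miss_run <- 0L
  rows <- vector("list", nf)
  edges <- matrix(NA_real_, nf, 2)
  for (f in seq_len(nf)) {
    prof <- extract_profile(stack, roi, f, channel)
    cols <- as.numeric(names(prof))
    if (is.finite(prev_center)) {
      half <- max(21, 3 * ifelse(is.finite(prev_fwhm), prev_fwhm, 0)) / 2
      keep <- cols >= prev_center - half & cols <= prev_center + half
      if (sum(keep) >= 7) prof <- prof[keep]
    }
    ft <- fitfun(prof, frame = f)
    if (ft$converged) {
      # refit once with the window implied by THIS frame's width, so the
      # window is self-consistent rather than lagging the growing region
      half2 <- max(21, 3 * ft$fwhm_px) / 2
      keep2 <- cols >= ft$center_px - half2 & cols <= ft$center_px + half2
      prof2 <- extract_profile(stack, roi, f, channel)[keep2]
      if (sum(keep2) >= 7) {
        ft2 <- fitfun(prof2, frame = f)
        if (ft2$converged) ft <- ft2
      }
    }
    if (ft$converged) {
      prev_center <- ft$center_px
      prev_fwhm <- ft$fwhm_px
      miss_run <- 0L
      edges[f, ] <- ft$edges_px
    } else {
      # after two consecutive failures stop trusting the tracked window;
      # a spurious early detection must not corrupt later frames
      miss_run <- miss_run + 1L
      if (miss_run >= 2L) {
        prev_center <- NA_real_
        prev_fwhm <- NA_real_
      }
    }
    ext_px <- if (ft$converged) calib(ft$fwhm_px) else NA_real_
    rows[[f]] <- data.frame(
      frame = f, time_s = (f - 1) * dt, model = model,
      center_px = if (ft$converged) ft$center_px else NA_real_,
      fwhm_px = if (ft$converged) ft$fwhm_px else NA_real_,
      fwhm_nt = if (ft$converged) ft$fwhm_px * npp else NA_real_,
      extent_px = ext_px,
      extent_nt = ext_px * npp,
      amplitude = if (ft$converged) ft$amplitude else NA_real_,
      resid_sd = ft$resid_sd,
      r2 = ft$r2, converged = ft$converged)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("clearance_trace", "data.frame")
  attr(out, "molecule_id") <- roi$molecule_id
  attr(out, "channel") <- channel
  attr(out, "nt_per_px") <- npp
  attr(out, "usable") <- mean(!out$converged) <= 0.5
  attr(out, "edges_px") <- edges
  attr(out, "psf_sigma_px") <- psf_sigma_px
  out
}
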