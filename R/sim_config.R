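#' Simulation configuration for synthetic DNA-curtain kymographs
#'
#' Collects the physical and camera parameters of a simulated single-molecule
#' DNA-curtain field of view: one ssDNA molecule tethered between a barrier
#' (5' end, low column index) and a pedestal, imaged in two channels
#' ("green" = RPA-GFP, "magenta" = Atto647N-labelled complementary oligo).
#'
#' The nucleotides-per-pixel calibration is derived from the molecule length
#' and the tethered span in pixels: `nt_per_px = molecule_length_knt * 1000 /
#' span_px`. The tethered span defaults to 13 micrometers, the
#' barrier-to-pedestal distance of a double-tethered curtain flowcell.
#'
#' @param molecule_length_knt Molecule length in kilonucleotides (> 0). The
#'   default 25 knt over a 13 um span corresponds to ~0.5 nm per nucleotide,
#'   the extension of protein-coated ssDNA under flow.
#' @param tether_span_um Barrier-to-pedestal distance in micrometers.
#' @param span_px Tethered span in pixels (columns between barrier and anchor).
#' @param frame_interval_s Time between frames in seconds.
#' @param n_frames Number of frames in the movie.
#' @param psf_sigma_px Gaussian point-spread-function sigma in pixels. The
#'   default 1.3 px gives a diffraction-limited spot spanning about 3 px
#'   (FWHM ~ 3.1 px), matching the 3-pixel ROI convention.
#' @param bleach_rate_per_frame Photobleaching rate (1/frame) applied to the
#'   green channel; the magenta oligo exchanges with solution and does not
#'   bleach appreciably.
#' @param gain_green,gain_magenta Expected photons per pixel column at unit
#'   coverage, per channel.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param background Expected background photons per pixel.
#' @param n_rows Image height in pixels; the molecule lies along the center row.
#' @param margin_px Dark columns outside the tethered span on each side.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return An object of class `sim_config` (a named list) with the derived
#'   fields `nt_per_px`, `barrier_px`, `anchor_px`, `n_cols` and `row_center`.
#' @examples
#' cfg <- sim_config(molecule_length_knt = 50, n_frames = 40)
#' cfg$nt_per_px
#' @export
sim_config <- function(molecule_length_knt = 25,
                       tether_span_um = 13,
                       span_px = 122,
                       frame_interval_s = 15,
                       n_frames = 80,
                       psf_sigma_px = 1.3,
                       bleach_rate_per_frame = 0.002,
                       gain_green = 120,
                       gain_magenta = 120,
                       read_noise_sd = 5,
                       background = 50,
                       n_rows = 15,
                       margin_px = 8,
                       seed = 1L) {
  stopifnot(
    molecule_length_knt > 0, tether_span_um > 0, span_px >= 8,
    frame_interval_s > 0, n_frames >= 2, psf_sigma_px > 0,
    bleach_rate_per_frame >= 0, gain_green > 0, gain_magenta > 0,
    read_noise_sd >= 0, background >= 0, n_rows >= 13, margin_px >= 3
  )
  cfg <- list(
    molecule_length_knt = molecule_length_knt,
    tether_span_um = tether_span_um,
    span_px = as.integer(span_px),
    nt_per_px = molecule_length_knt * 1000 / span_px,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    psf_sigma_px = psf_sigma_px,
    bleach_rate_per_frame = bleach_rate_per_frame,
    gain_green = gain_green,
    gain_magenta = gain_magenta,
    read_noise_sd = read_noise_sd,
    background = background,
    n_rows = as.integer(n_rows),
    row_center = as.integer(ceiling(n_rows / 2)),
    margin_px = as.integer(margin_px),
    barrier_px = as.integer(margin_px + 1),
    anchor_px = as.integer(margin_px + 1 + span_px),
    n_cols = as.integer(span_px + 2 * margin_px + 1),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulated DNA-curtain configuration\n")
  cat(sprintf("  molecule: %.1f knt over %d px (%.0f nt/px), span %.1f um\n",
              x$molecule_length_knt, x$span_px, x$nt_per_px, x$tether_span_um))
  cat(sprintf("  movie: %d frames x %.0f s, image %d x %d px\n",
              x$n_frames, x$frame_interval_s, x$n_rows, x$n_cols))
  cat(sprintf("  optics: PSF sigma %.2f px, bleach %.4f /frame\n",
              x$psf_sigma_px, x$bleach_rate_per_frame))
  cat(sprintf("  camera: gain %g/%g, background %g, read noise %g\n",
              x$gain_green, x$gain_magenta, x$background, x$read_noise_sd))
  invisible(x)
}
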