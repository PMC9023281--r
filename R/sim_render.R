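#' @importFrom stats dnorm rnorm rpois convolve median mad quantile setNames
NULL

# normalized Gaussian kernel truncated at +/- 4 sigma (odd length)
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k / sum(k)
}

# "same" 1-D convolution with zero padding
conv_same <- function(x, kernel) {
  half <- (length(kernel) - 1L) / 2L
  out <- convolve(c(rep(0, half), x, rep(0, half)), kernel, type = "filter")
  out
}

# fraction of each pixel column covered by the union of intervals (nt)
# pixels i = 1..span_px cover [(i-1), i) * nt_per_px from the 5' tether
pixel_coverage <- function(intervals, span_px, nt_per_px) {
  cov <- numeric(span_px)
  if (length(intervals) == 0) return(cov)
  m <- do.call(rbind, intervals)
  m <- m[m[, 2] > m[, 1], , drop = FALSE]
  if (nrow(m) == 0) return(cov)
  # merge overlapping intervals so overlapping motors are never double-counted
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      j <- nrow(merged)
      if (m[i, 1] <= merged[j, 2]) {
        merged[j, 2] <- max(merged[j, 2], m[i, 2])
      } else {
        merged <- rbind(merged, m[i, ])
      }
    }
  }
  px_lo <- (seq_len(span_px) - 1) * nt_per_px
  for (i in seq_len(nrow(merged))) {
    ov <- pmin(px_lo + nt_per_px, merged[i, 2]) - pmax(px_lo, merged[i, 1])
    cov <- cov + pmax(0, ov) / nt_per_px
  }
  pmin(cov, 1)
}

#' Render a synthetic two-channel kymograph stack
#'
#' Forward model of one tethered ssDNA molecule imaged over time. Per frame,
#' the green-channel coverage is the protein-coated fraction of each pixel
#' (1 minus the union of motor-cleared intervals) attenuated by exponential
#' photobleaching; the magenta-channel coverage is the cleared-interval
#' indicator (a complementary fluorescent oligo hybridizes, effectively
#' instantaneously, behind the motor). Each channel image is
#' `gain x coverage` spread across rows and convolved along columns with a
#' Gaussian PSF, plus a constant background, Poisson shot noise and Gaussian
#' read noise.
#'
#' In `mode = "rad51"` the molecule starts dark (coated with unlabelled
#' RAD51) and the *green* channel gains signal in cleared regions (RPA-GFP
#' influx); the magenta channel carries background only. Because the
#' reporting RPA exchanges with the solution pool, no bleaching is applied in
#' this mode.
#'
#' @param motors A `motor_truth` data frame from [sample_motors()] (may have
#'   zero rows).
#' @param config A [sim_config()].
#' @param mode `"rpa"` (green = coated, magenta = cleared) or `"rad51"`
#'   (green = cleared, magenta = dark).
#' @param noise Logical; add Poisson shot noise and Gaussian read noise.
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `kymo_stack`: a list with 3-D arrays `green`
#'   and `magenta` indexed `[frame, row, column]`, the calibration fields
#'   `frame_interval_s` and `nt_per_px`, the `config`, and a `ground_truth`
#'   data frame (`motor`, `frame`, `cleared_nt`) of per-motor cleared extents.
#' @examples
#' cfg <- sim_config(n_frames = 10, span_px = 40, molecule_length_knt = 10)
#' pop <- motor_population(63, c(28, 117), 3.9, c(2.7, 5.1), 1)
#' stk <- render_kymograph(sample_motors(pop, cfg, seed = 1), cfg, seed = 1)
#' dim(stk$green)
#' @export
render_kymograph <- function(motors, config, mode = c("rpa", "rad51"),
                             noise = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nf <- config$n_frames
  nr <- config$n_rows
  nc <- config$n_cols
  span <- config$span_px
  npp <- config$nt_per_px
  dt <- config$frame_interval_s

  row_w <- dnorm(seq_len(nr), mean = config$row_center,
                 sd = config$psf_sigma_px)
  row_w <- row_w / sum(row_w)
  kern <- gaussian_kernel(config$psf_sigma_px)

  green <- array(0, dim = c(nf, nr, nc))
  magenta <- array(0, dim = c(nf, nr, nc))
  gt <- NULL
  nmot <- if (is.null(motors)) 0L else nrow(motors)
  if (nmot > 0)
    gt <- expand.grid(motor = motors$motor, frame = seq_len(nf))

  for (f in seq_len(nf)) {
    intervals <- list()
    if (nmot > 0) {
      for (i in seq_len(nmot)) {
        t_active <- (f - motors$start_frame[i]) * dt
        iv <- cleared_interval(motors$init_position_nt[i],
                               motors$velocity_nt_s[i],
                               motors$processivity_knt[i] * 1000,
                               t_active)
        intervals[[i]] <- iv
        gt$cleared_nt[gt$motor == motors$motor[i] & gt$frame == f] <-
          iv[2] - iv[1]
      }
    }
    cleared <- pixel_coverage(intervals, span, npp)
    occupied <- 1 - cleared
    bleach <- exp(-config$bleach_rate_per_frame * (f - 1))
    cov_g <- if (mode == "rpa") occupied * bleach else cleared
    cov_m <- if (mode == "rpa") cleared else numeric(span)

    for (ch in c("green", "magenta")) {
      cov <- if (ch == "green") cov_g else cov_m
      gain <- if (ch == "green") config$gain_green else config$gain_magenta
      line <- numeric(nc)
      line[config$barrier_px:(config$barrier_px + span - 1L)] <- gain * cov
      line <- conv_same(line, kern)
      img <- outer(row_w, line) + config$background
      if (noise) {
        img <- matrix(rpois(length(img), img), nr, nc) +
          matrix(rnorm(length(img), 0, config$read_noise_sd), nr, nc)
      }
      if (ch == "green") green[f, , ] <- img else magenta[f, , ] <- img
    }
  }

  structure(list(
    green = green, magenta = magenta,
    channels = c("green", "magenta"),
    frame_interval_s = dt, nt_per_px = npp,
    mode = mode, config = config,
    motors = motors, ground_truth = gt
  ), class = "kymo_stack")
}

#' @export
print.kymo_stack <- function(x, ...) {
  d <- dim(x$green)
  cat(sprintf(
    "kymo_stack: %d frames x %d rows x %d cols, 2 channels (%s mode)\n",
    d[1], d[2], d[3], x$mode))
  cat(sprintf("  %.0f nt/px, %.0f s/frame, %d motor(s)\n",
              x$nt_per_px, x$frame_interval_s,
              if (is.null(x$motors)) 0L else nrow(x$motors)))
  invisible(x)
}
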