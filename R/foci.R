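#' Detect diffraction-limited foci in a 1-D intensity profile
#'
#' Finds local maxima exceeding `z_threshold` robust standard deviations of
#' the profile noise (MAD-based), then suppresses non-maximal peaks within
#' `min_separation_px` of a stronger one. The default threshold of 5 robust
#' SDs keeps the Monte-Carlo false-positive rate well below one focus per
#' molecule; the default separation of 3 px is the diffraction limit. Ties
#' are broken toward the lower column index.
#'
#' @param profile Background-subtracted numeric profile; names, if present,
#'   are absolute column positions.
#' @param min_separation_px Minimum separation between retained foci.
#' @param z_threshold Detection threshold in robust noise SDs.
#' @return A `data.frame` with columns `position_px` and `intensity`
#'   (possibly zero rows).
#' @examples
#' x <- 1:60
#' prof <- 100 * exp(-(x - 20)^2 / 3) + 100 * exp(-(x - 40)^2 / 3)
#' detect_foci(prof + rnorm(60))
#' @export
detect_foci <- function(profile, min_separation_px = 3, z_threshold = 5) {
  n <- length(profile)
  pos <- if (!is.null(names(profile))) as.numeric(names(profile)) else
    seq_len(n)
  y <- as.numeric(profile)
  noise_sd <- mad(y, center = median(y))
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- stats::sd(y)
  if (!is.finite(noise_sd) || noise_sd == 0)
    return(data.frame(position_px = numeric(0), intensity = numeric(0)))
  thr <- median(y) + z_threshold * noise_sd

  is_peak <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    # strict on the left, non-strict on the right: ties go to lower index
    is_peak[i] <- y[i] >= thr &&
      (i == 1 || y[i] > y[i - 1]) && (i == n || y[i] >= y[i + 1])
  }
  idx <- which(is_peak)
  if (length(idx) == 0)
    return(data.frame(position_px = numeric(0), intensity = numeric(0)))
  # non-maximum suppression, strongest first (ties toward lower index)
  ord <- idx[order(-y[idx], idx)]
  kept <- numeric(0)
  for (i in ord) {
    if (all(abs(pos[i] - pos[kept]) >= min_separation_px) || !length(kept))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  data.frame(position_px = pos[kept], intensity = y[kept])
}

#' Foci count per unit molecule length
#'
#' @param foci A foci `data.frame` from [detect_foci()] (or any object whose
#'   row count is the focus count).
#' @param roi A [molecule_roi()].
#' @param nt_per_px Optional calibration; when supplied the density is per
#'   knt, otherwise per pixel-derived micrometer.
#' @param um_per_px Pixel size in micrometers (default 13/122, the simulated
#'   curtain geometry).
#' @return Foci per µm (or per knt), with attribute `basis`.
#' @examples
#' roi <- molecule_roi(1, 123, 8)
#' foci <- data.frame(position_px = c(10, 30, 50, 80), intensity = 1)
#' foci_per_unit_length(foci, roi)   # 4 foci / 13 um
#' @export
foci_per_unit_length <- function(foci, roi, nt_per_px = NULL,
                                 um_per_px = 13 / 122) {
  len_px <- roi$anchor_px - roi$barrier_px
  if (len_px <= 0) stop("zero-length ROI")
  if (!is.null(nt_per_px)) {
    out <- nrow(foci) / (len_px * nt_per_px / 1000)
    attr(out, "basis") <- "per_knt"
  } else {
    out <- nrow(foci) / (len_px * um_per_px)
    attr(out, "basis") <- "per_um"
  }
  out
}

#' Per-molecule foci time series
#'
#' Runs [detect_foci()] on the background-subtracted profile of every frame.
#'
#' @param stack A `kymo_stack`.
#' @param roi A [molecule_roi()].
#' @param channel Channel to analyze.
#' @param ... Passed to [detect_foci()].
#' @return A `data.frame` with columns `frame`, `position_px`, `intensity`.
#' @export
foci_time_series <- function(stack, roi = roi_from_config(stack),
                             channel = "magenta", ...) {
  nf <- dim(stack[[channel]])[1]
  rows <- lapply(seq_len(nf), function(f) {
    fo <- detect_foci(extract_profile(stack, roi, f, channel), ...)
    if (nrow(fo) == 0) return(NULL)
    cbind(frame = f, fo)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame = integer(0), position_px = numeric(0),
                      intensity = numeric(0))
  out
}

#' Normalized total-intensity trace of a molecule
#'
#' Total background-subtracted ROI intensity per frame, divided by the
#' tethered length (correcting for molecule-to-molecule length
#' heterogeneity) and normalized to the value at the reference frame, which
#' is therefore exactly 1.
#'
#' @param stack A `kymo_stack`.
#' @param roi A [molecule_roi()].
#' @param channel Channel to integrate.
#' @param reference Reference frame index (default 1).
#' @return A `data.frame` with columns `frame`, `time_s`,
#'   `intensity_per_px` and `normalized`; attribute `reference_value`.
#' @export
intensity_trace <- function(stack, roi = roi_from_config(stack),
                            channel = "green", reference = 1) {
  nf <- dim(stack[[channel]])[1]
  if (reference < 1 || reference > nf) stop("reference frame out of range")
  len_px <- roi$anchor_px - roi$barrier_px
  tot <- vapply(seq_len(nf), function(f)
    sum(extract_profile(stack, roi, f, channel)) / len_px, numeric(1))
  ref <- tot[reference]
  if (!is.finite(ref) || ref <= 0)
    stop("reference intensity <= 0 for molecule '", roi$molecule_id,
         "'; molecule dropped")
  data.frame(frame = seq_len(nf),
             time_s = (seq_len(nf) - 1) * stack$frame_interval_s,
             intensity_per_px = tot,
             normalized = tot / ref)
}

#' Condition-level mean +/- SEM of normalized intensity traces
#'
#' @param traces List of per-molecule `data.frame`s from [intensity_trace()].
#' @return A `data.frame` with columns `frame`, `mean`, `sem`, `n` (SEM is
#'   computed across molecules, not frames).
#' @export
aggregate_intensity <- function(traces) {
  mat <- vapply(traces, function(tr) tr$normalized,
                numeric(nrow(traces[[1]])))
  mat <- matrix(mat, nrow = nrow(traces[[1]]))
  data.frame(frame = traces[[1]]$frame,
             mean = rowMeans(mat),
             sem = apply(mat, 1, stats::sd) / sqrt(ncol(mat)),
             n = ncol(mat))
}

#' Focus intensity by 3x3-pixel averaging
#'
#' Mean of the 3x3 neighborhood centered on a focus, minus the background
#' level.
#'
#' @param image 2-D numeric matrix (rows x columns).
#' @param position Length-2 integer `(row, col)` of the focus center; must be
#'   at least 1 px from every border.
#' @param background Background level per pixel subtracted from the mean.
#' @return Background-subtracted mean intensity of the 3x3 region.
#' @examples
#' img <- matrix(10, 9, 9); img[5, 5] <- 100
#' focus_intensity_3x3(img, c(5, 5), background = 10)  # (100 + 8*10)/9 - 10
#' @export
focus_intensity_3x3 <- function(image, position, background = 0) {
  r <- position[1]; c <- position[2]
  if (r < 2 || c < 2 || r > nrow(image) - 1 || c > ncol(image) - 1)
    stop("3x3 region exceeds the image border")
  mean(image[(r - 1):(r + 1), (c - 1):(c + 1)]) - background
}

#' Survival of DNA bridges after a challenge
#'
#' Kaplan-Meier estimate of the fraction of bridged molecules surviving as a
#' function of time since the challenge condition entered the flowcell.
#' Molecules still bridged at the last frame are right-censored. The
#' bridged/unbridged call per frame is an input annotation, not derived from
#' images.
#'
#' @param state Logical matrix `[molecule, frame]`: `TRUE` while bridged.
#' @param challenge_frame Frame at which the challenge is introduced.
#' @param frame_interval_s Seconds per frame.
#' @param condition Optional label column.
#' @return A `data.frame` with columns `condition`, `time_s`,
#'   `fraction_surviving`, `n_risk`; attribute `fit` holds the underlying
#'   `survival::survfit` object.
#' @export
tether_lifetime <- function(state, challenge_frame, frame_interval_s = 5,
                            condition = NA_character_) {
  stopifnot(is.matrix(state), challenge_frame >= 1,
            challenge_frame <= ncol(state))
  nf <- ncol(state)
  time <- numeric(nrow(state)); event <- integer(nrow(state))
  for (i in seq_len(nrow(state))) {
    post <- state[i, challenge_frame:nf]
    brk <- which(!post)[1]
    if (is.na(brk)) {          # survived to movie end: censored
      time[i] <- (nf - challenge_frame) * frame_interval_s
      event[i] <- 0L
    } else {
      time[i] <- (brk - 1) * frame_interval_s
      event[i] <- 1L
    }
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(condition = condition,
                    time_s = c(0, fit$time),
                    fraction_surviving = c(1, fit$surv),
                    n_risk = c(nrow(state), fit$n.risk))
  attr(out, "fit") <- fit
  out
}
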