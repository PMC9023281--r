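# calibrated cleared extent when present, fitted FWHM otherwise
trace_extent_nt <- function(trace) {
  if ("extent_nt" %in% names(trace)) trace$extent_nt else trace$fwhm_nt
}

# Smallest cleared extent (nt) the profile fit can detect, from the
# amplitude gate (3 x residual SD) and the blurred-tophat amplitude response
# 2 Phi(W / (2 sigma)) - 1. Needs the trace's amplitude/resid_sd columns.
detection_limit_nt <- function(trace) {
  if (!all(c("amplitude", "resid_sd") %in% names(trace)))
    return(NA_real_)
  ok <- trace$converged & is.finite(trace$amplitude)
  if (sum(ok) < 3) return(NA_real_)
  a_inf <- stats::quantile(trace$amplitude[ok], 0.9, names = FALSE)
  noise <- stats::median(trace$resid_sd[ok], na.rm = TRUE)
  psf <- attr(trace, "psf_sigma_px")
  npp <- attr(trace, "nt_per_px")
  if (is.null(psf) || is.null(npp) || !is.finite(a_inf) ||
      !is.finite(noise) || a_inf <= 0)
    return(NA_real_)
  q <- 3 * noise / a_inf
  if (q >= 0.95) return(NA_real_)
  2 * psf * stats::qnorm((q + 1) / 2) * npp
}

# drop isolated leading detections more than 2 frames before the first
# sustained (>= 2 consecutive frames) detection run: noise blips, not onset
prune_onset_blips <- function(ok) {
  runs <- rle(ok)
  if (length(runs$lengths) > 1) {
    sustained <- which(runs$values & runs$lengths >= 2)
    if (length(sustained)) {
      first_sust <- sum(runs$lengths[seq_len(sustained[1] - 1)]) + 1L
      blip <- which(ok[seq_len(first_sust - 1)])
      blip <- blip[first_sust - blip > 2]
      if (length(blip) && length(blip) <= 2) ok[blip] <- FALSE
    }
  }
  ok
}

#' Segment the active (rising) phase of a clearance trace
#'
#' Fits a flat-rising-flat piecewise-linear model to the FWHM(t) series by
#' exhaustive search over all changepoint pairs on the observed frame grid,
#' with the two plateau levels estimated by conditional linear least squares
#' for every pair, then refines the two changepoints continuously (the
#' motor's start and stop need not coincide with a camera frame). A trace
#' whose best model rises to the final frame is censored: the motor was still
#' translocating when the movie ended.
#'
#' Frames before the cleared region first becomes detectable are not missing
#' at random: they constrain the cleared extent to below the detection
#' limit. The segmentation therefore treats leading non-converged frames as
#' censored observations -- the fitted model is penalized only where it
#' predicts an extent above the first detected FWHM at those times -- and
#' anchors the leading plateau at zero extent whenever no detected point
#' precedes the rise (the cleared extent is physically zero before the motor
#' starts). This recovers the rise slope even when its early part is below
#' the detection limit, without biasing it in either direction. Interior
#' and trailing non-converged frames remain missing.
#'
#' @param trace A `clearance_trace` from [build_trace()].
#' @return A list of class `active_phase`: `start_frame` / `end_frame` (first
#'   and last frames of the rising phase), `start_s` / `end_s` (continuous
#'   changepoint times), `slope_nt_s` (ramp slope, the least-squares FWHM
#'   growth rate over the rising phase), `level_start` / `level_end` (plateau
#'   FWHM in nt), `censored`, `sse`, `n_used`.
#' @export
segment_active_phase <- function(trace) {
  ext <- trace_extent_nt(trace)
  ok <- trace$converged & is.finite(ext)
  if (nrow(trace) < 5) stop("trace has fewer than 5 frames")
  ok <- prune_onset_blips(ok)
  first_ok <- which(ok)[1]
  if (is.na(first_ok)) stop("trace has no converged frames")
  lead_t <- if (first_ok > 1) trace$time_s[seq_len(first_ok - 1)] else
    numeric(0)
  detect_limit <- detection_limit_nt(trace)
  dlim_physical <- is.finite(detect_limit)
  if (!dlim_physical) detect_limit <- ext[first_ok]
  t <- trace$time_s[ok]
  y <- ext[ok]
  m <- length(t)
  if (m < 5) stop("trace has fewer than 5 usable (converged) frames")

  fit_pair <- function(c1, c2) {
    phi2 <- pmin(1, pmax(0, (t - c1) / (c2 - c1)))
    phi1 <- 1 - phi2
    # the leading level is free only where detected points constrain it;
    # before the motor starts the cleared extent is physically zero
    if (any(phi1 > 0.99)) {
      X <- cbind(phi1, phi2)
      cf <- tryCatch(stats::lm.fit(X, y)$coefficients,
                     error = function(e) NULL)
      if (is.null(cf) || any(!is.finite(cf))) return(NULL)
      a <- unname(cf[1]); b <- unname(cf[2])
    } else {
      s2 <- sum(phi2^2)
      if (s2 <= 0) return(NULL)
      a <- 0; b <- sum(phi2 * y) / s2
    }
    res <- y - (a * phi1 + b * phi2)
    sse <- sum(res^2)
    if (length(lead_t)) {
      pred_lead <- a + (b - a) *
        pmin(1, pmax(0, (lead_t - c1) / (c2 - c1)))
      sse <- sse + sum(pmax(0, pred_lead - detect_limit)^2)
    }
    list(a = a, b = b, sse = sse)
  }

  c1_cands <- c(lead_t, t[-m])
  best <- NULL
  for (c1 in c1_cands) {
    for (c2 in t[t > c1]) {
      f <- fit_pair(c1, c2)
      if (!is.null(f) && (is.null(best) || f$sse < best$sse))
        best <- c(f, list(c1 = c1, c2 = c2))
    }
  }
  if (is.null(best)) stop("piecewise-linear segmentation failed")

  # continuous changepoint refinement (motors start/stop between frames)
  obj <- function(p) {
    if (p[2] - p[1] < 1e-6) return(.Machine$double.xmax)
    f <- fit_pair(p[1], p[2])
    if (is.null(f)) .Machine$double.xmax else f$sse
  }
  t_all_min <- min(c(lead_t, t))
  opt <- tryCatch(
    suppressWarnings(
      stats::optim(c(best$c1, best$c2), obj, method = "L-BFGS-B",
                   lower = c(t_all_min - diff(range(t)) / m, t_all_min),
                   upper = c(max(t), max(t)))),
    error = function(e) NULL)
  c1 <- best$c1; c2 <- best$c2
  if (!is.null(opt) && opt$value <= best$sse) {
    c1 <- opt$par[1]; c2 <- opt$par[2]
  }
  f <- fit_pair(c1, c2)

  dt <- if (m > 1) min(diff(t)) else 1
  frame_dt <- min(diff(trace$time_s))
  censored <- c2 >= max(t) - dt / 2
  slope <- (f$b - f$a) / (c2 - c1)
  # rise not resolved by any detected sample: either the motor finished
  # within one frame interval (plateau far above the detection limit -> the
  # one-frame lower bound) or the plateau itself sits at the detection
  # limit, where fast and slow motors are indistinguishable (-> velocity
  # unmeasurable)
  slope_lower_bound <- FALSE
  slope_unresolved <- FALSE
  plateau_y <- y[t >= c2 - 1e-9]
  s_plateau <- if (length(plateau_y) >= 3) stats::sd(plateau_y) else
    sqrt(f$sse / max(1, m - 2))
  mid_rise_n <- sum(t <= c2 + 1e-9 & y < f$b - 2 * s_plateau)
  time_to_plateau <- c2 - max(c(lead_t, -Inf))
  if (length(lead_t) && time_to_plateau <= 2 * frame_dt &&
      (c2 <= t[1] + 1e-9 || mid_rise_n == 0)) {
    # no detected sample sits significantly below the plateau before it is
    # reached: the rise duration is not identifiable. The longest duration
    # consistent with the data -- last dark observation to plateau arrival
    # -- gives a lower bound on the velocity
    c1 <- c2 - time_to_plateau
    slope <- f$b / time_to_plateau
    slope_lower_bound <- TRUE
  }
  # a plateau within ~2x the detection limit never rises clear of the
  # detection flicker: any apparent rise is indistinguishable from noise
  # (only meaningful when the limit was computed from the fit amplitudes)
  if (dlim_physical && f$b <= 2 * detect_limit) {
    slope <- NA_real_
    slope_lower_bound <- FALSE
    slope_unresolved <- TRUE
  }
  rising <- which(trace$time_s >= c1 - 1e-9 & trace$time_s <= c2 + 1e-9 &
                    trace$converged)
  structure(list(
    start_frame = if (length(rising)) min(rising) else NA_integer_,
    end_frame = if (length(rising)) max(rising) else NA_integer_,
    start_s = c1, end_s = c2,
    slope_nt_s = slope,
    slope_lower_bound = slope_lower_bound,
    slope_unresolved = slope_unresolved,
    detect_limit_nt = detect_limit,
    level_start = unname(f$a), level_end = unname(f$b),
    censored = censored, sse = f$sse, n_used = m
  ), class = "active_phase")
}

#' Estimate motor velocity from a clearance trace
#'
#' The cleared region expands one-sidedly, so the front velocity equals the
#' FWHM growth rate: the least-squares slope of FWHM(nt) versus time over the
#' rising phase of the segmented trace. Negative estimates are clipped to 0
#' and flagged (`attr(, "clipped")`).
#'
#' @param trace A `clearance_trace`.
#' @param phase An `active_phase` from [segment_active_phase()]; computed if
#'   missing.
#' @return Velocity in nt/s.
#' @export
estimate_velocity <- function(trace, phase = segment_active_phase(trace)) {
  if (isTRUE(phase$slope_unresolved)) {
    out <- NA_real_
    attr(out, "clipped") <- FALSE
    attr(out, "lower_bound") <- FALSE
    attr(out, "unresolved") <- TRUE
    return(out)
  }
  v <- phase$slope_nt_s
  if (!is.finite(v)) stop("non-finite velocity slope; event dropped")
  out <- max(0, v)
  attr(out, "clipped") <- v < 0
  attr(out, "lower_bound") <- isTRUE(phase$slope_lower_bound)
  attr(out, "unresolved") <- FALSE
  out
}

#' Estimate motor processivity from a clearance trace
#'
#' Processivity is the total cleared extent: the mean FWHM (in nt) over the
#' terminal plateau of the segmented trace, reported in kilonucleotides. For
#' censored traces (motor still moving at the last frame) the last observed
#' FWHM is returned as a lower bound with `attr(, "censored") = TRUE`.
#'
#' @inheritParams estimate_velocity
#' @return Processivity in knt.
#' @export
estimate_processivity <- function(trace,
                                  phase = segment_active_phase(trace)) {
  ext <- trace_extent_nt(trace)
  ok <- trace$converged & is.finite(ext)
  if (phase$censored) {
    p <- ext[max(which(ok))]
  } else {
    plateau <- ok & trace$time_s >= phase$end_s - 1e-9
    p <- if (any(plateau)) mean(ext[plateau]) else phase$level_end
  }
  out <- max(0, p) / 1000
  attr(out, "censored") <- phase$censored
  out
}

#' Classify the polarity of a clearance event
#'
#' The ssDNA 5' end is at the barrier (low column index). A 3'->5' motor
#' expands the cleared region toward the barrier, so only the barrier-side
#' (left) edge of the region moves while the 3'-side (right) edge stays at
#' the initiation position. Edge positions per frame are taken from the
#' Heaviside fit when available, else derived as `center +/- extent/2` from
#' the Gaussian fit. The first converged frames of the rise are compared
#' with the terminal plateau frames: an edge "moves" when its displacement
#' exceeds twice its standard error (estimated from the plateau scatter).
#' Left-only movement is `"3to5"`, right-only is `"5to3"`, anything else --
#' both edges moving (symmetric clearance) or neither resolvable above
#' noise -- is `"ambiguous"`.
#'
#' @inheritParams estimate_velocity
#' @return One of `"3to5"`, `"5to3"`, `"ambiguous"`.
#' @export
classify_polarity <- function(trace, phase = segment_active_phase(trace)) {
  ok <- which(prune_onset_blips(trace$converged))
  # fits clamped at the diffraction floor localize a sub-resolution spot,
  # not two resolvable edges; they carry no polarity information
  if ("extent_px" %in% names(trace))
    ok <- ok[is.finite(trace$extent_px[ok]) & trace$extent_px[ok] > 0.75]
  if (length(ok) < 4) return("ambiguous")
  edges <- attr(trace, "edges_px")
  if (!is.null(edges) && any(is.finite(edges[ok, 1]))) {
    left <- edges[, 1]; right <- edges[, 2]
  } else {
    wpx <- if ("extent_px" %in% names(trace)) trace$extent_px else
      trace$fwhm_px
    left <- trace$center_px - wpx / 2
    right <- trace$center_px + wpx / 2
  }
  # early rise frames versus terminal plateau frames
  plateau <- ok[trace$time_s[ok] >= phase$end_s - 1e-9]
  early <- setdiff(ok, plateau)
  if (length(early) == 0) early <- ok[1]
  early <- utils::head(early, 2)
  if (length(plateau) < 2) plateau <- utils::tail(ok, 3)
  late <- utils::tail(plateau, 8)
  if (length(late) < 2 || length(intersect(early, late)))
    return("ambiguous")
  noise <- function(e) {
    s <- stats::sd(e[late])
    if (!is.finite(s) || s == 0) s <- 0.5
    s
  }
  se <- function(e) noise(e) * sqrt(1 / length(early) + 1 / length(late))
  d_left <- mean(left[late]) - mean(left[early])
  d_right <- mean(right[late]) - mean(right[early])
  left_moves <- d_left < -2 * se(left)
  right_moves <- d_right > 2 * se(right)
  tot <- abs(d_left) + abs(d_right)
  if (tot == 0) return("ambiguous")
  # the moving edge must also dominate the displacement: a statistically
  # significant but small counter-drift of the far edge is fit bias, not
  # bidirectional clearance
  if (left_moves && (!right_moves || abs(d_right) < 0.25 * tot)) "3to5"
  else if (right_moves && (!left_moves || abs(d_left) < 0.25 * tot)) "5to3"
  else "ambiguous"
}

#' Summarize one clearance trace as a motor event
#'
#' @inheritParams estimate_velocity
#' @param molecule_id Identifier copied to the output row.
#' @return One-row `data.frame`: `molecule_id`, `velocity_nt_s`,
#'   `processivity_knt`, `polarity`, `censored`, `usable`, `start_frame`,
#'   `end_frame`, `sse`.
#' @export
motor_event <- function(trace, molecule_id = attr(trace, "molecule_id")) {
  usable <- isTRUE(attr(trace, "usable"))
  if (!usable) {
    return(data.frame(molecule_id = molecule_id, velocity_nt_s = NA_real_,
                      processivity_knt = NA_real_, polarity = "ambiguous",
                      censored = NA, usable = FALSE,
                      start_frame = NA_integer_, end_frame = NA_integer_,
                      sse = NA_real_))
  }
  phase <- segment_active_phase(trace)
  v <- estimate_velocity(trace, phase)
  p <- estimate_processivity(trace, phase)
  data.frame(molecule_id = molecule_id,
             velocity_nt_s = as.numeric(v),
             processivity_knt = as.numeric(p),
             polarity = classify_polarity(trace, phase),
             censored = phase$censored, usable = TRUE,
             start_frame = phase$start_frame, end_frame = phase$end_frame,
             sse = phase$sse)
}

#' Median and interquartile range of a population statistic
#'
#' Quartiles use the linear-interpolation convention (R's default type 7).
#' Censored events are excluded from processivity summaries (an endpoint
#' quantity) but retained for velocity.
#'
#' @param events A motor-events `data.frame` (rows from [motor_event()]).
#' @param statistic `"velocity"` or `"processivity"`.
#' @param condition Optional label stored in the output.
#' @return One-row `data.frame`: `condition`, `statistic`, `median`, `q1`,
#'   `q3`, `n`, `units`.
#' @examples
#' ev <- data.frame(velocity_nt_s = 1:5, processivity_knt = 1:5,
#'                  censored = FALSE, usable = TRUE)
#' population_summary(ev, "velocity")
#' @export
population_summary <- function(events,
                               statistic = c("velocity", "processivity"),
                               condition = NA_character_) {
  statistic <- match.arg(statistic)
  ev <- events[!is.na(events$usable) & events$usable, , drop = FALSE]
  if (statistic == "processivity")
    ev <- ev[!is.na(ev$censored) & !ev$censored, , drop = FALSE]
  vals <- if (statistic == "velocity") ev$velocity_nt_s else
    ev$processivity_knt
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("no usable events for ", statistic, " summary")
  q <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(condition = condition, statistic = statistic,
             median = q[2], q1 = q[1], q3 = q[3], n = length(vals),
             units = if (statistic == "velocity") "nt/s" else "knt")
}

#' Run the clearance pipeline over a list of simulated or loaded stacks
#'
#' Convenience wrapper: builds one trace per stack (one molecule per stack),
#' converts each to a motor event, and binds the rows.
#'
#' @param stacks List of `kymo_stack` objects.
#' @param model Profile model passed to [build_trace()].
#' @return A motor-events `data.frame`, one row per molecule.
#' @export
clearance_events <- function(stacks, model = "gaussian") {
  rows <- lapply(seq_along(stacks), function(i) {
    tr <- build_trace(stacks[[i]], model = model)
    ev <- tryCatch(motor_event(tr, molecule_id = paste0("mol", i)),
                   error = function(e) NULL)
    if (is.null(ev))
      data.frame(molecule_id = paste0("mol", i), velocity_nt_s = NA_real_,
                 processivity_knt = NA_real_, polarity = "ambiguous",
                 censored = NA, usable = FALSE, start_frame = NA_integer_,
                 end_frame = NA_integer_, sse = NA_real_)
    else ev
  })
  do.call(rbind, rows)
}
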