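#' Link per-frame foci into trajectories
#'
#' Frame-to-frame linking by minimum-displacement assignment: candidate
#' links between consecutive occupied frames are sorted by distance and
#' accepted greedily, each focus participating in at most one link and links
#' longer than `max_disp_px` rejected. Because candidates are consumed in
#' global distance order, ambiguous pairs resolve to the lower-cost
#' assignment. Trajectories interrupted for up to `max_gap_frames` frames
#' are re-joined when a focus reappears within `max_disp_px * gap` of the
#' trajectory end. Unlinked foci become length-1 trajectories.
#'
#' @param foci A `data.frame` with columns `frame`, `position_px` (e.g. from
#'   [foci_time_series()]).
#' @param max_disp_px Maximum displacement per frame for a valid link.
#' @param max_gap_frames Maximum number of missed frames to bridge.
#' @return The input with an added `traj` column (integer trajectory id).
#' @examples
#' foci <- data.frame(frame = rep(1:5, each = 2),
#'                    position_px = c(rbind(10 + 1:5, 40)))
#' link_foci(foci, max_disp_px = 3)
#' @export
link_foci <- function(foci, max_disp_px = 5, max_gap_frames = 2) {
  n <- nrow(foci)
  traj <- rep(NA_integer_, n)
  if (n == 0) { foci$traj <- traj; return(foci) }
  ord <- order(foci$frame, foci$position_px)
  foci <- foci[ord, , drop = FALSE]
  next_id <- 0L
  # active trajectory ends: id, last frame, last position
  ends <- data.frame(id = integer(0), frame = integer(0), pos = numeric(0))
  for (f in sort(unique(foci$frame))) {
    idx <- which(foci$frame == f)
    ends <- ends[f - ends$frame <= max_gap_frames + 1L, , drop = FALSE]
    assigned <- rep(FALSE, length(idx))
    if (nrow(ends) > 0 && length(idx) > 0) {
      cand <- expand.grid(e = seq_len(nrow(ends)), i = seq_along(idx))
      cand$gap <- f - ends$frame[cand$e]
      cand$d <- abs(foci$position_px[idx[cand$i]] - ends$pos[cand$e])
      cand <- cand[cand$d <= max_disp_px * cand$gap, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_e <- logical(nrow(ends))
      for (k in seq_len(nrow(cand))) {
        e <- cand$e[k]; i <- cand$i[k]
        if (!used_e[e] && !assigned[i]) {
          traj[ord[idx[i]]] <- ends$id[e]
          ends$frame[e] <- f
          ends$pos[e] <- foci$position_px[idx[i]]
          used_e[e] <- TRUE
          assigned[i] <- TRUE
        }
      }
    }
    for (i in which(!assigned)) {
      next_id <- next_id + 1L
      traj[ord[idx[i]]] <- next_id
      ends <- rbind(ends, data.frame(id = next_id, frame = f,
                                     pos = foci$position_px[idx[i]]))
    }
  }
  foci_out <- foci[order(ord), , drop = FALSE]  # restore input order
  out <- foci
  out$traj <- traj[ord]
  out[order(out$traj, out$frame), , drop = FALSE]
}

#' Trajectory velocity from a position-time fit
#'
#' Least-squares slope of position versus time, converted to nt/s. The sign
#' convention follows the curtain geometry: negative velocity is motion
#' toward the 5' end (the barrier, lower column index).
#'
#' @param traj A `data.frame` with columns `frame` and `position_px` for one
#'   trajectory (>= 3 points).
#' @param nt_per_px Calibration, nucleotides per pixel.
#' @param frame_interval_s Seconds per frame.
#' @return Velocity in nt/s (signed); attribute `duration_s` and
#'   `displacement_nt`.
#' @examples
#' traj <- data.frame(frame = 1:6, position_px = 10 + 2 * (0:5))
#' trajectory_velocity(traj, nt_per_px = 500, frame_interval_s = 15) # 66.7
#' @export
trajectory_velocity <- function(traj, nt_per_px, frame_interval_s) {
  if (nrow(traj) < 3) stop("trajectory has fewer than 3 points")
  t <- traj$frame * frame_interval_s
  fit <- stats::lm(traj$position_px ~ t)
  v <- unname(stats::coef(fit)[2]) * nt_per_px
  attr(v, "duration_s") <- diff(range(t))
  attr(v, "displacement_nt") <-
    (traj$position_px[nrow(traj)] - traj$position_px[1]) * nt_per_px
  v
}

#' Velocities of all trajectories in a linked foci table
#'
#' @param linked Output of [link_foci()].
#' @inheritParams trajectory_velocity
#' @param min_points Trajectories with fewer points are excluded.
#' @return A `data.frame` with columns `traj`, `velocity_nt_s`,
#'   `duration_s`, `displacement_nt`, `n_points`.
#' @export
trajectory_velocities <- function(linked, nt_per_px, frame_interval_s,
                                  min_points = 3) {
  ids <- unique(linked$traj)
  rows <- lapply(ids, function(id) {
    tr <- linked[linked$traj == id, , drop = FALSE]
    if (nrow(tr) < min_points) return(NULL)
    v <- trajectory_velocity(tr, nt_per_px, frame_interval_s)
    data.frame(traj = id, velocity_nt_s = as.numeric(v),
               duration_s = attr(v, "duration_s"),
               displacement_nt = attr(v, "displacement_nt"),
               n_points = nrow(tr))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(traj = integer(0), velocity_nt_s = numeric(0),
                      duration_s = numeric(0), displacement_nt = numeric(0),
                      n_points = integer(0))
  out
}
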