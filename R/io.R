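#' Write a kymograph stack to multi-page TIFF plus sidecar metadata
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_green.tif`,
#' `<prefix>_magenta.tif`, page = frame), with intensities scaled by a
#' per-channel factor recorded in `<prefix>_meta.yaml` together with the
#' full simulation configuration, so reading is lossless to the 16-bit
#' quantization. The ground-truth motor table, when present, is written to
#' `<prefix>_truth.csv`.
#'
#' @param stack A `kymo_stack`.
#' @param prefix Output path prefix (directories must exist).
#' @return Invisibly, the paths written.
#' @export
write_kymograph_tiff <- function(stack, prefix) {
  paths <- character(0)
  meta <- list(channels = stack$channels,
               frame_interval_s = stack$frame_interval_s,
               nt_per_px = stack$nt_per_px,
               mode = stack$mode,
               scale = list())
  for (ch in stack$channels) {
    arr <- stack[[ch]]
    mx <- max(arr, 1e-9)
    meta$scale[[ch]] <- mx
    pages <- lapply(seq_len(dim(arr)[1]),
                    function(f) pmin(pmax(arr[f, , ] / mx, 0), 1))
    p <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, p, bits.per.sample = 16)
    paths <- c(paths, p)
  }
  cfg <- stack$config
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  mp <- paste0(prefix, "_meta.yaml")
  yaml::write_yaml(meta, mp)
  paths <- c(paths, mp)
  if (!is.null(stack$motors)) {
    tp <- paste0(prefix, "_truth.csv")
    utils::write.csv(as.data.frame(stack$motors), tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read a kymograph stack written by [write_kymograph_tiff()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `kymo_stack` (without ground truth unless the sidecar CSV is
#'   present).
#' @export
read_kymograph_tiff <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  out <- list(channels = unlist(meta$channels),
              frame_interval_s = meta$frame_interval_s,
              nt_per_px = meta$nt_per_px,
              mode = meta$mode)
  for (ch in out$channels) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    arr <- array(0, dim = c(length(pages), nrow(pages[[1]]),
                            ncol(pages[[1]])))
    for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * meta$scale[[ch]]
    out[[ch]] <- arr
  }
  if (!is.null(meta$config)) {
    cfg <- meta$config
    class(cfg) <- "sim_config"
    out$config <- cfg
  }
  tp <- paste0(prefix, "_truth.csv")
  if (file.exists(tp)) out$motors <- utils::read.csv(tp)
  class(out) <- "kymo_stack"
  out
}

#' Read molecule ROI annotations from CSV
#'
#' Expected columns: `molecule_id`, `row_center_px`, `barrier_px`,
#' `anchor_px`, optional `width_px` (default 3).
#'
#' @param path CSV path.
#' @return A list of [molecule_roi()] objects named by molecule id.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("molecule_id", "row_center_px", "barrier_px", "anchor_px")
  if (!all(need %in% names(df)))
    stop("ROI file must have columns: ", paste(need, collapse = ", "))
  if (!"width_px" %in% names(df)) df$width_px <- 3L
  rois <- lapply(seq_len(nrow(df)), function(i)
    molecule_roi(df$barrier_px[i], df$anchor_px[i], df$row_center_px[i],
                 df$width_px[i], molecule_id = df$molecule_id[i]))
  names(rois) <- df$molecule_id
  rois
}

#' Write a clearance trace to CSV
#' @param trace A `clearance_trace`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$molecule_id <- attr(trace, "molecule_id")
  utils::write.csv(
    df[, c("molecule_id", "frame", "time_s", "model", "center_px",
           "fwhm_px", "fwhm_nt", "r2", "converged")],
    path, row.names = FALSE)
  invisible(path)
}
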