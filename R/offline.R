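# Offline tracking: run the measurement pipeline and state machine over
# a pre-recorded image stack (no stage in the loop; the emitted commands
# are logged but drive nothing).

#' Track a target through a list of frames
#'
#' Applies [tracker_update()] to each frame in order: detection, ROI
#' propagation and loss handling behave exactly as in the closed loop,
#' but the camera geometry is whatever the recording had.
#'
#' @param frames List of [new_frame()] objects (e.g. from
#'   [read_frame_stack()]).
#' @param tracker A [tracker_config()].
#' @param start_mode `"TRACK"` or `"SEARCH"` (in offline use SEARCH just
#'   means "wait for the detection threshold").
#' @return `data.frame` with one row per frame: mode, COG, posture,
#'   area, threshold, ROI parameters and the (hypothetical) stage
#'   command.
#' @export
track_frames <- function(frames, tracker = tracker_config(),
                         start_mode = c("TRACK", "SEARCH")) {
  start_mode <- match.arg(start_mode)
  stopifnot(length(frames) > 0)
  cfg <- tracker
  cfg$sensor_px <- nrow(frames[[1]]$pixels)
  trk <- tracker_init(cfg, start_mode = start_mode)
  rows <- lapply(frames, function(fr) {
    upd <- tracker_update(trk, fr)
    tgt <- upd$target
    ru <- upd$roi_used
    data.frame(
      frame_index = fr$frame_index, t = fr$t, mode = upd$mode,
      area = upd$area,
      xg = if (is.null(tgt)) NA_real_ else tgt$xg,
      yg = if (is.null(tgt)) NA_real_ else tgt$yg,
      phi = if (is.null(tgt)) NA_real_ else tgt$phi,
      threshold = upd$threshold,
      roi_cx = if (is.null(ru)) NA_real_ else ru$cx,
      roi_cy = if (is.null(ru)) NA_real_ else ru$cy,
      roi_a = if (is.null(ru)) NA_real_ else ru$a,
      roi_b = if (is.null(ru)) NA_real_ else ru$b,
      roi_angle_deg = if (is.null(ru)) NA_real_ else ru$angle * 180 / pi,
      cmd_vx = if (is.null(upd$cmd_um_s)) NA_real_ else upd$cmd_um_s[1],
      cmd_vy = if (is.null(upd$cmd_um_s)) NA_real_ else upd$cmd_um_s[2])
  })
  do.call(rbind, rows)
}

#' Write a frame as a PNG or TIFF image
#'
#' @param frame A [new_frame()] object or intensity matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  px <- frame_pixels(frame) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}
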