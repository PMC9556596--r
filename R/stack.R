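#' Calibrated fluorescence time-lapse stack
#'
#' One or two channels of a time-lapse, each stored as a numeric array of
#' dimension `c(height, width, n_frames)` (rows = y downward, columns = x
#' rightward), with the physical calibration attached: pixel size in
#' micrometres and frame interval in seconds.
#'
#' @param channels named list of `H x W x T` numeric arrays (or `H x W`
#'   matrices for a single frame). All channels must share dimensions.
#' @param pixel_size_um pixel edge length in micrometres (> 0).
#' @param frame_interval_s time between frames in seconds (> 0).
#' @param background_subtracted logical flag, recorded once the background
#'   has been removed.
#' @return an object of class `timelapse_stack`.
#' @export
timelapse_stack <- function(channels, pixel_size_um, frame_interval_s,
                            background_subtracted = FALSE) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  if (!is.list(channels) || length(channels) < 1 || is.null(names(channels)))
    stop("'channels' must be a non-empty named list of arrays")
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    if (length(dim(a)) != 3) stop("each channel must be an H x W x T array")
    a
  })
  d0 <- dim(channels[[1]])
  for (a in channels)
    if (!all(dim(a) == d0)) stop("all channels must share dimensions")
  if (d0[3] < 1) stop("a stack needs at least one frame")
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 background_subtracted = isTRUE(background_subtracted)),
            class = "timelapse_stack")
}

#' @export
print.timelapse_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "timelapse_stack: %d x %d px, %d frame(s), channel(s): %s\n",
    d[2], d[1], d[3], paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  pixel %.3g um, interval %.3g s, background subtracted: %s\n",
              x$pixel_size_um, x$frame_interval_s, x$background_subtracted))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a [timelapse_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "timelapse_stack"))
  dim(stack$channels[[1]])[3]
}

#' Extract one frame of one channel
#' @param stack a [timelapse_stack()].
#' @param t frame index (1-based).
#' @param channel channel name or index (default first).
#' @return numeric matrix.
#' @export
get_frame <- function(stack, t, channel = 1) {
  stopifnot(inherits(stack, "timelapse_stack"))
  a <- stack$channels[[channel]]
  if (t < 1 || t > dim(a)[3]) stop("frame index out of range")
  a[, , t]
}
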