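# Frame container.  A frame is one grayscale image from the high-speed
# sensor together with its acquisition time, the physical pixel pitch at
# the current magnification, and a running frame index.
#
# Pixel coordinate convention (used throughout the package): 0-based,
# x = column index increasing rightward, y = row index increasing
# downward, origin at the top-left pixel centre.  A pixel at matrix
# position [i, j] therefore has coordinates (x, y) = (j - 1, i - 1).
# FOV-centred coordinates (the servo's "(0, 0) at image centre") are used
# only at the servo interface.

#' Construct a sensor frame
#'
#' @param pixels Numeric matrix of grayscale intensities in `[0, 255]`
#'   (rows = image y, columns = image x).
#' @param t Acquisition time in seconds.
#' @param pixel_pitch Physical pixel pitch in micrometres per pixel.
#' @param frame_index Non-negative integer frame counter.
#' @return An object of class `servo_frame`.
#' @examples
#' f <- new_frame(matrix(200, 32, 32), t = 0, pixel_pitch = 5.5)
#' dim(f$pixels)
#' @export
new_frame <- function(pixels, t = 0, pixel_pitch = 5.5, frame_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || any(dim(pixels) == 0L))
    stop("`pixels` must be a non-empty numeric matrix")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("`pixel_pitch` must be a single positive number")
  if (frame_index < 0) stop("`frame_index` must be >= 0")
  structure(
    list(pixels = pixels, t = as.numeric(t),
         pixel_pitch = as.numeric(pixel_pitch),
         frame_index = as.integer(frame_index)),
    class = "servo_frame"
  )
}

#' @export
print.servo_frame <- function(x, ...) {
  cat(sprintf("<servo_frame> %d x %d px, t = %.4f s, pitch = %.3f um/px, index = %d\n",
              nrow(x$pixels), ncol(x$pixels), x$t, x$pixel_pitch, x$frame_index))
  invisible(x)
}

# Coerce either a servo_frame or a bare matrix to a pixel matrix.
frame_pixels <- function(frame) {
  if (inherits(frame, "servo_frame")) frame$pixels
  else if (is.matrix(frame)) frame
  else stop("expected a `servo_frame` or a numeric matrix")
}

#' Read a grayscale image as a frame
#'
#' Reads an 8-bit grayscale PNG or TIFF image (colour images are averaged
#' over channels) and rescales intensities to `[0, 255]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams new_frame
#' @return A [new_frame()] object.
#' @export
read_frame <- function(path, t = 0, pixel_pitch = 5.5, frame_index = 0L) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  new_frame(round(img * 255), t = t, pixel_pitch = pixel_pitch,
            frame_index = frame_index)
}

#' Read an image stack as a list of frames
#'
#' @param paths Character vector of image paths, in temporal order.
#' @param fps Frame rate used to assign timestamps.
#' @param pixel_pitch Pixel pitch in micrometres per pixel.
#' @return List of `servo_frame` objects with consecutive frame indices.
#' @export
read_frame_stack <- function(paths, fps = 500, pixel_pitch = 5.5) {
  lapply(seq_along(paths), function(k) {
    read_frame(paths[[k]], t = (k - 1) / fps, pixel_pitch = pixel_pitch,
               frame_index = k - 1L)
  })
}

#' Write a binary mask as a PNG image
#'
#' Foreground pixels are written white on black background.
#'
#' @param mask Binary mask matrix (values in `{0, 1}`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
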