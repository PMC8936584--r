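# Frame preprocessing: bicubic resize to the square working resolution and
# intensity normalization.

#' Working-resolution echo frame
#'
#' @param values `[H,W,C]` array with intensities in \[0,1\].
#' @param spacing Optional mm-per-pixel.
#' @return An object of class `echo_image`.
#' @export
echo_image <- function(values, spacing = NULL) {
  v <- as_hwc(values)
  structure(list(values = v, spacing = spacing), class = "echo_image")
}

#' @export
print.echo_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<echo_image> %dx%d, %d channel(s), range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' Preprocess a raw frame to the working resolution
#'
#' Bicubic (Catmull-Rom) resize to `target_size x target_size` and intensity
#' scaling to \[0,1\] (8-bit inputs are divided by 255; interpolation
#' overshoot is clipped).
#'
#' @param raw_image `[H,W]` matrix or `[H,W,C]` array, at least 8x8.
#' @param target_size Output side length.
#' @return An [echo_image].
#' @export
preprocess <- function(raw_image, target_size = 512L) {
  x <- as_hwc(raw_image)
  d <- dim(x)
  if (d[1] < 8 || d[2] < 8 || length(x) == 0)
    stop("preprocess: image must be at least 8x8")
  if (max(x) > 1) x <- x / 255
  out <- if (d[1] == target_size && d[2] == target_size) x
  else cpp_resize_bicubic(x, d[1], d[2], d[3], target_size, target_size)
  echo_image(pmin(pmax(out, 0), 1))
}
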