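# Frame streams: lazy, uniform access to an image sequence. Frames are
# numeric matrices [height x width] with intensities on [0, 255]; streams
# are addressed by 0-based frame index. A stream never holds the whole
# stack in memory, so multi-minute 60 Hz recordings run on a desktop.

#' Open a frame stream
#'
#' @param x A directory containing a numbered PNG image sequence, or a
#'   synthetic scene from [synth_scene()] (rendered on demand).
#' @param fps Frames per second (default 60).
#' @param ... Unused.
#' @return An object of class `mt_frames` with fields `n_frames`, `width`,
#'   `height`, `fps` and `get_frame(i)` (0-based).
#' @export
frame_stream <- function(x, ...) UseMethod("frame_stream")

#' @rdname frame_stream
#' @export
frame_stream.character <- function(x, fps = 60, ...) {
  if (!dir.exists(x)) stop("frame_stream: no such directory: ", x)
  files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("frame_stream: no PNG frames in ", x)
  first <- read_frame_png(files[1])
  structure(
    list(
      n_frames = length(files),
      width = ncol(first), height = nrow(first), fps = fps,
      get_frame = function(i) {
        stopifnot(i >= 0, i < length(files))
        read_frame_png(files[i + 1L])
      },
      source = x
    ),
    class = "mt_frames"
  )
}

#' @export
print.mt_frames <- function(x, ...) {
  cat(sprintf("Frame stream: %d frames, %dx%d px @ %g fps\n",
              x$n_frames, x$width, x$height, x$fps))
  invisible(x)
}

#' Read one frame from a PNG file
#'
#' RGB images are converted to grayscale with luma weights
#' 0.299/0.587/0.114; intensities are rescaled to `[0, 255]`.
#'
#' @param path PNG file path.
#' @return Numeric matrix `[height x width]` on `[0, 255]`.
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  to_gray255(img)
}

# Accept [h x w], [h x w x 1..4]; values on [0,1] (PNG) or [0,255].
to_gray255 <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  if (max(img) <= 1) img <- img * 255
  img
}

#' Write a frame stream to numbered PNG files
#'
#' @param stream An `mt_frames` stream (or a [synth_scene()], coerced).
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_frames_png <- function(stream, dir) {
  if (inherits(stream, "mt_scene")) stream <- frame_stream(stream)
  stopifnot(inherits(stream, "mt_frames"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(stream$n_frames) - 1L) {
    m <- stream$get_frame(i)
    png::writePNG(m / 255, file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}
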