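#' Arena calibration
#'
#' A single isotropic pixel-to-centimetre scale derived from the side length
#' of the square arena, assuming an overhead, distortion-free camera. The
#' default arena is 32 cm on a side.
#'
#' @param arena_px Arena side length in pixels.
#' @param arena_cm Arena side length in centimetres (default 32).
#' @return An object of class `mt_calibration` with fields `arena_cm`,
#'   `arena_px` and `px_per_cm`.
#' @examples
#' cal <- calibration(arena_px = 640)
#' px_to_cm(320, cal) # 16 cm
#' @export
calibration <- function(arena_px, arena_cm = 32) {
  stopifnot(is.numeric(arena_px), length(arena_px) == 1L, is.finite(arena_px),
            is.numeric(arena_cm), length(arena_cm) == 1L, is.finite(arena_cm))
  if (arena_px <= 0) stop("arena_px must be > 0")
  if (arena_cm <= 0) stop("arena_cm must be > 0")
  structure(
    list(arena_cm = arena_cm, arena_px = arena_px,
         px_per_cm = arena_px / arena_cm),
    class = "mt_calibration"
  )
}

#' @rdname calibration
#' @param px,cm Numeric vectors of lengths in pixels / centimetres.
#' @param cal An `mt_calibration` object.
#' @export
px_to_cm <- function(px, cal) {
  stopifnot(inherits(cal, "mt_calibration"))
  px / cal$px_per_cm
}

#' @rdname calibration
#' @export
cm_to_px <- function(cm, cal) {
  stopifnot(inherits(cal, "mt_calibration"))
  cm * cal$px_per_cm
}

#' @export
print.mt_calibration <- function(x, ...) {
  cat(sprintf("Arena calibration: %g cm = %g px  (%.4f px/cm)\n",
              x$arena_cm, x$arena_px, x$px_per_cm))
  invisible(x)
}
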