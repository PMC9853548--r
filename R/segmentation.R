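# Classical instance segmentation: threshold the (dark-on-bright) frame,
# label 8-connected foreground components, filter by area. This is the
# bundled detector; any callable frame -> list of mask regions can stand in
# for it (e.g. polygons from an external neural detector via VIA JSON).

#' Segmentation parameters
#'
#' @param threshold_mode `"fixed"` or `"otsu"`. Animals are assumed darker
#'   than the background; foreground is `intensity < threshold`.
#' @param threshold Intensity cut on `[0, 255]` for `"fixed"` mode.
#' @param min_area_px,max_area_px Area filter for connected components.
#' @param expand_px Contour expansion radius in pixels (default 5).
#' @param rdp_epsilon Polygon simplification tolerance in pixels
#'   (default 1.5).
#' @return An object of class `mt_seg_params`.
#' @export
segmentation_params <- function(threshold_mode = c("fixed", "otsu"),
                                threshold = 160,
                                min_area_px = 500, max_area_px = Inf,
                                expand_px = 5, rdp_epsilon = 1.5) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(min_area_px >= 0, min_area_px < max_area_px,
            expand_px >= 0, rdp_epsilon >= 0)
  structure(list(threshold_mode = threshold_mode, threshold = threshold,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 expand_px = expand_px, rdp_epsilon = rdp_epsilon),
            class = "mt_seg_params")
}

# A detection: bbox-local logical mask + 0-based offset of the bbox's
# top-left pixel, area, centroid (0-based float px), outer-boundary polygon.
mask_region <- function(mask, offset, frame_dim, frame_index = NA_integer_) {
  stopifnot(is.logical(mask), length(offset) == 2L)
  area <- sum(mask)
  if (area == 0L) stop("mask_region: empty mask")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(
    x = mean(idx[, 2] - 1) + offset[1],
    y = mean(idx[, 1] - 1) + offset[2]
  )
  structure(
    list(frame_index = frame_index, mask = mask,
         offset = as.numeric(offset), frame_dim = frame_dim,
         area_px = area, centroid = centroid,
         contour = trace_contour(mask, offset)),
    class = "mt_region"
  )
}

#' @export
print.mt_region <- function(x, ...) {
  cat(sprintf(
    "Mask region: frame %s, area %d px, centroid (%.1f, %.1f), %d contour vertices\n",
    x$frame_index, x$area_px, x$centroid[1], x$centroid[2], nrow(x$contour)))
  invisible(x)
}

# Outer boundary of a bbox-local mask as an ordered polygon in 0-based
# frame coordinates, consecutive duplicates removed.
trace_contour <- function(mask, offset) {
  oc <- EBImage::ocontour(label8(mask))[[1]]
  # ocontour returns 0-based (first-index, second-index) = (y, x) local
  poly <- cbind(x = oc[, 2] + offset[1], y = oc[, 1] + offset[2])
  if (nrow(poly) > 1) {
    dup <- c(FALSE, rowSums(abs(diff(poly))) == 0)
    poly <- poly[!dup, , drop = FALSE]
  }
  poly
}

#' Segment one frame into animal mask regions
#'
#' Thresholds the frame (foreground = darker than the cut), labels
#' 8-connected components, filters them to `[min_area_px, max_area_px]` and
#' returns them in descending area order. Deterministic given
#' `(image, params)`; an empty list is a valid result.
#'
#' @param image Numeric matrix `[height x width]` on `[0, 255]` (an RGB
#'   array is converted to grayscale first).
#' @param params [segmentation_params()].
#' @param frame_index Optional 0-based frame index stamped on the regions.
#' @return List of `mt_region` detections, largest first.
#' @export
segment_frame <- function(image, params = segmentation_params(),
                          frame_index = NA_integer_) {
  image <- to_gray255(image)
  thr <- if (params$threshold_mode == "otsu") {
    255 * EBImage::otsu(EBImage::Image(image / 255), range = c(0, 1))
  } else {
    params$threshold
  }
  fg <- image < thr
  if (!any(fg)) return(list())
  lab <- label8(fg)
  n <- max(lab)
  regions <- list()
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx)
    if (area < params$min_area_px || area > params$max_area_px) next
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    local <- lab[r0:r1, c0:c1, drop = FALSE] == l
    regions[[length(regions) + 1L]] <- mask_region(
      local, offset = c(c0 - 1, r0 - 1),
      frame_dim = dim(image), frame_index = frame_index
    )
  }
  if (!length(regions)) return(list())
  regions[order(-vapply(regions, function(r) r$area_px, numeric(1)))]
}

#' Expand a detection's contour by disk dilation
#'
#' Dilates the region's mask with a disk of radius `expand_px` (clipped to
#' the frame bounds) and re-extracts area, centroid and boundary polygon.
#' With `expand_px = 0` the region is returned unchanged.
#'
#' @param region An `mt_region` from [segment_frame()].
#' @param expand_px Dilation radius in pixels (default 5).
#' @return The expanded `mt_region`.
#' @export
expand_contour <- function(region, expand_px = 5) {
  stopifnot(inherits(region, "mt_region"), expand_px >= 0)
  r <- as.integer(round(expand_px))
  if (r == 0L) return(region)
  fd <- region$frame_dim # c(nrow, ncol)
  # grow the working window by r, clipped to the frame
  x0 <- max(0, region$offset[1] - r)
  y0 <- max(0, region$offset[2] - r)
  x1 <- min(fd[2] - 1, region$offset[1] + ncol(region$mask) - 1 + r)
  y1 <- min(fd[1] - 1, region$offset[2] + nrow(region$mask) - 1 + r)
  win <- matrix(FALSE, y1 - y0 + 1, x1 - x0 + 1)
  ry <- (region$offset[2] - y0) + seq_len(nrow(region$mask))
  rx <- (region$offset[1] - x0) + seq_len(ncol(region$mask))
  win[ry, rx] <- region$mask
  dil <- binary_dilate(win, disk_kernel(r))
  mask_region(dil, offset = c(x0, y0), frame_dim = fd,
              frame_index = region$frame_index)
}

# Rasterize a polygon (0-based float vertices) to a frame-sized logical
# mask by even-odd scanline filling at pixel centres; used to turn VIA
# polygons into detections.
polygon_to_mask <- function(poly, width, height) {
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  mask <- matrix(FALSE, height, width)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  jj <- c(n, seq_len(n - 1L))
  y_range <- max(0L, floor(min(ys))):min(height - 1L, ceiling(max(ys)))
  for (yc in y_range) {
    crosses <- (ys > yc) != (ys[jj] > yc)
    if (!any(crosses)) next
    xi <- xs[crosses] + (yc - ys[crosses]) *
      (xs[jj][crosses] - xs[crosses]) / (ys[jj][crosses] - ys[crosses])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      a <- max(0L, ceiling(xi[k])); b <- min(width - 1L, floor(xi[k + 1]))
      if (a <= b) mask[yc + 1L, (a:b) + 1L] <- TRUE
    }
  }
  mask
}

#' Turn VIA polygon annotations into a detector
#'
#' Returns a detector function `(image, frame_index) -> list of mt_region`
#' that ignores the image and rasterizes the annotated polygons of the
#' matching frame, so externally computed masks (e.g. from a neural
#' detector) can drive the tracker in place of [segment_frame()].
#'
#' @param annotations An `mt_via` list from [read_via_annotations()]; frames
#'   are taken in file order and matched to stream frames 0, 1, ....
#' @param width,height Frame size in pixels.
#' @return A detector closure.
#' @export
via_detector <- function(annotations, width, height) {
  force(annotations)
  function(image, frame_index = NA_integer_) {
    if (is.na(frame_index) || frame_index + 1L > length(annotations))
      return(list())
    fr <- annotations[[frame_index + 1L]]
    regions <- lapply(fr$polygons, function(poly) {
      full <- polygon_to_mask(poly, width, height)
      if (!any(full)) return(NULL)
      idx <- which(full, arr.ind = TRUE)
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      mask_region(full[r0:r1, c0:c1, drop = FALSE], offset = c(c0 - 1, r0 - 1),
                  frame_dim = c(height, width), frame_index = frame_index)
    })
    regions <- Filter(Negate(is.null), regions)
    regions[order(-vapply(regions, function(r) r$area_px, numeric(1)))]
  }
}
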