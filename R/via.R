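# VGG Image Annotator (VIA 2.x) JSON import/export. Both export dialects are
# accepted: the bare image-map {"img.png-123": {filename, regions, ...}, ...}
# and the full project file with regions nested under "_via_img_metadata".

#' Read polygon annotations from a VIA 2.x JSON export
#'
#' Each image entry becomes one annotated frame holding its polygon regions
#' in file order. Regions whose `shape_attributes$name` is not `"polygon"`
#' (rectangles, circles, ...) are skipped; the skip count is attached as the
#' `skipped` attribute and reported via [message()].
#'
#' @param path Path to a VIA JSON file (bare image-map or full project).
#' @param quiet Suppress the skipped-region message.
#' @return A list of class `mt_via`; each element has fields `filename`,
#'   `polygons` (list of n x 2 numeric matrices, columns x and y in pixels)
#'   and `attributes` (region attributes, one per polygon). Attribute
#'   `skipped` counts non-polygon regions dropped.
#' @export
read_via_annotations <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("VIA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(doc[["_via_img_metadata"]])) {
    imgs <- doc[["_via_img_metadata"]]
  } else {
    imgs <- doc[!startsWith(names(doc), "_via_")]
  }
  skipped <- 0L
  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    key <- names(imgs)[i]
    entry <- imgs[[i]]
    fname <- entry$filename
    if (is.null(fname))
      stop("VIA parse error: image entry '", key, "' has no filename")
    polys <- list()
    attrs <- list()
    for (j in seq_along(entry$regions)) {
      reg <- entry$regions[[j]]
      sh <- reg$shape_attributes
      if (is.null(sh) || is.null(sh$name))
        stop("VIA parse error: image '", key, "' region ", j,
             " has no shape_attributes$name")
      if (!identical(sh$name, "polygon")) {
        skipped <- skipped + 1L
        next
      }
      xs <- unlist(sh$all_points_x, use.names = FALSE)
      ys <- unlist(sh$all_points_y, use.names = FALSE)
      if (is.null(xs) || is.null(ys) || length(xs) != length(ys))
        stop("VIA parse error: image '", key, "' region ", j,
             " has malformed all_points_x/all_points_y")
      if (length(xs) < 3L)
        stop("invalid polygon: image '", key, "' region ", j,
             " has fewer than 3 vertices")
      polys[[length(polys) + 1L]] <- cbind(x = as.numeric(xs),
                                           y = as.numeric(ys))
      ra <- reg$region_attributes
      attrs[[length(polys)]] <- if (is.null(ra)) list() else ra
    }
    out[[i]] <- list(filename = fname, polygons = polys, attributes = attrs)
  }
  if (skipped > 0L && !quiet)
    message("read_via_annotations: skipped ", skipped, " non-polygon region",
            if (skipped > 1L) "s")
  structure(out, skipped = skipped, class = "mt_via")
}

#' Write polygon annotations as a VIA 2.x image-map JSON
#'
#' The inverse of [read_via_annotations()] for polygon regions: writing and
#' re-reading reproduces the vertex arrays exactly.
#'
#' @param frames A list as returned by [read_via_annotations()], or any list
#'   of elements with `filename` and `polygons` fields.
#' @param path Output path.
#' @export
write_via_annotations <- function(frames, path) {
  out <- list()
  for (fr in frames) {
    regions <- lapply(seq_along(fr$polygons), function(j) {
      poly <- fr$polygons[[j]]
      ra <- if (!is.null(fr$attributes) && length(fr$attributes) >= j)
        fr$attributes[[j]] else list()
      list(
        shape_attributes = list(
          name = "polygon",
          all_points_x = as.numeric(poly[, 1]),
          all_points_y = as.numeric(poly[, 2])
        ),
        region_attributes = ra
      )
    })
    key <- paste0(fr$filename, "-1")
    out[[key]] <- list(filename = fr$filename, size = -1L, regions = regions)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
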