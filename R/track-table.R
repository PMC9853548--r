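# The track table: one row per (frame, animal id) with the detection's
# geometric centre and area, plus `filled` (miss filled by carry-forward)
# and `warned` (tracking warning) flags. This is the pipeline's central
# artifact, written/read as plain CSV with both pixel and cm coordinates.

mt_track_cols <- c("frame", "id", "cx_px", "cy_px", "area_px",
                   "filled", "warned")

#' Construct a track table
#'
#' @param df A data.frame with columns `frame`, `id`, `cx_px`, `cy_px`,
#'   `area_px`, `filled`, `warned` (the flag columns may be omitted and
#'   default to 0).
#' @param n_mice Number of animals tracked (ids are `0..n_mice-1`).
#' @param calibration Optional [calibration()] attached for unit conversion.
#' @return A data.frame of class `mt_tracks`, sorted by (frame, id), with
#'   attributes `n_mice` and `calibration`.
#' @export
track_table <- function(df, n_mice, calibration = NULL) {
  if (!"filled" %in% names(df)) df$filled <- 0L
  if (!"warned" %in% names(df)) df$warned <- 0L
  missing_cols <- setdiff(mt_track_cols, names(df))
  if (length(missing_cols))
    stop("track table missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[mt_track_cols]
  n_mice <- as.integer(n_mice)
  if (nrow(df)) {
    if (any(df$id < 0 | df$id >= n_mice))
      stop("track table contains ids outside 0..", n_mice - 1L)
    if (anyDuplicated(df[c("frame", "id")]))
      stop("track table contains duplicate (frame, id) rows")
    df <- df[order(df$frame, df$id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$frame <- as.integer(df$frame)
  df$id <- as.integer(df$id)
  df$filled <- as.integer(df$filled)
  df$warned <- as.integer(df$warned)
  structure(df, n_mice = n_mice, calibration = calibration,
            class = c("mt_tracks", "data.frame"))
}

#' @export
print.mt_tracks <- function(x, ...) {
  fr <- if (nrow(x)) range(x$frame) else c(NA, NA)
  cat(sprintf(
    "Track table: %d records, %d animal(s), frames %s..%s, %d filled, %d warned\n",
    nrow(x), attr(x, "n_mice"), fr[1], fr[2], sum(x$filled), sum(x$warned)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Plot animal trajectories
#'
#' Draws each animal's centroid path in arena pixel coordinates, y axis
#' downward to match the image frame.
#'
#' @param x An `mt_tracks` table.
#' @param ... Passed to [plot()].
#' @export
plot.mt_tracks <- function(x, ...) {
  n <- attr(x, "n_mice")
  cols <- hcl.colors(max(n, 2L), "Dark 2")
  plot(NA, xlim = range(x$cx_px), ylim = rev(range(x$cy_px)),
       xlab = "x (px)", ylab = "y (px)", asp = 1, ...)
  for (i in seq_len(n) - 1L) {
    sub <- x[x$id == i, ]
    lines(sub$cx_px, sub$cy_px, col = cols[i + 1L])
  }
  legend("topright", legend = paste0("#", seq_len(n) - 1L),
         col = cols[seq_len(n)], lty = 1, bty = "n")
  invisible(x)
}

#' Write / read a track table as CSV
#'
#' Columns: `frame,id,cx_px,cy_px,cx_cm,cy_cm,area_px,filled,warned`, rows
#' sorted by (frame, id); the cm columns are derived from the calibration;
#' flags are serialized as 0/1.
#'
#' @param table An `mt_tracks` table.
#' @param calibration A [calibration()] object (defaults to the one attached
#'   to the table).
#' @param path Output / input CSV path.
#' @export
write_track_csv <- function(table, calibration = attr(table, "calibration"),
                            path) {
  stopifnot(inherits(table, "mt_tracks"))
  if (is.null(calibration))
    stop("write_track_csv: no calibration supplied or attached")
  out <- data.frame(
    frame = table$frame, id = table$id,
    cx_px = table$cx_px, cy_px = table$cy_px,
    cx_cm = px_to_cm(table$cx_px, calibration),
    cy_cm = px_to_cm(table$cy_px, calibration),
    area_px = table$area_px,
    filled = as.integer(table$filled), warned = as.integer(table$warned)
  )
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("write_track_csv: cannot write '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

#' @rdname write_track_csv
#' @param n_mice Number of animals; inferred as `max(id) + 1` when missing.
#' @export
read_track_csv <- function(path, n_mice = NULL, calibration = NULL) {
  df <- read.csv(path)
  need <- c("frame", "id", "cx_px", "cy_px", "area_px", "filled", "warned")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("track CSV missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(n_mice)) n_mice <- max(df$id) + 1L
  if (is.null(calibration) && all(c("cx_cm", "cx_px") %in% names(df))) {
    nz <- which(df$cx_cm != 0)[1]
    if (!is.na(nz)) {
      ppc <- df$cx_px[nz] / df$cx_cm[nz]
      calibration <- calibration(arena_px = 32 * ppc, arena_cm = 32)
    }
  }
  track_table(df[need], n_mice = n_mice, calibration = calibration)
}

#' Read / write tracking warnings and swap directives
#'
#' Warnings CSV columns: `frame,id,dist_same,dist_min,other_id` (distances
#' in pixels). Swaps CSV columns: `frame,id_a,id_b` — each directive
#' exchanges the two id labels from `frame` to the end of the table.
#'
#' @param warnings,swaps Data frames with the columns above.
#' @param path CSV path.
#' @export
write_warnings_csv <- function(warnings, path) {
  need <- c("frame", "id", "dist_same", "dist_min", "other_id")
  stopifnot(all(need %in% names(warnings)))
  write.csv(warnings[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_warnings_csv
#' @export
read_swaps_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "id_a", "id_b")
  if (!all(need %in% names(df)))
    stop("swaps CSV must have columns frame,id_a,id_b")
  df[need]
}

#' @rdname write_warnings_csv
#' @export
write_swaps_csv <- function(swaps, path) {
  need <- c("frame", "id_a", "id_b")
  stopifnot(all(need %in% names(swaps)))
  write.csv(swaps[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
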