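# Semi-automated correction: sporadic detection misses are filled by
# carrying the last known record forward; candidate identity switches are
# flagged as advisory "tracking warnings" (never auto-applied); confirmed
# irreversible switches are repaired by human swap directives that
# exchange two id labels from a frame to the end of the table.

#' Fill sporadic misses by carry-forward
#'
#' For every frame after the initialization frame where an ID has no
#' record, a record is copied from that ID's most recent record (centroid
#' and area held constant) with `filled = 1`. Gaps longer than `max_gap`
#' frames are structural rather than sporadic: they are left unfilled and
#' reported in the `unfilled_gaps` attribute.
#'
#' @param table An uncorrected `mt_tracks` table.
#' @param max_gap Longest gap (frames) that is still filled (default 60,
#'   i.e. 1 s at 60 Hz).
#' @return The filled `mt_tracks` table; attribute `unfilled_gaps` is a
#'   data.frame `id,start,end,length` of gaps left open.
#' @export
fill_misses <- function(table, max_gap = 60) {
  stopifnot(inherits(table, "mt_tracks"))
  n <- attr(table, "n_mice")
  frames <- min(table$frame):max(table$frame)
  add <- list()
  unfilled <- list()
  for (i in seq_len(n) - 1L) {
    sub <- table[table$id == i, ]
    present <- sub$frame
    missing <- setdiff(frames, present)
    if (!length(missing)) next
    # split missing frames into consecutive runs
    runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
    for (run in runs) {
      if (length(run) > max_gap) {
        unfilled[[length(unfilled) + 1L]] <- data.frame(
          id = i, start = run[1], end = run[length(run)],
          length = length(run))
        next
      }
      prev <- sub[sub$frame < run[1], ]
      if (!nrow(prev)) next  # no record to carry forward (before init)
      src <- prev[nrow(prev), ]
      add[[length(add) + 1L]] <- data.frame(
        frame = run, id = i, cx_px = src$cx_px, cy_px = src$cy_px,
        area_px = src$area_px, filled = 1L, warned = 0L)
    }
  }
  out <- table
  if (length(add)) {
    df <- rbind(as.data.frame(table), do.call(rbind, add))
    out <- track_table(df, n_mice = n,
                       calibration = attr(table, "calibration"))
    attr(out, "init_frame") <- attr(table, "init_frame")
  }
  attr(out, "unfilled_gaps") <- if (length(unfilled))
    do.call(rbind, unfilled)
  else data.frame(id = integer(), start = integer(), end = integer(),
                  length = integer())
  out
}

#' Detect tracking warnings (candidate identity switches)
#'
#' For each consecutive frame pair (N, N+1) and each ID i, the Euclidean
#' distance from i's centroid at N to every ID's centroid at N+1 is
#' computed; a warning is emitted iff some other ID's new position is
#' strictly closer to i's old position than i's own new position.
#' Warnings are advisory: they mark candidate irreversible ID switches for
#' human review and never modify the table.
#'
#' @param table A miss-filled `mt_tracks` table (run [fill_misses()]
#'   first); every frame in range must have all `n_mice` records.
#' @return A data.frame `frame,id,dist_same,dist_min,other_id` (distances
#'   in pixels, `frame` is N+1), sorted by frame then ID.
#' @export
detect_warnings <- function(table) {
  stopifnot(inherits(table, "mt_tracks"))
  n <- attr(table, "n_mice")
  frames <- sort(unique(table$frame))
  counts <- table(factor(table$frame, levels = frames))
  if (any(counts != n))
    stop("detect_warnings: table has frames without all ", n,
         " records; run fill_misses() first")
  if (n < 2L || length(frames) < 2L)
    return(data.frame(frame = integer(), id = integer(),
                      dist_same = numeric(), dist_min = numeric(),
                      other_id = integer()))
  tab <- table[order(table$frame, table$id), ]
  xs <- matrix(tab$cx_px, nrow = n)  # [id, frame]
  ys <- matrix(tab$cy_px, nrow = n)
  out <- list()
  for (t in seq_len(length(frames) - 1L)) {
    dx <- outer(xs[, t], xs[, t + 1L], "-")
    dy <- outer(ys[, t], ys[, t + 1L], "-")
    D <- sqrt(dx * dx + dy * dy)
    for (i in seq_len(n)) {
      others <- D[i, -i]
      mo <- which.min(others)
      if (others[mo] < D[i, i]) {
        other <- (seq_len(n)[-i])[mo]
        out[[length(out) + 1L]] <- data.frame(
          frame = frames[t + 1L], id = i - 1L,
          dist_same = D[i, i], dist_min = others[mo],
          other_id = other - 1L)
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), id = integer(),
                      dist_same = numeric(), dist_min = numeric(),
                      other_id = integer()))
  res <- do.call(rbind, out)
  res[order(res$frame, res$id), , drop = FALSE]
}

# Set warned = 1 on the records named by a warnings data.frame.
flag_warnings <- function(table, warnings) {
  if (!nrow(warnings)) return(table)
  key <- paste(table$frame, table$id)
  wkey <- paste(warnings$frame, warnings$id)
  table$warned <- as.integer(table$warned | key %in% wkey)
  table
}

#' Apply human swap directives to repair irreversible ID switches
#'
#' Each directive `(from_frame, id_a, id_b)` exchanges the two id labels on
#' every record from `from_frame` to the final frame (the
#' irreversible-switch semantics); all other fields are untouched.
#' Invalid directives (unknown ID, out-of-range frame, `id_a == id_b`) are
#' skipped with their messages collected in the `swap_errors` attribute;
#' the remaining directives are still applied.
#'
#' @param table An `mt_tracks` table.
#' @param directives A data.frame `frame,id_a,id_b` (see
#'   [read_swaps_csv()]), applied in frame order.
#' @return The corrected `mt_tracks` table; attribute `swap_errors` holds
#'   the messages of rejected directives (empty character vector if none).
#' @export
apply_swaps <- function(table, directives) {
  stopifnot(inherits(table, "mt_tracks"))
  n <- attr(table, "n_mice")
  fr <- range(table$frame)
  errors <- character()
  if (nrow(directives)) {
    directives <- directives[order(directives$frame), , drop = FALSE]
    for (r in seq_len(nrow(directives))) {
      f <- directives$frame[r]
      a <- directives$id_a[r]; b <- directives$id_b[r]
      if (a == b) {
        errors <- c(errors, sprintf("directive %d: id_a == id_b (%d)", r, a))
        next
      }
      if (a < 0 || a >= n || b < 0 || b >= n) {
        errors <- c(errors, sprintf(
          "directive %d: unknown id (%d, %d) for n_mice = %d", r, a, b, n))
        next
      }
      if (f < fr[1] || f > fr[2]) {
        errors <- c(errors, sprintf(
          "directive %d: frame %d outside table range %d..%d",
          r, f, fr[1], fr[2]))
        next
      }
      sel <- table$frame >= f
      ia <- sel & table$id == a
      ib <- sel & table$id == b
      table$id[ia] <- b
      table$id[ib] <- a
    }
  }
  out <- track_table(as.data.frame(table), n_mice = n,
                     calibration = attr(table, "calibration"))
  attr(out, "init_frame") <- attr(table, "init_frame")
  attr(out, "swap_errors") <- errors
  out
}

#' Run the full correction stage
#'
#' Convenience wrapper: [fill_misses()], then [detect_warnings()] and
#' warning flagging, then [apply_swaps()] (if any directives), then a
#' final [detect_warnings()] pass on the corrected table.
#'
#' @inheritParams fill_misses
#' @param swaps Optional swap-directive data.frame.
#' @return List with `table` (corrected `mt_tracks`), `warnings`
#'   (pre-swap), `warnings_after` (post-swap), `unfilled_gaps`,
#'   `swap_errors`.
#' @export
correct_tracks <- function(table, max_gap = 60, swaps = NULL) {
  filled <- fill_misses(table, max_gap = max_gap)
  gaps <- attr(filled, "unfilled_gaps")
  warnings <- detect_warnings(filled)
  filled <- flag_warnings(filled, warnings)
  swap_errors <- character()
  warnings_after <- warnings
  if (!is.null(swaps) && nrow(swaps)) {
    filled <- apply_swaps(filled, swaps)
    swap_errors <- attr(filled, "swap_errors")
    warnings_after <- detect_warnings(filled)
  }
  list(table = filled, warnings = warnings,
       warnings_after = warnings_after,
       unfilled_gaps = gaps,
       swap_errors = swap_errors)
}
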