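# Social-behavior analytics from a corrected track table: per-animal
# cumulative travel distance, per-pair centre distance, and cumulative
# proximity time (strictly closer than the proximity threshold,
# default 6 cm). All outputs are in centimetres / seconds via the arena
# calibration; filled (carry-forward) frames contribute zero-length steps.

#' Analysis parameters
#'
#' @param proximity_cm Two animals are "proximate" on a frame when their
#'   centre distance is strictly less than this threshold (default 6 cm).
#' @param fps Frames per second (default 60).
#' @param calibration A [calibration()] object.
#' @return An object of class `mt_analysis_params`.
#' @export
analysis_params <- function(proximity_cm = 6.0, fps = 60, calibration) {
  stopifnot(proximity_cm > 0, fps > 0, inherits(calibration, "mt_calibration"))
  structure(list(proximity_cm = proximity_cm, fps = fps,
                 calibration = calibration),
            class = "mt_analysis_params")
}

tracks_of <- function(table, id) {
  n <- attr(table, "n_mice")
  if (id < 0 || id >= n) stop("unknown animal id: ", id)
  sub <- table[table$id == id, , drop = FALSE]
  sub[order(sub$frame), , drop = FALSE]
}

#' Cumulative travel distance of one animal
#'
#' Element t is the sum over frames up to t of the Euclidean step length
#' between consecutive centroids, in centimetres.
#'
#' @param table A corrected `mt_tracks` table.
#' @param id Animal ID.
#' @param calibration A [calibration()]; defaults to the table's.
#' @return A data.frame `frame,cum_cm`, one row per frame of the animal.
#' @export
cumulative_distance <- function(table, id,
                                calibration = attr(table, "calibration")) {
  stopifnot(inherits(table, "mt_tracks"), !is.null(calibration))
  sub <- tracks_of(table, id)
  steps <- sqrt(diff(sub$cx_px)^2 + diff(sub$cy_px)^2)
  data.frame(frame = sub$frame,
             cum_cm = cumsum(c(0, px_to_cm(steps, calibration))))
}

#' Per-frame distance between two animals
#'
#' @param table A corrected `mt_tracks` table in which both IDs are present
#'   on every frame of the range (run [fill_misses()] first otherwise).
#' @param id_a,id_b Animal IDs.
#' @inheritParams cumulative_distance
#' @return A data.frame `frame,dist_cm`.
#' @export
pair_distance <- function(table, id_a, id_b,
                          calibration = attr(table, "calibration")) {
  stopifnot(inherits(table, "mt_tracks"), !is.null(calibration))
  a <- tracks_of(table, id_a)
  b <- tracks_of(table, id_b)
  if (!identical(a$frame, b$frame))
    stop("pair_distance: ids ", id_a, " and ", id_b,
         " do not cover the same frames; correct the table first")
  data.frame(
    frame = a$frame,
    dist_cm = px_to_cm(sqrt((a$cx_px - b$cx_px)^2 + (a$cy_px - b$cy_px)^2),
                       calibration),
    filled = as.integer(a$filled | b$filled)
  )
}

#' Cumulative proximity time between two animals
#'
#' Element t is the count of frames up to t on which the pair distance is
#' strictly less than `proximity_cm`, divided by `fps` — the running
#' seconds the two animals have spent close together.
#'
#' @inheritParams pair_distance
#' @param params An [analysis_params()]; defaults built from the table's
#'   calibration with a 6 cm threshold at 60 fps.
#' @param exclude_filled Do not count frames where either record was
#'   miss-filled (default `FALSE`: filled frames carry coordinates and
#'   count).
#' @return A data.frame `frame,proximate,cum_s`.
#' @export
proximity_time <- function(table, id_a, id_b,
                           params = analysis_params(
                             calibration = attr(table, "calibration")),
                           exclude_filled = FALSE) {
  pd <- pair_distance(table, id_a, id_b, params$calibration)
  prox <- pd$dist_cm < params$proximity_cm
  if (exclude_filled) prox <- prox & pd$filled == 0L
  data.frame(frame = pd$frame, proximate = as.integer(prox),
             cum_s = cumsum(prox) / params$fps)
}

#' Compute all per-animal and per-pair statistics
#'
#' @inheritParams proximity_time
#' @param out_dir Optional directory: writes `cumdist_id<i>.csv`,
#'   `pairdist_<a>_<b>.csv` and `proximity_<a>_<b>.csv` series.
#' @return List with `cumulative` (per-ID), `pair_dist` and `proximity`
#'   (per unordered pair), plus a one-row `summary` data.frame.
#' @export
analyze_tracks <- function(table,
                           params = analysis_params(
                             calibration = attr(table, "calibration")),
                           exclude_filled = FALSE, out_dir = NULL) {
  n <- attr(table, "n_mice")
  ids <- seq_len(n) - 1L
  cum <- lapply(ids, function(i)
    cumulative_distance(table, i, params$calibration))
  names(cum) <- paste0("id", ids)
  pairs <- if (n >= 2) utils::combn(ids, 2, simplify = FALSE) else list()
  pd <- lapply(pairs, function(p)
    pair_distance(table, p[1], p[2], params$calibration))
  pt <- lapply(pairs, function(p)
    proximity_time(table, p[1], p[2], params, exclude_filled))
  pnames <- vapply(pairs, function(p) paste0(p[1], "_", p[2]), character(1))
  names(pd) <- pnames
  names(pt) <- pnames
  summary <- data.frame(
    id = ids,
    total_cm = vapply(cum, function(d) d$cum_cm[nrow(d)], numeric(1))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in ids)
      write.csv(cum[[i + 1L]],
                file.path(out_dir, sprintf("cumdist_id%d.csv", i)),
                row.names = FALSE)
    for (k in seq_along(pairs)) {
      write.csv(pd[[k]],
                file.path(out_dir, sprintf("pairdist_%s.csv", pnames[k])),
                row.names = FALSE)
      write.csv(pt[[k]],
                file.path(out_dir, sprintf("proximity_%s.csv", pnames[k])),
                row.names = FALSE)
    }
  }
  list(cumulative = cum, pair_dist = pd, proximity = pt, summary = summary)
}
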