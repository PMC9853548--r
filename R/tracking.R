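# Identity assignment across frames. IDs are seeded on the first frame
# with at least n_mice detections (largest n by area, ordered by centroid
# y then x). Each subsequent frame is matched by sorting every
# (ID, detection) dissimilarity ascending and greedily accepting pairs
# whose ID and detection are both still free; surplus detections are
# ignored, unmatched IDs are misses and keep their last real fingerprint.

#' Initialize identities from the first usable frame
#'
#' The `n_mice` largest-area detections receive IDs `0..n-1` ordered by
#' centroid (y, x) ascending; smaller detections are ignored.
#'
#' @param detections List of `mt_region` detections for one frame.
#' @param n_mice Number of animals.
#' @return A data.frame with columns `det` (index into `detections`) and
#'   `id`, or `NULL` when fewer than `n_mice` detections are present.
#' @export
initialize_ids <- function(detections, n_mice) {
  if (length(detections) < n_mice) return(NULL)
  areas <- vapply(detections, function(r) r$area_px, numeric(1))
  top <- order(-areas)[seq_len(n_mice)]
  cents <- t(vapply(detections[top], function(r) r$centroid, numeric(2)))
  ord <- order(cents[, 2], cents[, 1])
  data.frame(det = top[ord], id = seq_len(n_mice) - 1L)
}

#' Greedy ascending-dissimilarity assignment for one frame
#'
#' Builds the full dissimilarity matrix between each ID's latest real
#' fingerprint and each detection, sorts all (ID, detection) pairs
#' ascending (exact ties broken by lowest ID, then lowest detection index)
#' and accepts a pair iff neither its ID nor its detection is already
#' used, stopping at `min(n_mice, n_detections)` accepted pairs. This is
#' the sorted-list greedy rule, which can differ from the optimal-sum
#' bipartite assignment.
#'
#' @param state An identity state from [track_video()]'s loop: list with
#'   `fingerprints` (per-ID `mt_correlogram`), `centroids`, `last_frame`.
#' @param fingerprints List of `mt_correlogram`, one per detection.
#' @return List of class `mt_assignment`: `pairs` (data.frame `id`, `det`,
#'   `dissim`), `ignored` (detection indices), `unmatched` (IDs missed).
#' @export
match_frame <- function(state, fingerprints) {
  n_ids <- length(state$fingerprints)
  n_det <- length(fingerprints)
  if (n_det == 0L) {
    return(structure(list(
      pairs = data.frame(id = integer(), det = integer(), dissim = numeric()),
      ignored = integer(), unmatched = seq_len(n_ids) - 1L
    ), class = "mt_assignment"))
  }
  dm <- matrix(0, n_ids, n_det)
  for (i in seq_len(n_ids))
    for (j in seq_len(n_det))
      dm[i, j] <- dissimilarity(state$fingerprints[[i]], fingerprints[[j]])
  greedy_assign(dm)
}

# The sorted-ascending greedy rule on a dissimilarity matrix
# [ids x detections]; ids are reported 0-based, detections 1-based.
greedy_assign <- function(dm) {
  n_ids <- nrow(dm); n_det <- ncol(dm)
  ids <- rep(seq_len(n_ids), times = n_det)
  dets <- rep(seq_len(n_det), each = n_ids)
  ord <- order(as.vector(dm), ids, dets)
  used_id <- logical(n_ids)
  used_det <- logical(n_det)
  pairs <- data.frame(id = integer(), det = integer(), dissim = numeric())
  target <- min(n_ids, n_det)
  for (t in ord) {
    i <- ids[t]; j <- dets[t]
    if (used_id[i] || used_det[j]) next
    used_id[i] <- TRUE; used_det[j] <- TRUE
    pairs <- rbind(pairs,
                   data.frame(id = i - 1L, det = j, dissim = dm[i, j]))
    if (nrow(pairs) == target) break
  }
  structure(list(
    pairs = pairs,
    ignored = which(!used_det),
    unmatched = which(!used_id) - 1L
  ), class = "mt_assignment")
}

#' Track animals through a frame stream
#'
#' Runs detection and greedy identity assignment frame by frame. Matched
#' IDs update their reference fingerprint and centroid to the new
#' detection (adjacent-frame comparison); unmatched IDs retain their last
#' real fingerprint. One track record is emitted per matched ID per frame;
#' missed (frame, ID) slots are simply absent and are handled later by
#' [fill_misses()].
#'
#' @param stream An [frame_stream()] (or a [synth_scene()], coerced).
#' @param config An [mt_config()] with `n_mice` set.
#' @param detector Optional detector `function(image, frame_index)`
#'   returning a list of `mt_region`; defaults to [segment_frame()] with
#'   the config's segmentation parameters (see [via_detector()] for
#'   precomputed masks).
#' @param progress Print a line every 100 frames.
#' @return An uncorrected `mt_tracks` table with attributes
#'   `init_frame` (frame where IDs were seeded) and `skipped_init_frames`.
#' @export
track_video <- function(stream, config, detector = NULL, progress = FALSE) {
  if (inherits(stream, "mt_scene")) stream <- frame_stream(stream)
  stopifnot(inherits(stream, "mt_frames"), inherits(config, "mt_config"))
  n <- config$n_mice
  if (is.null(detector)) {
    sp <- seg_params_from_config(config)
    detector <- function(image, frame_index) {
      segment_frame(image, sp, frame_index = frame_index)
    }
  }
  fpp <- fp_params_from_config(config)
  cal <- calibration(arena_px = config$arena_px, arena_cm = config$arena_cm)

  state <- NULL
  init_frame <- NA_integer_
  max_seen <- 0L
  skipped <- integer()
  rows <- vector("list", stream$n_frames)

  for (f in seq_len(stream$n_frames) - 1L) {
    img <- stream$get_frame(f)
    dets <- detector(img, f)
    if (is.null(state)) {
      max_seen <- max(max_seen, length(dets))
      seed_map <- initialize_ids(dets, n)
      if (is.null(seed_map)) {
        skipped <- c(skipped, f)
        next
      }
      init_frame <- f
      state <- list(
        fingerprints = vector("list", n),
        centroids = matrix(NA_real_, n, 2),
        last_frame = rep(NA_integer_, n)
      )
      recs <- vector("list", n)
      for (r in seq_len(nrow(seed_map))) {
        det <- dets[[seed_map$det[r]]]
        id <- seed_map$id[r]
        state$fingerprints[[id + 1L]] <- region_fingerprint(img, det, fpp)
        state$centroids[id + 1L, ] <- det$centroid
        state$last_frame[id + 1L] <- f
        recs[[r]] <- data.frame(
          frame = f, id = id, cx_px = det$centroid[1], cy_px = det$centroid[2],
          area_px = det$area_px, filled = 0L, warned = 0L)
      }
      rows[[f + 1L]] <- do.call(rbind, recs)
    } else {
      fps_list <- lapply(dets, function(d) region_fingerprint(img, d, fpp))
      asg <- match_frame(state, fps_list)
      if (nrow(asg$pairs)) {
        recs <- vector("list", nrow(asg$pairs))
        for (r in seq_len(nrow(asg$pairs))) {
          id <- asg$pairs$id[r]
          det <- dets[[asg$pairs$det[r]]]
          state$fingerprints[[id + 1L]] <- fps_list[[asg$pairs$det[r]]]
          state$centroids[id + 1L, ] <- det$centroid
          state$last_frame[id + 1L] <- f
          recs[[r]] <- data.frame(
            frame = f, id = id, cx_px = det$centroid[1],
            cy_px = det$centroid[2], area_px = det$area_px,
            filled = 0L, warned = 0L)
        }
        rows[[f + 1L]] <- do.call(rbind, recs)
      }
    }
    if (progress && (f + 1L) %% 100L == 0L)
      message("tracked frame ", f + 1L, "/", stream$n_frames)
  }
  if (is.null(state))
    stop("track_video: no frame had >= ", n, " detections (max seen: ",
         max_seen, ")")
  tab <- track_table(do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                     n_mice = n, calibration = cal)
  attr(tab, "init_frame") <- init_frame
  attr(tab, "skipped_init_frames") <- skipped
  tab
}
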