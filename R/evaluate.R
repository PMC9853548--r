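# Tracking evaluation against synthetic ground truth: centroid error under
# the truth-optimal fixed ID mapping, miss percentage, identity-switch
# events (per-frame nearest-animal changes), and the error histogram at
# the 0.5 cm / 1.5 cm reporting thresholds.

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

#' Evaluate a predicted track table against ground truth
#'
#' Predicted IDs are mapped to ground-truth animals by the fixed
#' permutation minimizing the summed centroid distance over all real
#' (non-filled) records; per-frame centroid errors are reported in cm
#' under that mapping. Identity switches are counted as frames where at
#' least one ID's nearest ground-truth animal changes relative to the
#' previous frame. Misses are (frame, ID) slots between the predicted
#' table's first and last frame with no record.
#'
#' @param predicted An `mt_tracks` table from [track_video()] (corrected
#'   or not).
#' @param truth An `mt_truth` from [scene_truth()] (or its `table`).
#' @param calibration A [calibration()]; defaults to the predicted
#'   table's.
#' @return An object of class `mt_eval`: list with `miss_pct`,
#'   `n_switches`, `switch_frames`, `mapping` (predicted id ->
#'   truth id), `error_cm` (per real record), `max_error_cm`,
#'   `mean_error_cm`, `pct_below_0.5cm`, `pct_below_1.5cm`, `n_filled`,
#'   `n_warned`.
#' @export
evaluate_tracks <- function(predicted, truth,
                            calibration = attr(predicted, "calibration")) {
  stopifnot(inherits(predicted, "mt_tracks"))
  tt <- if (inherits(truth, "mt_truth")) truth$table else truth
  stopifnot(inherits(tt, "mt_tracks"), !is.null(calibration))
  n <- attr(predicted, "n_mice")
  if (attr(tt, "n_mice") != n)
    stop("evaluate_tracks: predicted and truth disagree on n_mice")
  if (!all(predicted$frame %in% tt$frame))
    stop("evaluate_tracks: predicted frames missing from ground truth")

  f0 <- min(predicted$frame); f1 <- max(predicted$frame)
  slots <- (f1 - f0 + 1) * n
  miss_pct <- 100 * (slots - nrow(predicted)) / slots

  real <- predicted[predicted$filled == 0L, , drop = FALSE]
  # distance from every real record to every truth animal at its frame
  tx <- matrix(NA_real_, max(tt$frame) + 1L, n)
  ty <- tx
  tx[cbind(tt$frame + 1L, tt$id + 1L)] <- tt$cx_px
  ty[cbind(tt$frame + 1L, tt$id + 1L)] <- tt$cy_px
  dists <- matrix(NA_real_, nrow(real), n)
  for (j in seq_len(n)) {
    dists[, j] <- sqrt((real$cx_px - tx[cbind(real$frame + 1L, j)])^2 +
                         (real$cy_px - ty[cbind(real$frame + 1L, j)])^2)
  }

  # fixed truth-optimal mapping: permutation minimizing total distance
  cost <- matrix(0, n, n)  # [predicted id, truth id]
  for (i in seq_len(n)) {
    sel <- real$id == i - 1L
    cost[i, ] <- colSums(dists[sel, , drop = FALSE])
  }
  pp <- perms(n)
  tot <- vapply(pp, function(p) sum(cost[cbind(seq_len(n), p)]), numeric(1))
  best <- pp[[which.min(tot)]]
  mapping <- best - 1L
  names(mapping) <- paste0("pred", seq_len(n) - 1L)

  err_px <- dists[cbind(seq_len(nrow(real)), best[real$id + 1L])]
  err_cm <- px_to_cm(err_px, calibration)

  # switch events: per-frame nearest truth animal, per predicted ID
  nearest <- max.col(-dists, ties.method = "first")
  switch_frames <- integer()
  for (i in seq_len(n)) {
    sel <- which(real$id == i - 1L)
    if (length(sel) < 2L) next
    ch <- which(diff(nearest[sel]) != 0)
    switch_frames <- c(switch_frames, real$frame[sel[ch + 1L]])
  }
  switch_frames <- sort(unique(switch_frames))

  structure(list(
    miss_pct = miss_pct,
    n_switches = length(switch_frames),
    switch_frames = switch_frames,
    mapping = mapping,
    error_cm = err_cm,
    max_error_cm = if (length(err_cm)) max(err_cm) else NA_real_,
    mean_error_cm = if (length(err_cm)) mean(err_cm) else NA_real_,
    `pct_below_0.5cm` = 100 * mean(err_cm < 0.5),
    `pct_below_1.5cm` = 100 * mean(err_cm < 1.5),
    n_filled = sum(predicted$filled),
    n_warned = sum(predicted$warned)
  ), class = "mt_eval")
}

#' @export
print.mt_eval <- function(x, ...) {
  cat("Tracking evaluation vs ground truth\n")
  cat(sprintf("  misses:        %.3f%% of slots\n", x$miss_pct))
  cat(sprintf("  ID switches:   %d%s\n", x$n_switches,
              if (x$n_switches)
                paste0(" (frames ", paste(x$switch_frames, collapse = ", "), ")")
              else ""))
  cat(sprintf("  centroid error: max %.3f cm, mean %.3f cm\n",
              x$max_error_cm, x$mean_error_cm))
  cat(sprintf("  error < 0.5 cm: %.1f%%   < 1.5 cm: %.1f%%\n",
              x$`pct_below_0.5cm`, x$`pct_below_1.5cm`))
  invisible(x)
}
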