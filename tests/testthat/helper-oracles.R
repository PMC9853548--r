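# Independent reference implementations used as oracles. These are written
# naively (explicit recursion / double loops) and share no code with the
# package internals they check.

# --- closed-contour RDP, textbook recursive form ------------------------

oracle_point_line_dist <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(sqrt(sum((p - a)^2)))
  abs((p[1] - a[1]) * ab[2] - (p[2] - a[2]) * ab[1]) / len
}

oracle_rdp_chain <- function(pts, idx, eps) {
  if (length(idx) <= 2) return(idx[c(1, length(idx))])
  a <- pts[idx[1], ]; b <- pts[idx[length(idx)], ]
  dmax <- -1; imax <- NA
  for (k in 2:(length(idx) - 1)) {
    d <- oracle_point_line_dist(pts[idx[k], ], a, b)
    if (d > dmax) { dmax <- d; imax <- k }
  }
  if (dmax > eps) {
    left <- oracle_rdp_chain(pts, idx[1:imax], eps)
    right <- oracle_rdp_chain(pts, idx[imax:length(idx)], eps)
    c(left, right[-1])
  } else {
    idx[c(1, length(idx))]
  }
}

oracle_rdp_closed <- function(poly, eps) {
  n <- nrow(poly)
  besti <- 1; bestj <- 2; bestd <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sum((poly[i, ] - poly[j, ])^2)
    if (d > bestd) { bestd <- d; besti <- i; bestj <- j }
  }
  keep <- sort(unique(c(
    oracle_rdp_chain(poly, besti:bestj, eps),
    oracle_rdp_chain(poly, c(bestj:n, 1:besti), eps)
  )))
  poly[keep, , drop = FALSE]
}

# random star-shaped polygon (sorted angles, random radii) around a centre
random_polygon <- function(n_vertices, radius = 10, centre = c(0, 0)) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.3 * radius, radius)
  cbind(x = centre[1] + rad * cos(ang), y = centre[2] + rad * sin(ang))
}

# --- brute-force binary dilation ---------------------------------------

brute_dilate <- function(mask, kern) {
  nr <- nrow(mask); nc <- ncol(mask)
  kr <- (nrow(kern) - 1) / 2; kc <- (ncol(kern) - 1) / 2
  out <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    for (dr in -kr:kr) for (dc in -kc:kc) {
      if (kern[dr + kr + 1, dc + kc + 1] == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) out[rr, cc] <- TRUE
    }
  }
  out
}

# --- exhaustive all-pairs correlogram ----------------------------------

brute_correlogram_counts <- function(patch, mask, n_dist_bins, n_sum_bins,
                                     max_dist_px) {
  idx <- which(mask, arr.ind = TRUE)
  k <- nrow(idx)
  counts <- matrix(0L, n_dist_bins, n_sum_bins)
  if (k < 2) return(counts)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    dx <- idx[j, 2] - idx[i, 2]
    dy <- idx[j, 1] - idx[i, 1]
    d <- sqrt(dx^2 + dy^2)
    s <- patch[idx[i, 1], idx[i, 2]] + patch[idx[j, 1], idx[j, 2]]
    db <- min(floor(d / max_dist_px * n_dist_bins), n_dist_bins - 1)
    sb <- min(floor(s / 511 * n_sum_bins), n_sum_bins - 1)
    counts[db + 1, sb + 1] <- counts[db + 1, sb + 1] + 1L
  }
  counts
}

# --- shared small-scale scene setup ------------------------------------

# Desk-scale scene for unit tests: 160 px arena at 5 px/cm keeps animals
# ~40 x 16 px so every stage runs in well under a second per frame.
tiny_scene <- function(n_mice = 2, n_frames = 30, seed = 1, ...) {
  synth_scene(n_mice = n_mice, n_frames = n_frames, arena_px = 160,
              seed = seed, ...)
}

tiny_config <- function(n_mice = 2, ...) {
  mt_config(n_mice = n_mice, arena_px = 160, min_area_px = 50, ...)
}

# minimal correlogram object for metric tests
raw_correlogram <- function(mass) {
  structure(list(mass = mass, counts = mass, total_pairs = sum(mass),
                 n_dist_bins = nrow(mass), n_sum_bins = ncol(mass),
                 max_dist_px = 64),
            class = "mt_correlogram")
}

# hand-built track table
make_table <- function(df, n_mice, arena_px = 320, arena_cm = 32) {
  track_table(df, n_mice = n_mice,
              calibration = calibration(arena_px = arena_px,
                                        arena_cm = arena_cm))
}

# min distance from point p to the closed polyline through vertices vs
clamp_scalar <- function(t) max(0, min(1, t))

dist_to_polyline <- function(p, vs) {
  n <- nrow(vs)
  d <- Inf
  for (k in 1:n) {
    a <- vs[k, ]; b <- vs[if (k == n) 1 else k + 1, ]
    ab <- b - a
    t <- if (sum(ab^2) == 0) 0 else
      clamp_scalar(sum((p - a) * ab) / sum(ab^2))
    q <- a + t * ab
    d <- min(d, sqrt(sum((p - q)^2)))
  }
  d
}
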