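# Synthetic arena scenes with full ground truth. The generator emulates
# the recording setup the tracker is built for: a bright square open-field
# arena (32 cm side) filmed from above at 60 Hz, with 1-4 dark, textured,
# elliptical animals (~8 cm body length) moving as a smooth seeded random
# walk with reflecting walls and ellipse-level collision avoidance. Each
# animal's multiplicative texture field is fixed in its body frame and
# rotates with its heading, so appearance fingerprints are informative but
# not trivially constant. Detection misses (an animal omitted from the
# render) and irreversible ID switches (two animals exchanging appearance
# from a frame onward) can be injected, and every injection is logged.

#' Generate a synthetic arena scene
#'
#' Deterministic given `seed`: trajectories, textures, per-frame background
#' noise and injections are all drawn from one seeded stream, and frames
#' are rendered on demand from stored state.
#'
#' @param n_mice Number of animals (1-4 is the intended range).
#' @param n_frames Number of frames.
#' @param arena_px Arena side in pixels (default 640, i.e. 20 px/cm for a
#'   32 cm arena).
#' @param arena_cm Arena side in centimetres (default 32).
#' @param fps Frame rate (default 60).
#' @param body_len_cm Body (major-axis) length in centimetres (default 8).
#' @param body_aspect Minor/major axis ratio (default 0.4).
#' @param base_intensity Per-animal base gray level; default evenly spaced
#'   on `[40, 90]` (dark animals on a bright floor).
#' @param texture_amp Multiplicative texture amplitude (default 0.35).
#' @param texture_cell_px Texture cell size in body-frame pixels
#'   (default 4).
#' @param bg_intensity,bg_noise_sd Background gray level and Gaussian noise
#'   standard deviation (defaults 230 and 5).
#' @param step_mean_px,step_sd_px,max_step_px Per-frame step length model:
#'   `|N(mean, sd)|` clamped to `max_step_px` (defaults 3, 1.5, 8 px; at
#'   20 px/cm and 60 Hz the mean is ~9 cm/s).
#' @param turn_sd Heading random-walk standard deviation in radians/frame
#'   (default 0.4).
#' @param min_sep_px Minimum clearance kept between animal boundaries so
#'   that blobs never merge (default 3 px).
#' @param miss_rate Fraction of (frame, animal) slots omitted from the
#'   render as injected detection misses (default 0); frame 0 is never
#'   missed so identities can initialize.
#' @param miss_list Explicit data.frame `frame,id` of injected misses
#'   (0-based), overriding `miss_rate`.
#' @param swap_events Data.frame `frame,id_a,id_b`: from `frame` onward the
#'   two animals exchange appearance (texture and base intensity), the
#'   mechanism that makes an appearance-based tracker commit an
#'   irreversible ID switch while ground-truth positions stay with the
#'   animals.
#' @param seed Integer seed.
#' @return An object of class `mt_scene`.
#' @export
synth_scene <- function(n_mice = 2, n_frames = 600,
                        arena_px = 640, arena_cm = 32, fps = 60,
                        body_len_cm = 8, body_aspect = 0.4,
                        base_intensity = NULL,
                        texture_amp = 0.35, texture_cell_px = 4,
                        bg_intensity = 230, bg_noise_sd = 5,
                        step_mean_px = 3, step_sd_px = 1.5, max_step_px = 8,
                        turn_sd = 0.4, min_sep_px = 3,
                        miss_rate = 0, miss_list = NULL, swap_events = NULL,
                        seed = 1L) {
  stopifnot(n_mice >= 1, n_frames >= 1, arena_px > 0, arena_cm > 0)
  cal <- calibration(arena_px = arena_px, arena_cm = arena_cm)
  a <- body_len_cm * cal$px_per_cm / 2    # semi-major axis, px
  b <- a * body_aspect                    # semi-minor axis, px
  margin <- a + 2
  if (2 * margin >= arena_px)
    stop("config error: animals larger than arena (body ", 2 * a,
         " px vs arena ", arena_px, " px)")
  if (is.null(base_intensity))
    base_intensity <- if (n_mice == 1) 65 else
      seq(40, 90, length.out = n_mice)
  stopifnot(length(base_intensity) == n_mice)

  set.seed(seed)
  # body-frame texture fields, one per animal
  cell <- texture_cell_px
  nu <- ceiling(2 * a / cell) + 1L
  nv <- ceiling(2 * b / cell) + 1L
  textures <- lapply(seq_len(n_mice), function(i)
    matrix(1 + texture_amp * (2 * runif(nu * nv) - 1), nu, nv))

  # initial placement along the arena diagonal, random headings
  fr <- (seq_len(n_mice) - 0.5) / n_mice
  pos <- cbind(margin + fr * (arena_px - 2 * margin),
               margin + fr * (arena_px - 2 * margin))
  theta <- runif(n_mice, 0, 2 * pi)

  states <- array(NA_real_, c(n_frames, n_mice, 3),
                  dimnames = list(NULL, NULL, c("x", "y", "theta")))
  states[1, , ] <- cbind(pos, theta)
  for (t in seq_len(n_frames - 1L)) {
    for (i in seq_len(n_mice)) {
      cur <- states[t, i, ]
      placed <- FALSE
      for (try in 1:30) {
        th <- cur[3] + rnorm(1, 0, turn_sd)
        st <- clamp(abs(rnorm(1, step_mean_px, step_sd_px)), 0, max_step_px)
        x <- cur[1] + st * cos(th)
        y <- cur[2] + st * sin(th)
        if (x < margin) { x <- 2 * margin - x; th <- pi - th }
        if (x > arena_px - margin) { x <- 2 * (arena_px - margin) - x; th <- pi - th }
        if (y < margin) { y <- 2 * margin - y; th <- -th }
        if (y > arena_px - margin) { y <- 2 * (arena_px - margin) - y; th <- -th }
        ok <- TRUE
        for (j in seq_len(n_mice)) {
          if (j == i) next
          other <- if (j < i) states[t + 1L, j, ] else states[t, j, ]
          if (ellipses_collide(c(x, y), th, other[1:2], other[3],
                               a, b, min_sep_px)) { ok <- FALSE; break }
        }
        if (ok) {
          states[t + 1L, i, ] <- c(x, y, th)
          placed <- TRUE
          break
        }
      }
      if (!placed)  # boxed in: stay put, reverse heading
        states[t + 1L, i, ] <- c(cur[1], cur[2], cur[3] + pi)
    }
  }

  frame_seeds <- sample.int(.Machine$integer.max - 1L, n_frames)

  # injected misses
  if (is.null(miss_list)) {
    miss_list <- data.frame(frame = integer(), id = integer())
    if (miss_rate > 0 && n_frames > 1L) {
      slots <- expand.grid(frame = seq_len(n_frames - 1L), id = seq_len(n_mice) - 1L)
      k <- min(nrow(slots), round(miss_rate * n_frames * n_mice))
      if (k > 0) {
        sel <- sample(nrow(slots), k)
        miss_list <- slots[sort(sel), , drop = FALSE]
        rownames(miss_list) <- NULL
      }
    }
  } else {
    stopifnot(all(c("frame", "id") %in% names(miss_list)))
    if (any(miss_list$frame < 0 | miss_list$frame >= n_frames))
      stop("miss_list frames out of range")
  }

  # appearance-ownership schedule for injected ID switches
  tex_owner <- matrix(rep(seq_len(n_mice) - 1L, each = n_frames),
                      n_frames, n_mice)
  if (is.null(swap_events))
    swap_events <- data.frame(frame = integer(), id_a = integer(),
                              id_b = integer())
  if (nrow(swap_events)) {
    stopifnot(all(c("frame", "id_a", "id_b") %in% names(swap_events)))
    for (r in order(swap_events$frame)) {
      f <- swap_events$frame[r]
      ia <- swap_events$id_a[r] + 1L; ib <- swap_events$id_b[r] + 1L
      rows <- (f + 1L):n_frames
      tmp <- tex_owner[rows, ia]
      tex_owner[rows, ia] <- tex_owner[rows, ib]
      tex_owner[rows, ib] <- tmp
    }
  }

  structure(list(
    n_mice = n_mice, n_frames = n_frames,
    arena_px = arena_px, arena_cm = arena_cm, fps = fps,
    calibration = cal,
    semi_major = a, semi_minor = b,
    base_intensity = base_intensity, textures = textures,
    texture_amp = texture_amp, texture_cell_px = cell,
    bg_intensity = bg_intensity, bg_noise_sd = bg_noise_sd,
    states = states, tex_owner = tex_owner, frame_seeds = frame_seeds,
    miss_list = miss_list, swap_events = swap_events, seed = seed
  ), class = "mt_scene")
}

#' @export
print.mt_scene <- function(x, ...) {
  cat(sprintf(
    "Synthetic scene: %d animal(s), %d frames, %d px arena (%g cm), seed %d\n",
    x$n_mice, x$n_frames, x$arena_px, x$arena_cm, x$seed))
  if (nrow(x$miss_list))
    cat("  injected misses:", nrow(x$miss_list), "\n")
  if (nrow(x$swap_events))
    cat("  injected ID switches:", nrow(x$swap_events), "\n")
  invisible(x)
}

# Conservative ellipse-ellipse collision test with clearance `margin`:
# quick accept/reject on centre distance, then mutual boundary sampling.
ellipses_collide <- function(c1, t1, c2, t2, a, b, margin) {
  d <- sqrt(sum((c1 - c2)^2))
  if (d >= 2 * a + margin) return(FALSE)
  if (d <= 2 * b + margin) return(TRUE)
  phi <- seq(0, 2 * pi, length.out = 73)[-73]
  inside <- function(p, cc, tt, aa, bb) {
    u <- cos(tt) * (p[, 1] - cc[1]) + sin(tt) * (p[, 2] - cc[2])
    v <- -sin(tt) * (p[, 1] - cc[1]) + cos(tt) * (p[, 2] - cc[2])
    any((u / aa)^2 + (v / bb)^2 <= 1)
  }
  bdry <- function(cc, tt, aa, bb) {
    u <- aa * cos(phi); v <- bb * sin(phi)
    cbind(cc[1] + cos(tt) * u - sin(tt) * v,
          cc[2] + sin(tt) * u + cos(tt) * v)
  }
  inside(bdry(c1, t1, a + margin, b + margin), c2, t2, a, b) ||
    inside(bdry(c2, t2, a + margin, b + margin), c1, t1, a, b)
}

# Pixel membership of animal i's ellipse at frame t (both 0-based args use
# t 0-based, i 1-based internally). Returns list(rows, cols) 1-based frame
# indices plus 0-based x/y vectors of member pixels.
animal_pixels <- function(scene, t, i) {
  st <- scene$states[t + 1L, i, ]
  a <- scene$semi_major; b <- scene$semi_minor
  x0 <- max(0L, floor(st[1] - a)); x1 <- min(scene$arena_px - 1L, ceiling(st[1] + a))
  y0 <- max(0L, floor(st[2] - a)); y1 <- min(scene$arena_px - 1L, ceiling(st[2] + a))
  xs <- x0:x1; ys <- y0:y1
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  u <- cos(st[3]) * (X - st[1]) + sin(st[3]) * (Y - st[2])
  v <- -sin(st[3]) * (X - st[1]) + cos(st[3]) * (Y - st[2])
  inside <- (u / a)^2 + (v / b)^2 <= 1
  list(X = X, Y = Y, u = u, v = v, inside = inside,
       x0 = x0, y0 = y0)
}

#' Render one frame of a synthetic scene
#'
#' @param scene An [synth_scene()].
#' @param t 0-based frame index.
#' @return Numeric matrix `[arena_px x arena_px]` on `[0, 255]`.
#' @export
render_frame <- function(scene, t) {
  stopifnot(inherits(scene, "mt_scene"), t >= 0, t < scene$n_frames)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(scene$frame_seeds[t + 1L])
  n <- scene$arena_px
  img <- matrix(clamp(scene$bg_intensity + rnorm(n * n, 0, scene$bg_noise_sd),
                      0, 255), n, n)
  missed <- scene$miss_list$id[scene$miss_list$frame == t]
  for (i in seq_len(scene$n_mice)) {
    if ((i - 1L) %in% missed) next
    ap <- animal_pixels(scene, t, i)
    if (!any(ap$inside)) next
    owner <- scene$tex_owner[t + 1L, i] + 1L
    tex <- scene$textures[[owner]]
    a <- scene$semi_major; b <- scene$semi_minor
    cellsz <- scene$texture_cell_px
    iu <- clamp(floor((ap$u[ap$inside] + a) / cellsz) + 1L, 1L, nrow(tex))
    iv <- clamp(floor((ap$v[ap$inside] + b) / cellsz) + 1L, 1L, ncol(tex))
    val <- clamp(scene$base_intensity[owner] * tex[cbind(iu, iv)], 0, 255)
    rows <- ap$Y[ap$inside] + 1L
    cols <- ap$X[ap$inside] + 1L
    img[cbind(rows, cols)] <- val
  }
  img
}

#' @rdname frame_stream
#' @export
frame_stream.mt_scene <- function(x, ...) {
  force(x)
  structure(
    list(
      n_frames = x$n_frames, width = x$arena_px, height = x$arena_px,
      fps = x$fps,
      get_frame = function(i) render_frame(x, i),
      source = "synthetic scene"
    ),
    class = "mt_frames"
  )
}

#' Ground truth of a synthetic scene
#'
#' True per-frame centroids and areas (arithmetic means / counts of the
#' exact pixel membership the renderer draws, so they match rendered masks
#' pixel-for-pixel), the per-animal cumulative path-length ledger, and the
#' injected-event log.
#'
#' @param scene An [synth_scene()].
#' @return An object of class `mt_truth`: list with `table` (an
#'   `mt_tracks` with one record per frame per animal, injections
#'   included), `path_cm` (list of per-animal cumulative path series),
#'   `total_path_cm`, `miss_list`, `swap_events`.
#' @export
scene_truth <- function(scene) {
  stopifnot(inherits(scene, "mt_scene"))
  n <- scene$n_mice
  rows <- vector("list", scene$n_frames * n)
  k <- 0L
  for (t in seq_len(scene$n_frames) - 1L) {
    for (i in seq_len(n)) {
      ap <- animal_pixels(scene, t, i)
      xs <- ap$X[ap$inside]; ys <- ap$Y[ap$inside]
      k <- k + 1L
      rows[[k]] <- data.frame(
        frame = t, id = i - 1L, cx_px = mean(xs), cy_px = mean(ys),
        area_px = length(xs), filled = 0L, warned = 0L)
    }
  }
  tab <- track_table(do.call(rbind, rows), n_mice = n,
                     calibration = scene$calibration)
  path <- lapply(seq_len(n) - 1L, function(i)
    cumulative_distance(tab, i, scene$calibration))
  names(path) <- paste0("id", seq_len(n) - 1L)
  structure(list(
    table = tab,
    path_cm = path,
    total_path_cm = vapply(path, function(d) d$cum_cm[nrow(d)], numeric(1)),
    miss_list = scene$miss_list,
    swap_events = scene$swap_events
  ), class = "mt_truth")
}

#' Ground-truth masks of one frame
#'
#' Bbox-local ground-truth masks as `mt_region` objects, omitting
#' injected misses when `rendered_only` (so they correspond
#' pixel-for-pixel to what [render_frame()] drew).
#'
#' @param scene An [synth_scene()].
#' @param t 0-based frame index.
#' @param rendered_only Omit animals missed by injection at this frame.
#' @return List of `mt_region`.
#' @export
scene_masks <- function(scene, t, rendered_only = TRUE) {
  missed <- scene$miss_list$id[scene$miss_list$frame == t]
  out <- list()
  for (i in seq_len(scene$n_mice)) {
    if (rendered_only && (i - 1L) %in% missed) next
    ap <- animal_pixels(scene, t, i)
    rr <- range(which(rowSums(ap$inside) > 0))
    cc <- range(which(colSums(ap$inside) > 0))
    local <- ap$inside[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    out[[length(out) + 1L]] <- mask_region(
      local, offset = c(ap$x0 + cc[1] - 1, ap$y0 + rr[1] - 1),
      frame_dim = c(scene$arena_px, scene$arena_px), frame_index = t)
  }
  out
}

#' Write a scene to disk
#'
#' PNG frames, the ground-truth table in the track-CSV schema, the injected
#' event logs, and a VIA 2.x JSON of the true contours (so annotation
#' import can be exercised on generated data).
#'
#' @param scene An [synth_scene()].
#' @param dir Output directory.
#' @param via_frames How many initial frames to include in the VIA JSON
#'   (contour extraction per frame is the slow part; default 10).
#' @export
write_scene <- function(scene, dir, via_frames = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_frames_png(frame_stream(scene), file.path(dir, "frames"))
  truth <- scene_truth(scene)
  write_track_csv(truth$table, scene$calibration,
                  file.path(dir, "truth.csv"))
  write.csv(scene$miss_list, file.path(dir, "events_miss.csv"),
            row.names = FALSE)
  write.csv(scene$swap_events, file.path(dir, "events_swap.csv"),
            row.names = FALSE)
  nf <- min(via_frames, scene$n_frames)
  ann <- lapply(seq_len(nf) - 1L, function(t) {
    regs <- scene_masks(scene, t)
    list(filename = sprintf("frame_%06d.png", t),
         polygons = lapply(regs, function(r) r$contour),
         attributes = rep(list(list()), length(regs)))
  })
  write_via_annotations(ann, file.path(dir, "truth_contours_via.json"))
  invisible(dir)
}
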