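# Semi-automated correction: miss filling, tracking warnings, swaps.

grid_table <- function(n_frames, n_mice, fx = function(f, i) 10 * i + f,
                       fy = function(f, i) 50 * i) {
  df <- expand.grid(frame = 0:(n_frames - 1), id = 0:(n_mice - 1))
  df$cx_px <- mapply(fx, df$frame, df$id)
  df$cy_px <- mapply(fy, df$frame, df$id)
  df$area_px <- 100
  df$filled <- 0L
  df$warned <- 0L
  make_table(df, n_mice)
}

test_that("fill_misses is the identity on complete tables", {
  tab <- grid_table(10, 2)
  out <- fill_misses(tab)
  expect_equal(as.data.frame(out), as.data.frame(tab), ignore_attr = TRUE)
  expect_equal(nrow(attr(out, "unfilled_gaps")), 0)
})

test_that("a single-frame miss is filled from the prior frame", {
  tab <- grid_table(20, 3)
  dropped <- tab[!(tab$frame == 10 & tab$id == 2), ]
  out <- fill_misses(make_table(dropped, 3))
  expect_equal(sum(out$frame == 10), 3)
  rec <- out[out$frame == 10 & out$id == 2, ]
  prev <- tab[tab$frame == 9 & tab$id == 2, ]
  expect_equal(rec$cx_px, prev$cx_px)
  expect_equal(rec$cy_px, prev$cy_px)
  expect_equal(rec$filled, 1L)
  # real records untouched
  expect_equal(as.data.frame(out[out$filled == 0, ]),
               as.data.frame(make_table(dropped, 3)), ignore_attr = TRUE)
})

test_that("gaps longer than max_gap are reported, not filled", {
  tab <- grid_table(200, 2)
  dropped <- tab[!(tab$id == 1 & tab$frame %in% 50:149), ]
  out <- fill_misses(make_table(dropped, 2), max_gap = 60)
  expect_equal(sum(out$frame %in% 50:149 & out$id == 1), 0)
  gaps <- attr(out, "unfilled_gaps")
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$start, 50)
  expect_equal(gaps$end, 149)
  expect_equal(gaps$length, 100)
  # a 60-frame gap is still sporadic and gets filled
  dropped2 <- tab[!(tab$id == 1 & tab$frame %in% 50:109), ]
  out2 <- fill_misses(make_table(dropped2, 2), max_gap = 60)
  expect_equal(sum(out2$filled), 60)
})

test_that("stationary animals and single animals yield no warnings", {
  expect_equal(nrow(detect_warnings(grid_table(30, 3))), 0)
  tab1 <- grid_table(30, 1, fx = function(f, i) 5 * f,
                     fy = function(f, i) 3 * f)
  expect_equal(nrow(detect_warnings(tab1)), 0)
})

test_that("a positional exchange triggers warnings for both IDs", {
  # IDs 0 and 1 walk on parallel tracks, then exchange positions
  # between frames 4 and 5
  fx <- function(f, i) if (f <= 4) 10 * f else 10 * f
  fy <- function(f, i) {
    if (f <= 4) 100 * i else 100 * (1 - i)
  }
  tab <- grid_table(10, 2, fx, fy)
  w <- detect_warnings(tab)
  expect_equal(unique(w$frame), 5)
  expect_setequal(w$id, c(0, 1))
  # hand-computed distances: own move = sqrt(10^2 + 100^2), cross = 10
  expect_equal(w$dist_same, rep(sqrt(10^2 + 100^2), 2))
  expect_equal(w$dist_min, rep(10, 2))
  expect_equal(w$other_id, c(1, 0))
})

test_that("warning emission requires strict inequality", {
  # both IDs converge to the same point: distances tie exactly
  df <- data.frame(frame = c(0, 0, 1, 1), id = c(0, 1, 0, 1),
                   cx_px = c(0, 20, 10, 10), cy_px = 0,
                   area_px = 1, filled = 0L, warned = 0L)
  expect_equal(nrow(detect_warnings(make_table(df, 2))), 0)
})

test_that("detect_warnings demands a complete table", {
  tab <- grid_table(5, 2)
  expect_error(detect_warnings(make_table(tab[-3, ], 2)), "fill_misses")
})

test_that("apply_swaps exchanges labels from the frame onward", {
  tab <- grid_table(20, 3)
  expect_equal(as.data.frame(apply_swaps(tab, data.frame(
    frame = integer(), id_a = integer(), id_b = integer()))),
    as.data.frame(tab), ignore_attr = TRUE)

  sw <- data.frame(frame = 10, id_a = 0, id_b = 2)
  out <- apply_swaps(tab, sw)
  expect_equal(out[out$frame == 12 & out$id == 0, ]$cy_px,
               tab[tab$frame == 12 & tab$id == 2, ]$cy_px)
  expect_equal(out[out$frame == 9 & out$id == 0, ]$cy_px,
               tab[tab$frame == 9 & tab$id == 0, ]$cy_px)
  # involution
  back <- apply_swaps(out, sw)
  expect_equal(as.data.frame(back), as.data.frame(tab), ignore_attr = TRUE)
})

test_that("invalid directives are skipped and reported, valid ones applied", {
  tab <- grid_table(10, 2)
  sw <- data.frame(frame = c(3, 99, 5), id_a = c(0, 0, 7), id_b = c(1, 1, 1))
  out <- apply_swaps(tab, sw)
  errs <- attr(out, "swap_errors")
  expect_length(errs, 2)
  expect_true(any(grepl("frame 99", errs)))
  expect_true(any(grepl("unknown id", errs)))
  # the valid directive (frame 3) was applied
  expect_equal(out[out$frame == 5 & out$id == 0, ]$cy_px,
               tab[tab$frame == 5 & tab$id == 1, ]$cy_px)
})

test_that("swap correction restores ground truth after an injected switch", {
  sc <- tiny_scene(n_mice = 2, n_frames = 80, seed = 19,
                   swap_events = data.frame(frame = 40, id_a = 0, id_b = 1))
  tr <- track_video(frame_stream(sc), tiny_config(2))
  truth <- scene_truth(sc)
  filled <- fill_misses(tr)
  ev_pre <- evaluate_tracks(filled, truth)
  expect_equal(ev_pre$n_switches, 1)
  expect_equal(ev_pre$switch_frames, 40)

  w <- detect_warnings(filled)
  expect_gte(nrow(w), 1)
  expect_lte(min(abs(w$frame - 40)), 1)

  # control: same scene without the injection warns nowhere
  sc0 <- tiny_scene(n_mice = 2, n_frames = 80, seed = 19)
  tr0 <- track_video(frame_stream(sc0), tiny_config(2))
  expect_equal(nrow(detect_warnings(fill_misses(tr0))), 0)

  fixed <- apply_swaps(filled, data.frame(frame = w$frame[1],
                                          id_a = 0, id_b = 1))
  ev <- evaluate_tracks(fixed, truth)
  expect_equal(ev$n_switches, 0)
  expect_lt(ev$max_error_cm, 1e-9)
})
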