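# I/O: VIA annotation import/export, track-table CSV, flat config files,
# and the arena calibration.

make_via_file <- function(polys_by_image, extra_region = NULL,
                          project_style = FALSE) {
  doc <- list()
  for (img in names(polys_by_image)) {
    regions <- lapply(polys_by_image[[img]], function(p) list(
      shape_attributes = list(name = "polygon",
                              all_points_x = p[, 1], all_points_y = p[, 2]),
      region_attributes = list()
    ))
    if (!is.null(extra_region)) regions <- c(regions, list(extra_region))
    doc[[paste0(img, "-1")]] <- list(filename = img, size = -1,
                                     regions = regions)
  }
  if (project_style)
    doc <- list(`_via_settings` = list(ui = list()),
                `_via_img_metadata` = doc)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

test_that("VIA polygon import handles both dialects and filters shapes", {
  p1 <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  p2 <- cbind(c(20, 30, 25), c(20, 20, 30))
  f <- make_via_file(list("a.png" = list(p1, p2)))
  ann <- read_via_annotations(f)
  expect_length(ann, 1)
  expect_length(ann[[1]]$polygons, 2)
  expect_equal(ann[[1]]$polygons[[1]][, 1], p1[, 1])
  expect_identical(attr(ann, "skipped"), 0L)

  rect <- list(shape_attributes = list(name = "rect", x = 1, y = 1,
                                       width = 5, height = 5),
               region_attributes = list())
  f2 <- make_via_file(list("a.png" = list(p1)), extra_region = rect)
  expect_message(ann2 <- read_via_annotations(f2), "skipped 1")
  expect_length(ann2[[1]]$polygons, 1)
  expect_identical(attr(ann2, "skipped"), 1L)

  f3 <- make_via_file(list("a.png" = list(p1)), project_style = TRUE)
  ann3 <- read_via_annotations(f3)
  expect_equal(ann3[[1]]$polygons[[1]], ann[[1]]$polygons[[1]])
})

test_that("VIA import rejects malformed input", {
  bad <- tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(read_via_annotations(bad), "parse error")

  tri <- cbind(c(0, 5), c(0, 5)) # 2 vertices
  f <- make_via_file(list("a.png" = list(tri)))
  expect_error(read_via_annotations(f), "fewer than 3 vertices")
})

test_that("VIA round-trip preserves vertex arrays exactly", {
  set.seed(31)
  for (rep in 1:5) {
    frames <- lapply(1:3, function(i) {
      polys <- lapply(seq_len(sample(1:4, 1)), function(j)
        random_polygon(sample(3:12, 1), radius = 50, centre = c(60, 60)))
      list(filename = sprintf("img%d.png", i), polygons = polys,
           attributes = rep(list(list()), length(polys)))
    })
    path <- tempfile(fileext = ".json")
    write_via_annotations(frames, path)
    back <- read_via_annotations(path)
    for (i in 1:3) {
      expect_length(back[[i]]$polygons, length(frames[[i]]$polygons))
      for (j in seq_along(frames[[i]]$polygons))
        expect_equal(unname(back[[i]]$polygons[[j]]),
                     unname(frames[[i]]$polygons[[j]]))
    }
  }
})

test_that("track CSV round-trips field-by-field with cm columns", {
  cal <- calibration(arena_px = 320, arena_cm = 32) # 10 px/cm
  df <- data.frame(
    frame = c(0, 0, 1, 1), id = c(0, 1, 0, 1),
    cx_px = c(320, 10.5, 33, 44), cy_px = c(0, 20.25, 35, 46),
    area_px = c(100, 200, 101, 201), filled = c(0, 0, 1, 0),
    warned = c(0, 1, 0, 0))
  tab <- track_table(df, n_mice = 2, calibration = cal)
  path <- tempfile(fileext = ".csv")
  write_track_csv(tab, cal, path)

  raw <- read.csv(path)
  expect_identical(names(raw),
                   c("frame", "id", "cx_px", "cy_px", "cx_cm", "cy_cm",
                     "area_px", "filled", "warned"))
  expect_equal(nrow(raw), 4)                    # 2 frames x 2 ids
  expect_equal(raw$cx_cm[1], 32.0)              # 320 px at 10 px/cm
  back <- read_track_csv(path)
  for (col in c("frame", "id", "cx_px", "cy_px", "area_px", "filled",
                "warned"))
    expect_equal(back[[col]], tab[[col]], info = col)
  expect_equal(attr(back, "calibration")$px_per_cm, 10)
})

test_that("config defaults carry the method constants and validate", {
  path <- tempfile(fileext = ".cfg")
  writeLines(c("# comment", "n_mice = 2"), path)
  cfg <- load_config(path)
  expect_equal(cfg$rdp_epsilon, 1.5)
  expect_equal(cfg$expand_px, 5)
  expect_equal(cfg$dilation_iters, 10)
  expect_equal(cfg$dilation_kernel, 3)
  expect_equal(cfg$blur_kernel, 7)
  expect_equal(cfg$downscale, 4)
  expect_equal(cfg$proximity_cm, 6.0)
  expect_equal(cfg$fps, 60)
  expect_equal(cfg$arena_cm, 32)

  writeLines(c("n_mice = 3", "proximity_cm = 4.5"), path)
  expect_equal(load_config(path)$proximity_cm, 4.5)

  writeLines("n_mice = 0", path)
  expect_error(load_config(path), "config error")
  expect_error(mt_config(), "n_mice")
  expect_error(mt_config(n_mice = 2, blur_kernel = 4), "odd")
  expect_error(mt_config(n_mice = 2, dilation_kernel = 0), "odd")
})

test_that("calibration is a bijection on finite coordinates", {
  set.seed(99)
  for (ppc in c(0.5, 3, 20, 33.75)) {
    cal <- calibration(arena_px = 32 * ppc, arena_cm = 32)
    px <- runif(100, -1e4, 1e4)
    expect_lt(max(abs(cm_to_px(px_to_cm(px, cal), cal) - px)), 1e-9)
    expect_equal(px_to_cm(320, calibration(arena_px = 320)), 32)
  }
})
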