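# Correlogram fingerprints: buffering, pair histogram, dissimilarity.

# build a detection from a full-frame logical mask
region_from_mask <- function(full, frame_index = 0L) {
  idx <- which(full, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  mousetrackr:::mask_region(full[r0:r1, c0:c1, drop = FALSE],
                            offset = c(c0 - 1, r0 - 1),
                            frame_dim = dim(full),
                            frame_index = frame_index)
}

test_that("identity configuration returns the raw masked crop", {
  set.seed(1)
  frame <- matrix(runif(900, 0, 255), 30, 30)
  full <- matrix(FALSE, 30, 30)
  full[10:15, 12:20] <- TRUE
  reg <- region_from_mask(full)
  p <- buffer_and_crop(frame, reg,
                       fingerprint_params(dilation_iters = 0,
                                          blur_kernel = 1, downscale = 1))
  expect_equal(p$patch, frame[10:15, 12:20])
  expect_true(all(p$mask))
})

test_that("buffering strictly grows the support of a 1-px mask", {
  frame <- matrix(100, 41, 41)
  full <- matrix(FALSE, 41, 41)
  full[21, 21] <- TRUE
  reg <- region_from_mask(full)
  p <- buffer_and_crop(frame, reg, fingerprint_params(downscale = 1))
  expect_gt(sum(p$mask), 1)
  # 10 iterations of 3x3 dilation -> 21x21 box; 7x7 blur adds 3 more
  expect_equal(dim(p$mask), c(27, 27))
  expect_true(all(p$mask))
})

test_that("buffered support equals brute-force dilation + blur threshold", {
  set.seed(2)
  sc <- tiny_scene(n_mice = 1, n_frames = 1, seed = 9)
  frame <- render_frame(sc, 0)
  reg <- scene_masks(sc, 1 - 1, rendered_only = TRUE)[[1]]
  fpp <- fingerprint_params(downscale = 1)
  p <- buffer_and_crop(frame, reg, fpp)

  full <- matrix(FALSE, nrow(frame), ncol(frame))
  full[reg$offset[2] + seq_len(nrow(reg$mask)),
       reg$offset[1] + seq_len(ncol(reg$mask))] <- reg$mask
  buf <- full
  for (i in 1:10) buf <- brute_dilate(buf, matrix(1, 3, 3))
  gk <- mousetrackr:::gaussian_kernel(7)
  # blur > 0 on a binary mask grows support by the kernel footprint
  buf <- brute_dilate(buf, (gk > 0) * 1)
  idx <- which(buf, arr.ind = TRUE)
  got <- matrix(FALSE, nrow(frame), ncol(frame))
  got[p$offset[2] + seq_len(nrow(p$mask)),
      p$offset[1] + seq_len(ncol(p$mask))] <- p$mask
  expect_identical(got, buf)
})

test_that("degenerate patches give the zero correlogram", {
  fpp <- fingerprint_params(downscale = 1)
  h <- compute_correlogram(matrix(5, 1, 1), fpp)
  expect_equal(h$total_pairs, 0)
  expect_equal(sum(h$mass), 0)
  expect_equal(dim(h$mass), c(32, 32))
})

test_that("a single pair lands in the hand-computed bin", {
  fpp <- fingerprint_params(downscale = 1)
  patch <- matrix(c(10, 20), 2, 1) # two pixels, d = 1, s = 30
  h <- compute_correlogram(patch, fpp)
  expect_equal(h$total_pairs, 1)
  # d = 1 -> floor(1/64*32) = 0; s = 30 -> floor(30/511*32) = 1
  expect_equal(h$counts[1, 2], 1L)
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$mass[1, 2], 1.0)
})

test_that("correlogram equals the exhaustive double-loop oracle", {
  fpp <- fingerprint_params(downscale = 1)
  set.seed(11)
  for (rep in 1:20) {
    patch <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    mask <- matrix(runif(64) < 0.7, 8, 8)
    h <- compute_correlogram(patch, fpp, mask = mask)
    want <- brute_correlogram_counts(patch, mask, 32, 32, 64)
    expect_identical(unname(h$counts), unname(want))
    k <- sum(mask)
    if (k >= 2) expect_equal(h$total_pairs, k * (k - 1) / 2)
  }
})

test_that("seeded pair subsampling caps the enumeration deterministically", {
  fpp <- fingerprint_params(downscale = 1, max_pairs = 50, seed = 123)
  set.seed(77)
  patch <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  h1 <- compute_correlogram(patch, fpp)
  h2 <- compute_correlogram(patch, fpp)
  expect_equal(h1$total_pairs, 50)
  expect_identical(h1$counts, h2$counts)
})

test_that("dissimilarity is zero at identity, symmetric, and bounded", {
  set.seed(13)
  for (rep in 1:50) {
    a <- matrix(runif(1024), 32, 32); a <- a / sum(a)
    b <- matrix(runif(1024), 32, 32); b <- b / sum(b)
    ha <- raw_correlogram(a); hb <- raw_correlogram(b)
    expect_equal(dissimilarity(ha, ha), 0)
    expect_equal(dissimilarity(ha, hb), dissimilarity(hb, ha))
    expect_lte(dissimilarity(ha, hb), 2 / 1024)
  }
  expect_error(dissimilarity(raw_correlogram(matrix(1, 2, 2)),
                             raw_correlogram(matrix(1, 3, 3))),
               "dimensions")
})

test_that("disjoint one-hot correlograms attain the exact range bound", {
  a <- matrix(0, 32, 32); a[1, 1] <- 1
  b <- matrix(0, 32, 32); b[20, 5] <- 1
  expect_equal(dissimilarity(raw_correlogram(a), raw_correlogram(b)),
               2 / 1024)
})

test_that("correlogram is invariant to translation and 90-degree rotation", {
  fpp <- fingerprint_params(downscale = 1)
  set.seed(17)
  patch <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  mask <- matrix(runif(49) < 0.8, 7, 7)
  h0 <- compute_correlogram(patch, fpp, mask = mask)

  big <- matrix(0, 20, 20); bigm <- matrix(FALSE, 20, 20)
  big[9:15, 4:10] <- patch; bigm[9:15, 4:10] <- mask
  expect_equal(compute_correlogram(big, fpp, mask = bigm)$counts, h0$counts)

  rot <- t(patch)[ncol(patch):1, ] # 90-degree rotation
  rotm <- t(mask)[ncol(mask):1, ]
  expect_equal(compute_correlogram(rot, fpp, mask = rotm)$counts, h0$counts)
})

test_that("fingerprints separate animals with different textures", {
  sc <- tiny_scene(n_mice = 2, n_frames = 12, seed = 21)
  cfg <- tiny_config(2)
  fpp <- mousetrackr:::fp_params_from_config(cfg)
  fps <- lapply(0:11, function(t) {
    regs <- scene_masks(sc, t)
    frame <- render_frame(sc, t)
    # scene_masks returns animals in id order
    lapply(regs, function(r)
      compute_correlogram(buffer_and_crop(frame, r, fpp), fpp))
  })
  same <- c(); diff <- c()
  for (t in 1:11) {
    same <- c(same,
              dissimilarity(fps[[t]][[1]], fps[[t + 1]][[1]]),
              dissimilarity(fps[[t]][[2]], fps[[t + 1]][[2]]))
    diff <- c(diff, dissimilarity(fps[[t]][[1]], fps[[t]][[2]]))
  }
  expect_lt(max(same), min(diff))
})
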