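# Correlogram appearance fingerprints. A detection's mask is "buffered"
# (iterated 3x3 dilation, then Gaussian blur of the mask thresholded at
# > 0) so that the crop keeps a margin of context around the animal; the
# frame is cropped to the buffered support, downscaled by block averaging,
# and every unordered pair of included pixels contributes its Euclidean
# distance d and intensity sum s = I(p) + I(q) to a 2-D histogram. The
# normalized histogram is translation- and 90-degree-rotation-invariant
# and is compared between frames by the mean absolute bin difference.

#' Fingerprint parameters
#'
#' @param dilation_iters Iterations of 3x3-kernel mask dilation for the
#'   buffer (default 10).
#' @param dilation_kernel Square dilation kernel side, odd (default 3).
#' @param blur_kernel Gaussian blur kernel side applied to the mask, odd
#'   (default 7); the blurred mask is thresholded at > 0.
#' @param downscale Integer block-averaging factor before pair enumeration
#'   (default 4, i.e. quarter size).
#' @param n_dist_bins,n_sum_bins Histogram dimensions (default 32 x 32).
#' @param max_dist_px Distance-domain upper edge in (downscaled) pixels;
#'   larger distances overflow into the last bin (default 64).
#' @param max_pairs Optional cap on enumerated pairs; when exceeded, a
#'   seeded uniform subsample of pairs is used (default `Inf`, all pairs).
#' @param seed Seed for the pair subsample (only used when `max_pairs` is
#'   exceeded).
#' @return An object of class `mt_fp_params`.
#' @export
fingerprint_params <- function(dilation_iters = 10, dilation_kernel = 3,
                               blur_kernel = 7, downscale = 4,
                               n_dist_bins = 32, n_sum_bins = 32,
                               max_dist_px = 64, max_pairs = Inf,
                               seed = 1L) {
  stopifnot(dilation_iters >= 0,
            dilation_kernel >= 1, dilation_kernel %% 2 == 1,
            blur_kernel >= 1, blur_kernel %% 2 == 1,
            downscale >= 1, downscale == round(downscale),
            n_dist_bins >= 2, n_sum_bins >= 2, max_dist_px > 0,
            max_pairs > 0)
  structure(list(dilation_iters = as.integer(dilation_iters),
                 dilation_kernel = as.integer(dilation_kernel),
                 blur_kernel = as.integer(blur_kernel),
                 downscale = as.integer(downscale),
                 n_dist_bins = as.integer(n_dist_bins),
                 n_sum_bins = as.integer(n_sum_bins),
                 max_dist_px = max_dist_px, max_pairs = max_pairs,
                 seed = seed),
            class = "mt_fp_params")
}

#' Buffer a detection's mask and crop the frame around it
#'
#' The mask is dilated `dilation_iters` times with the square kernel, then
#' blurred with a Gaussian kernel and thresholded at > 0 (so the support
#' also grows by the blur's half-width). The frame is cropped to the
#' buffered support's bounding box, pixels outside the buffered mask are
#' zeroed and excluded, and the patch is downscaled by block averaging
#' over included pixels.
#'
#' @param frame Numeric matrix `[height x width]` on `[0, 255]` (RGB arrays
#'   are converted with luma weights 0.299/0.587/0.114).
#' @param region An `mt_region` detection lying within the frame.
#' @param params [fingerprint_params()].
#' @return An object of class `mt_patch`: list with `patch` (numeric
#'   matrix, excluded pixels zero), `mask` (logical inclusion matrix),
#'   `offset` (0-based full-resolution origin of the crop) and `scale`.
#' @export
buffer_and_crop <- function(frame, region, params = fingerprint_params()) {
  stopifnot(inherits(region, "mt_region"))
  frame <- to_gray255(frame)
  fd <- dim(frame)
  if (region$area_px == 0) stop("buffer_and_crop: empty mask")
  margin <- params$dilation_iters * (params$dilation_kernel %/% 2) +
    (params$blur_kernel %/% 2)
  x0 <- max(0, region$offset[1] - margin)
  y0 <- max(0, region$offset[2] - margin)
  x1 <- min(fd[2] - 1, region$offset[1] + ncol(region$mask) - 1 + margin)
  y1 <- min(fd[1] - 1, region$offset[2] + nrow(region$mask) - 1 + margin)
  win <- matrix(FALSE, y1 - y0 + 1, x1 - x0 + 1)
  win[(region$offset[2] - y0) + seq_len(nrow(region$mask)),
      (region$offset[1] - x0) + seq_len(ncol(region$mask))] <- region$mask
  buf <- binary_dilate(win, box_kernel(params$dilation_kernel),
                       params$dilation_iters)
  if (params$blur_kernel > 1)
    buf <- blur_zero(buf * 1, gaussian_kernel(params$blur_kernel)) > 1e-12
  # crop to the buffered support's bbox
  idx <- which(buf, arr.ind = TRUE)
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  mask <- buf[r0:r1, c0:c1, drop = FALSE]
  patch <- frame[(y0 + r0):(y0 + r1), (x0 + c0):(x0 + c1), drop = FALSE]
  patch[!mask] <- 0
  f <- params$downscale
  if (f > 1L) {
    ds <- block_average(patch, mask, f)
    patch <- ds$patch; mask <- ds$mask
  }
  structure(list(patch = patch, mask = mask,
                 offset = c(x0 + c0 - 1, y0 + r0 - 1), scale = f),
            class = "mt_patch")
}

# Block-average downscale over included pixels only: a low-res pixel is
# included iff its block contains any included pixel; its intensity is the
# mean of the included pixels in the block.
block_average <- function(patch, mask, f) {
  nr <- nrow(patch); nc <- ncol(patch)
  NR <- ceiling(nr / f); NC <- ceiling(nc / f)
  padr <- NR * f - nr; padc <- NC * f - nc
  if (padr || padc) {
    patch <- rbind(patch, matrix(0, padr, nc))
    mask <- rbind(mask, matrix(FALSE, padr, nc))
    patch <- cbind(patch, matrix(0, NR * f, padc))
    mask <- cbind(mask, matrix(FALSE, NR * f, padc))
  }
  bi <- (seq_len(NR * f) - 1L) %/% f            # block row of each row
  bj <- (seq_len(NC * f) - 1L) %/% f
  gsum <- function(m) {
    t(rowsum(t(rowsum(m * 1, bi, reorder = TRUE)), bj, reorder = TRUE))
  }
  cnt <- gsum(mask)
  tot <- gsum(patch * mask)
  keep <- cnt > 0
  out <- matrix(0, NR, NC)
  out[keep] <- tot[keep] / cnt[keep]
  list(patch = out, mask = keep)
}

#' Compute a correlogram fingerprint from a masked patch
#'
#' Enumerates every unordered pair of included pixels; each pair
#' contributes one count at bin
#' `(min(floor(d / max_dist_px * n_dist_bins), n_dist_bins - 1),
#'   floor(s / 511 * n_sum_bins))` where `d` is the Euclidean pair distance
#' and `s = I(p) + I(q)`. Counts are normalized to unit total mass so
#' patches of different sizes are comparable. Fewer than two included
#' pixels yield the zero correlogram with `total_pairs = 0`.
#'
#' @param patch An `mt_patch` from [buffer_and_crop()], or a plain numeric
#'   matrix (then `mask` defaults to all pixels, or pass `mask`).
#' @param params [fingerprint_params()].
#' @param mask Optional logical inclusion matrix for plain-matrix input.
#' @return An object of class `mt_correlogram`: list with `mass`
#'   (normalized matrix), `counts` (integer matrix), `total_pairs`, and the
#'   binning parameters.
#' @export
compute_correlogram <- function(patch, params = fingerprint_params(),
                                mask = NULL) {
  if (inherits(patch, "mt_patch")) {
    mask <- patch$mask
    patch <- patch$patch
  } else if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(patch), ncol(patch))
  }
  nd <- params$n_dist_bins; ns <- params$n_sum_bins
  idx <- which(mask, arr.ind = TRUE)
  k <- nrow(idx)
  if (k < 2L) {
    return(structure(
      list(mass = matrix(0, nd, ns), counts = matrix(0L, nd, ns),
           total_pairs = 0L, n_dist_bins = nd, n_sum_bins = ns,
           max_dist_px = params$max_dist_px),
      class = "mt_correlogram"))
  }
  xs <- as.numeric(idx[, 2] - 1)
  ys <- as.numeric(idx[, 1] - 1)
  iv <- patch[mask]
  npairs <- k * (k - 1) / 2
  if (is.finite(params$max_pairs) && npairs > params$max_pairs) {
    counts <- subsampled_pair_counts(xs, ys, iv, params)
    total <- sum(counts)
  } else {
    counts <- corr_pair_counts(xs, ys, iv, nd, ns, params$max_dist_px)
    total <- npairs
  }
  structure(
    list(mass = counts / total, counts = counts, total_pairs = total,
         n_dist_bins = nd, n_sum_bins = ns,
         max_dist_px = params$max_dist_px),
    class = "mt_correlogram")
}

# Seeded uniform subsample of unordered pairs, binned in vectorized R.
# The RNG state of the caller is left untouched.
subsampled_pair_counts <- function(xs, ys, iv, params) {
  k <- length(xs)
  npairs <- k * (k - 1) / 2
  m <- as.integer(params$max_pairs)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)
  sel <- sample(npairs, m) - 1  # 0-based linear pair index
  # invert the (j < i) column-major pair ordering used by dist():
  # pair t (0-based) -> j = smallest col with cum pairs > t
  csum <- cumsum((k - 1):1)
  jj <- findInterval(sel, c(0, csum), rightmost.closed = FALSE)  # 1-based col
  off <- sel - c(0, csum)[jj]
  ii <- jj + 1 + off
  d <- sqrt((xs[ii] - xs[jj])^2 + (ys[ii] - ys[jj])^2)
  s <- iv[ii] + iv[jj]
  nd <- params$n_dist_bins; ns <- params$n_sum_bins
  db <- pmin(floor(d / params$max_dist_px * nd), nd - 1)
  sb <- pmin(floor(s / 511 * ns), ns - 1)
  matrix(tabulate(db * ns + sb + 1, nbins = nd * ns),
         nrow = nd, ncol = ns, byrow = TRUE)
}

#' @export
print.mt_correlogram <- function(x, ...) {
  cat(sprintf("Correlogram: %d x %d bins, %d pairs\n",
              x$n_dist_bins, x$n_sum_bins, x$total_pairs))
  invisible(x)
}

#' Mean absolute difference between two correlograms
#'
#' The appearance dissimilarity used for identity assignment: the mean over
#' all bins of the absolute mass difference. Symmetric; zero iff the
#' histograms are equal; at most `2 / (n_dist_bins * n_sum_bins)` for
#' normalized inputs.
#'
#' @param a,b `mt_correlogram` objects of equal dimensions.
#' @return A single non-negative number.
#' @export
dissimilarity <- function(a, b) {
  stopifnot(inherits(a, "mt_correlogram"), inherits(b, "mt_correlogram"))
  if (a$n_dist_bins != b$n_dist_bins || a$n_sum_bins != b$n_sum_bins)
    stop("dissimilarity: correlogram dimensions differ")
  mean(abs(a$mass - b$mass))
}

# Fingerprint a detection in one call.
region_fingerprint <- function(frame, region, params) {
  compute_correlogram(buffer_and_crop(frame, region, params), params)
}
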