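# Internal raster helpers built on EBImage: structuring elements, binary
# dilation, Gaussian blur with zero boundary, and 8-connected labeling
# (EBImage::bwlabel is 4-connected; diagonally touching labels are merged
# with a union-find pass).

disk_kernel <- function(r) {
  r <- as.integer(round(r))
  if (r <= 0) return(matrix(1, 1, 1))
  off <- -r:r
  k <- outer(off, off, function(dy, dx) as.numeric(dx * dx + dy * dy <= r * r))
  k
}

box_kernel <- function(k) matrix(1, k, k)

# Separable Gaussian kernel of odd size k; sigma follows the common
# image-processing default tied to kernel size.
gaussian_kernel <- function(k, sigma = 0.3 * ((k - 1) * 0.5 - 1) + 0.8) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1) return(matrix(1, 1, 1))
  off <- -(k %/% 2):(k %/% 2)
  g1 <- exp(-off^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  outer(g1, g1)
}

binary_dilate <- function(mask, kern, iters = 1L) {
  m <- mask * 1
  if (iters < 1L || all(dim(kern) == 1L)) return(m > 0)
  for (i in seq_len(iters)) m <- EBImage::dilate(m, kern)
  as.matrix(m) > 0
}

blur_zero <- function(m, kern) {
  as.matrix(EBImage::filter2(m, kern, boundary = 0))
}

# 8-connected labeling: 4-connected bwlabel, then merge labels that touch
# diagonally. Labels are renumbered 1..k in order of first appearance in
# column-major scan for determinism.
label8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  k <- max(lab)
  if (k <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  # renumber roots by first appearance
  remap <- integer(k)
  nz <- lab > 0
  first_lab <- roots[lab[nz]]
  uniq <- unique(first_lab)
  remap[uniq] <- seq_along(uniq)
  lab[nz] <- remap[first_lab]
  lab
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
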