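# Ramer-Douglas-Peucker simplification of closed contours. The closed
# polygon is split at its two mutually farthest vertices and each open
# chain is simplified by the classic recursion: find the interior vertex
# farthest (perpendicular distance) from the endpoint chord; if it exceeds
# epsilon, keep it and recurse on both halves, else drop the interior.
# Simplification is done on vertex *indices*, so output vertices appear in
# their original order.

# Perpendicular distance from points p (n x 2) to the infinite line through
# a and b; plain Euclidean distance to a when a == b.
perp_dist <- function(p, a, b) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / len
}

# Indices (into pts) kept by RDP on the open chain pts[idx, ]; endpoints
# always kept. Iterative stack to avoid deep recursion.
rdp_open_keep <- function(pts, idx, epsilon) {
  keep <- c(idx[1], idx[length(idx)])
  stack <- list(idx)
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(seg) <= 2L) next
    interior <- seg[-c(1L, length(seg))]
    d <- perp_dist(pts[interior, , drop = FALSE],
                   pts[seg[1], ], pts[seg[length(seg)], ])
    imax <- which.max(d)
    if (d[imax] > epsilon) {
      split_at <- which(seg == interior[imax])
      keep <- c(keep, interior[imax])
      stack[[length(stack) + 1L]] <- seg[1:split_at]
      stack[[length(stack) + 1L]] <- seg[split_at:length(seg)]
    }
  }
  sort(unique(keep))
}

#' Simplify a closed polygon with Ramer-Douglas-Peucker
#'
#' Splits the closed contour at its two mutually farthest vertices (first
#' such pair in scan order on ties), simplifies each open chain with the
#' classic recursion at tolerance `epsilon`, and returns the kept vertices
#' in their original order. Every discarded vertex lies within `epsilon` of
#' the simplified chain. A fully collinear polygon degenerates to its two
#' extreme vertices, flagged with attribute `degenerate = TRUE`.
#'
#' @param poly Numeric `n x 2` matrix of vertices (columns x, y), `n >= 3`,
#'   closed implicitly.
#' @param epsilon Tolerance in the same units as the vertices
#'   (default 1.5 px).
#' @return The simplified vertex matrix, rows a subset of the input rows in
#'   input order.
#' @examples
#' sq <- cbind(c(0, 1, 2, 2, 0), c(0, 0, 0, 2, 2))
#' simplify_rdp(sq, 0.5) # collinear (1,0) removed
#' @export
simplify_rdp <- function(poly, epsilon = 1.5) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3, epsilon >= 0)
  n <- nrow(poly)
  # farthest vertex pair (i < j), first in scan order on exact ties
  d2 <- as.matrix(stats::dist(poly))^2
  best <- c(1L, 2L); bestd <- -1
  for (i in 1:(n - 1)) {
    j <- which.max(d2[i, (i + 1):n]) + i
    if (d2[i, j] > bestd) {
      bestd <- d2[i, j]
      best <- c(i, j)
    }
  }
  i <- best[1]; j <- best[2]
  # degenerate: all vertices collinear with the extreme chord
  dev <- perp_dist(poly, poly[i, ], poly[j, ])
  if (max(dev) < 1e-12) {
    out <- poly[c(i, j), , drop = FALSE]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  chain1 <- i:j
  chain2 <- c(j:n, 1:i)
  keep <- sort(unique(c(
    rdp_open_keep(poly, chain1, epsilon),
    rdp_open_keep(poly, chain2, epsilon)
  )))
  poly[keep, , drop = FALSE]
}
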