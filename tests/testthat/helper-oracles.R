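# Brute-force oracles, independent of the package's implementations:
# direct set definitions with explicit loops, used to validate morphology,
# labelling, boundary tracing and morphometry.

# pixel value with out-of-raster treated as `outside`
px_at <- function(a, r, c, outside = FALSE) {
  if (r < 1 || r > nrow(a) || c < 1 || c > ncol(a)) outside else a[r, c]
}

# erosion by definition: out[r,c] = TRUE iff every TRUE offset of b maps
# to a foreground pixel (outside the raster counts as background)
oracle_erode <- function(a, b) {
  d <- dim(b)
  ctr <- (d + 1L) %/% 2L
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    ok <- TRUE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (b[i, j] && !px_at(a, r + i - ctr[1], c + j - ctr[2])) {
        ok <- FALSE
        break
      }
    }
    out[r, c] <- ok
  }
  out
}

# dilation by definition: union of translates of a by the offsets of b
oracle_dilate <- function(a, b) {
  d <- dim(b)
  ctr <- (d + 1L) %/% 2L
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    hit <- FALSE
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (b[i, j] && px_at(a, r - (i - ctr[1]), c - (j - ctr[2]))) {
        hit <- TRUE
        break
      }
    }
    out[r, c] <- hit
  }
  out
}

oracle_open <- function(a, b) oracle_dilate(oracle_erode(a, b), b)

# 180-degree rotation of a structuring element (for the duality check)
reflect_se <- function(b) b[rev(seq_len(nrow(b))), rev(seq_len(ncol(b))), drop = FALSE]

# connected-component labelling by the classic two-pass row-scan with
# union-find label merging, machinery disjoint from the package's
# frontier BFS
oracle_label <- function(a, connectivity = 8) {
  nr <- nrow(a)
  nc <- ncol(a)
  prev <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0), c(-1, 0, 1, -1))  # NW, N, NE, W
  } else {
    cbind(c(-1, 0), c(0, -1))  # N, W
  }
  parent <- integer(0)
  find_root <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  lab <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!a[r, c]) next
    nb <- integer(0)
    for (j in seq_len(nrow(prev))) {
      rr <- r + prev[j, 1]
      cc <- c + prev[j, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && lab[rr, cc] > 0L) {
        nb <- c(nb, lab[rr, cc])
      }
    }
    if (length(nb) == 0) {
      parent <- c(parent, length(parent) + 1L)
      lab[r, c] <- length(parent)
    } else {
      roots <- unique(vapply(nb, find_root, integer(1)))
      lab[r, c] <- min(roots)
      for (x in roots) parent[x] <- min(roots)
    }
  }
  roots <- vapply(seq_along(parent), find_root, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  lab[lab > 0L] <- relabel[lab[lab > 0L]]
  lab
}

# edge pixels by brute force. `exposure = 4`: foreground pixels with at
# least one background (or out-of-raster) 4-neighbour — exactly the set a
# backtrack-anchored Moore walk visits. `exposure = 8`: at least one
# background pixel anywhere in the r = 1 Moore neighbourhood — a superset
# that additionally contains concave corners whose only background
# contact is diagonal, which no ring-scan contour can enter.
oracle_edge_pixels <- function(a, exposure = 4) {
  nb <- if (exposure == 4) {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  } else {
    cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, , drop = FALSE]
  }
  out <- NULL
  for (r in seq_len(nrow(a))) for (c in seq_len(ncol(a))) {
    if (!a[r, c]) next
    edge <- FALSE
    for (j in seq_len(nrow(nb))) {
      if (!px_at(a, r + nb[j, 1], c + nb[j, 2])) edge <- TRUE
    }
    if (edge) out <- rbind(out, c(r, c))
  }
  out
}

# canonical form of a pixel set for set-equality assertions
pixel_set <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(character(0))
  sort(unique(paste(m[, 1], m[, 2], sep = ",")))
}

# digitized disk: pixel-centre membership, the renderer's image model
digitized_disk <- function(nr, nc, cr, cc, rad) {
  outer((seq_len(nr) - cr)^2, (seq_len(nc) - cc)^2, `+`) <= rad^2
}

# seeded random mask, optionally cleaned by an opening (oracle path so
# boundary-module inputs do not depend on the code under test)
random_mask <- function(nr = 32, nc = 32, p = 0.45, opened = TRUE) {
  a <- matrix(stats::runif(nr * nc) < p, nr, nc)
  if (opened) a <- oracle_open(a, matrix(TRUE, 3, 3))
  a
}

# closed-form least squares for the trend oracle
oracle_polyfit <- function(t, y, degree = 2) {
  X <- outer(t, 0:degree, `^`)
  drop(solve(t(X) %*% X, t(X) %*% y))
}
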