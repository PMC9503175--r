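# Moore-neighbour boundary tracing with Jacob's stopping criterion.
#
# Conventions: 1-based (row, col) coordinates, rows increasing downward.
# The traversal is clockwise; the neighbourhood scan is anchored at the
# backtrack pixel (the background pixel examined immediately before the
# current contour pixel was found). Objects are 8-connected throughout.

# clockwise r = 1 Moore ring starting at the west neighbour
MOORE_CW <- cbind(
  dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
  dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
)

#' Moore neighbourhood of a pixel
#'
#' All pixels within Chebyshev distance `r` of the centre, excluding the
#' centre itself: `(2r+1)^2 - 1` coordinates. For `r = 1` the 8 neighbours
#' are returned in the fixed clockwise order used by the tracer, starting
#' from the west neighbour; for larger `r` the ring is returned in
#' row-major order.
#'
#' @param center Integer `c(row, col)`.
#' @param r Neighbourhood range in pixels (>= 1).
#' @return Integer matrix with columns `row`, `col`.
#' @examples
#' nrow(moore_neighbours(c(5, 5), 1))  # 8
#' nrow(moore_neighbours(c(5, 5), 2))  # 24
#' @export
moore_neighbours <- function(center, r = 1) {
  if (r < 1) stop("r must be >= 1")
  r <- as.integer(r)
  center <- as.integer(center)
  if (r == 1L) {
    out <- cbind(row = center[1] + MOORE_CW[, "dr"],
                 col = center[2] + MOORE_CW[, "dc"])
    return(out)
  }
  g <- expand.grid(dc = -r:r, dr = -r:r)  # row-major: row varies slowest
  keep <- !(g$dr == 0L & g$dc == 0L)
  cbind(row = center[1] + g$dr[keep], col = center[2] + g$dc[keep])
}

#' Find the tracing start pixel
#'
#' Scans the mask in row-major order (top-left origin, left to right
#' within a row) and returns the first foreground pixel together with the
#' implied entry: the scan reaches each pixel from the west, and the west
#' neighbour of the first foreground pixel is always background.
#'
#' @param mask Logical matrix.
#' @return `NULL` for an all-background mask, otherwise a list with
#'   `start = c(row, col)` and `backtrack = c(row, col)` (the west
#'   neighbour, possibly outside the raster).
#' @export
find_start <- function(mask) {
  mask <- check_mask(mask)
  fg <- which(t(mask))
  if (length(fg) == 0) return(NULL)
  nc <- ncol(mask)
  r <- ((fg[1] - 1L) %/% nc) + 1L
  cc <- ((fg[1] - 1L) %% nc) + 1L
  list(start = c(r, cc), backtrack = c(r, cc - 1L))
}

mask_at <- function(mask, r, c) {
  r >= 1L && r <= nrow(mask) && c >= 1L && c <= ncol(mask) && mask[r, c]
}

#' Trace the external boundary of one object
#'
#' Clockwise Moore-neighbour tracing: from the current contour pixel, the
#' r = 1 Moore neighbourhood is scanned clockwise beginning at the
#' backtrack pixel; the first foreground pixel found becomes the next
#' contour pixel and the background pixel examined just before it becomes
#' the new backtrack. Tracing terminates by Jacob's stopping criterion:
#' the walk stops when the start pixel is entered a second time the same
#' way it was entered initially (same backtrack pixel), which prevents
#' premature stops on contours that touch themselves. A single isolated
#' pixel yields a one-pixel closed boundary.
#'
#' The traced pixel set is exactly the component's pixels with at least
#' one background 4-neighbour (side exposure). Concave-corner pixels
#' whose only background contact is diagonal are never entered by a
#' backtrack-anchored ring scan, in whichever rotation it is started, so
#' they are interior to the walk; every traced pixel does have a
#' background pixel somewhere in its Moore neighbourhood.
#'
#' @param mask Logical matrix, `TRUE` = foreground.
#' @param start Integer `c(row, col)` of a foreground pixel, normally from
#'   [find_start()].
#' @param backtrack Integer `c(row, col)` of the background pixel the start
#'   was entered from (default: its west neighbour).
#' @param component_id Identifier stored on the result.
#' @return A `drop_boundary`: list with `pixels` (ordered n x 2 matrix of
#'   contour coordinates, closed cyclically), `component_id`, `closed`.
#' @export
trace_boundary <- function(mask, start, backtrack = start - c(0L, 1L),
                           component_id = 1L) {
  mask <- check_mask(mask)
  start <- as.integer(start)
  backtrack <- as.integer(backtrack)
  if (!mask_at(mask, start[1], start[2])) stop("start pixel is not foreground")

  # direction index (1..8 into MOORE_CW) from pixel p to adjacent pixel q
  dir_of <- function(p, q) {
    d <- q - p
    which(MOORE_CW[, "dr"] == d[1] & MOORE_CW[, "dc"] == d[2])
  }

  pixels <- matrix(0L, 64L, 2L)
  pixels[1L, ] <- start
  n <- 1L
  p <- start
  b <- backtrack
  b0 <- backtrack
  max_steps <- 8L * (sum(mask) + 2L) + 8L

  for (step in seq_len(max_steps)) {
    d0 <- dir_of(p, b)
    found <- FALSE
    last_bg <- b
    for (i in 0:7) {
      k <- ((d0 - 1L + i) %% 8L) + 1L
      cand <- p + c(MOORE_CW[k, "dr"], MOORE_CW[k, "dc"])
      if (mask_at(mask, cand[1], cand[2])) {
        found <- TRUE
        break
      }
      last_bg <- cand
    }
    if (!found) break  # isolated single pixel
    if (all(cand == start) && all(last_bg == b0)) break  # Jacob
    if (n == nrow(pixels)) pixels <- rbind(pixels, matrix(0L, n, 2L))
    n <- n + 1L
    pixels[n, ] <- cand
    p <- cand
    b <- last_bg
  }

  structure(
    list(pixels = pixels[seq_len(n), , drop = FALSE],
         component_id = component_id, closed = TRUE),
    class = "drop_boundary"
  )
}

#' @export
print.drop_boundary <- function(x, ...) {
  cat(sprintf("<drop_boundary #%s> %d contour pixels%s\n",
              format(x$component_id), nrow(x$pixels),
              if (isTRUE(x$closed)) " (closed)" else ""))
  invisible(x)
}

#' Trace the external boundary of every object in a mask
#'
#' Labels the 8-connected components of the mask and traces each one once,
#' starting from its first pixel in row-major scan order (entered from the
#' west). Only external boundaries are produced; holes inside objects are
#' ignored. Output order is first-encounter scan order.
#'
#' @param mask Logical matrix.
#' @return List of `drop_boundary` objects, one per component.
#' @export
find_all_boundaries <- function(mask) {
  lab <- label_components(mask, connectivity = 8)
  k <- max(lab)
  if (k == 0L) return(list())
  nc <- ncol(mask)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    comp <- lab == i
    fg <- which(t(comp))
    r <- ((fg[1] - 1L) %/% nc) + 1L
    cc <- ((fg[1] - 1L) %% nc) + 1L
    out[[i]] <- trace_boundary(comp, c(r, cc), component_id = i)
  }
  out
}
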