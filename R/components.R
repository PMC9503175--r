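# Connected-component labelling and size-based filtering.
# Flood fill with a vectorized frontier (whole BFS layers at a time), so
# cost scales with droplet area and boundary length, not raster area.

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 0L, 0L, 1L), dc = c(0L, -1L, 1L, 0L))
  } else {
    cbind(dr = rep(-1L:1L, each = 3L), dc = rep(-1L:1L, 3L))[-5L, , drop = FALSE]
  }
}

# linear (column-major) indices of the connected component of `mask`
# containing linear index `seed`
flood_fill <- function(mask, seed, connectivity = 8L) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  off <- neighbour_offsets(connectivity)
  seen <- logical(nr * nc)
  seen[seed] <- TRUE
  frontier <- seed
  pixels <- seed
  while (length(frontier) > 0) {
    r <- ((frontier - 1L) %% nr) + 1L
    cc <- ((frontier - 1L) %/% nr) + 1L
    nxt <- integer(0)
    for (j in seq_len(nrow(off))) {
      rr <- r + off[j, 1]
      c2 <- cc + off[j, 2]
      ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
      cand <- (c2[ok] - 1L) * nr + rr[ok]
      nxt <- c(nxt, cand[mask[cand] & !seen[cand]])
    }
    nxt <- unique(nxt)
    seen[nxt] <- TRUE
    pixels <- c(pixels, nxt)
    frontier <- nxt
  }
  pixels
}

#' Label connected components of a binary mask
#'
#' @param a Logical matrix, `TRUE` = foreground.
#' @param connectivity 4 or 8 (default 8, consistent with the Moore
#'   neighbourhood used for boundary tracing).
#' @return Integer matrix: 0 for background, 1..k for the k components,
#'   numbered in row-major first-encounter order.
#' @export
label_components <- function(a, connectivity = 8) {
  a <- check_mask(a)
  connectivity <- as.integer(match.arg(as.character(connectivity), c("8", "4")))
  nr <- nrow(a)
  nc <- ncol(a)
  lab <- integer(nr * nc)
  # foreground in row-major scan order, as column-major linear indices
  fg_rm <- which(t(a))
  if (length(fg_rm) == 0) return(matrix(lab, nr, nc))
  r <- ((fg_rm - 1L) %/% nc) + 1L
  cc <- ((fg_rm - 1L) %% nc) + 1L
  fg <- (cc - 1L) * nr + r
  k <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    k <- k + 1L
    lab[flood_fill(a, seed, connectivity)] <- k
  }
  matrix(lab, nr, nc)
}

#' Remove small objects from a binary mask
#'
#' Clears every connected component whose pixel count is strictly below
#' `min_area`; larger components are untouched. This is the size-based
#' noise filter that follows morphological opening: specks from debris
#' and stray water particles survive thresholding but fall below the size
#' of a real droplet.
#'
#' @param a Logical matrix, `TRUE` = foreground.
#' @param min_area Minimum pixel count to keep (components of exactly
#'   `min_area` pixels are kept).
#' @param connectivity 4 or 8 (default 8).
#' @return Filtered logical mask.
#' @examples
#' a <- matrix(FALSE, 8, 8); a[2:5, 2:5] <- TRUE; a[8, 8] <- TRUE
#' sum(remove_small_objects(a, min_area = 5))  # 16: the speck is gone
#' @export
remove_small_objects <- function(a, min_area = 25, connectivity = 8) {
  if (min_area < 1) stop("min_area must be >= 1")
  lab <- label_components(a, connectivity)
  if (max(lab) == 0L) return(a)
  sizes <- tabulate(lab)
  keep <- sizes >= min_area
  out <- a
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}
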