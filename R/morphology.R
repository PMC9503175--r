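#' Structuring elements for binary morphology
#'
#' Builds the boolean stencil used by [erode()], [dilate()] and [opening()].
#' The origin is the central element and must be part of the stencil; side
#' lengths must be odd so the origin is well defined.
#'
#' @param size Side length in pixels (odd integer), or a 2-vector
#'   `c(rows, cols)` of odd integers.
#' @param shape `"square"` (all elements on) or `"cross"` (the 4-connected
#'   plus shape).
#' @return A logical matrix of class `struct_elem` with `TRUE` at member
#'   offsets and the origin at its centre.
#' @examples
#' struct_elem(3)            # 3 x 3 full square (the pipeline default)
#' struct_elem(3, "cross")
#' @export
struct_elem <- function(size = 3, shape = c("square", "cross")) {
  shape <- match.arg(shape)
  if (length(size) == 1) size <- c(size, size)
  size <- as.integer(size)
  if (any(size < 1) || any(size %% 2 == 0)) {
    stop("structuring element sides must be odd and >= 1")
  }
  m <- matrix(TRUE, size[1], size[2])
  if (shape == "cross") {
    cr <- (size[1] + 1L) %/% 2L
    cc <- (size[2] + 1L) %/% 2L
    m[] <- FALSE
    m[cr, ] <- TRUE
    m[, cc] <- TRUE
  }
  structure(m, class = c("struct_elem", "matrix", "array"))
}

# validate a structuring element supplied by the user; accepts a plain
# logical matrix with odd sides and a TRUE origin
as_struct_elem <- function(b) {
  if (is.numeric(b) && length(b) == 1) return(struct_elem(b))
  b <- as.matrix(b)
  storage.mode(b) <- "logical"
  d <- dim(b)
  if (any(d %% 2 == 0)) stop("structuring element sides must be odd")
  if (!b[(d[1] + 1L) %/% 2L, (d[2] + 1L) %/% 2L]) {
    stop("structuring element origin must be TRUE")
  }
  b
}

# offsets (dr, dc) of the TRUE elements of a structuring element,
# relative to its centre
se_offsets <- function(b) {
  d <- dim(b)
  idx <- which(b, arr.ind = TRUE)
  cbind(idx[, 1] - (d[1] + 1L) %/% 2L, idx[, 2] - (d[2] + 1L) %/% 2L)
}

# shift a logical matrix by (dr, dc), padding with `fill`;
# out[r, c] == a[r + dr, c + dc] where defined
shift_mask <- function(a, dr, dc, fill = FALSE) {
  nr <- nrow(a)
  nc <- ncol(a)
  out <- matrix(fill, nr, nc)
  r_dst <- max(1L, 1L - dr):min(nr, nr - dr)
  c_dst <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(r_dst) < 1 || length(c_dst) < 1 || r_dst[1] > r_dst[length(r_dst)]) {
    return(out)
  }
  out[r_dst, c_dst] <- a[r_dst + dr, c_dst + dc]
  out
}

check_mask <- function(a) {
  if (!is.matrix(a) || !is.logical(a)) stop("mask must be a logical matrix")
  if (anyNA(a)) stop("mask must not contain NA")
  a
}

#' Binary erosion, dilation and opening
#'
#' From-scratch implementations of the three morphological operators on
#' logical masks. Pixels outside the raster are treated as background:
#' they can veto an erosion but never contribute to a dilation. `opening()`
#' is erosion followed by dilation with the same element and is the noise
#' suppressor used between thresholding and size filtering.
#'
#' @param a Logical matrix, `TRUE` = foreground.
#' @param b Structuring element (see [struct_elem()]); a single odd integer
#'   is promoted to a full square.
#' @return Logical matrix of the same dimensions.
#' @examples
#' a <- matrix(FALSE, 12, 12); a[4:9, 4:9] <- TRUE
#' identical(opening(a, struct_elem(3)), a)  # solid square survives opening
#' @export
erode <- function(a, b = struct_elem(3)) {
  a <- check_mask(a)
  b <- as_struct_elem(b)
  off <- se_offsets(b)
  out <- matrix(TRUE, nrow(a), ncol(a))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mask(a, off[i, 1], off[i, 2], fill = FALSE)
  }
  out
}

#' @rdname erode
#' @export
dilate <- function(a, b = struct_elem(3)) {
  a <- check_mask(a)
  b <- as_struct_elem(b)
  off <- se_offsets(b)
  out <- matrix(FALSE, nrow(a), ncol(a))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(a, -off[i, 1], -off[i, 2], fill = FALSE)
  }
  out
}

#' @rdname erode
#' @export
opening <- function(a, b = struct_elem(3)) {
  dilate(erode(a, b), b)
}
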