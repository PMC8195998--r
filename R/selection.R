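# Reciprocity between image space and phasor space: polygon gating of the
# phasor plot to voxel masks, and image-mask restriction of phasor
# histograms.

#' Polygon region of interest on the phasor plot
#'
#' @param vertices Two-column numeric matrix (or data frame) of `(G, S)`
#'   vertices, in drawing order, at least 3 and with nonzero area.
#' @param name Label for the selection.
#' @param color Display tag (any R color) used by pseudocolor renders.
#' @return An object of class `phasor_polygon`.
#' @export
phasor_polygon <- function(vertices, name = "roi", color = "red") {
  vertices <- as.matrix(vertices)
  stopifnot(is.numeric(vertices), ncol(vertices) == 2L)
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  x <- vertices[, 1L]; y <- vertices[, 2L]
  area2 <- sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)
  if (abs(area2) <= 1e-12) stop("degenerate polygon: zero area")
  colnames(vertices) <- c("G", "S")
  structure(list(vertices = vertices, name = name, color = color),
            class = "phasor_polygon")
}

#' Even-odd point-in-polygon test (boundary-inclusive)
#'
#' Ray-casting with the even-odd rule; points exactly on an edge or vertex
#' count as inside (polygons are drawn around clusters, so boundary points
#' belong to the selection).
#'
#' @param px,py Point coordinates (vectors).
#' @param vx,vy Polygon vertex coordinates.
#' @param eps Absolute tolerance for the boundary test.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, vx, vy, eps = 1e-12) {
  stopifnot(length(px) == length(py), length(vx) == length(vy),
            length(vx) >= 3L)
  n <- length(px)
  inside <- logical(n)
  on_edge <- logical(n)
  nv <- length(vx)
  j <- nv
  for (i in seq_len(nv)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary: zero cross product and within the edge's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    scale <- max(abs(x2 - x1), abs(y2 - y1), 1)
    on_edge <- on_edge | (abs(cross) <= eps * scale &
                            px >= min(x1, x2) - eps & px <= max(x1, x2) + eps &
                            py >= min(y1, y2) - eps & py <= max(y1, y2) + eps)
    # even-odd crossing of the rightward ray (half-open in y)
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside | on_edge
}

#' Select image voxels by a phasor-plot polygon
#'
#' The reciprocity principle, phasor-to-image direction: the mask is true
#' where a voxel's unjittered `(G, S)` lies inside or on the polygon.
#' Invalid voxels are never selected, and display jitter never affects
#' selection.
#'
#' @param f A [phasor_field()].
#' @param poly A [phasor_polygon()].
#' @return Logical 3-D array (a voxel mask).
#' @export
select_by_polygon <- function(f, poly) {
  stopifnot(inherits(f, "phasor_field"), inherits(poly, "phasor_polygon"))
  mask <- array(FALSE, dim = f$shape)
  idx <- which(f$valid)
  if (length(idx)) {
    mask[idx] <- point_in_polygon(f$G[idx], f$S[idx],
                                  poly$vertices[, 1L], poly$vertices[, 2L])
  }
  mask
}

#' Phasor histogram restricted to an image mask
#'
#' The reciprocity principle, image-to-phasor direction: bins only the
#' masked valid voxels.
#'
#' @param f A [phasor_field()].
#' @param image_mask Logical array matching the field shape.
#' @param jitter_halfwidth,seed,bins As in [phasor_histogram()].
#' @return A [phasor_histogram()].
#' @export
histogram_from_mask <- function(f, image_mask, jitter_halfwidth = 0.02,
                                seed = 1L, bins = 256L) {
  phasor_histogram(f, jitter_halfwidth = jitter_halfwidth, seed = seed,
                   mask = image_mask, bins = bins)
}

#' Pseudocolor voxels by phasor-polygon membership
#'
#' Labels each valid voxel with the first polygon (in list order) whose
#' region contains its `(G, S)`; list order is the explicit precedence
#' rule for overlapping polygons.  The render is a maximum-intensity
#' projection along z in which selected voxels take their polygon's color
#' modulated by intensity and unselected voxels stay grayscale.
#'
#' @param f A [phasor_field()].
#' @param polygons List of [phasor_polygon()]s with distinct colors.
#' @param intensity 3-D array modulating the render (e.g. `I_total`).
#' @return List with `label` (integer array, 0 = unselected, `NA`
#'   invalid) and `rgb` (ny x nx x 3 array in `[0, 1]`, the z-MIP render).
#' @export
masked_pseudocolor <- function(f, polygons, intensity) {
  stopifnot(inherits(f, "phasor_field"), is.list(polygons),
            length(polygons) >= 1L,
            is.array(intensity), identical(dim(intensity), f$shape))
  cols <- vapply(polygons, `[[`, character(1), "color")
  if (anyDuplicated(cols))
    stop("polygons must carry pairwise distinct display colors")
  label <- array(0L, dim = f$shape)
  for (i in rev(seq_along(polygons))) {  # first in list wins
    m <- select_by_polygon(f, polygons[[i]])
    label[m] <- i
  }
  label[!f$valid] <- NA_integer_
  inten <- intensity / max(intensity, 1e-12)
  rgb_cols <- grDevices::col2rgb(cols) / 255
  ny <- f$shape[2L]; nx <- f$shape[3L]
  out <- array(0, dim = c(ny, nx, 3L))
  lab0 <- label
  lab0[is.na(lab0)] <- 0L
  for (ch in 1:3) {
    w <- array(0, dim = f$shape)
    gray <- lab0 == 0L
    w[gray] <- inten[gray]  # grayscale outside all polygons
    for (i in seq_along(polygons)) {
      sel <- lab0 == i
      w[sel] <- inten[sel] * rgb_cols[ch, i]
    }
    out[, , ch] <- apply(w, c(2L, 3L), max)
  }
  list(label = label, rgb = pmin(pmax(out, 0), 1))
}
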