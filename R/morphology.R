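## Binary morphology on 0/1 matrices.
##
## Masks are integer matrices with values 0/1; row index = y (down),
## column index = x (right). Pixels outside the image are background.

#' Structuring element
#'
#' Builds a flat, origin-centred structuring element for [dilate()] and
#' [erode()].
#'
#' @param shape `"disk"` (pixels with `dx^2 + dy^2 <= r^2`) or `"square"`
#'   (full `(2r+1) x (2r+1)` block).
#' @param radius integer radius / half-width in pixels (>= 0).
#' @return An object of class `"vb_se"`: a two-column integer matrix of
#'   `(dy, dx)` offsets relative to the origin.
#' @examples
#' struct_element("disk", 2)
#' @export
struct_element <- function(shape = c("disk", "square"), radius = 1L) {
  shape <- match.arg(shape)
  radius <- as.integer(radius)
  if (radius < 0) stop_field("radius", "must be >= 0")
  g <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  if (shape == "disk") g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  se <- as.matrix(g)
  storage.mode(se) <- "integer"
  attr(se, "shape") <- shape
  attr(se, "radius") <- radius
  class(se) <- c("vb_se", class(se))
  se
}

se_offsets <- function(se) {
  if (!inherits(se, "vb_se")) stop("expected a structuring element from struct_element()", call. = FALSE)
  se
}

#' Binary dilation
#'
#' Dilation by a structuring element B: a pixel z belongs to the output iff
#' the reflection of B translated to z hits the foreground set A. Equivalently
#' the output is the union of A translated by every offset of B.
#'
#' @param mask 0/1 matrix.
#' @param se structuring element from [struct_element()].
#' @return 0/1 integer matrix of the same shape.
#' @seealso [erode()]
#' @export
dilate <- function(mask, se) {
  m <- as_mask(mask)
  off <- se_offsets(se)
  out <- matrix(0L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mat(m, off[i, "dy"], off[i, "dx"])
  }
  as_mask(out * 1L)
}

#' Binary erosion
#'
#' Standard fit-condition erosion: a pixel z is kept iff B translated to z
#' lies entirely inside the foreground set A (pixels outside the image count
#' as background). This is the complement-dual of [dilate()].
#'
#' @inheritParams dilate
#' @return 0/1 integer matrix of the same shape.
#' @export
erode <- function(mask, se) {
  m <- as_mask(mask)
  off <- se_offsets(se)
  out <- matrix(1L, nrow(m), ncol(m))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mat(m, -off[i, "dy"], -off[i, "dx"])
  }
  as_mask(out * 1L)
}

#' Morphological closing (dilation followed by erosion)
#' @inheritParams dilate
#' @export
morph_close <- function(mask, se) erode(dilate(mask, se), se)

#' Morphological opening (erosion followed by dilation)
#' @inheritParams dilate
#' @export
morph_open <- function(mask, se) dilate(erode(mask, se), se)

# Connected-component labelling via the pixel-adjacency graph.
# Foreground components use 8-connectivity by default; holes are labelled on
# the background with 4-connectivity (the Jordan-consistent pairing).
# Labels are assigned in raster-scan order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  m <- as_mask(mask)
  h <- nrow(m); w <- ncol(m)
  idx <- which(m == 1L)                     # column-major linear indices
  lab <- matrix(0L, h, w)
  if (length(idx) == 0) return(lab)
  inset <- logical(h * w); inset[idx] <- TRUE
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  edge_from <- integer(0); edge_to <- integer(0)
  neigh <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) neigh <- c(neigh, list(c(1L, 1L), c(-1L, 1L)))
  for (d in neigh) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    j <- (c2[ok] - 1L) * h + r2[ok]
    keep <- inset[j]
    edge_from <- c(edge_from, idx[ok][keep])
    edge_to <- c(edge_to, j[keep])
  }
  vmap <- integer(h * w); vmap[idx] <- seq_along(idx)
  g <- igraph::graph_from_edgelist(
    cbind(vmap[edge_from], vmap[edge_to]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(idx)]
  # relabel so component 1 is the first in raster (column-major) order
  first_seen <- !duplicated(comp)
  relab <- integer(max(comp)); relab[comp[first_seen]] <- seq_len(sum(first_seen))
  lab[idx] <- relab[comp]
  lab
}

#' Fill holes
#'
#' Background regions (4-connected) not reachable from the image border are
#' turned into foreground.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix.
#' @export
fill_holes <- function(mask) {
  m <- as_mask(mask)
  bg <- 1L - m
  lab <- label_components(bg, connectivity = 4L)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0]
  hole <- lab > 0 & !(lab %in% border_labs)
  as_mask((m | hole) * 1L)
}

#' Remove components touching the image border
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix with every 8-connected component that has at
#'   least one border pixel removed.
#' @export
clear_border <- function(mask) {
  m <- as_mask(mask)
  lab <- label_components(m, connectivity = 8L)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0]
  m[lab %in% border_labs] <- 0L
  as_mask(m)
}
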