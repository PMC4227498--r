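## Interface surface extraction: the oriented triangle set bounding a
## region (faces owned by exactly one element of the region, kept in the
## owner's outward ordering, so normals point out of the region).

#' Extract the closed boundary surface of a region
#'
#' @param mesh a `head_mesh`.
#' @param region one or more region labels; their union is bounded.
#' @param require_closed error (reporting the offending edges) if the
#'   extracted surface is not a closed 2-manifold.
#' @return An object of class `interface_surface`: list with `tris`
#'   (t x 3 node indices into `mesh$nodes`, outward orientation) and
#'   `region`.
#' @export
extract_region_surface <- function(mesh, region, require_closed = TRUE) {
  sel <- which(mesh$region %in% region)
  if (!length(sel)) stop("region not found: ", paste(region, collapse = ", "))
  tris <- boundary_faces(mesh, sel)
  surf <- structure(list(tris = tris, region = region), class = "interface_surface")
  if (require_closed) {
    bad <- open_edges(surf)
    if (nrow(bad))
      stop("surface of region '", paste(region, collapse = "+"),
           "' is not closed; ", nrow(bad), " offending edge(s), first: ",
           bad[1, 1], "-", bad[1, 2])
  }
  surf
}

## Edges not shared by exactly two triangles.
open_edges <- function(surface) {
  tr <- surface$tris
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
  key <- paste(lo, hi)
  cnt <- table(key)
  unique(cbind(lo, hi)[cnt[key] != 2L, , drop = FALSE])
}

#' Is a surface a closed 2-manifold?
#' @param surface an `interface_surface`.
#' @return `TRUE` if every edge is shared by exactly two triangles.
#' @export
surface_is_closed <- function(surface) nrow(open_edges(surface)) == 0L

#' Euler characteristic of a triangle surface
#'
#' V - E + F; equals 2 per spherical shell (4 for an annular region whose
#' boundary is two nested shells).
#' @param surface an `interface_surface`.
#' @return integer Euler characteristic.
#' @export
surface_euler <- function(surface) {
  tr <- surface$tris
  v <- length(unique(as.vector(tr)))
  e <- rbind(tr[, c(1L, 2L)], tr[, c(2L, 3L)], tr[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  v - nrow(e) + nrow(tr)
}

#' Total area of a triangle surface
#' @param surface an `interface_surface`.
#' @param coords node coordinates (defaults required; pass `mesh$nodes`).
#' @return total area (m^2).
#' @export
surface_area <- function(surface, coords) {
  tr <- surface$tris
  a <- coords[tr[, 1L], , drop = FALSE]
  b <- coords[tr[, 2L], , drop = FALSE]
  c_ <- coords[tr[, 3L], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
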