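## Core tetrahedral mesh container and primitives.
## A head_mesh is a plain list: nodes (n x 3, metres), elems (m x 4 node
## indices, positively oriented), region (character, length m). All
## geometry is SI; the coordinate convention is x anterior, y left,
## z superior, origin at the head centroid.

#' Construct a tetrahedral mesh object
#'
#' @param nodes numeric matrix, n x 3 node coordinates (m).
#' @param elems integer matrix, m x 4 node indices (1-based). Elements are
#'   reoriented to positive signed volume.
#' @param region character vector of per-element region labels (length m,
#'   recycled if length 1).
#' @param validate check invariants (positive volumes, index range).
#' @return An object of class `head_mesh`.
#' @export
head_mesh <- function(nodes, elems, region = "body", validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  dimnames(nodes) <- NULL
  dimnames(elems) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(elems) != 4L) stop("elems must be an m x 4 matrix")
  region <- rep_len(as.character(region), nrow(elems))
  if (nrow(elems) > 0L) {
    if (min(elems) < 1L || max(elems) > nrow(nodes))
      stop("element node indices out of range")
    v <- tet_volumes(nodes, elems)
    neg <- which(v < 0)
    if (length(neg)) { # swap two nodes to flip orientation
      elems[neg, c(3L, 4L)] <- elems[neg, c(4L, 3L)]
      v[neg] <- -v[neg]
    }
    if (validate && any(v <= 0))
      stop("degenerate element(s) with zero volume: ",
           paste(utils::head(which(v <= 0), 5L), collapse = ", "))
  }
  structure(list(nodes = nodes, elems = elems, region = region),
            class = "head_mesh")
}

#' @export
print.head_mesh <- function(x, ...) {
  cat("head_mesh:", nrow(x$nodes), "nodes,", nrow(x$elems), "tetrahedra\n")
  tab <- table(x$region)
  for (r in names(tab)) cat(sprintf("  %-14s %6d elements\n", r, tab[[r]]))
  v <- tet_volumes(x$nodes, x$elems)
  cat(sprintf("  total volume %.4g m^3, min element volume %.3g m^3\n",
              sum(v), if (length(v)) min(v) else NA_real_))
  invisible(x)
}

#' Signed volumes of tetrahedra
#'
#' @param nodes n x 3 coordinate matrix.
#' @param elems m x 4 index matrix.
#' @return Numeric vector of signed volumes (m^3).
#' @export
tet_volumes <- function(nodes, elems) {
  if (nrow(elems) == 0L) return(numeric(0))
  a <- nodes[elems[, 1L], , drop = FALSE]
  b <- nodes[elems[, 2L], , drop = FALSE] - a
  c_ <- nodes[elems[, 3L], , drop = FALSE] - a
  d <- nodes[elems[, 4L], , drop = FALSE] - a
  # det[b c d] / 6 via scalar triple product
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

#' Element centroids
#' @param mesh a `head_mesh`.
#' @return m x 3 matrix of tetrahedron centroids.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elems[, 1L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 2L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 3L], , drop = FALSE] +
   mesh$nodes[mesh$elems[, 4L], , drop = FALSE]) / 4
}

## The four faces of tet (n1,n2,n3,n4), ordered so each face normal points
## outward of the tetrahedron when the tet has positive orientation.
tet_face_index <- rbind(c(2L, 3L, 4L), c(1L, 4L, 3L), c(1L, 2L, 4L), c(1L, 3L, 2L))

## All element faces as an (4m x 3) matrix of node indices (owner order).
all_faces <- function(elems) {
  m <- nrow(elems)
  f <- matrix(0L, 4L * m, 3L)
  for (k in 1:4) f[seq_len(m) + (k - 1L) * m, ] <- elems[, tet_face_index[k, ], drop = FALSE]
  f
}

face_keys <- function(faces) {
  s <- t(apply(faces, 1L, sort.int))
  paste(s[, 1L], s[, 2L], s[, 3L], sep = ".")
}

## Unique undirected edges of the mesh, as a 2-column index matrix.
mesh_edges <- function(elems) {
  pairs <- rbind(elems[, c(1L, 2L)], elems[, c(1L, 3L)], elems[, c(1L, 4L)],
                 elems[, c(2L, 3L)], elems[, c(2L, 4L)], elems[, c(3L, 4L)])
  lo <- pmin(pairs[, 1L], pairs[, 2L]); hi <- pmax(pairs[, 1L], pairs[, 2L])
  unique(cbind(lo, hi))
}

#' Boundary faces of a mesh or element subset
#'
#' Faces owned by exactly one element of the subset, in outward orientation.
#' @param mesh a `head_mesh`.
#' @param elem_subset integer indices of elements (default all).
#' @return t x 3 matrix of node indices (outward normal ordering).
#' @export
boundary_faces <- function(mesh, elem_subset = seq_len(nrow(mesh$elems))) {
  el <- mesh$elems[elem_subset, , drop = FALSE]
  f <- all_faces(el)
  k <- face_keys(f)
  cnt <- table(k)
  f[cnt[k] == 1L, , drop = FALSE]
}

#' Nodes on the outer boundary of the whole mesh
#' @param mesh a `head_mesh`.
#' @return integer vector of node indices.
#' @export
boundary_nodes <- function(mesh) sort(unique(as.vector(boundary_faces(mesh))))

#' Nodes shared by two or more region labels (tissue interfaces)
#' @param mesh a `head_mesh`.
#' @return integer vector of node indices.
#' @export
interface_nodes <- function(mesh) {
  regs <- unique(mesh$region)
  if (length(regs) < 2L) return(integer(0))
  seen <- matrix(FALSE, nrow(mesh$nodes), length(regs))
  for (j in seq_along(regs)) {
    idx <- unique(as.vector(mesh$elems[mesh$region == regs[j], , drop = FALSE]))
    seen[idx, j] <- TRUE
  }
  which(rowSums(seen) >= 2L)
}

#' Structured tetrahedral block mesh
#'
#' A rectangular block subdivided into nx x ny x nz cells, each cell split
#' into 6 tetrahedra (Kuhn subdivision; conforming across cells). Used for
#' patch tests and as a smoothing-test substrate.
#'
#' @param nx,ny,nz cell counts per axis.
#' @param size length-3 block edge lengths (m).
#' @param origin length-3 lower corner.
#' @param region region label.
#' @return A `head_mesh`.
#' @export
tet_block_mesh <- function(nx = 4L, ny = 4L, nz = 4L, size = c(1, 1, 1),
                           origin = c(0, 0, 0), region = "block") {
  xs <- seq(0, size[1], length.out = nx + 1L) + origin[1]
  ys <- seq(0, size[2], length.out = ny + 1L) + origin[2]
  zs <- seq(0, size[3], length.out = nz + 1L) + origin[3]
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (nx + 1L) * (j - 1L) + (nx + 1L) * (ny + 1L) * (k - 1L)
  # Kuhn: 6 tets around the main diagonal c000 -> c111 of each cell
  paths <- list(c(1L, 2L, 4L, 8L), c(1L, 2L, 6L, 8L), c(1L, 3L, 4L, 8L),
                c(1L, 3L, 7L, 8L), c(1L, 5L, 6L, 8L), c(1L, 5L, 7L, 8L))
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  corner <- function(ci, cj, ck, c8) {
    di <- c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L)[c8]
    dj <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)[c8]
    dk <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)[c8]
    nid(ci + di, cj + dj, ck + dk)
  }
  elems <- do.call(rbind, lapply(paths, function(p)
    cbind(corner(cells$i, cells$j, cells$k, p[1]),
          corner(cells$i, cells$j, cells$k, p[2]),
          corner(cells$i, cells$j, cells$k, p[3]),
          corner(cells$i, cells$j, cells$k, p[4]))))
  head_mesh(nodes, elems, region)
}

#' Triangulated sphere surface (subdivided icosahedron)
#'
#' @param radius sphere radius (m).
#' @param level subdivision level (0 = icosahedron, each level quadruples
#'   the triangle count).
#' @return list with `verts` (v x 3) and `tris` (t x 3, outward oriented).
#' @export
icosphere <- function(radius = 1, level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  storage.mode(f) <- "integer"
  for (lv in seq_len(level)) {
    nv <- nrow(v); nf <- nrow(f)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
    key <- lo + hi * (nv + 1)
    ukey <- unique(key)
    mid_id <- nv + match(key, ukey)
    ue <- cbind(lo, hi)[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1L], m12, m31), cbind(f[, 2L], m23, m12),
               cbind(f[, 3L], m31, m23), cbind(m12, m23, m31))
    storage.mode(f) <- "integer"
  }
  list(verts = v * radius, tris = f)
}
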