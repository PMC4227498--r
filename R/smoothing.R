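## Mesh smoothing: uniform-weight Laplacian relaxation and a local
## optimization pass that maximises the worst incident dihedral angle.
## Both preserve topology (node/element counts, region labels) and hold
## boundary and tissue-interface nodes fixed when locked; any relocation
## that would produce a non-positively-oriented element is rejected.

## Apply a proposed node relocation, reverting nodes whose incident
## elements would invert, until the mesh is valid (Jacobi update with
## inversion guard).
guarded_move <- function(mesh, proposed, movable) {
  node_elem <- elements_by_node(mesh)
  cur <- mesh$nodes
  cur[movable, ] <- proposed[movable, , drop = FALSE]
  repeat {
    v <- tet_volumes(cur, mesh$elems)
    bad <- which(v <= 0)
    if (!length(bad)) break
    revert <- intersect(unique(as.vector(mesh$elems[bad, , drop = FALSE])), movable)
    if (!length(revert)) stop("inversion guard failed on locked nodes")
    cur[revert, ] <- mesh$nodes[revert, , drop = FALSE]
    movable <- setdiff(movable, revert)
  }
  mesh$nodes <- cur
  mesh
}

elements_by_node <- function(mesh) {
  n <- nrow(mesh$nodes)
  idx <- as.vector(mesh$elems)
  eid <- rep(seq_len(nrow(mesh$elems)), times = 4L)
  split(eid, factor(idx, levels = seq_len(n)))
}

smoothing_free_nodes <- function(mesh, lock_boundary) {
  if (!lock_boundary) return(seq_len(nrow(mesh$nodes)))
  setdiff(seq_len(nrow(mesh$nodes)),
          union(boundary_nodes(mesh), interface_nodes(mesh)))
}

#' Laplacian mesh smoothing
#'
#' Moves each free node toward the centroid of its edge-connected
#' neighbours (uniform weights). Boundary and tissue-interface nodes are
#' locked when `lock_boundary` is `TRUE`; moves that would invert an
#' element are rejected for the offending nodes.
#'
#' @param mesh a `head_mesh`.
#' @param iterations number of smoothing sweeps.
#' @param lock_boundary keep boundary/interface nodes fixed.
#' @param relax under-relaxation factor in (0, 1].
#' @return The smoothed `head_mesh` (same topology and labels).
#' @export
laplacian_smooth <- function(mesh, iterations = 1L, lock_boundary = TRUE,
                             relax = 1) {
  free <- smoothing_free_nodes(mesh, lock_boundary)
  if (!length(free) || nrow(mesh$elems) == 0L) return(mesh)
  ed <- mesh_edges(mesh$elems)
  both <- rbind(ed, ed[, c(2L, 1L)])
  n <- nrow(mesh$nodes)
  deg <- tabulate(both[, 1L], nbins = n)
  for (it in seq_len(iterations)) {
    sums <- rowsum(mesh$nodes[both[, 2L], , drop = FALSE],
                   group = both[, 1L], reorder = TRUE)
    have <- as.integer(rownames(sums))
    cent <- mesh$nodes
    cent[have, ] <- sums / deg[have]
    prop <- mesh$nodes + relax * (cent - mesh$nodes)
    mesh <- guarded_move(mesh, prop, free)
  }
  mesh
}

## Worst (minimum) dihedral angle among the given elements for a candidate
## position of one node.
local_min_dihedral <- function(nodes, elems) {
  v <- tet_volumes(nodes, elems)
  if (any(v <= 0)) return(-Inf)
  sub <- head_mesh(nodes, elems, validate = FALSE)
  min(quality_report(sub)$min_dihedral)
}

#' Optimization-based mesh smoothing
#'
#' For each free node in turn, searches a shrinking pattern of candidate
#' positions (neighbour centroid direction plus axis offsets) and accepts
#' the candidate that most improves the worst dihedral angle of the
#' incident elements; non-improving moves are rejected, so the global
#' minimum dihedral angle never decreases.
#'
#' @param mesh a `head_mesh`.
#' @param passes number of sweeps over the free nodes.
#' @param lock_boundary keep boundary/interface nodes fixed.
#' @param step initial search step as a fraction of the local mean edge.
#' @return The smoothed `head_mesh`.
#' @export
optimization_smooth <- function(mesh, passes = 1L, lock_boundary = TRUE,
                                step = 0.25) {
  free <- smoothing_free_nodes(mesh, lock_boundary)
  if (!length(free) || nrow(mesh$elems) == 0L) return(mesh)
  node_elem <- elements_by_node(mesh)
  ed <- mesh_edges(mesh$elems)
  both <- rbind(ed, ed[, c(2L, 1L)])
  nbrs <- split(both[, 2L], factor(both[, 1L], levels = seq_len(nrow(mesh$nodes))))
  offsets <- rbind(c(0, 0, 0), diag(3), -diag(3))
  for (p in seq_len(passes)) {
    for (i in free) {
      els <- node_elem[[i]]
      if (!length(els)) next
      sube <- mesh$elems[els, , drop = FALSE]
      nb <- nbrs[[i]]
      hloc <- mean(sqrt(rowSums((mesh$nodes[nb, , drop = FALSE] -
        matrix(mesh$nodes[i, ], length(nb), 3L, byrow = TRUE))^2)))
      best <- local_min_dihedral(mesh$nodes, sube)
      best_x <- mesh$nodes[i, ]
      cen_dir <- colMeans(mesh$nodes[nb, , drop = FALSE]) - mesh$nodes[i, ]
      s <- step * hloc
      while (s > 0.02 * hloc) {
        here <- matrix(mesh$nodes[i, ], nrow(offsets), 3L, byrow = TRUE)
        cand <- rbind(here + s * offsets,
                      mesh$nodes[i, ] + s * cen_dir / max(sqrt(sum(cen_dir^2)), 1e-30))
        improved <- FALSE
        for (k in seq_len(nrow(cand))) {
          trial <- mesh$nodes
          trial[i, ] <- cand[k, ]
          q <- local_min_dihedral(trial, sube)
          if (q > best + 1e-10) { best <- q; best_x <- cand[k, ]; improved <- TRUE }
        }
        if (improved) {
          mesh$nodes[i, ] <- best_x
        } else s <- s / 2
      }
    }
  }
  mesh
}
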