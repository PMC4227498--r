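## Mesh quality audit. Aspect ratio is circumradius / (3 * inradius),
## which equals 1 for the regular tetrahedron (the ratio R/r is minimised
## at 3); the max/min edge ratio is reported as a secondary metric.

#' Audit tetrahedral mesh quality
#'
#' Computes per-element aspect ratio (circumradius over three times the
#' inradius), minimum and maximum dihedral angles, edge-length statistics,
#' and counts of elements violating quality thresholds.
#'
#' @param mesh a `head_mesh`.
#' @param ar_threshold aspect ratio above which an element is flagged.
#' @param dihedral_min_threshold minimum dihedral angle (degrees) below
#'   which an element is flagged.
#' @return An object of class `mesh_quality`: list with per-element
#'   vectors `aspect_ratio`, `min_dihedral`, `max_dihedral`, `edge_ratio`,
#'   scalars `edge_mean`, `edge_min`, `edge_max`, and flag counts.
#' @export
quality_report <- function(mesh, ar_threshold = 5, dihedral_min_threshold = 10) {
  m <- nrow(mesh$elems)
  if (m == 0L) stop("empty mesh")
  p <- lapply(1:4, function(k) mesh$nodes[mesh$elems[, k], , drop = FALSE])
  a <- p[[2]] - p[[1]]; b <- p[[3]] - p[[1]]; c_ <- p[[4]] - p[[1]]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  dot <- function(u, v) rowSums(u * v)
  nrm <- function(u) sqrt(rowSums(u^2))
  vol6 <- dot(a, cross(b, c_))                      # 6V > 0 by construction
  # circumcentre offset: (|a|^2 (b x c) + |b|^2 (c x a) + |c|^2 (a x b)) / (2 a.(b x c))
  o <- (cross(b, c_) * dot(a, a) + cross(c_, a) * dot(b, b) +
        cross(a, b) * dot(c_, c_)) / (2 * vol6)
  circum <- nrm(o)
  areas <- cbind(nrm(cross(b - a, c_ - a)), nrm(cross(b, c_)),
                 nrm(cross(c_, a)), nrm(cross(a, b))) / 2
  inr <- (vol6 / 6) * 3 / rowSums(areas)            # r = 3V / sum(face areas)
  aspect <- circum / (3 * inr)

  # dihedral angle at each of the 6 edges: pi - angle between the outward
  # normals of the two faces sharing the edge
  fn <- list(cross(p[[3]] - p[[2]], p[[4]] - p[[2]]),  # face (2,3,4)
             cross(p[[4]] - p[[1]], p[[3]] - p[[1]]),  # face (1,4,3)
             cross(p[[2]] - p[[1]], p[[4]] - p[[1]]),  # face (1,2,4)
             cross(p[[3]] - p[[1]], p[[2]] - p[[1]]))  # face (1,3,2)
  fn <- lapply(fn, function(n) n / nrm(n))
  edge_faces <- rbind(c(3, 4), c(2, 4), c(2, 3), c(1, 4), c(1, 3), c(1, 2))
  dih <- matrix(0, m, 6L)
  for (e in 1:6) {
    cs <- pmin(1, pmax(-1, dot(fn[[edge_faces[e, 1]]], fn[[edge_faces[e, 2]]])))
    dih[, e] <- 180 - acos(cs) * 180 / pi
  }
  edges <- cbind(nrm(a), nrm(b), nrm(c_), nrm(p[[3]] - p[[2]]),
                 nrm(p[[4]] - p[[2]]), nrm(p[[4]] - p[[3]]))
  min_dih <- apply(dih, 1L, min); max_dih <- apply(dih, 1L, max)
  structure(list(
    aspect_ratio = aspect,
    min_dihedral = min_dih,
    max_dihedral = max_dih,
    edge_ratio = apply(edges, 1L, max) / apply(edges, 1L, min),
    edge_mean = mean(edges), edge_min = min(edges), edge_max = max(edges),
    n_flagged_aspect = sum(aspect > ar_threshold),
    n_flagged_dihedral = sum(min_dih < dihedral_min_threshold),
    ar_threshold = ar_threshold,
    dihedral_min_threshold = dihedral_min_threshold,
    n_elements = m), class = "mesh_quality")
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat("mesh quality over", x$n_elements, "tetrahedra\n")
  cat(sprintf("  aspect ratio   mean %.3f  max %.3f  (> %.3g flagged: %d)\n",
              mean(x$aspect_ratio), max(x$aspect_ratio), x$ar_threshold,
              x$n_flagged_aspect))
  cat(sprintf("  dihedral (deg) min %.2f  max %.2f  (< %.3g flagged: %d)\n",
              min(x$min_dihedral), max(x$max_dihedral),
              x$dihedral_min_threshold, x$n_flagged_dihedral))
  cat(sprintf("  edge length (m) min %.4g  mean %.4g  max %.4g\n",
              x$edge_min, x$edge_mean, x$edge_max))
  invisible(x)
}
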