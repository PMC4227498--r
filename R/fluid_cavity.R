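## Surface-based hydrostatic fluid cavity for the CSF. The cavity is the
## closed oriented boundary surface of the fluid region; its volume comes
## from the divergence theorem, a single uniform pressure follows the
## linearised compressible law p = K_f (V0 - V) / V0, and the nodal
## coupling forces are the exact gradient of the pressure-volume
## potential, so fluid work equals -p dV and the coupling is conservative.

#' Construct a fluid cavity
#'
#' @param surface an `interface_surface` oriented outward from the fluid.
#' @param coords reference node coordinates (n x 3).
#' @param bulk_modulus fluid bulk stiffness K_f (Pa). The default is the
#'   bulk modulus of water; a numerically softened value (e.g. 2.19e7)
#'   admits larger stable time steps.
#' @return An object of class `fluid_cavity` with fields `surface`,
#'   `V0` (reference volume, m^3), `Kf` (Pa).
#' @export
fluid_cavity <- function(surface, coords, bulk_modulus = 2.19e9) {
  if (!surface_is_closed(surface)) stop("cavity surface must be closed")
  V0 <- cavity_volume(surface, coords)
  if (V0 <= 0) stop("cavity reference volume must be positive")
  structure(list(surface = surface, V0 = V0, Kf = bulk_modulus),
            class = "fluid_cavity")
}

#' Enclosed volume of a closed oriented surface
#'
#' Divergence-theorem volume V = (1/6) sum over triangles of
#' x1 . (x2 x x3); translation-invariant for closed surfaces. For the
#' boundary of an annular region (two nested shells) the result is the
#' annulus volume.
#'
#' @param surface an `interface_surface` (outward orientation).
#' @param coords node coordinates (n x 3).
#' @return volume (m^3).
#' @export
cavity_volume <- function(surface, coords) {
  tr <- surface$tris
  x1 <- coords[tr[, 1L], , drop = FALSE]
  x2 <- coords[tr[, 2L], , drop = FALSE]
  x3 <- coords[tr[, 3L], , drop = FALSE]
  sum(x1[, 1] * (x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2]) -
      x1[, 2] * (x2[, 1] * x3[, 3] - x2[, 3] * x3[, 1]) +
      x1[, 3] * (x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])) / 6
}

#' Uniform cavity pressure from current volume
#'
#' Linearised compressible hydrostatic law: p = K_f (V0 - V) / V0.
#' Compression (V < V0) gives positive pressure; expansion gives tension
#' (no cavitation clamp by default).
#'
#' @param V current cavity volume (m^3).
#' @param cavity a `fluid_cavity`.
#' @param p_cavitation optional lower pressure bound (Pa); `NULL` disables
#'   the clamp.
#' @return pressure (Pa).
#' @export
cavity_pressure <- function(V, cavity, p_cavitation = NULL) {
  p <- cavity$Kf * (cavity$V0 - V) / cavity$V0
  if (!is.null(p_cavitation)) p <- max(p, p_cavitation)
  p
}

#' Nodal coupling forces exerted by the cavity fluid
#'
#' The force on each surface node is p times the exact gradient of the
#' enclosed volume with respect to that node's position (for the triangle
#' (x1,x2,x3): dV/dx1 = (x2 x x3)/6, cyclic). Summed over a closed
#' surface this equals the p*A*n/3 per-triangle lumping and the net force
#' vanishes identically.
#'
#' @param cavity a `fluid_cavity`.
#' @param coords current node coordinates (n x 3).
#' @param p cavity pressure (Pa); computed from the current volume when
#'   `NULL`.
#' @return n x 3 matrix of nodal forces (N); rows of non-surface nodes are
#'   zero.
#' @export
cavity_nodal_forces <- function(cavity, coords, p = NULL) {
  if (is.null(p)) p <- cavity_pressure(cavity_volume(cavity$surface, coords), cavity)
  tr <- cavity$surface$tris
  x1 <- coords[tr[, 1L], , drop = FALSE]
  x2 <- coords[tr[, 2L], , drop = FALSE]
  x3 <- coords[tr[, 3L], , drop = FALSE]
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  f <- matrix(0, nrow(coords), 3L)
  add <- function(f, idx, contrib) {
    s <- rowsum(contrib, group = idx, reorder = TRUE)
    ids <- as.integer(rownames(s))
    f[ids, ] <- f[ids, , drop = FALSE] + s
    f
  }
  f <- add(f, tr[, 1L], p * cross(x2, x3) / 6)
  f <- add(f, tr[, 2L], p * cross(x3, x1) / 6)
  f <- add(f, tr[, 3L], p * cross(x1, x2) / 6)
  f
}

#' Elastic energy stored in the cavity fluid
#' @param V current volume (m^3).
#' @param cavity a `fluid_cavity`.
#' @return potential energy K_f (V0-V)^2 / (2 V0) in joules.
#' @export
cavity_energy <- function(V, cavity) cavity$Kf * (cavity$V0 - V)^2 / (2 * cavity$V0)
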