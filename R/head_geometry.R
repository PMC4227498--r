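## Parametric layered head geometry: nested tri-axial ellipsoidal shells
## (brain with labeled subregions, CSF gap, skull, optional soft tissue)
## meshed deterministically by radial extrusion of a subdivided-icosahedron
## direction lattice. Concentric shells stand in for the segmented anatomy;
## the construction is watertight and layer interfaces are exact shared
## node sheets, so region surfaces extract as closed 2-manifolds.

#' Configuration for the parametric head geometry
#'
#' @param brain_semiaxes length-3 brain ellipsoid semi-axes (m), order
#'   (anterior x, lateral y, superior z).
#' @param csf_thickness subarachnoid CSF gap thickness (m).
#' @param skull_thickness skull shell thickness (m).
#' @param scalp_thickness optional outer soft-tissue layer thickness (m);
#'   0 disables the layer.
#' @param edge_length target element edge length (m).
#' @param skull_layers radial element layers through the skull.
#' @param include_brainstem label an inferior-central brain wedge as
#'   brainstem (otherwise it is merged with cerebellum/white matter).
#' @param foramen_magnum carve a circular opening in the inferior skull.
#' @param fm_radius foramen magnum radius (m).
#' @param jitter relative interior-node jitter (fraction of local edge
#'   length) used to exercise the smoothers; 0 = deterministic mesh.
#' @param seed RNG seed for the jitter.
#' @return object of class `head_config`.
#' @export
head_config <- function(brain_semiaxes = c(0.085, 0.065, 0.060),
                        csf_thickness = 0.003,
                        skull_thickness = 0.007,
                        scalp_thickness = 0,
                        edge_length = 0.008,
                        skull_layers = 1L,
                        include_brainstem = FALSE,
                        foramen_magnum = FALSE,
                        fm_radius = 0.008,
                        jitter = 0,
                        seed = 1L) {
  cfg <- list(brain_semiaxes = as.numeric(brain_semiaxes),
              csf_thickness = csf_thickness,
              skull_thickness = skull_thickness,
              scalp_thickness = scalp_thickness,
              edge_length = edge_length,
              skull_layers = as.integer(skull_layers),
              include_brainstem = isTRUE(include_brainstem),
              foramen_magnum = isTRUE(foramen_magnum),
              fm_radius = fm_radius,
              jitter = jitter, seed = as.integer(seed))
  if (length(cfg$brain_semiaxes) != 3L || any(cfg$brain_semiaxes <= 0))
    stop("brain_semiaxes must be 3 positive lengths")
  if (cfg$csf_thickness <= 0) stop("csf_thickness must be > 0")
  if (cfg$skull_thickness <= 0) stop("skull_thickness must be > 0")
  if (cfg$scalp_thickness < 0) stop("scalp_thickness must be >= 0")
  if (cfg$edge_length <= 0) stop("edge_length must be > 0")
  if (cfg$skull_layers < 1L) stop("skull_layers must be >= 1")
  structure(cfg, class = "head_config")
}

## Radius of the ellipsoid with semi-axes ax along unit directions u.
ellipsoid_radius <- function(u, ax) {
  1 / sqrt((u[, 1] / ax[1])^2 + (u[, 2] / ax[2])^2 + (u[, 3] / ax[3])^2)
}

## Split a triangular prism (bottom b, top t, bottom global ids sorted
## ascending) into 3 tets whose quad-face diagonals run from the largest
## bottom id to the smallest top id; neighbouring prisms therefore agree
## on shared quads and the layer stitching is conforming.
prism_tets <- function(bot, top) {
  o <- t(apply(bot, 1L, order))
  n <- nrow(bot)
  b0 <- bot[cbind(seq_len(n), o[, 1L])]; t0 <- top[cbind(seq_len(n), o[, 1L])]
  b1 <- bot[cbind(seq_len(n), o[, 2L])]; t1 <- top[cbind(seq_len(n), o[, 2L])]
  b2 <- bot[cbind(seq_len(n), o[, 3L])]; t2 <- top[cbind(seq_len(n), o[, 3L])]
  rbind(cbind(b0, b1, b2, t0), cbind(b1, b2, t0, t1), cbind(b2, t0, t1, t2))
}

#' Build the parametric layered head mesh
#'
#' Generates the nested brain / CSF-gap / skull (/ soft tissue) tetrahedral
#' mesh. Brain elements are sub-labeled `gray_matter` (outer shell),
#' `white_matter` (deep), `cerebellum` (posterior-inferior fossa) and
#' optionally `brainstem`, so that pressure probes and NDT columns can be
#' placed anatomically. The CSF gap is meshed as one radial element layer
#' tagged `csf` for cavity extraction.
#'
#' @param config a [head_config()].
#' @return A `head_mesh` with attribute `config`.
#' @export
build_head_mesh <- function(config = head_config()) {
  if (!inherits(config, "head_config")) config <- do.call(head_config, config)
  ax <- config$brain_semiaxes
  tg <- config$csf_thickness; ts <- config$skull_thickness
  tp <- config$scalp_thickness
  h <- config$edge_length
  r_ref <- mean(ax) + tg + ts + tp
  level <- max(1L, round(log2(1.0515 * r_ref / h)))
  ico <- icosphere(1, level)
  u <- ico$verts; tris <- ico$tris
  nv <- nrow(u)

  r_brain <- ellipsoid_radius(u, ax)
  r_csf <- ellipsoid_radius(u, ax + tg)
  r_skull <- ellipsoid_radius(u, ax + tg + ts)
  r_scalp <- if (tp > 0) ellipsoid_radius(u, ax + tg + ts + tp) else NULL

  n_b <- max(2L, round(mean(r_brain) / h))
  shell_radii <- vector("list", 0L)
  shell_region <- character(0)           # region of layer BELOW each shell
  for (j in seq_len(n_b)) {
    shell_radii[[length(shell_radii) + 1L]] <- r_brain * j / n_b
    shell_region <- c(shell_region, "brain")
  }
  shell_radii[[length(shell_radii) + 1L]] <- r_csf
  shell_region <- c(shell_region, "csf")
  for (j in seq_len(config$skull_layers)) {
    shell_radii[[length(shell_radii) + 1L]] <-
      r_csf + (r_skull - r_csf) * j / config$skull_layers
    shell_region <- c(shell_region, "skull")
  }
  if (tp > 0) {
    shell_radii[[length(shell_radii) + 1L]] <- r_scalp
    shell_region <- c(shell_region, "soft_tissue")
  }
  nshell <- length(shell_radii)

  nodes <- matrix(0, 1L + nshell * nv, 3L)     # node 1 = centre
  for (s in seq_len(nshell))
    nodes[1L + (s - 1L) * nv + seq_len(nv), ] <- u * shell_radii[[s]]

  sid <- function(s) 1L + (s - 1L) * nv        # index offset of shell s
  elems <- matrix(0L, 0L, 4L)
  region <- character(0)
  # centre fan
  fan <- cbind(1L, tris[, 1L] + sid(1L), tris[, 2L] + sid(1L), tris[, 3L] + sid(1L))
  elems <- rbind(elems, fan); region <- c(region, rep("brain", nrow(fan)))
  for (s in seq_len(nshell - 1L)) {
    pe <- prism_tets(tris + sid(s), tris + sid(s + 1L))
    elems <- rbind(elems, pe)
    region <- c(region, rep(shell_region[s + 1L], nrow(pe)))
  }

  mesh <- head_mesh(nodes, elems, region)

  ## label brain subregions by element centroid
  cen <- element_centroids(mesh)
  is_brain <- mesh$region == "brain"
  rf <- sqrt((cen[, 1] / ax[1])^2 + (cen[, 2] / ax[2])^2 + (cen[, 3] / ax[3])^2)
  lab <- ifelse(rf < 0.65, "white_matter", "gray_matter")
  fossa <- cen[, 1] < -0.25 * ax[1] & cen[, 3] < -0.35 * ax[3]
  lab[fossa] <- "cerebellum"
  if (config$include_brainstem) {
    stem <- abs(cen[, 1]) < 0.25 * ax[1] & abs(cen[, 2]) < 0.3 * ax[2] &
      cen[, 3] < -0.45 * ax[3]
    lab[stem] <- "brainstem"
  }
  mesh$region[is_brain] <- lab[is_brain]

  if (config$foramen_magnum) {
    keep <- !(mesh$region == "skull" &
              cen[, 3] < 0 &
              sqrt(cen[, 1]^2 + cen[, 2]^2) < config$fm_radius)
    mesh$elems <- mesh$elems[keep, , drop = FALSE]
    mesh$region <- mesh$region[keep]
  }

  if (config$jitter > 0) {
    set.seed(config$seed)
    lock <- union(boundary_nodes(mesh), interface_nodes(mesh))
    free <- setdiff(seq_len(nrow(mesh$nodes)), lock)
    amp <- config$jitter * h
    prop <- mesh$nodes
    prop[free, ] <- prop[free, ] +
      matrix(runif(3 * length(free), -amp, amp), ncol = 3L)
    mesh <- guarded_move(mesh, prop, free)
  }

  attr(mesh, "config") <- config
  mesh
}

#' Regions that make up the brain
#' @return character vector of brain region labels.
#' @export
brain_regions <- function() c("gray_matter", "white_matter", "cerebellum", "brainstem")
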