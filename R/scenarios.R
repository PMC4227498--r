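## Validation load cases and measurement probes: frontal cadaver-style
## impact (force pulse or cylindrical impactor at 45 degrees to the
## horizontal), hemispherical-anvil skull-loading cases, intracranial
## pressure probes (coup, contrecoup, bilateral occipital, posterior
## fossa), and the two six-marker neutral-density-target columns used for
## skull-brain relative-motion measurement.

#' Haversine force pulse
#'
#' F(t) = peak * sin^2(pi t / T) on [0, T], zero outside; the impulse is
#' peak * T / 2. Stands in for a digitised experimental force history.
#'
#' @param peak peak force (N), > 0.
#' @param duration pulse duration T (s), > 0.
#' @return object of class `force_pulse`.
#' @export
haversine_pulse <- function(peak = 7400, duration = 0.006) {
  if (peak < 0) stop("peak must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(shape = "haversine", peak = peak, duration = duration,
                 impulse = peak * duration / 2), class = "force_pulse")
}

#' Evaluate a force pulse
#' @param pulse a `force_pulse`.
#' @param t time(s), seconds.
#' @return force (N) at each `t`.
#' @export
pulse_eval <- function(pulse, t) {
  ifelse(t >= 0 & t <= pulse$duration,
         pulse$peak * sin(pi * t / pulse$duration)^2, 0)
}

## Outer-surface patch of nodes within a cone about a site direction,
## with area-consistent load weights.
surface_patch <- function(mesh, site_dir, half_angle = 20 * pi / 180) {
  site_dir <- site_dir / sqrt(sum(site_dir^2))
  tris <- boundary_faces(mesh)
  nodes <- sort(unique(as.vector(tris)))
  u <- mesh$nodes[nodes, , drop = FALSE]
  u <- u / sqrt(rowSums(u^2))
  sel <- nodes[u %*% site_dir > cos(half_angle)]
  if (!length(sel)) stop("no surface nodes found in the load patch")
  # area weights: each boundary triangle contributes A/3 to its nodes
  a <- mesh$nodes[tris[, 1L], , drop = FALSE]
  b <- mesh$nodes[tris[, 2L], , drop = FALSE]
  c_ <- mesh$nodes[tris[, 3L], , drop = FALSE]
  ab <- b - a; ac <- c_ - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  area3 <- sqrt(rowSums(cr^2)) / 6
  w <- numeric(nrow(mesh$nodes))
  for (k in 1:3) {
    s <- rowsum(area3, group = tris[, k], reorder = TRUE)
    ids <- as.integer(rownames(s))
    w[ids] <- w[ids] + s
  }
  weights <- w[sel]
  list(nodes = sel, weights = weights / sum(weights), site_dir = site_dir)
}

#' Frontal cadaver-impact load case
#'
#' Frontal impact with the anatomical (Frankfort) plane inclined 45
#' degrees to the horizontal, applied as a haversine force pulse on the
#' frontal patch (default) or as a rigid cylindrical impactor (5.59 kg at
#' 9.94 m/s) in penalty contact. Free boundary: no constraint on the six
#' rigid-body degrees of freedom.
#'
#' @param mesh a `head_mesh`.
#' @param peak pulse peak force (N); default just under the 7.5 kN
#'   experimental bound.
#' @param duration pulse duration (s).
#' @param angle_deg inclination of the impact direction to the transverse
#'   plane (degrees).
#' @param mode `"pulse"` (prescribed force amplitude) or `"impactor"`.
#' @param half_angle_deg angular radius of the loaded frontal patch.
#' @param impactor_mass,impactor_velocity,impactor_radius,impactor_stiffness
#'   rigid-impactor parameters for `mode = "impactor"`.
#' @return object of class `loadcase`.
#' @export
nahum_case37 <- function(mesh, peak = 7400, duration = 0.006, angle_deg = 45,
                         mode = c("pulse", "impactor"),
                         half_angle_deg = 20,
                         impactor_mass = 5.59, impactor_velocity = 9.94,
                         impactor_radius = 0.06, impactor_stiffness = 5e6) {
  mode <- match.arg(mode)
  a <- angle_deg * pi / 180
  direction <- c(-cos(a), 0, -sin(a))         # posterior-inferior
  site <- -direction                          # anterior-superior frontal bone
  patch <- surface_patch(mesh, site, half_angle_deg * pi / 180)
  lc <- list(name = "nahum_case37", mode = mode, patch = patch,
             direction = direction, duration = duration,
             boundary = "free",
             meta = list(impactor_mass_kg = 5.59,
                         impactor_velocity_ms = 9.94,
                         frankfort_angle_deg = angle_deg))
  if (mode == "pulse") {
    lc$pulse <- haversine_pulse(peak, duration)
  } else {
    r_site <- max(mesh$nodes[patch$nodes, , drop = FALSE] %*% site)
    lc$impactor <- list(shape = "plane", radius = impactor_radius,
                        mass = impactor_mass, stiffness = impactor_stiffness,
                        position = site * (r_site + 1e-4),
                        velocity = direction * impactor_velocity,
                        axis = direction)
  }
  structure(lc, class = "loadcase")
}

#' Null load case (no applied force)
#' @param mesh a `head_mesh`.
#' @return a `loadcase` producing a quiescent run.
#' @export
null_loadcase <- function(mesh) {
  patch <- surface_patch(mesh, c(1, 0, 0))
  structure(list(name = "null", mode = "pulse", patch = patch,
                 direction = c(-1, 0, 0), duration = 0,
                 pulse = haversine_pulse(0, 1), boundary = "free",
                 meta = list()), class = "loadcase")
}

#' Hemispherical-anvil skull-loading case
#'
#' Rigid hemispherical impactor in penalty contact at a named site
#' (vertex, occipital or angled frontal), used for peak-contact-force and
#' skull principal-stress assessment.
#'
#' @param mesh a `head_mesh`.
#' @param site `"vertex"`, `"occipital"` or `"frontal"`.
#' @param velocity impact speed (m/s).
#' @param radius anvil radius (m).
#' @param mass anvil mass (kg).
#' @param stiffness penalty stiffness (N/m).
#' @return a `loadcase` in impactor mode.
#' @export
anvil_case <- function(mesh, site = c("vertex", "occipital", "frontal"),
                       velocity = 5, radius = 0.048, mass = 1.2,
                       stiffness = 2e7) {
  site <- match.arg(site)
  site_dir <- switch(site,
    vertex = c(0, 0, 1),
    occipital = c(-1, 0, 0),
    frontal = c(cos(pi / 4), 0, sin(pi / 4)))
  direction <- -site_dir
  patch <- surface_patch(mesh, site_dir, 35 * pi / 180)
  r_site <- max(mesh$nodes[patch$nodes, , drop = FALSE] %*% site_dir)
  structure(list(name = paste0("anvil_", site), mode = "impactor",
                 patch = patch, direction = direction,
                 duration = NA,
                 impactor = list(shape = "sphere", radius = radius,
                                 mass = mass, stiffness = stiffness,
                                 position = site_dir * (r_site + radius + 1e-4),
                                 velocity = direction * velocity),
                 boundary = "free",
                 meta = list(site = site, velocity_ms = velocity)),
            class = "loadcase")
}

#' Locate the element containing a point
#'
#' Searches elements (optionally restricted to regions) for one whose
#' barycentric coordinates of the point are all non-negative; falls back
#' to the element with the nearest centroid, with clipped barycentric
#' coordinates.
#'
#' @param mesh a `head_mesh`.
#' @param point length-3 coordinates (m).
#' @param regions restrict the search to these region labels.
#' @return list with `elem` (index), `bary` (length 4), `inside`
#'   (logical).
#' @export
locate_point <- function(mesh, point, regions = NULL) {
  sel <- if (is.null(regions)) seq_len(nrow(mesh$elems))
         else which(mesh$region %in% regions)
  if (!length(sel)) stop("no elements in requested regions")
  cen <- element_centroids(mesh)[sel, , drop = FALSE]
  d2 <- rowSums((cen - matrix(point, nrow(cen), 3, byrow = TRUE))^2)
  ord <- sel[order(d2)]
  for (e in ord[seq_len(min(64L, length(ord)))]) {
    b <- tet_barycentric(mesh, e, point)
    if (all(b > -1e-9)) return(list(elem = e, bary = pmax(b, 0) / sum(pmax(b, 0)),
                                    inside = TRUE))
  }
  e <- ord[1]
  b <- tet_barycentric(mesh, e, point)
  b <- pmax(b, 0); b <- b / sum(b)
  list(elem = e, bary = b, inside = FALSE)
}

tet_barycentric <- function(mesh, e, point) {
  nd <- mesh$elems[e, ]
  A <- rbind(t(mesh$nodes[nd, , drop = FALSE]), rep(1, 4))
  as.vector(solve(A, c(point, 1)))
}

## Support radius of the brain region along a unit direction.
brain_support <- function(mesh, dir) {
  sel <- unique(as.vector(mesh$elems[mesh$region %in% brain_regions(), ,
                                     drop = FALSE]))
  max(mesh$nodes[sel, , drop = FALSE] %*% (dir / sqrt(sum(dir^2))))
}

#' Place the intracranial pressure probes
#'
#' Five probes inside the brain: coup at the anterior pole, contrecoup at
#' the posterior pole, bilateral occipital (left/right posterior-lateral),
#' and the posterior-fossa (cerebellum) centroid. Pressure at a probe is
#' reported as the negative mean stress of its element (compression
#' positive).
#'
#' @param mesh a `head_mesh` with labeled brain subregions.
#' @param radial_fraction how far along the pole direction (fraction of
#'   the brain support radius) the pole probes sit; keeps them safely
#'   inside brain elements.
#' @return data frame of class `probe_set`: name, elem, b1..b4, x, y, z.
#' @export
place_pressure_probes <- function(mesh, radial_fraction = 0.85) {
  if (!any(mesh$region %in% brain_regions()))
    stop("mesh has no labeled brain region")
  occ <- c(-1, 1, 0) / sqrt(2)
  dirs <- list(coup = c(1, 0, 0), contrecoup = c(-1, 0, 0),
               occipital_left = occ, occipital_right = occ * c(1, -1, 1))
  rows <- lapply(names(dirs), function(nm) {
    d <- dirs[[nm]]
    p <- radial_fraction * brain_support(mesh, d) * d
    loc <- locate_point(mesh, p, regions = brain_regions())
    data.frame(name = nm, elem = loc$elem, b1 = loc$bary[1], b2 = loc$bary[2],
               b3 = loc$bary[3], b4 = loc$bary[4],
               x = p[1], y = p[2], z = p[3])
  })
  if (any(mesh$region == "cerebellum")) {
    sel <- which(mesh$region == "cerebellum")
    v <- tet_volumes(mesh$nodes, mesh$elems)[sel]
    cen <- element_centroids(mesh)[sel, , drop = FALSE]
    p <- colSums(cen * v) / sum(v)
    loc <- locate_point(mesh, p, regions = brain_regions())
    rows <- c(rows, list(data.frame(name = "posterior_fossa", elem = loc$elem,
                                    b1 = loc$bary[1], b2 = loc$bary[2],
                                    b3 = loc$bary[3], b4 = loc$bary[4],
                                    x = p[1], y = p[2], z = p[3])))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("probe_set", "data.frame")
  out
}

#' Place the two neutral-density-target marker columns
#'
#' Twelve markers: an anterior column (a1..a6) in the frontal lobe and a
#' posterior column (p1..p6) in the parietal lobe, six markers each at
#' uniform vertical spacing, sorted superior to inferior. If a column
#' would leave the brain the spacing is shrunk with a warning. A skull
#' reference node (fixed point on the skull) is attached as attribute
#' `skull_ref` for relative-motion measurement.
#'
#' @param mesh a `head_mesh`.
#' @param x_anterior,x_posterior column x positions (m).
#' @param y_offset lateral offset (m); negative is the right side.
#' @param spacing vertical marker spacing (m).
#' @param z_top z of the top marker (m).
#' @return data frame of class `ndt_set`: name, column, elem, b1..b4,
#'   x, y, z; attribute `skull_ref`.
#' @export
place_ndt_columns <- function(mesh, x_anterior = 0.035, x_posterior = -0.035,
                              y_offset = -0.02, spacing = 0.010,
                              z_top = 0.025) {
  build_col <- function(x0, prefix, spacing) {
    z <- z_top - (0:5) * spacing
    pts <- cbind(x0, y_offset, z)
    ok <- vapply(seq_len(6), function(i)
      locate_point(mesh, pts[i, ], regions = brain_regions())$inside, TRUE)
    if (!all(ok)) return(NULL)
    do.call(rbind, lapply(seq_len(6), function(i) {
      loc <- locate_point(mesh, pts[i, ], regions = brain_regions())
      data.frame(name = paste0(prefix, i), column = prefix, elem = loc$elem,
                 b1 = loc$bary[1], b2 = loc$bary[2], b3 = loc$bary[3],
                 b4 = loc$bary[4], x = pts[i, 1], y = pts[i, 2], z = pts[i, 3])
    }))
  }
  cols <- list()
  for (colspec in list(c(x_anterior, "a"), c(x_posterior, "p"))) {
    sp <- spacing
    col <- NULL
    while (is.null(col) && sp > spacing / 8) {
      col <- build_col(as.numeric(colspec[1]), colspec[2], sp)
      if (is.null(col)) {
        sp <- sp * 0.8
        warning("NDT column '", colspec[2], "' left the brain; spacing shrunk to ",
                signif(sp, 3), " m")
      }
    }
    if (is.null(col)) stop("could not fit NDT column '", colspec[2], "' in the brain")
    cols[[colspec[2]]] <- col
  }
  out <- rbind(cols$a, cols$p)
  class(out) <- c("ndt_set", "data.frame")
  # skull reference: skull node nearest the vertex (superior pole)
  skull_nodes <- unique(as.vector(mesh$elems[mesh$region == "skull", ,
                                             drop = FALSE]))
  zs <- mesh$nodes[skull_nodes, 3]
  attr(out, "skull_ref") <- skull_nodes[which.max(zs)]
  out
}

#' Relative skull-brain displacement of a marker
#'
#' Component-wise difference of marker and skull-reference displacement
#' (each relative to its own initial position), expressed in the
#' translation-following skull frame. A marker rigidly attached to the
#' skull yields identically zero under pure translation.
#'
#' @param marker T x 3 (or T x k) marker trajectory (m).
#' @param skull_ref T x 3 (or T x k) skull fixed-point trajectory (m).
#' @return matrix of relative displacement components (m), marker minus
#'   skull.
#' @export
relative_displacement <- function(marker, skull_ref) {
  marker <- as.matrix(marker); skull_ref <- as.matrix(skull_ref)
  if (nrow(marker) != nrow(skull_ref))
    stop("marker and skull series must have equal length")
  um <- sweep(marker, 2L, marker[1, ])
  us <- sweep(skull_ref, 2L, skull_ref[1, ])
  unname(um - us)
}

#' Pearson correlation between simulated and reference series
#'
#' @param sim,ref equal-length numeric series (length >= 2, nonzero
#'   variance).
#' @return correlation coefficient in [-1, 1].
#' @export
ndt_correlation <- function(sim, ref) {
  if (length(sim) != length(ref)) stop("series must have equal length")
  if (length(sim) < 2) stop("need at least 2 samples")
  if (stats::sd(sim) == 0 || stats::sd(ref) == 0)
    stop("zero-variance series has no correlation")
  stats::cor(sim, ref)
}

#' Extract marker trajectories from a run
#'
#' @param history an `impact_history` run with an NDT set.
#' @param marker marker name (e.g. `"a1"`).
#' @return T x 3 matrix of positions (m).
#' @export
ndt_trajectory <- function(history, marker) {
  cols <- paste0(marker, c("_x", "_y", "_z"))
  if (!all(cols %in% names(history$channels)))
    stop("marker not recorded: ", marker)
  as.matrix(history$channels[, cols])
}
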