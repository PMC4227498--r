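## Explicit dynamics: lumped mass, CFL time-step control, and the main
## simulation driver wrapping the compiled central-difference core.

## Resolve per-element material rows for a mesh.
resolve_materials <- function(mesh, registry, material_map = default_region_materials()) {
  regs <- unique(mesh$region)
  missing <- setdiff(regs, names(material_map))
  if (length(missing))
    stop("no material mapped for region(s): ", paste(missing, collapse = ", "))
  mats <- lapply(regs, function(r) registry_material(registry, material_map[[r]]))
  names(mats) <- regs
  mats
}

#' Assemble the lumped (diagonal) mass
#'
#' Each element's rho*V is split equally among its four nodes. When
#' `target_mass` is given, all densities are scaled by a single global
#' factor so the total equals the target (the density adjustment used to
#' reach a realistic total head mass).
#'
#' @param mesh a `head_mesh`.
#' @param registry a [material_registry()].
#' @param target_mass optional total mass (kg) to scale to.
#' @param material_map named vector region -> registry component name.
#' @return list with `mass` (nodal masses, kg), `total` (kg), `scale`
#'   (density scale factor applied), `rho` (per-element scaled density).
#' @export
assemble_lumped_mass <- function(mesh, registry = material_registry(),
                                 target_mass = NULL,
                                 material_map = default_region_materials()) {
  mats <- resolve_materials(mesh, registry, material_map)
  rho <- vapply(mats, function(m) m$density, 0)[mesh$region]
  v <- tet_volumes(mesh$nodes, mesh$elems)
  raw_total <- sum(rho * v)
  scale <- if (is.null(target_mass)) 1 else target_mass / raw_total
  rho <- rho * scale
  mvec <- numeric(nrow(mesh$nodes))
  share <- rho * v / 4
  for (k in 1:4) {
    s <- rowsum(share, group = mesh$elems[, k], reorder = TRUE)
    ids <- as.integer(rownames(s))
    mvec[ids] <- mvec[ids] + s
  }
  list(mass = mvec, total = sum(mvec), scale = scale, rho = rho)
}

## Characteristic element length: minimum altitude 3V/A_max.
element_char_length <- function(mesh) {
  p <- lapply(1:4, function(k) mesh$nodes[mesh$elems[, k], , drop = FALSE])
  cross <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm <- function(u) sqrt(rowSums(u^2))
  areas <- cbind(nrm(cross(p[[3]] - p[[2]], p[[4]] - p[[2]])),
                 nrm(cross(p[[4]] - p[[1]], p[[3]] - p[[1]])),
                 nrm(cross(p[[2]] - p[[1]], p[[4]] - p[[1]])),
                 nrm(cross(p[[3]] - p[[1]], p[[2]] - p[[1]]))) / 2
  3 * tet_volumes(mesh$nodes, mesh$elems) / apply(areas, 1L, max)
}

## Per-element dilatational wave modulus (lambda + 2 mu), instantaneous
## moduli for Prony materials; the soft CSF-gap stand-in uses its own
## bulk/shear pair.
element_wave_modulus <- function(mesh, mats, csf_shear, csf_bulk) {
  vapply(mesh$region, function(r) {
    m <- mats[[r]]
    if (inherits(m, "fluid_material")) {
      csf_bulk + 4 * csf_shear / 3
    } else if (inherits(m, "prony_material")) {
      m$K + 4 * m$G0 / 3
    } else {
      lam <- elastic_moduli(m)
      lam$lambda + 2 * lam$mu
    }
  }, 0)
}

#' CFL-stable time step
#'
#' dt = safety * min over elements of (characteristic length / dilatational
#' wave speed), with the instantaneous moduli for viscoelastic materials.
#' When a fluid cavity is supplied, the breathing-mode bound
#' 2/omega with omega^2 = (K_f/V0) * sum |dV/dx_i|^2 / m_i is also
#' applied.
#'
#' @param mesh a `head_mesh`.
#' @param registry a [material_registry()].
#' @param safety Courant safety factor (default 0.8).
#' @param material_map region -> component mapping.
#' @param density_scale global density scale factor (from the mass
#'   adjustment); stiffness-to-mass ratios use scaled densities.
#' @param csf_shear,csf_bulk soft-solid stand-in moduli (Pa) used for
#'   `csf`-region elements.
#' @param cavity optional `fluid_cavity` for the breathing-mode bound.
#' @param mass nodal masses (needed with `cavity`).
#' @return list with `dt` (s, the step to use: safety times the tightest
#'   bound), `dt_element` (altitude/wave-speed CFL estimate), `dt_eigen`
#'   (rigorous per-element frequency bound), `dt_cavity`, and the index
#'   of the governing element.
#' @export
stable_timestep <- function(mesh, registry = material_registry(), safety = 0.8,
                            material_map = default_region_materials(),
                            density_scale = 1,
                            csf_shear = 1e3, csf_bulk = 2.19e7,
                            cavity = NULL, mass = NULL) {
  mats <- resolve_materials(mesh, registry, material_map)
  rho <- vapply(mats, function(m) m$density, 0)[mesh$region] * density_scale
  mod <- element_wave_modulus(mesh, mats, csf_shear, csf_bulk)
  c_dil <- sqrt(mod / rho)
  h <- element_char_length(mesh)
  dte <- h / c_dil
  dt_el <- min(dte)
  # rigorous per-element eigenvalue bound (the altitude/wave-speed CFL
  # estimate can overshoot the true stability limit on near-regular tets)
  lam_mu <- vapply(mesh$region, function(r) {
    m <- mats[[r]]
    if (inherits(m, "fluid_material"))
      c(csf_bulk - 2 * csf_shear / 3, csf_shear)
    else if (inherits(m, "prony_material"))
      c(m$K - 2 * m$G0 / 3, m$G0)
    else unlist(elastic_moduli(m))[c("lambda", "mu")]
  }, c(0, 0))
  dt_eig <- min(elem_critical_dt(mesh$nodes, mesh$elems - 1L,
                                 lam_mu[1, ], lam_mu[2, ], rho))
  dt_cav <- Inf
  if (!is.null(cavity)) {
    if (is.null(mass)) stop("mass required for the cavity time-step bound")
    g <- cavity_nodal_forces(cavity, mesh$nodes, p = 1)  # = dV/dx
    g2 <- rowSums(g^2)
    on_surf <- g2 > 0
    omega2 <- cavity$Kf / cavity$V0 * sum(g2[on_surf] / mass[on_surf])
    dt_cav <- 2 / sqrt(omega2)
  }
  list(dt = safety * min(dt_el, dt_eig, dt_cav), dt_element = dt_el,
       dt_eigen = dt_eig, dt_cavity = dt_cav,
       governing_element = which.min(dte), safety = safety)
}

#' Internal nodal forces for a displaced configuration
#'
#' Reference linear-tetrahedron assembly (constant strain per element,
#' f = -B^T sigma V): elastic materials only, no volumetric averaging.
#' This is the plain small-strain assembly used by the patch and
#' oscillator tests; the time integrator uses the compiled equivalent.
#'
#' @param mesh a `head_mesh`.
#' @param registry a [material_registry()].
#' @param displacement n x 3 nodal displacement matrix.
#' @param material_map region -> component mapping.
#' @return list with `forces` (n x 3, N) and `stress` (m x 6 Voigt, Pa).
#' @export
internal_forces <- function(mesh, registry = material_registry(), displacement,
                            material_map = default_region_materials()) {
  mats <- resolve_materials(mesh, registry, material_map)
  v <- tet_volumes(mesh$nodes, mesh$elems)
  if (any(v <= 0)) stop("inverted element: ", which(v <= 0)[1])
  n <- nrow(mesh$nodes)
  f <- matrix(0, n, 3L)
  sig <- matrix(0, nrow(mesh$elems), 6L)
  for (e in seq_len(nrow(mesh$elems))) {
    nd <- mesh$elems[e, ]
    D <- t(mesh$nodes[nd[2:4], , drop = FALSE] -
           matrix(mesh$nodes[nd[1], ], 3, 3, byrow = TRUE))
    Di <- solve(D)
    g <- rbind(-colSums(Di), Di)              # 4 x 3 shape gradients
    H <- t(displacement[nd, , drop = FALSE]) %*% g   # sum_k u_k (grad N_k)^T
    eps <- (H + t(H)) / 2
    mat <- mats[[mesh$region[e]]]
    sg <- if (inherits(mat, "prony_material")) {
      # instantaneous response
      unvoigt(mat$K * sum(diag(eps)) * c(1, 1, 1, 0, 0, 0) +
              2 * mat$G0 * voigt_dev(voigt(eps)))
    } else {
      stress_elastic(mat, eps)
    }
    sig[e, ] <- voigt(sg)
    f[nd, ] <- f[nd, , drop = FALSE] - v[e] * g %*% sg
  }
  list(forces = f, stress = sig)
}

#' Penalty contact force of a rigid impactor against nodes
#'
#' Single-configuration evaluation used for inspection and testing; the
#' time integrator applies the same law internally.
#'
#' @param impactor list with `shape` ("sphere" or "plane"), `radius` (m),
#'   `mass` (kg), `stiffness` (N/m penalty), `position` (3), `velocity`
#'   (3), and for "plane" the travel `axis` (unit 3-vector toward the
#'   head).
#' @param coords node coordinates (n x 3).
#' @param nodes candidate node indices (default all).
#' @return list with `forces` (n x 3 on the structure), `reaction` (3,
#'   on the impactor), `total` (scalar contact force magnitude).
#' @export
impactor_contact <- function(impactor, coords, nodes = seq_len(nrow(coords))) {
  f <- matrix(0, nrow(coords), 3L)
  X <- impactor$position; k <- impactor$stiffness; R <- impactor$radius
  for (i in nodes) {
    d <- coords[i, ] - X
    if (identical(impactor$shape, "sphere")) {
      dist <- sqrt(sum(d^2))
      if (dist < R && dist > 1e-12)
        f[i, ] <- k * (R - dist) * d / dist
    } else {
      a <- impactor$axis
      along <- sum(d * a)
      lat <- d - along * a
      if (along < 0 && sqrt(sum(lat^2)) <= R)
        f[i, ] <- -k * along * a
    }
  }
  list(forces = f, reaction = -colSums(f), total = sum(sqrt(rowSums(f^2))))
}

#' Run an explicit head-impact simulation
#'
#' Integrates the labeled tetrahedral head mesh through an impact load
#' case with the central-difference scheme: lumped mass (optionally
#' density-scaled to a target head mass), linear elastic and one-term
#' Prony viscoelastic tissues, the surface-based CSF fluid cavity, free
#' boundary (no constraint on the six rigid-body degrees of freedom),
#' and an energy audit. Returns the channel time histories and peak
#' field values.
#'
#' @param mesh a `head_mesh` (typically from [build_head_mesh()]).
#' @param loadcase a load case from [nahum_case37()], [anvil_case()] or
#'   [null_loadcase()].
#' @param registry a [material_registry()].
#' @param duration simulated time (s).
#' @param safety CFL safety factor.
#' @param output_interval channel sampling interval (s).
#' @param target_mass total head mass to scale densities to (kg);
#'   `NULL` keeps table densities.
#' @param probes a probe set from [place_pressure_probes()], or `NULL`.
#' @param ndt an NDT marker set from [place_ndt_columns()], or `NULL`.
#' @param use_cavity couple the CSF region as a hydrostatic fluid cavity.
#' @param cavity_bulk cavity fluid bulk stiffness K_f (Pa).
#' @param csf_shear,csf_bulk soft-solid moduli (Pa) of the meshed CSF-gap
#'   elements (local load transmission; see the vignette).
#' @param vol_average nodal volumetric-strain averaging over brain
#'   elements (anti-locking); disable for patch tests.
#' @param corotational extract per-element rotations (polar
#'   decomposition) before the small-strain update.
#' @param damping mass-proportional damping coefficient (1/s); used by
#'   relaxation runs, 0 for impacts.
#' @param body_accel uniform body acceleration (m/s^2, length 3) applied
#'   as nodal forces.
#' @param fixed_nodes node indices held fixed.
#' @param material_map region -> registry component mapping.
#' @return An object of class `impact_history`.
#' @export
simulate_impact <- function(mesh, loadcase, registry = material_registry(),
                            duration = 0.006, safety = 0.8,
                            output_interval = 5e-5, target_mass = 4.5,
                            probes = NULL, ndt = NULL,
                            use_cavity = TRUE, cavity_bulk = 2.19e9,
                            csf_shear = 1e3, csf_bulk = 2.19e7,
                            vol_average = TRUE, corotational = FALSE,
                            damping = 0, body_accel = c(0, 0, 0),
                            fixed_nodes = integer(0),
                            material_map = default_region_materials()) {
  mats <- resolve_materials(mesh, registry, material_map)
  lm <- assemble_lumped_mass(mesh, registry, target_mass, material_map)

  has_csf <- any(mesh$region == "csf")
  cavity <- NULL
  if (use_cavity && has_csf) {
    surf <- extract_region_surface(mesh, "csf")
    cavity <- fluid_cavity(surf, mesh$nodes, bulk_modulus = cavity_bulk)
  }

  ts <- stable_timestep(mesh, registry, safety, material_map,
                        density_scale = lm$scale,
                        csf_shear = csf_shear, csf_bulk = csf_bulk,
                        cavity = cavity, mass = lm$mass)
  dt <- ts$dt
  nsteps <- max(1L, as.integer(ceiling(duration / dt)))
  out_every <- max(1L, as.integer(round(output_interval / dt)))
  # keep the channel sampling uniform to the last record
  nsteps <- as.integer(out_every * ceiling(nsteps / out_every))

  # per-element material arrays for the compiled core
  m <- nrow(mesh$elems)
  etype <- integer(m)
  eprops <- matrix(0, m, 6L)
  for (r in unique(mesh$region)) {
    idx <- mesh$region == r
    mat <- mats[[r]]
    if (inherits(mat, "fluid_material")) {
      etype[idx] <- 0L
      eprops[idx, 1] <- mat$density * lm$scale
      eprops[idx, 2] <- csf_bulk - 2 * csf_shear / 3   # lambda
      eprops[idx, 3] <- csf_shear                      # mu
    } else if (inherits(mat, "prony_material")) {
      etype[idx] <- 1L
      eprops[idx, 1] <- mat$density * lm$scale
      eprops[idx, 2] <- mat$K
      eprops[idx, 3] <- mat$G0
      eprops[idx, 4] <- mat$Ginf
      eprops[idx, 5] <- mat$beta
    } else {
      lame <- elastic_moduli(mat)
      etype[idx] <- 0L
      eprops[idx, 1] <- mat$density * lm$scale
      eprops[idx, 2] <- lame$lambda
      eprops[idx, 3] <- lame$mu
    }
  }
  avg_el <- etype == 1L   # average volumetric strain over brain tissue only

  # load case
  tgrid <- (0:nsteps) * dt
  pulse <- numeric(nsteps + 1L)
  lnodes <- integer(0); lw <- numeric(0); ldir <- c(1, 0, 0)
  imp_type <- -1L
  imp_par <- c(0, 1, 0); imp_x0 <- c(0, 0, 0); imp_v0 <- c(0, 0, 0)
  imp_axis <- c(0, 0, 1); contact_nodes <- integer(0)
  if (loadcase$mode == "pulse") {
    pulse <- pulse_eval(loadcase$pulse, tgrid)
    lnodes <- loadcase$patch$nodes
    lw <- loadcase$patch$weights
    ldir <- loadcase$direction
  } else if (loadcase$mode == "impactor") {
    imp <- loadcase$impactor
    imp_type <- if (identical(imp$shape, "plane")) 1L else 0L
    imp_par <- c(imp$radius, imp$mass, imp$stiffness)
    imp_x0 <- imp$position; imp_v0 <- imp$velocity
    imp_axis <- imp$axis %||% (imp$velocity / sqrt(sum(imp$velocity^2)))
    contact_nodes <- loadcase$patch$nodes
  }

  probe_el <- if (!is.null(probes)) probes$elem - 1L else integer(0)
  ndt_el <- if (!is.null(ndt)) ndt$elem - 1L else integer(0)
  ndt_bary <- if (!is.null(ndt))
    as.matrix(ndt[, c("b1", "b2", "b3", "b4")]) else matrix(0, 0, 4)
  track_nodes <- integer(0)
  if (!is.null(ndt) && !is.null(attr(ndt, "skull_ref")))
    track_nodes <- attr(ndt, "skull_ref") - 1L

  brain_el <- mesh$region %in% brain_regions()
  skull_el <- mesh$region == "skull"

  res <- fe_explicit_run(
    mesh$nodes, mesh$elems - 1L, etype, eprops, lm$mass,
    if (!is.null(cavity)) cavity$surface$tris - 1L else matrix(0L, 0, 3),
    if (!is.null(cavity)) cavity$V0 else 1,
    if (!is.null(cavity)) cavity$Kf else 0,
    lnodes - 1L, lw, ldir, pulse, as.numeric(body_accel), damping,
    as.integer(fixed_nodes) - 1L, avg_el, as.integer(vol_average),
    as.integer(corotational), imp_type, imp_par, imp_x0, imp_v0, imp_axis,
    as.integer(contact_nodes) - 1L, brain_el, skull_el,
    probe_el, ndt_el, ndt_bary, track_nodes,
    dt, nsteps, out_every)

  # relative energy-balance error: raw imbalance over the run's energy scale
  escale <- max(abs(res$energy[, 4]), res$energy[, 1], 1e-12)
  balance_rel <- res$energy[, 5] / escale
  channels <- data.frame(time = res$time,
                         impact_force = res$force,
                         acc_x = res$acc[, 1], acc_y = res$acc[, 2],
                         acc_z = res$acc[, 3], acc_mag = res$acc[, 4],
                         kinetic_energy = res$energy[, 1],
                         internal_energy = res$energy[, 2],
                         cavity_energy = res$energy[, 3],
                         external_work = res$energy[, 4],
                         balance_error = balance_rel,
                         cavity_volume = res$cavity[, 1],
                         cavity_pressure = res$cavity[, 2])
  units <- c(time = "s", impact_force = "N", acc_x = "m/s^2", acc_y = "m/s^2",
             acc_z = "m/s^2", acc_mag = "m/s^2", kinetic_energy = "J",
             internal_energy = "J", cavity_energy = "J", external_work = "J",
             balance_error = "-", cavity_volume = "m^3", cavity_pressure = "Pa")
  if (!is.null(probes)) {
    pm <- res$probes
    colnames(pm) <- paste0("p_", probes$name)
    channels <- cbind(channels, pm)
    units <- c(units, setNames(rep("Pa", ncol(pm)), colnames(pm)))
  }
  if (!is.null(ndt)) {
    nd <- res$ndt
    colnames(nd) <- as.vector(t(outer(ndt$name, c("_x", "_y", "_z"), paste0)))
    channels <- cbind(channels, nd)
    units <- c(units, setNames(rep("m", ncol(nd)), colnames(nd)))
    if (length(track_nodes)) {
      tk <- res$track
      colnames(tk) <- paste0("skull_ref", c("_x", "_y", "_z"))
      channels <- cbind(channels, tk)
      units <- c(units, setNames(rep("m", 3), colnames(tk)))
    }
  }
  if (imp_type >= 0L) {
    im <- res$impactor
    colnames(im) <- c("imp_x", "imp_y", "imp_z", "imp_vx", "imp_vy", "imp_vz")
    channels <- cbind(channels, im)
    units <- c(units, setNames(c(rep("m", 3), rep("m/s", 3)), colnames(im)))
  }

  structure(list(
    channels = channels, units = units, dt = dt, nsteps = nsteps,
    total_mass = lm$total, density_scale = lm$scale,
    peaks = list(brain_von_mises = res$vm_peak, brain_von_mises_time = res$vm_time,
                 brain_von_mises_elem = res$vm_elem,
                 skull_principal = res$ps_peak, skull_principal_time = res$ps_time,
                 skull_principal_elem = res$ps_elem),
    final_stress = res$final_stress,
    loadcase = loadcase, probes = probes, ndt = ndt,
    settings = list(cavity_bulk = if (!is.null(cavity)) cavity$Kf else NA,
                    cavity_V0 = if (!is.null(cavity)) cavity$V0 else NA,
                    csf_shear = csf_shear, csf_bulk = csf_bulk,
                    unit_interpretation = attr(registry, "units"),
                    vol_average = vol_average, corotational = corotational,
                    safety = safety, target_mass = target_mass)),
    class = "impact_history")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.impact_history <- function(x, ...) {
  ch <- x$channels
  cat(sprintf("impact_history: %d samples over %.4g ms (dt = %.3g us, %d steps)\n",
              nrow(ch), max(ch$time) * 1e3, x$dt * 1e6, x$nsteps))
  cat(sprintf("  total mass %.3f kg (density scale %.3f)\n",
              x$total_mass, x$density_scale))
  cat(sprintf("  peak impact force %.4g N, peak CG acceleration %.4g m/s^2\n",
              max(ch$impact_force), max(ch$acc_mag)))
  pp <- grep("^p_", names(ch), value = TRUE)
  for (p in pp)
    cat(sprintf("  %-16s max %8.4g kPa  min %8.4g kPa\n",
                p, max(ch[[p]]) / 1e3, min(ch[[p]]) / 1e3))
  cat(sprintf("  peak brain von Mises %.4g kPa, peak skull principal %.4g MPa\n",
              x$peaks$brain_von_mises / 1e3, x$peaks$skull_principal / 1e6))
  cat(sprintf("  energy balance error %.3g%%\n",
              100 * max(abs(ch$balance_error))))
  invisible(x)
}

#' Energy audit of a completed run
#'
#' @param history an `impact_history`.
#' @return list with final kinetic, internal and cavity energy, external
#'   work (J), and the maximum relative balance error over the run.
#' @export
energy_audit <- function(history) {
  ch <- history$channels
  last <- nrow(ch)
  list(kinetic = ch$kinetic_energy[last],
       internal = ch$internal_energy[last],
       cavity = ch$cavity_energy[last],
       external_work = ch$external_work[last],
       balance_error = max(abs(ch$balance_error)))
}
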