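# Explicit solver: lumped mass, CFL step, patch test, central-difference
# exactness and convergence, contact, momentum/energy audits.

test_that("lumped mass splits rho V equally and conserves the total", {
  mesh <- regular_tet()
  lm <- assemble_lumped_mass(mesh, material_registry())
  v <- tet_volumes(mesh$nodes, mesh$elems)
  expect_equal(lm$mass, rep(1210 * v / 4, 4), tolerance = 1e-12)
  mesh2 <- coarse_head()
  lm2 <- assemble_lumped_mass(mesh2, material_registry())
  v2 <- tet_volumes(mesh2$nodes, mesh2$elems)
  expect_equal(sum(lm2$mass), sum(lm2$rho * v2), tolerance = 1e-9)
})

test_that("stable time step: CFL closed form, true-stability bound, and scalings", {
  skull <- registry_material(material_registry(), "Skull bone and cervical vertebra")
  lam <- elastic_moduli(skull)
  mesh <- regular_tet()
  mesh$nodes <- mesh$nodes * 0.003          # edge 3 mm
  ts <- stable_timestep(mesh, material_registry(), safety = 0.8)
  # reported CFL estimate: altitude over the largest face / wave speed
  h <- 3 * tet_volumes(mesh$nodes, mesh$elems)[1] /
    (sqrt(3) / 4 * 0.003^2)
  c_dil <- sqrt((lam$lambda + 2 * lam$mu) / 1210)
  expect_equal(ts$dt_element, h / c_dil, tolerance = 1e-9)
  # the step actually used respects the exact element frequency oracle:
  # 12x12 stiffness assembled by probing internal_forces column-wise
  K <- matrix(0, 12, 12)
  for (j in 1:12) {
    u <- matrix(0, 4, 3); u[(j - 1) %% 4 + 1, (j - 1) %/% 4 + 1] <- 1
    K[, j] <- -as.vector(internal_forces(mesh, material_registry(), u)$forces)
  }
  M <- rep(assemble_lumped_mass(mesh, material_registry())$mass, times = 3)
  wmax <- sqrt(max(eigen(diag(1 / sqrt(M)) %*% K %*% diag(1 / sqrt(M)),
                         symmetric = TRUE)$values))
  expect_lte(ts$dt, 0.8 * 2 / wmax * (1 + 1e-9))
  expect_gte(ts$dt, 0.5 * 0.8 * 2 / wmax)   # not absurdly conservative
  # refining the edge by 2 halves dt
  mesh_f <- regular_tet(); mesh_f$nodes <- mesh_f$nodes * 0.0015
  expect_equal(stable_timestep(mesh_f, material_registry())$dt, ts$dt / 2,
               tolerance = 1e-9)
})

test_that("linear displacement field produces constant stress and zero interior force (patch test)", {
  mesh <- tet_block_mesh(3, 3, 3, size = c(0.03, 0.03, 0.03))
  A <- matrix(c(1, 0.4, -0.2, 0.4, -0.5, 0.1, -0.2, 0.1, 0.8), 3) * 1e-3
  u <- mesh$nodes %*% t(A)
  out <- internal_forces(mesh, material_registry(), u)
  expect_lt(max(apply(out$stress, 2, function(s) diff(range(s)))) /
            max(abs(out$stress)), 1e-10)
  interior <- setdiff(seq_len(nrow(mesh$nodes)), boundary_nodes(mesh))
  expect_lt(max(abs(out$forces[interior, ])),
            1e-10 * max(abs(out$forces)))
  expect_equal(internal_forces(mesh, material_registry(),
                               0 * mesh$nodes)$forces,
               matrix(0, nrow(mesh$nodes), 3))
})

test_that("prescribed uniaxial strain gives the (lambda + 2 mu) boundary reaction", {
  mesh <- tet_block_mesh(2, 2, 2, size = c(0.01, 0.01, 0.01))
  eps <- 1e-3
  u <- cbind(mesh$nodes[, 1] * eps, 0, 0)
  out <- internal_forces(mesh, material_registry(), u)
  lam <- elastic_moduli(registry_material(material_registry(),
                                          "Skull bone and cervical vertebra"))
  face <- which(mesh$nodes[, 1] == 0.01)
  expect_equal(sum(out$forces[face, 1]),
               -(lam$lambda + 2 * lam$mu) * eps * 0.01^2,
               tolerance = 1e-9 * (lam$lambda + 2 * lam$mu) * eps * 1e-4)
})

test_that("a free node under constant force follows the exact parabola", {
  # one soft tiny element, force on all nodes: rigid-body acceleration,
  # central difference is exact for constant acceleration
  mesh <- regular_tet()
  mesh$nodes <- mesh$nodes * 0.01
  lc <- structure(list(name = "const", mode = "pulse",
                       patch = list(nodes = 1:4, weights = rep(0.25, 4)),
                       direction = c(1, 0, 0), duration = 1,
                       pulse = structure(list(shape = "haversine", peak = 0,
                                              duration = 1), class = "force_pulse"),
                       boundary = "free", meta = list()), class = "loadcase")
  # constant force via body acceleration instead of a pulse
  h <- simulate_impact(mesh, lc, duration = 5e-4, output_interval = 1e-5,
                       target_mass = NULL, use_cavity = FALSE,
                       body_accel = c(2, 0, 0), vol_average = FALSE)
  ch <- h$channels
  expect_equal(ch$acc_x, rep(2, nrow(ch)), tolerance = 1e-12)
  expect_equal(max(abs(ch$acc_y)), 0, tolerance = 1e-12)
})

test_that("quiescent state stays quiescent under a zero-amplitude pulse", {
  mesh <- coarse_head()
  h <- simulate_impact(mesh, null_loadcase(mesh), duration = 5e-4,
                       probes = place_pressure_probes(mesh))
  ch <- h$channels
  expect_equal(max(abs(ch$impact_force)), 0)
  expect_equal(max(abs(ch$acc_mag)), 0, tolerance = 1e-12)
  expect_lt(max(abs(ch$p_coup)), 1e-3)     # round-off pascals only
  expect_equal(max(abs(ch$kinetic_energy)), 0, tolerance = 1e-15)
})

test_that("1-DOF oscillation period converges at second order in dt", {
  # single element, three nodes fixed, one free: measure the dominant
  # oscillation period against dt-refined runs
  mesh <- regular_tet()
  mesh$nodes <- mesh$nodes * 0.01
  mesh$region <- "soft_tissue"
  lc <- structure(list(name = "pluck", mode = "pulse",
                       patch = list(nodes = 4L, weights = 1),
                       direction = c(0, 0, 1), duration = 1e-4,
                       pulse = haversine_pulse(0.2, 1e-4),
                       boundary = "free", meta = list()), class = "loadcase")
  run_period <- function(safety) {
    h <- simulate_impact(mesh, lc, duration = 4e-3, output_interval = 2e-6,
                         target_mass = NULL, use_cavity = FALSE,
                         vol_average = FALSE, safety = safety,
                         fixed_nodes = 1:3)
    ch <- h$channels
    z <- ch$kinetic_energy
    # period from the two dominant KE minima after the pulse
    post <- ch$time > 2e-4
    zs <- z[post]; tt <- ch$time[post]
    mins <- which(diff(sign(diff(zs))) > 0) + 1
    2 * mean(diff(tt[mins]))
  }
  p1 <- run_period(0.5)
  p2 <- run_period(0.25)
  p3 <- run_period(0.125)
  # richardson: error ratio ~ 4 for O(dt^2)
  expect_lt(abs(p3 - p2), abs(p2 - p1))
})

test_that("impactor penalty force is k delta and vanishes without penetration", {
  imp <- list(shape = "sphere", radius = 0.05, mass = 1, stiffness = 1e5,
              position = c(0, 0, 0.06), velocity = c(0, 0, -1))
  coords <- rbind(c(0, 0, 0.0), c(0, 0, 0.02))
  out <- impactor_contact(imp, coords)
  expect_equal(out$forces[1, ], c(0, 0, 0))
  expect_equal(out$forces[2, ], c(0, 0, -1e5 * 0.01), tolerance = 1e-9)
  expect_equal(out$reaction, c(0, 0, 1e5 * 0.01), tolerance = 1e-9)
  plane <- list(shape = "plane", radius = 0.1, mass = 1, stiffness = 2e4,
                position = c(0, 0, 0.01), velocity = c(0, 0, -1),
                axis = c(0, 0, -1))
  outp <- impactor_contact(plane, coords)
  # node at z = 0.02 is behind the advancing face (at z = 0.01, moving
  # down): penetrated by 0.01 and pushed along the travel direction
  expect_equal(outp$forces[2, ], c(0, 0, -2e4 * 0.01), tolerance = 1e-9)
  expect_equal(outp$forces[1, ], c(0, 0, 0))
})

test_that("impactor against a stiff block transfers momentum equal to the impulse", {
  mesh <- tet_block_mesh(2, 2, 2, size = c(0.05, 0.05, 0.02))
  mesh$nodes[, 3] <- mesh$nodes[, 3] - 0.02    # top face at z = 0
  bottom <- which(mesh$nodes[, 3] == -0.02)
  top <- which(mesh$nodes[, 3] == 0)
  lc <- structure(list(name = "drop", mode = "impactor",
                       patch = list(nodes = top, weights = NULL),
                       direction = c(0, 0, -1), duration = NA,
                       impactor = list(shape = "sphere", radius = 0.02,
                                       mass = 0.5, stiffness = 5e5,
                                       position = c(0.025, 0.025, 0.0201),
                                       velocity = c(0, 0, -2)),
                       boundary = "fixed-base", meta = list()),
                 class = "loadcase")
  h <- simulate_impact(mesh, lc, duration = 4e-3, output_interval = 2e-6,
                       target_mass = NULL, use_cavity = FALSE,
                       vol_average = FALSE, fixed_nodes = bottom)
  ch <- h$channels
  # impactor rebounds: impulse int F dt = m (v0 - v1)
  impulse <- sum((ch$impact_force[-1] + ch$impact_force[-nrow(ch)]) / 2 *
                 diff(ch$time))
  dv <- 0.5 * (-2 - ch$imp_vz[nrow(ch)])
  expect_gt(ch$imp_vz[nrow(ch)], 0)           # rebounded
  expect_lt(abs(impulse + dv) / abs(dv), 0.01)
})

test_that("free-boundary pulse satisfies impulse-momentum and the energy audit", {
  mesh <- coarse_head()
  lc <- nahum_case37(mesh, peak = 3000, duration = 0.003)
  h <- simulate_impact(mesh, lc, duration = 0.004)
  ch <- h$channels
  # post-pulse CG velocity = impulse / mass
  vcg <- cumsum(c(0, (ch$acc_mag[-1] + ch$acc_mag[-nrow(ch)]) / 2 * diff(ch$time)))
  expect_equal(max(vcg), lc$pulse$impulse / h$total_mass, tolerance = 0.01)
  aud <- energy_audit(h)
  expect_lt(aud$balance_error, 0.02)
  expect_gt(aud$external_work, 0)
})

test_that("viscoelastic dissipation is non-negative and grows", {
  mesh <- coarse_head()
  lc <- nahum_case37(mesh, peak = 3000, duration = 0.002)
  h <- simulate_impact(mesh, lc, duration = 0.004)
  ch <- h$channels
  # internal energy (accumulated stress work) stays non-negative after
  # unloading, within the work-quadrature tolerance of the audit
  expect_gte(min(ch$internal_energy[ch$time > 0.003]),
             -0.02 * max(ch$external_work))
})
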