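# Load cases, probes and NDT machinery.

test_that("haversine pulse satisfies its closed forms", {
  p <- haversine_pulse(7400, 0.006)
  expect_equal(pulse_eval(p, 0.003), 7400)
  expect_equal(pulse_eval(p, 0), 0)
  expect_equal(pulse_eval(p, 0.006), 0, tolerance = 1e-9)
  expect_equal(pulse_eval(p, -1), 0)
  expect_equal(p$impulse, 22.2, tolerance = 1e-12)
  tt <- seq(0, 0.006, length.out = 20001)
  expect_equal(sum(pulse_eval(p, tt)) * diff(tt)[1], 22.2, tolerance = 1e-3)
})

test_that("frontal load case records the experimental parameters", {
  mesh <- coarse_head()
  lc <- nahum_case37(mesh)
  expect_equal(lc$meta$impactor_mass_kg, 5.59)
  expect_equal(lc$meta$impactor_velocity_ms, 9.94)
  expect_equal(lc$pulse$duration, 0.006)
  expect_equal(lc$pulse$peak, 7400)
  expect_equal(sqrt(sum(lc$direction^2)), 1, tolerance = 1e-12)
  expect_equal(lc$direction, c(-cos(pi / 4), 0, -sin(pi / 4)), tolerance = 1e-12)
  expect_identical(lc$boundary, "free")
  expect_gt(length(lc$patch$nodes), 3)
  expect_equal(sum(lc$patch$weights), 1, tolerance = 1e-12)
  zero <- nahum_case37(mesh, peak = 0)
  expect_equal(pulse_eval(zero$pulse, 0.003), 0)
})

test_that("pressure probes sit inside brain elements at the stated anatomy", {
  mesh <- coarse_head()
  probes <- place_pressure_probes(mesh)
  expect_identical(nrow(probes), 5L)
  expect_setequal(probes$name, c("coup", "contrecoup", "occipital_left",
                                 "occipital_right", "posterior_fossa"))
  expect_true(all(mesh$region[probes$elem] %in% brain_regions()))
  bary <- as.matrix(probes[, c("b1", "b2", "b3", "b4")])
  expect_true(all(bary >= 0 & bary <= 1))
  expect_equal(rowSums(bary), rep(1, 5), tolerance = 1e-9)
  # coup and contrecoup are antipodal as seen from the brain centre
  pc <- as.numeric(probes[probes$name == "coup", c("x", "y", "z")])
  pcc <- as.numeric(probes[probes$name == "contrecoup", c("x", "y", "z")])
  ang <- acos(sum(pc * pcc) / sqrt(sum(pc^2) * sum(pcc^2))) * 180 / pi
  expect_gt(ang, 175)
})

test_that("barycentric interpolation is exact for linear fields", {
  mesh <- coarse_head()
  a <- c(3, -2, 5); b <- 0.7
  fld <- as.vector(mesh$nodes %*% a) + b
  probes <- place_pressure_probes(mesh)
  for (i in seq_len(nrow(probes))) {
    nd <- mesh$elems[probes$elem[i], ]
    bb <- as.numeric(probes[i, c("b1", "b2", "b3", "b4")])
    interp <- sum(bb * fld[nd])
    expect_equal(interp, sum(a * as.numeric(probes[i, c("x", "y", "z")])) + b,
                 tolerance = 1e-9)
  }
})

test_that("NDT columns give 12 in-brain markers, 6 + 6, sorted superior to inferior", {
  mesh <- default_head()
  ndt <- place_ndt_columns(mesh)
  expect_identical(nrow(ndt), 12L)
  expect_identical(sum(ndt$column == "a"), 6L)
  expect_identical(sum(ndt$column == "p"), 6L)
  expect_true(all(mesh$region[ndt$elem] %in% brain_regions()))
  for (cl in c("a", "p"))
    expect_true(all(diff(ndt$z[ndt$column == cl]) < 0))
  expect_true(attr(ndt, "skull_ref") %in%
              unique(as.vector(mesh$elems[mesh$region == "skull", ])))
})

test_that("relative displacement contracts hold", {
  t <- seq(0, 1, by = 0.1)
  skull <- cbind(0.01 * t, 0 * t, 0.02 * t^2)
  marker <- sweep(skull, 2, c(0.05, 0, 0.03), "+")   # rigidly attached
  expect_equal(relative_displacement(marker, skull),
               matrix(0, length(t), 3), tolerance = 1e-15)
  # skull moves +u x, brain held: relative x-displacement is -u
  brain <- matrix(rep(c(0.05, 0, 0.03), each = length(t)), ncol = 3)
  rel <- relative_displacement(brain, skull)
  expect_equal(rel[, 1], -0.01 * t, tolerance = 1e-12)
  # analytic paths
  mk <- cbind(sin(t), cos(t), t)
  sk <- cbind(t^2, 0 * t, -t)
  expect_equal(relative_displacement(mk, sk),
               cbind(sin(t) - t^2, cos(t) - 1, 2 * t), tolerance = 1e-12)
  expect_error(relative_displacement(mk[1:5, ], sk), "equal length")
})

test_that("correlation coefficient matches the direct formula and its identities", {
  x <- c(0.2, 1.3, 2.1, 4.5, 4.9, 7.2)
  expect_equal(ndt_correlation(x, x), 1)
  expect_equal(ndt_correlation(x, -x), -1)
  y <- rev(x)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ndt_correlation(x, y), direct, tolerance = 1e-12)
  expect_error(ndt_correlation(x, rep(1, 6)), "variance")
  expect_error(ndt_correlation(x, x[1:3]), "equal length")
})

test_that("anvil cases follow the site conventions", {
  mesh <- coarse_head()
  occ <- anvil_case(mesh, "occipital", velocity = 5)
  expect_equal(occ$direction, c(1, 0, 0))   # posterior -> anterior travel
  expect_identical(occ$impactor$shape, "sphere")
  expect_lt(occ$impactor$position[1], min(mesh$nodes[, 1]))
  vtx <- anvil_case(mesh, "vertex", velocity = 3)
  expect_equal(vtx$impactor$velocity, c(0, 0, -3), tolerance = 1e-12)
  # six-case suite enumerable: 4 vertex + 1 occipital + 1 frontal
  suite <- c(replicate(4, anvil_case(mesh, "vertex"), simplify = FALSE),
             list(anvil_case(mesh, "occipital"), anvil_case(mesh, "frontal")))
  expect_length(suite, 6)
  expect_error(anvil_case(mesh, "nose"))
})

test_that("zero-velocity anvil produces no contact force", {
  mesh <- coarse_head()
  lc <- anvil_case(mesh, "occipital", velocity = 0)
  h <- simulate_impact(mesh, lc, duration = 5e-4)
  expect_equal(max(h$channels$impact_force), 0)
})

test_that("left/right occipital probes agree under a pure axial frontal pulse", {
  mesh <- coarse_head()
  probes <- place_pressure_probes(mesh)
  lc <- nahum_case37(mesh, peak = 5000, duration = 0.004, angle_deg = 0)
  h <- simulate_impact(mesh, lc, duration = 0.004, probes = probes)
  ch <- h$channels
  scale <- max(abs(ch$p_occipital_left), abs(ch$p_occipital_right))
  expect_lt(max(abs(ch$p_occipital_left - ch$p_occipital_right)) / scale, 0.25)
})
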