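# Constitutive registry and laws: printed-table exactness, relaxation
# monotonicity, closed-form elasticity, and the recursive viscoelastic
# update against a direct hereditary-integral oracle.

test_that("registry carries the printed table row-for-row", {
  reg <- material_registry()
  expect_identical(nrow(reg), 11L)
  expect_identical(anyDuplicated(reg$name), 0L)
  expect_true(all(reg$density > 0))
  skull <- registry_material(reg, "Skull bone and cervical vertebra")
  expect_equal(skull$density, 1210)
  expect_equal(skull$nu, 0.22)
  expect_equal(skull$E_table, 8.000)
  csf <- registry_material(reg, "CSF")
  expect_identical(csf$behaviour, "fluid")
  expect_equal(csf$density, 1000)
  gray <- registry_material(reg, "Gray matter")
  expect_equal(gray$nu, 0.4996)
  expect_equal(gray$G0_table, 0.034)
  expect_equal(gray$Ginf_table, 0.0064)
  expect_equal(gray$beta_table, 700)
  # all brain-tissue Poisson ratios are among the printed set
  visc <- reg[reg$behaviour == "viscoelastic", ]
  expect_true(all(visc$nu %in% c(0.48, 0.49, 0.4996)))
})

test_that("unit interpretations scale the printed values as documented", {
  mixed <- registry_material(material_registry("mixed"), "Brainstem")
  expect_equal(mixed$G0, 0.0225e6)    # MPa reading -> 22.5 kPa
  expect_equal(mixed$beta, 80)        # rate in 1/s
  lit <- registry_material(material_registry("literal"), "Brainstem")
  expect_equal(lit$G0, 0.0225e9)      # printed column head (GPa)
  expect_equal(lit$beta, 1 / 80)      # time constant reading
  # table-unit relaxation values agree under both readings
  expect_equal(relaxation_modulus(mixed, 0), relaxation_modulus(lit, 0))
})

test_that("relaxation modulus reproduces printed endpoints and the closed form", {
  bs <- registry_material(material_registry(), "Brainstem")
  expect_equal(relaxation_modulus(bs, 0), 0.0225)
  expect_equal(relaxation_modulus(bs, 1e9), 0.0045)
  expect_equal(relaxation_modulus(bs, 1 / bs$beta),
               0.0045 + 0.018 * exp(-1), tolerance = 1e-12)
  t <- seq(0, 0.2, by = 1e-3)
  g <- relaxation_modulus(bs, t)
  expect_true(all(diff(g) <= 0))
  expect_true(all(g <= 0.0225 & g >= 0.0045))
  expect_error(relaxation_modulus(bs, -1), ">= 0")
})

test_that("Lame conversion matches closed forms and rejects the incompressible limit", {
  m <- list(E = 1, nu = 0)
  lam <- elastic_moduli(m)
  expect_equal(lam$mu, 0.5)
  expect_equal(lam$lambda, 0)
  skull <- registry_material(material_registry(), "Skull bone and cervical vertebra")
  expect_equal(elastic_moduli(skull)$mu, 8e9 / (2 * 1.22), tolerance = 1e-12)
  expect_error(elastic_moduli(list(E = 1, nu = 0.5)), "< 0.5")
})

test_that("elastic stress update satisfies volumetric and uniaxial closed forms", {
  skull <- registry_material(material_registry(), "Skull bone and cervical vertebra")
  lam <- elastic_moduli(skull)
  expect_equal(stress_elastic(skull, numeric(6)), numeric(6))
  e <- 1e-3
  sv <- stress_elastic(skull, diag(rep(e / 3, 3)))
  K <- lam$lambda + 2 * lam$mu / 3
  expect_equal(sv, K * e * diag(3), tolerance = 1e-12)
  su <- stress_elastic(skull, c(e, 0, 0, 0, 0, 0))
  expect_equal(su[1], (lam$lambda + 2 * lam$mu) * e, tolerance = 1e-12)
})

test_that("held step shear strain relaxes along G(t)", {
  bs <- registry_material(material_registry(), "Brainstem")
  gam <- 1e-3
  dt <- 0.02 / bs$beta
  st <- visco_state()
  e <- c(0, 0, 0, gam / 2, 0, 0)      # tensor shear = gamma/2
  times <- seq(dt, 4 / bs$beta, by = dt)
  tau <- vapply(times, function(t) {
    up <- stress_viscoelastic(bs, st, e, dt)
    st <<- up$state
    up$stress[4]
  }, 0)
  expect_equal(tau, relaxation_modulus(bs, times - dt, units = "SI") * gam,
               tolerance = 0.01)
})

test_that("degenerate Prony (G0 = Ginf) reduces to linear elasticity and volumetric strain leaves the memory untouched", {
  bs <- registry_material(material_registry(), "Brainstem")
  bs$G0 <- bs$Ginf
  e <- c(1, -2, 0.5, 0.3, -0.1, 0.2) * 1e-3
  up <- stress_viscoelastic(bs, visco_state(), e, 1e-4)
  ev <- sum(e[1:3])
  exp_s <- 2 * bs$Ginf * (e - c(rep(ev / 3, 3), 0, 0, 0)) +
    bs$K * ev * c(1, 1, 1, 0, 0, 0)
  expect_equal(up$stress, exp_s, tolerance = 1e-12)
  vol <- c(2e-3, 2e-3, 2e-3, 0, 0, 0)
  up2 <- stress_viscoelastic(registry_material(material_registry(), "Brainstem"),
                             visco_state(), vol, 1e-4)
  expect_equal(up2$state$h, numeric(6))
  expect_equal(up2$stress[4:6], numeric(3))
})

test_that("recursive update tracks the hereditary-integral oracle on random paths", {
  reg <- material_registry()
  for (nm in c("Brainstem", "Gray matter", "Cerebellum")) {
    mat <- registry_material(reg, nm)
    set.seed(42)
    nstep <- 200
    dt <- 0.2 / mat$beta / nstep * 10     # resolves the relaxation time
    times <- (0:nstep) * dt
    # smooth random deviatoric strain path
    base <- matrix(rnorm(6 * 5, sd = 1e-3), 5, 6)
    dev6 <- t(vapply(times, function(t)
      colSums(base * sin((1:5) * (t * mat$beta / 2) + (1:5))), numeric(6)))
    tr3 <- rowMeans(dev6[, 1:3])
    dev6[, 1:3] <- dev6[, 1:3] - tr3     # make deviatoric
    dev6 <- sweep(dev6, 2, dev6[1, ])    # virgin state: path starts at zero
    st <- visco_state()
    sim <- matrix(0, nstep + 1, 6)
    for (i in 2:(nstep + 1)) {
      up <- stress_viscoelastic(mat, st, dev6[i, ], dt)
      st <- up$state
      sim[i, ] <- up$stress
    }
    oracle <- prony_convolution_oracle(mat, times, dev6)
    scale <- max(abs(oracle))
    expect_lt(max(abs(sim - oracle)) / scale, 0.01)
  }
})

test_that("halving the step improves the viscoelastic solution on smooth paths", {
  mat <- registry_material(material_registry(), "Gray matter")
  path <- function(t) c(sin(300 * t), -sin(300 * t), 0, cos(200 * t) - 1, 0, 0) * 1e-3
  run <- function(dt, Tend) {
    st <- visco_state()
    s <- NULL
    for (t in seq(dt, Tend, by = dt)) {
      up <- stress_viscoelastic(mat, st, path(t), dt)
      st <- up$state
      s <- up$stress
    }
    s
  }
  Tend <- 0.008
  ref <- run(Tend / 4096, Tend)
  e1 <- max(abs(run(Tend / 64, Tend) - ref))
  e2 <- max(abs(run(Tend / 128, Tend) - ref))
  expect_lt(e2, e1 * 0.75)
})

test_that("registry YAML round-trip preserves the table", {
  reg <- material_registry()
  path <- tempfile(fileext = ".yaml")
  write_material_registry(reg, path)
  back <- read_material_registry(path)
  expect_equal(as.data.frame(unclass(back)), as.data.frame(unclass(reg)))
  expect_identical(attr(back, "units"), "mixed")
})
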