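# Injury metrics: HIC closed forms and brute-force agreement, pressure
# extrema, Ward classification, stress invariants.

test_that("HIC closed forms: constant 100 g for 10 ms gives 1000, zero gives 0", {
  dt <- 1e-4
  a <- rep(100 * 9.81, 101)            # 10 ms record
  out <- hic(a, dt = dt, max_window = 0.036)
  expect_equal(out$hic, 100^2.5 * 0.010, tolerance = 1e-9)
  expect_equal(out$t2 - out$t1, 0.010, tolerance = 1e-9)
  expect_equal(hic(rep(0, 50), dt = dt)$hic, 0)
})

test_that("scaling acceleration by k scales HIC by k^2.5", {
  set.seed(9)
  dt <- 2e-4
  a <- abs(sin(seq(0, pi, length.out = 80))) * 500 + runif(80, 0, 100)
  h1 <- hic(a, dt = dt)$hic
  h2 <- hic(2 * a, dt = dt)$hic
  expect_equal(h2 / h1, 2^2.5, tolerance = 1e-9)
})

test_that("windowed search agrees with the O(n^2) brute-force oracle on seeded pulses", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60 + seed
    dt <- 5e-4
    a <- pmax(0, cumsum(rnorm(n))) * 50 + runif(n, 0, 30)
    fast <- hic(a, dt = dt, max_window = 0.015)$hic
    slow <- hic_bruteforce(a, dt, max_window = 0.015)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("pressure extrema report values and times", {
  t <- seq(0, 0.01, by = 1e-4)
  df <- data.frame(time = t,
                   p_a = rep(5, length(t)),
                   p_b = 1e3 * sin(2 * pi * t / 0.01))
  ext <- pressure_extrema(df)
  a <- ext[ext$probe == "a", ]
  expect_equal(a$max, 5); expect_equal(a$min, 5)
  b <- ext[ext$probe == "b", ]
  expect_equal(b$max, 1e3, tolerance = 1e-3)
  expect_equal(b$t_max, 0.0025, tolerance = 1e-4)
  expect_equal(b$t_min, 0.0075, tolerance = 1e-4)
})

test_that("Ward classification applies the printed thresholds and is monotone", {
  thr <- tolerance_thresholds()
  expect_equal(thr$compression, 234e3)
  expect_equal(thr$tension, -186e3)
  # the printed model extrema raise no flag
  f0 <- ward_classify(list(max = 170e3, min = -65e3), thr)
  expect_false(f0$compression_exceeded)
  expect_false(f0$tension_exceeded)
  f1 <- ward_classify(list(max = 250e3, min = -50e3), thr)
  expect_true(f1$compression_exceeded); expect_false(f1$tension_exceeded)
  f2 <- ward_classify(list(max = 100e3, min = -200e3), thr)
  expect_false(f2$compression_exceeded); expect_true(f2$tension_exceeded)
  # monotone: growing extrema never clear a flag
  set.seed(4)
  mx <- sort(runif(20, 0, 5e5)); mn <- sort(runif(20, -5e5, 0), decreasing = TRUE)
  fl <- t(vapply(1:20, function(i)
    unlist(ward_classify(list(max = mx[i], min = mn[i]), thr)), c(a = TRUE, b = TRUE)))
  expect_true(all(diff(fl[, 1]) >= 0))
  expect_true(all(diff(fl[, 2]) >= 0))
  expect_error(tolerance_thresholds(tension = 10), "tension")
})

test_that("von Mises satisfies its closed forms and rotation invariance", {
  expect_equal(von_mises(-5e4 * diag(3)), 0)
  expect_equal(von_mises(c(3e5, 0, 0, 0, 0, 0)), 3e5)
  tau <- 7e4
  expect_equal(von_mises(c(0, 0, 0, tau, 0, 0)), sqrt(3) * tau, tolerance = 1e-9)
  set.seed(12)
  for (i in 1:20) {
    s <- random_symmetric6()
    R <- random_rotation()
    expect_equal(von_mises(rotate_voigt(s, R)), von_mises(s),
                 tolerance = 1e-9 * max(1, von_mises(s)))
    expect_equal(max_principal(rotate_voigt(s, R)), max_principal(s),
                 tolerance = 1e-9 * max(abs(s)))
  }
})

test_that("max principal matches closed forms and the eigen oracle", {
  expect_equal(max_principal(c(2e5, 0, 0, 0, 0, 0)), 2e5)
  expect_equal(max_principal(-3e4 * diag(3)), -3e4)
  set.seed(21)
  for (i in 1:10) {
    s <- random_symmetric6()
    expect_equal(max_principal(s),
                 max(eigen(unvoigt(s), symmetric = TRUE)$values),
                 tolerance = 1e-9 * max(abs(s)))
  }
})

test_that("null run yields a zero report without flags", {
  mesh <- coarse_head()
  h <- simulate_impact(mesh, null_loadcase(mesh), duration = 5e-4,
                       probes = place_pressure_probes(mesh))
  rep <- injury_report(h)
  expect_equal(rep$hic, 0)
  expect_false(rep$compression_exceeded)
  expect_false(rep$tension_exceeded)
  expect_lt(rep$peak_brain_von_mises, 1e-3)   # round-off pascals
})

test_that("report on scripted synthetic channels equals hand-computed values", {
  t <- seq(0, 0.02, by = 1e-4)
  acc <- ifelse(t <= 0.010, 100 * 9.81, 0)
  ch <- data.frame(time = t, impact_force = ifelse(t <= 0.01, 1000, 0),
                   acc_mag = acc,
                   p_coup = 2e5 * sin(pi * t / 0.02),
                   p_contrecoup = -1e5 * sin(pi * t / 0.02))
  fake <- structure(list(channels = ch, loadcase = list(pulse = NULL),
                         peaks = list(brain_von_mises = 1.2e4,
                                      brain_von_mises_time = 0.004,
                                      brain_von_mises_elem = 7L,
                                      skull_principal = 3e6,
                                      skull_principal_time = 0.005,
                                      skull_principal_elem = 9L)),
                    class = "impact_history")
  rep <- injury_report(fake)
  expect_equal(rep$hic, 100^2.5 * 0.010, tolerance = 1e-6)
  ext <- rep$pressure_extrema
  expect_equal(ext$max[ext$probe == "coup"], 2e5, tolerance = 1e-3)
  expect_false(rep$compression_exceeded)
  expect_true(ward_classify(list(max = 2.5e5, min = 0))$compression_exceeded)
  expect_equal(rep$peak_brain_von_mises, 1.2e4)
  expect_false(is.null(rep$hic_t1))
})
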