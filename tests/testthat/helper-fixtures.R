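# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# coarse head (fast unit-test substrate)
coarse_head <- function() fixture("coarse_head", function()
  build_head_mesh(head_config(edge_length = 0.016)))

# default head (the nahum37-coarse substrate, ~40k elements)
default_head <- function() fixture("default_head", function()
  build_head_mesh(head_config()))

# default-resolution frontal-impact run (shared by acceptance checks)
nahum_run <- function() fixture("nahum_run", function() {
  mesh <- default_head()
  probes <- place_pressure_probes(mesh)
  simulate_impact(mesh, nahum_case37(mesh), duration = 0.006,
                  probes = probes)
})

# a single regular tetrahedron of unit edge
regular_tet <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
                 c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  head_mesh(nodes, matrix(1:4, 1), "block")
}

# jittered structured block for smoothing tests
jittered_block <- function(seed, n = 4L, amp = 0.25) {
  mesh <- tet_block_mesh(n, n, n)
  set.seed(seed)
  h <- 1 / n
  lock <- boundary_nodes(mesh)
  free <- setdiff(seq_len(nrow(mesh$nodes)), lock)
  repeat {
    prop <- mesh$nodes
    prop[free, ] <- prop[free, ] +
      matrix(runif(3 * length(free), -amp * h, amp * h), ncol = 3)
    if (all(tet_volumes(prop, mesh$elems) > 0)) break
    amp <- amp * 0.8
  }
  mesh$nodes <- prop
  mesh
}

# closed unit-cube surface as an interface_surface (12 triangles)
unit_cube_surface <- function(origin = c(0, 0, 0)) {
  mesh <- tet_block_mesh(1, 1, 1, origin = origin)
  extract_region_surface(mesh, "block")
}

# brute-force hereditary-integral oracle for the one-term Prony law:
# deviatoric stress via direct convolution of G(t - s) with the strain
# rate on a fine grid (linear strain interpolation between steps)
prony_convolution_oracle <- function(material, times, dev_strain, refine = 50L) {
  n <- length(times)
  out <- matrix(0, n, ncol(dev_strain))
  tf <- seq(0, times[n], length.out = (n - 1L) * refine + 1L)
  ef <- apply(dev_strain, 2L, function(y) approx(times, y, xout = tf)$y)
  G <- function(t) material$Ginf + (material$G0 - material$Ginf) *
    exp(-material$beta * t)
  dtf <- tf[2] - tf[1]
  rate <- apply(ef, 2L, function(y) diff(y) / dtf)
  tm <- (tf[-1] + tf[-length(tf)]) / 2
  for (i in 2:n) {
    keep <- tm <= times[i]
    w <- G(times[i] - tm[keep]) * dtf
    out[i, ] <- 2 * colSums(w * rate[keep, , drop = FALSE])
  }
  out
}

# O(n^2) brute-force HIC oracle over all sample pairs
hic_bruteforce <- function(accel, dt, max_window = 0.036, g = 9.81) {
  a <- accel / g
  n <- length(a)
  cum <- c(0, cumsum((a[-1] + a[-n]) / 2 * dt))
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    w <- (j - i) * dt
    if (w > max_window + 1e-12) next
    v <- w * max((cum[j] - cum[i]) / w, 0)^2.5
    if (v > best) best <- v
  }
  best
}

random_symmetric6 <- function() {
  v <- runif(6, -1, 1) * 1e5
  v
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_voigt <- function(v, R) voigt(R %*% unvoigt(v) %*% t(R))
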