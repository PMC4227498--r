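## Constitutive registry and laws. Eleven head-tissue components: linear
## isotropic elastic skeletal/soft tissues, one-term Prony linear
## viscoelastic brain tissues G(t) = Ginf + (G0 - Ginf) exp(-beta t), and
## the CSF (a fluid, handled by the surface-based cavity).
##
## UNITS. The source table prints one modulus column headed "GPa". Read
## literally this makes brain shear moduli MPa-scale, three orders of
## magnitude stiffer than the constitutive literature those rows cite
## (kPa-scale), and printed decay constants of 35-700 read as time
## constants in seconds would give no relaxation at all within a 6 ms
## impact. The default interpretation ("mixed") therefore reads elastic E
## in GPa, Prony G in MPa (so brainstem G0 = 22.5 kPa) and the printed
## decay constant as a rate in 1/s; `units = "literal"` keeps the printed
## column head (G in GPa, decay constant as a time constant in s).
## "Table units" in the accessors always means the printed numbers.

material_table_rows <- function() {
  # name, behaviour, density kg/m^3, nu, E (table, GPa) | G0, Ginf, beta (table)
  rows <- list(
    list("Brainstem",                       "viscoelastic", 1060, 0.4996, NA,      0.0225, 0.0045,  80),
    list("Cerebral peduncle",               "viscoelastic", 1060, 0.4996, NA,      0.0225, 0.0045,  80),
    list("Cerebellum",                      "viscoelastic", 1140, 0.48,   NA,      0.528,  0.168,   35),
    list("CSF",                             "fluid",        1000, NA,     NA,      NA,     NA,      NA),
    list("Gray matter",                     "viscoelastic", 1040, 0.4996, NA,      0.034,  0.0064, 700),
    list("Lateral cartilage",               "elastic",      1500, 0.45,   0.030,   NA,     NA,      NA),
    list("Septum cartilage",                "elastic",      1500, 0.32,   0.009,   NA,     NA,      NA),
    list("Skull bone and cervical vertebra","elastic",      1210, 0.22,   8.000,   NA,     NA,      NA),
    list("Neck and facial soft tissues",    "elastic",      1040, 0.46,   0.01667, NA,     NA,      NA),
    list("Ventricles",                      "viscoelastic", 1080, 0.49,   NA,      0.101,  0.00101, 100),
    list("White matter",                    "viscoelastic", 1040, 0.4996, NA,      0.041,  0.0078, 700))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], behaviour = r[[2]], density = r[[3]], nu = r[[4]],
               E_table = r[[5]], G0_table = r[[6]], Ginf_table = r[[7]],
               beta_table = r[[8]], stringsAsFactors = FALSE)))
  df
}

#' Load the head-tissue material registry
#'
#' @param units `"mixed"` (default: elastic E in GPa, Prony G in MPa,
#'   printed decay constant as a rate in 1/s) or `"literal"` (all moduli
#'   GPa, decay constant as a time constant in s). See the package
#'   vignette for the rationale.
#' @return An object of class `material_registry`: a data frame of the 11
#'   components with both table-unit and SI columns, plus the unit
#'   interpretation as attribute `units`. Use [registry_material()] to get
#'   a single material object.
#' @export
material_registry <- function(units = c("mixed", "literal")) {
  units <- match.arg(units)
  df <- material_table_rows()
  if (units == "mixed") {
    df$E <- df$E_table * 1e9
    df$G0 <- df$G0_table * 1e6
    df$Ginf <- df$Ginf_table * 1e6
    df$beta <- df$beta_table            # already a rate, 1/s
  } else {
    df$E <- df$E_table * 1e9
    df$G0 <- df$G0_table * 1e9
    df$Ginf <- df$Ginf_table * 1e9
    df$beta <- 1 / df$beta_table        # printed value is a time constant
  }
  # bulk modulus for Prony rows from instantaneous shear and Poisson ratio
  df$K <- ifelse(df$behaviour == "viscoelastic",
                 2 * df$G0 * (1 + df$nu) / (3 * (1 - 2 * df$nu)), NA)
  structure(df, units = units, class = c("material_registry", "data.frame"))
}

#' Fetch one material from the registry
#'
#' @param x a `material_registry`.
#' @param name component name (e.g. `"Gray matter"`) or row index.
#' @return A classed material object (`elastic_material`,
#'   `prony_material` or `fluid_material`).
#' @export
registry_material <- function(x, name) {
  df <- as.data.frame(unclass(x), stringsAsFactors = FALSE)
  if (is.character(name)) {
    i <- match(name, df$name)
    if (is.na(i)) stop("unknown material: ", name)
  } else i <- name
  r <- df[i, , drop = FALSE]
  m <- as.list(r)
  m$units <- attr(x, "units")
  class(m) <- c(switch(r$behaviour,
                       elastic = "elastic_material",
                       viscoelastic = "prony_material",
                       fluid = "fluid_material"), "head_material")
  m
}

#' @export
print.head_material <- function(x, ...) {
  cat(x$name, " (", x$behaviour, "), density ", x$density, " kg/m^3", sep = "")
  if (inherits(x, "elastic_material"))
    cat(sprintf(", E = %.4g Pa, nu = %.4g", x$E, x$nu))
  if (inherits(x, "prony_material"))
    cat(sprintf(", G0 = %.4g Pa, Ginf = %.4g Pa, beta = %.4g 1/s, nu = %.4g",
                x$G0, x$Ginf, x$beta, x$nu))
  cat("\n")
  invisible(x)
}

#' One-term Prony shear relaxation modulus
#'
#' G(t) = Ginf + (G0 - Ginf) exp(-beta t): monotone non-increasing from
#' G0 at t = 0 to Ginf as t -> infinity.
#'
#' @param material a `prony_material` from [material_registry()].
#' @param t time(s), seconds, >= 0.
#' @param units `"table"` for the printed-table units, `"SI"` for Pa.
#' @return relaxation modulus at each `t`.
#' @export
relaxation_modulus <- function(material, t, units = c("table", "SI")) {
  units <- match.arg(units)
  if (!inherits(material, "prony_material"))
    stop("relaxation_modulus needs a viscoelastic material")
  if (any(t < 0)) stop("t must be >= 0")
  if (units == "table") {
    g0 <- material$G0_table; gi <- material$Ginf_table
    bt <- if (material$units == "mixed") material$beta_table else 1 / material$beta_table
  } else {
    g0 <- material$G0; gi <- material$Ginf; bt <- material$beta
  }
  gi + (g0 - gi) * exp(-bt * t)
}

#' Lame parameters of an isotropic elastic material
#'
#' @param material an `elastic_material`, or any object with fields `E`
#'   and `nu`.
#' @return list with `lambda` and `mu` (Pa).
#' @export
elastic_moduli <- function(material) {
  E <- material$E; nu <- material$nu
  if (is.na(E) || is.na(nu)) stop("material has no elastic constants")
  if (nu >= 0.5) stop("Poisson ratio must be < 0.5 (incompressible limit)")
  if (nu < 0) stop("negative Poisson ratio not supported")
  list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

## --- small-strain tensor helpers (Voigt 6-vector: xx,yy,zz,xy,yz,xz,
## tensor shear components, NOT engineering shear) ---

#' Voigt 6-vector from a symmetric 3x3 tensor (and back)
#' @param m symmetric 3x3 matrix.
#' @return length-6 vector (xx, yy, zz, xy, yz, xz).
#' @export
voigt <- function(m) {
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("tensor must be symmetric")
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[2, 3], m[1, 3])
}

#' @rdname voigt
#' @param v length-6 Voigt vector.
#' @export
unvoigt <- function(v) {
  matrix(c(v[1], v[4], v[6], v[4], v[2], v[5], v[6], v[5], v[3]), 3, 3)
}

voigt_trace <- function(v) v[1] + v[2] + v[3]
voigt_dev <- function(v) v - c(rep(voigt_trace(v) / 3, 3), 0, 0, 0)

#' Linear elastic stress update
#'
#' sigma = lambda tr(eps) I + 2 mu eps.
#' @param material an `elastic_material`.
#' @param strain small-strain tensor, symmetric 3x3 or Voigt 6-vector.
#' @return stress in the same representation (Pa).
#' @export
stress_elastic <- function(material, strain) {
  lam <- elastic_moduli(material)
  as_mat <- is.matrix(strain)
  e <- if (as_mat) voigt(strain) else strain
  s <- lam$lambda * voigt_trace(e) * c(1, 1, 1, 0, 0, 0) + 2 * lam$mu * e
  if (as_mat) unvoigt(s) else s
}

#' Fresh viscoelastic internal state
#'
#' Virgin material: zero deviatoric internal stress and zero previous
#' strain.
#' @return list with `h` (internal deviatoric stress, Voigt, Pa) and
#'   `e_prev` (previous deviatoric strain, Voigt).
#' @export
visco_state <- function() list(h = numeric(6), e_prev = numeric(6))

#' Incremental one-term Prony viscoelastic stress update
#'
#' Volumetric response is elastic with bulk modulus K; the deviatoric
#' response uses the exact exponential recursion for one Prony term:
#' h_{n+1} = exp(-beta dt) h_n + 2 (G0-Ginf) (1-exp(-beta dt))/(beta dt)
#' * delta_e, sigma_dev = 2 Ginf e_{n+1} + h_{n+1}.
#'
#' @param material a `prony_material`.
#' @param state internal state from [visco_state()] or a previous update.
#' @param strain new total small-strain tensor (3x3 or Voigt).
#' @param dt time increment (s), > 0.
#' @return list with `stress` (same representation as `strain`, Pa) and
#'   the updated `state`.
#' @export
stress_viscoelastic <- function(material, state, strain, dt) {
  if (dt <= 0) stop("dt must be > 0")
  as_mat <- is.matrix(strain)
  e_tot <- if (as_mat) voigt(strain) else strain
  ev <- voigt_trace(e_tot)
  e_dev <- voigt_dev(e_tot)
  beta <- material$beta
  a <- exp(-beta * dt)
  b <- 2 * (material$G0 - material$Ginf) * (1 - a) / (beta * dt)
  h <- a * state$h + b * (e_dev - state$e_prev)
  s_dev <- 2 * material$Ginf * e_dev + h
  s <- s_dev + material$K * ev * c(1, 1, 1, 0, 0, 0)
  list(stress = if (as_mat) unvoigt(s) else s,
       state = list(h = h, e_prev = e_dev))
}

#' Export / import the material registry as YAML
#'
#' Mirrors the constitutive table column-for-column in table units, with
#' an explicit `unit_interpretation` field.
#' @param registry a `material_registry`.
#' @param path file path.
#' @return `path`, invisibly (write); a `material_registry` (read).
#' @export
write_material_registry <- function(registry, path) {
  df <- as.data.frame(unclass(registry), stringsAsFactors = FALSE)
  doc <- list(unit_interpretation = attr(registry, "units"),
              components = lapply(seq_len(nrow(df)), function(i) {
                r <- df[i, ]
                list(name = r$name, behaviour = r$behaviour,
                     density = r$density, poisson_ratio = r$nu,
                     E_table = r$E_table, G0_table = r$G0_table,
                     Ginf_table = r$Ginf_table, beta_table = r$beta_table)
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_material_registry
#' @export
read_material_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  reg <- material_registry(units = doc$unit_interpretation)
  # sanity: the file must mirror the packaged table
  for (comp in doc$components) {
    i <- match(comp$name, reg$name)
    if (is.na(i)) stop("unknown component in registry file: ", comp$name)
  }
  reg
}

## Default mapping of mesh region labels to registry component names.
#' @export
#' @rdname material_registry
default_region_materials <- function() c(
  skull = "Skull bone and cervical vertebra",
  csf = "CSF",
  gray_matter = "Gray matter",
  white_matter = "White matter",
  cerebellum = "Cerebellum",
  brainstem = "Brainstem",
  ventricles = "Ventricles",
  soft_tissue = "Neck and facial soft tissues",
  block = "Skull bone and cervical vertebra",
  brain = "Gray matter",
  body = "Gray matter")
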