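## Injury measures: HIC over an exhaustive window search, probe-pressure
## extrema with Ward threshold classification, von Mises (brain) and
## maximum principal (skull) stress fields, and the assembled report.

#' Tolerance thresholds for pressure and HIC classification
#'
#' Brain-pressure tolerance: 234 kPa in compression, -186 kPa in tension
#' (Ward-type thresholds); HIC safety limit 1000.
#'
#' @param compression compression pressure limit (Pa).
#' @param tension tension pressure limit (Pa, negative).
#' @param hic_limit HIC safety limit.
#' @return list of class `tolerance_thresholds`.
#' @export
tolerance_thresholds <- function(compression = 234e3, tension = -186e3,
                                 hic_limit = 1000) {
  if (!(compression > 0 && tension < 0))
    stop("compression limit must be > 0 > tension limit")
  structure(list(compression = compression, tension = tension,
                 hic_limit = hic_limit), class = "tolerance_thresholds")
}

#' Head Injury Criterion
#'
#' HIC = max over windows t2 - t1 <= `max_window` of
#' (t2 - t1) * [ mean resultant acceleration in g over (t1, t2) ]^2.5,
#' by exhaustive search over sample pairs of a uniformly sampled record.
#'
#' @param accel resultant acceleration (m/s^2 by default).
#' @param dt sample interval (s); or supply `time`.
#' @param time optional sample times (uniform).
#' @param max_window window cap (s); 36 ms by default (HIC36), 15 ms for
#'   HIC15.
#' @param g gravitational conversion (m/s^2 per g).
#' @param in_g set `TRUE` if `accel` is already in g.
#' @return list with `hic`, `t1`, `t2`.
#' @export
hic <- function(accel, dt = NULL, time = NULL, max_window = 0.036,
                g = 9.81, in_g = FALSE) {
  if (!length(accel)) stop("empty acceleration series")
  if (is.null(dt)) {
    if (is.null(time)) stop("supply dt or time")
    dt <- diff(time)
    if (diff(range(dt)) > 1e-9 * max(dt)) stop("non-uniform sampling")
    dt <- dt[1]
  }
  a <- if (in_g) accel else accel / g
  n <- length(a)
  # cumulative trapezoidal integral of a (in g * s)
  cum <- c(0, cumsum((a[-1] + a[-n]) / 2 * dt))
  wmax <- max(1L, min(n - 1L, floor(max_window / dt + 1e-9)))
  best <- 0; bt <- c(0, 0)
  for (w in seq_len(wmax)) {
    i <- seq_len(n - w)
    mean_a <- (cum[i + w] - cum[i]) / (w * dt)
    val <- (w * dt) * pmax(mean_a, 0)^2.5
    k <- which.max(val)
    if (val[k] > best) { best <- val[k]; bt <- c(i[k] - 1L, i[k] - 1L + w) * dt }
  }
  list(hic = best, t1 = bt[1], t2 = bt[2])
}

#' Per-probe pressure extrema
#'
#' @param history an `impact_history` with probe channels, or a data
#'   frame with a `time` column and pressure columns.
#' @return data frame: probe, max (Pa), t_max, min (Pa), t_min.
#' @export
pressure_extrema <- function(history) {
  ch <- if (inherits(history, "impact_history")) history$channels else history
  pcols <- grep("^p_", names(ch), value = TRUE)
  if (!length(pcols))
    pcols <- setdiff(names(ch), "time")
  if (!length(pcols)) stop("no pressure channels")
  do.call(rbind, lapply(pcols, function(p) {
    y <- ch[[p]]
    data.frame(probe = sub("^p_", "", p),
               max = max(y), t_max = ch$time[which.max(y)],
               min = min(y), t_min = ch$time[which.min(y)])
  }))
}

#' Ward-type threshold classification of pressure extrema
#'
#' Raises the compression flag iff any probe maximum exceeds the
#' compression limit; the tension flag iff any probe minimum falls below
#' the tension limit. Monotone: growing extrema never clear a flag.
#'
#' @param extrema data frame from [pressure_extrema()], or a list/vector
#'   with elements `max` and `min` (Pa).
#' @param thresholds a [tolerance_thresholds()].
#' @return list with logical `compression_exceeded`, `tension_exceeded`.
#' @export
ward_classify <- function(extrema, thresholds = tolerance_thresholds()) {
  mx <- max(unlist(extrema[["max"]]))
  mn <- min(unlist(extrema[["min"]]))
  list(compression_exceeded = mx > thresholds$compression,
       tension_exceeded = mn < thresholds$tension)
}

#' von Mises stress of symmetric stress tensors
#'
#' sqrt(3/2 s:s) with s the deviatoric part. Input may be one Voigt
#' 6-vector (xx, yy, zz, xy, yz, xz; tensor shear), an n x 6 matrix, or a
#' symmetric 3 x 3 matrix.
#'
#' @param stress stress tensor(s), Pa.
#' @return von Mises stress (Pa), one value per tensor.
#' @export
von_mises <- function(stress) {
  s <- canon_stress6(stress)
  m <- (s[, 1] + s[, 2] + s[, 3]) / 3
  sqrt(1.5 * ((s[, 1] - m)^2 + (s[, 2] - m)^2 + (s[, 3] - m)^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Maximum principal stress of symmetric stress tensors
#'
#' Largest eigenvalue per tensor. Same input conventions as
#' [von_mises()].
#'
#' @param stress stress tensor(s), Pa.
#' @return maximum principal stress (Pa), one value per tensor.
#' @export
max_principal <- function(stress) {
  s <- canon_stress6(stress)
  vapply(seq_len(nrow(s)), function(i)
    max(eigen(unvoigt(s[i, ]), symmetric = TRUE, only.values = TRUE)$values),
    0)
}

canon_stress6 <- function(stress) {
  if (is.matrix(stress) && ncol(stress) == 3 && nrow(stress) == 3)
    stress <- voigt(stress)
  if (!is.matrix(stress)) stress <- matrix(stress, nrow = 1)
  if (ncol(stress) != 6) stop("stress must be 3x3 symmetric or Voigt length 6")
  stress
}

#' Assemble the injury report for a completed run
#'
#' Collects HIC (with its window), per-probe pressure extrema and Ward
#' classification, peak brain von Mises stress and peak skull maximum
#' principal stress (with times and elements), and a consistency note on
#' whether the von Mises peak time falls within half a pulse duration of
#' the impact-force peak time.
#'
#' @param history an `impact_history`.
#' @param thresholds a [tolerance_thresholds()].
#' @param hic_window HIC window cap (s).
#' @return object of class `injury_report`.
#' @export
injury_report <- function(history, thresholds = tolerance_thresholds(),
                          hic_window = 0.036) {
  ch <- history$channels
  hh <- hic(ch$acc_mag, time = ch$time, max_window = hic_window)
  ext <- if (any(grepl("^p_", names(ch)))) pressure_extrema(history) else NULL
  flags <- if (!is.null(ext)) ward_classify(ext, thresholds)
           else list(compression_exceeded = FALSE, tension_exceeded = FALSE)
  tf <- ch$time[which.max(ch$impact_force)]
  pdur <- if (!is.null(history$loadcase$pulse))
    history$loadcase$pulse$duration else NA_real_
  peak_sync <- if (is.finite(pdur) && pdur > 0 && max(ch$impact_force) > 0)
    abs(history$peaks$brain_von_mises_time - tf) <= pdur / 2 else NA
  structure(list(
    hic = hh$hic, hic_t1 = hh$t1, hic_t2 = hh$t2, hic_window = hic_window,
    hic_exceeded = hh$hic > thresholds$hic_limit,
    pressure_extrema = ext,
    compression_exceeded = flags$compression_exceeded,
    tension_exceeded = flags$tension_exceeded,
    peak_brain_von_mises = history$peaks$brain_von_mises,
    peak_brain_von_mises_time = history$peaks$brain_von_mises_time,
    peak_brain_von_mises_elem = history$peaks$brain_von_mises_elem,
    peak_skull_principal = history$peaks$skull_principal,
    peak_skull_principal_time = history$peaks$skull_principal_time,
    peak_skull_principal_elem = history$peaks$skull_principal_elem,
    von_mises_peak_synchronous = peak_sync,
    thresholds = thresholds), class = "injury_report")
}

#' @export
print.injury_report <- function(x, ...) {
  cat("injury report\n")
  cat(sprintf("  HIC%2.0f = %.4g over (%.1f, %.1f) ms%s\n",
              x$hic_window * 1e3, x$hic, x$hic_t1 * 1e3, x$hic_t2 * 1e3,
              if (x$hic_exceeded) "  [exceeds safety limit]" else ""))
  if (!is.null(x$pressure_extrema)) {
    for (i in seq_len(nrow(x$pressure_extrema))) {
      r <- x$pressure_extrema[i, ]
      cat(sprintf("  %-16s max %8.1f kPa @ %.2f ms   min %8.1f kPa @ %.2f ms\n",
                  r$probe, r$max / 1e3, r$t_max * 1e3, r$min / 1e3, r$t_min * 1e3))
    }
  }
  cat(sprintf("  compression threshold (%.0f kPa) exceeded: %s\n",
              x$thresholds$compression / 1e3, x$compression_exceeded))
  cat(sprintf("  tension threshold (%.0f kPa) exceeded: %s\n",
              x$thresholds$tension / 1e3, x$tension_exceeded))
  cat(sprintf("  peak brain von Mises %.4g kPa @ %.2f ms\n",
              x$peak_brain_von_mises / 1e3, x$peak_brain_von_mises_time * 1e3))
  cat(sprintf("  peak skull principal %.4g MPa @ %.2f ms\n",
              x$peak_skull_principal / 1e6, x$peak_skull_principal_time * 1e3))
  invisible(x)
}

#' Write an injury report as JSON
#' @param report an `injury_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_injury_report <- function(report, path) {
  out <- unclass(report)
  out$thresholds <- unclass(out$thresholds)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}
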