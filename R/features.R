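#' Positional CoP features
#'
#' Dispersion and geometry of the CoP path after centering on its mean:
#' mean/RMS/maximal distances and ranges per axis and resultant, the 95%
#' confidence ellipse area (covariance-based, chi-square factor 5.991) and
#' the principal sway direction (orientation of the leading covariance
#' eigenvector, degrees in (-90, 90] relative to the ML axis). A constant
#' trajectory yields zero dispersion and an undefined (`NA`) direction.
#'
#' @param traj A [cop_trajectory()] with at least 2 samples.
#' @return Named numeric vector of the 14 positional registry features.
#' @export
positional_features <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (length(traj$ml) < 2L) stop("positional features require >= 2 samples")
  cc <- traj_center(traj)
  dx <- cc$ml; dy <- cc$ap
  r <- sqrt(dx^2 + dy^2)
  constant <- all(dx == 0) && all(dy == 0)

  sigma <- stats::cov(cbind(dx, dy))
  det_s <- max(det(sigma), 0)
  area <- 5.991 * pi * sqrt(det_s)
  if (constant) {
    direction <- NA_real_
  } else {
    ev <- eigen(sigma, symmetric = TRUE)$vectors[, 1]
    direction <- atan2(ev[2], ev[1]) * 180 / pi
    if (direction <= -90) direction <- direction + 180
    if (direction > 90) direction <- direction - 180
  }

  c(
    "Mean distance ML" = mean(abs(dx)),
    "Mean distance AP" = mean(abs(dy)),
    "Mean distance ML-AP" = mean(r),
    "RMS sway ML" = sqrt(mean(dx^2)),
    "RMS sway AP" = sqrt(mean(dy^2)),
    "RMS sway ML-AP" = sqrt(mean(r^2)),
    "Maximal distance ML" = max(abs(dx)),
    "Maximal distance AP" = max(abs(dy)),
    "Maximal distance (Radius)" = max(r),
    "Range ML" = diff(range(dx)),
    "Range AP" = diff(range(dy)),
    "Range ML-AP" = planar_range(dx, dy),
    "95% confidence ellipse area" = area,
    "Principal sway direction" = direction
  )
}

# largest pairwise distance of the path, via its convex hull
planar_range <- function(dx, dy) {
  pts <- unique(cbind(dx, dy))
  if (nrow(pts) == 1L) return(0)
  if (nrow(pts) > 3L) {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[h, , drop = FALSE]
  }
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

#' Dynamic CoP features
#'
#' Velocity-based descriptors from finite differences at the sampling rate
#' (differences bridging a concatenation break are excluded): sway path
#' length, mean/peak velocities, speed variability, sway area per second
#' (triangle areas swept by the centered position vector per unit time),
#' phase-plane parameters (dispersion combining position and velocity) and
#' velocity-based rotational mean frequencies. Peak velocities are means of
#' the local extrema of the signed per-axis velocity (positive maxima /
#' negative minima).
#'
#' @param traj A [cop_trajectory()] with at least 3 samples.
#' @return Named numeric vector of the 17 dynamic registry features.
#' @export
dynamic_features <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (length(traj$ml) < 3L) stop("dynamic features require >= 3 samples")
  v <- traj_velocity(traj)
  cc <- traj_center(traj)
  dx <- cc$ml; dy <- cc$ap
  r <- sqrt(dx^2 + dy^2)
  t_eff <- length(v$speed) / traj$fs
  path <- sum(v$speed) / traj$fs

  mean_peaks <- function(x, positive = TRUE) {
    n <- length(x)
    if (n < 3L) return(NA_real_)
    i <- 2:(n - 1L)
    if (positive) {
      sel <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L] & x[i] > 0]
    } else {
      sel <- i[x[i] < x[i - 1L] & x[i] <= x[i + 1L] & x[i] < 0]
    }
    if (!length(sel)) return(NA_real_)
    mean(x[sel])
  }

  # triangle areas swept by the centered position vector (break pairs excluded)
  i <- seq_len(length(dx) - 1L)
  if (length(traj$breaks)) i <- setdiff(i, traj$breaks)
  tri <- 0.5 * abs(dx[i] * dy[i + 1L] - dx[i + 1L] * dy[i])
  area_rate <- sum(tri) / (length(i) / traj$fs)

  md_ml <- mean(abs(dx)); md_ap <- mean(abs(dy)); md_r <- mean(r)
  mv_ml <- mean(abs(v$vx)); mv_ap <- mean(abs(v$vy)); mv_r <- mean(v$speed)

  c(
    "Sway path length ML-AP" = path,
    "Mean Velocity ML" = mv_ml,
    "Mean Velocity AP" = mv_ap,
    "Mean Velocity ML-AP" = mv_r,
    "Mean positive peak velocity ML" = mean_peaks(v$vx, TRUE),
    "Mean positive peak velocity AP" = mean_peaks(v$vy, TRUE),
    "Mean negative peak velocity ML" = mean_peaks(v$vx, FALSE),
    "Mean negative peak velocity AP" = mean_peaks(v$vy, FALSE),
    "Velocity standard deviation ML" = stats::sd(v$vx),
    "Velocity standard deviation AP" = stats::sd(v$vy),
    "Velocity standard deviation ML-AP" = stats::sd(v$speed),
    "Sway area per second ML-AP" = area_rate,
    "Phase plane parameter ML" = sqrt(stats::var(dx) + stats::var(v$vx)),
    "Phase plane parameter AP" = sqrt(stats::var(dy) + stats::var(v$vy)),
    "Mean frequency ML" = if (md_ml > 0) mv_ml / (4 * md_ml) else NA_real_,
    "Mean frequency AP" = if (md_ap > 0) mv_ap / (4 * md_ap) else NA_real_,
    "Mean frequency ML-AP" = if (md_r > 0) mv_r / (2 * pi * md_r) else NA_real_
  )
}

#' Frequency-domain CoP features
#'
#' Spectral descriptors per axis from the Welch PSD (DC bin excluded):
#' total power, power-weighted mean frequency, centroidal frequency (root
#' of the second spectral moment ratio), PSD mode, 50% and 95% power
#' frequencies (spectral quantiles), frequency quotient (power above 2 Hz
#' over power at or below 2 Hz) and the energy content of the three bands
#' <= 0.5 Hz, 0.5-2 Hz and > 2 Hz as fractions of total power (the three
#' fractions partition the spectrum and sum to 1). A zero-power axis yields
#' `NA` for all its spectral features.
#'
#' @param traj A [cop_trajectory()].
#' @param spec_ml,spec_ap Optional precomputed [welch_psd()] estimates; by
#'   default computed from the trajectory.
#' @return Named numeric vector of the 20 frequency registry features.
#' @export
frequency_features <- function(traj, spec_ml = NULL, spec_ap = NULL) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (is.null(spec_ml)) spec_ml <- welch_psd(traj, axis = "ml")
  if (is.null(spec_ap)) spec_ap <- welch_psd(traj, axis = "ap")
  c(axis_spectral(spec_ml, "ML"), axis_spectral(spec_ap, "AP"))
}

axis_spectral <- function(spec, axis) {
  f <- spec$freq[-1L]
  p <- spec$power[-1L]
  df <- spec$freq[2L]
  tot <- sum(p) * df
  nm <- function(s) sprintf(s, axis)
  out_names <- c(
    nm("Total power (Power Spectrum Density) %s"),
    nm("Mean frequency (Power Spectrum Density) %s"),
    nm("Centroidal frequency (Power Spectrum Density) %s"),
    nm("Mode of Power Spectrum Density %s"),
    nm("50%% Power Frequency %s"),
    nm("95%% Power Frequency %s"),
    nm("Frequency Quotient Power Spectrum Density %s"),
    nm("Energy content below 0.5 Hz (Power Spectrum Density) %s"),
    nm("Energy content 0.5-2 Hz (Power Spectrum Density) %s"),
    nm("Energy content above 2 Hz (Power Spectrum Density) %s")
  )
  if (!is.finite(tot) || tot <= 0) {
    out <- rep(NA_real_, 10L)
    names(out) <- out_names
    return(out)
  }
  psum <- sum(p)
  cum <- cumsum(p) / psum
  fq_low <- sum(p[f <= 2])
  fq_high <- sum(p[f > 2])
  bands <- c(sum(p[f <= 0.5]), sum(p[f > 0.5 & f <= 2]), sum(p[f > 2])) / psum
  out <- c(
    tot,
    sum(f * p) / psum,
    sqrt(sum(f^2 * p) / psum),
    f[which.max(p)],
    f[which(cum >= 0.5)[1L]],
    f[which(cum >= 0.95)[1L]],
    if (fq_low > 0) fq_high / fq_low else NA_real_,
    bands
  )
  names(out) <- out_names
  out
}

#' Stochastic (stabilogram diffusion) CoP features
#'
#' Mean squared displacement against lag per axis and for the planar
#' resultant, with short-term and long-term linear fits: diffusion
#' coefficients (slope/2 per axis, slope/4 planar), the critical point
#' (intersection of the two fits: critical time and critical displacement),
#' log-log scaling exponents H, and the fractal dimension `2 - H_short`.
#'
#' @param traj A [cop_trajectory()] long enough that the long-term fit
#'   window (lags up to 2.5 s by default) is supported by a contiguous run.
#' @param curves Optional named list of precomputed [msd_curve()]s with
#'   elements `ml`, `ap`, `planar`.
#' @return Named numeric vector of the 21 stochastic registry features.
#' @export
stochastic_features <- function(traj, curves = NULL) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (is.null(curves)) {
    curves <- list(
      ml = msd_curve(traj, "ml"),
      ap = msd_curve(traj, "ap"),
      planar = msd_curve(traj, "planar")
    )
  }
  out <- c(
    axis_stochastic(curves$ml, "ML"),
    axis_stochastic(curves$ap, "AP"),
    axis_stochastic(curves$planar, "ML-AP")
  )
  out
}

axis_stochastic <- function(curve, axis) {
  fits <- diffusion_fits(curve)
  out <- c(
    fits$d_short, fits$d_long,
    fits$critical_time, fits$critical_displacement,
    fits$h_short, fits$h_long, fits$fractal_dimension
  )
  names(out) <- sprintf(
    c(
      "Short-term diffusion coefficient %s",
      "Long-term diffusion coefficient %s",
      "Critical time %s",
      "Critical displacement %s",
      "Short-term scaling exponent %s",
      "Long-term scaling exponent %s",
      "Fractal dimension %s"
    ),
    axis
  )
  out
}

#' Extract the full 72-feature vector for one foot
#'
#' Concatenates the four feature families in registry order. A family whose
#' preconditions fail contributes `NA` values for its features, with a
#' warning naming the family -- never silently.
#'
#' @param traj A [cop_trajectory()].
#' @return Named numeric vector of length 72 (registry order) with a
#'   logical `missing` attribute flagging unavailable features.
#' @export
extract_all <- function(traj) {
  reg <- feature_registry()
  out <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  fams <- list(
    positional = positional_features,
    dynamic = dynamic_features,
    frequency = frequency_features,
    stochastic = stochastic_features
  )
  for (fam in names(fams)) {
    vals <- tryCatch(fams[[fam]](traj), error = function(e) {
      warning(sprintf("%s features unavailable: %s", fam, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(vals)) out[names(vals)] <- vals
  }
  stopifnot(length(out) == 72L)
  attr(out, "missing") <- is.na(out)
  class(out) <- c("cop_features", "numeric")
  out
}

#' @export
print.cop_features <- function(x, ...) {
  cat(sprintf("<cop_features> 72 features, %d missing\n", sum(is.na(x))))
  invisible(x)
}
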