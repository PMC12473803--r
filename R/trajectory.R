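#' Normalized CoP coordinate bounds of the insole coordinate system
#'
#' The insole firmware exports CoP in a foot-size-independent normalized
#' coordinate system, identical for left and right feet: the medio-lateral
#' (ML) axis spans -0.5 to +0.5 and the anterior-posterior (AP) axis spans
#' approximately -0.574 to +0.426. All analyses in this package stay in these
#' dimensionless units.
#'
#' @return Named list with `ml` and `ap`, each a length-2 numeric range.
#' @export
cop_bounds <- function() {
  list(ml = c(-0.5, 0.5), ap = c(-0.574, 0.426))
}

#' Construct a single-foot CoP trajectory
#'
#' A `cop_trajectory` holds one foot's time-indexed CoP path at a fixed
#' sampling rate, optionally with per-sample TUG phase labels and recorded
#' discontinuities ("breaks") introduced when non-adjacent segments are
#' concatenated (e.g. the walk-out and walk-back sub-walks of the walking
#' scenario). Velocity- and lag-based computations never bridge a break.
#'
#' @param ml,ap Numeric vectors of normalized ML / AP coordinates (equal
#'   length). Must lie within [cop_bounds()].
#' @param fs Sampling rate in Hz (> 0).
#' @param phase Optional character/factor vector of per-sample phase labels.
#' @param breaks Optional integer vector: sample indices `i` such that the
#'   step from sample `i` to `i + 1` is a concatenation discontinuity.
#' @return An object of class `cop_trajectory` with fields `time`, `ml`,
#'   `ap`, `fs`, `phase`, `breaks`.
#' @export
cop_trajectory <- function(ml, ap, fs, phase = NULL, breaks = integer()) {
  ml <- as.numeric(ml)
  ap <- as.numeric(ap)
  if (length(ml) != length(ap)) {
    stop("`ml` and `ap` must have equal length")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyNA(ml) || anyNA(ap)) stop("CoP samples must not contain NA")
  b <- cop_bounds()
  check_bounds_vec(ml, b$ml, "ml")
  check_bounds_vec(ap, b$ap, "ap")
  if (!is.null(phase)) {
    phase <- as.character(phase)
    if (length(phase) != length(ml)) {
      stop("`phase` must match the number of samples")
    }
  }
  breaks <- sort(unique(as.integer(breaks)))
  if (length(breaks) && (any(breaks < 1L) || any(breaks >= length(ml)))) {
    stop("`breaks` must be sample indices in [1, n - 1]")
  }
  structure(
    list(
      time = (seq_along(ml) - 1L) / fs,
      ml = ml, ap = ap, fs = fs,
      phase = phase, breaks = breaks
    ),
    class = "cop_trajectory"
  )
}

check_bounds_vec <- function(x, rng, name, rows = NULL) {
  bad <- which(x < rng[1] - 1e-12 | x > rng[2] + 1e-12)
  if (length(bad)) {
    where <- if (is.null(rows)) bad[1] else rows[bad[1]]
    stop(sprintf(
      "column `%s`: value %.6g at row %d outside normalized range [%g, %g]",
      name, x[bad[1]], where, rng[1], rng[2]
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cop_trajectory> %d samples @ %g Hz (%.2f s)%s%s\n",
    length(x$ml), x$fs, length(x$ml) / x$fs,
    if (!is.null(x$phase)) sprintf(", %d phases", length(unique(x$phase))) else "",
    if (length(x$breaks)) sprintf(", %d break(s)", length(x$breaks)) else ""
  ))
  invisible(x)
}

#' @export
length.cop_trajectory <- function(x) length(x$ml)

#' Duration of a trajectory in seconds
#' @param traj A `cop_trajectory`.
#' @return Duration `n / fs` in seconds.
#' @export
traj_duration <- function(traj) length(traj$ml) / traj$fs

#' Contiguous segments of a trajectory
#'
#' Splits the sample indices at the recorded concatenation breaks.
#'
#' @param traj A `cop_trajectory`.
#' @return List of integer index vectors, one per contiguous run.
#' @keywords internal
traj_segments <- function(traj) {
  n <- length(traj$ml)
  cuts <- c(0L, traj$breaks, n)
  lapply(seq_len(length(cuts) - 1L), function(i) (cuts[i] + 1L):cuts[i + 1L])
}

#' Finite-difference CoP velocities
#'
#' First differences scaled by the sampling rate. Differences that bridge a
#' concatenation break are excluded.
#'
#' @param traj A `cop_trajectory`.
#' @return List with `vx`, `vy` (velocity components, normalized units/s) and
#'   `speed` (resultant), each of length `n - 1 - length(breaks)`.
#' @export
traj_velocity <- function(traj) {
  n <- length(traj$ml)
  if (n < 3L) stop("velocity requires at least 3 samples")
  vx <- diff(traj$ml) * traj$fs
  vy <- diff(traj$ap) * traj$fs
  if (length(traj$breaks)) {
    vx <- vx[-traj$breaks]
    vy <- vy[-traj$breaks]
  }
  list(vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

#' Center a trajectory on its mean
#' @param traj A `cop_trajectory`.
#' @return List with centered `ml` and `ap` vectors.
#' @keywords internal
traj_center <- function(traj) {
  list(ml = traj$ml - mean(traj$ml), ap = traj$ap - mean(traj$ap))
}
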