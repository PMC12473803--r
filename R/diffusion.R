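#' Stabilogram diffusion curve (mean squared displacement vs lag)
#'
#' Computes \eqn{MSD(\Delta t) = \langle (x(t+\Delta t) - x(t))^2 \rangle}
#' over all sample pairs at each lag, using an FFT autocorrelation
#' identity (O(n log n)). For the planar component the squared ML and AP
#' displacements are summed. Displacement pairs never span a concatenation
#' break: the statistic is pooled over contiguous runs.
#'
#' @param traj A [cop_trajectory()].
#' @param component `"ml"`, `"ap"` or `"planar"`.
#' @param max_lag Largest lag in seconds (default 2.5, the upper edge of the
#'   long-term fit window).
#' @param short_window,long_window Lag windows (seconds) for the short-term
#'   and long-term linear fits of the diffusion analysis.
#' @return An object of class `diffusion_curve`: `lags` (seconds, from 0),
#'   `msd` (normalized units^2, `msd[1] = 0`), `dims` (1 for a single axis,
#'   2 planar), `short_window`, `long_window`, `fs`.
#' @export
msd_curve <- function(traj, component = c("ml", "ap", "planar"),
                      max_lag = 2.5,
                      short_window = c(0.02, 0.3),
                      long_window = c(1.0, 2.5)) {
  stopifnot(inherits(traj, "cop_trajectory"))
  component <- match.arg(component)
  fs <- traj$fs
  segs <- traj_segments(traj)
  max_seg <- max(lengths(segs))
  lag_max <- min(as.integer(round(max_lag * fs)), max_seg - 1L)
  if (lag_max < 1L) stop("trajectory too short for any displacement lag")

  chans <- switch(component,
    ml = list(traj$ml), ap = list(traj$ap),
    planar = list(traj$ml, traj$ap)
  )
  num <- numeric(lag_max)
  den <- numeric(lag_max)
  for (idx in segs) {
    m <- length(idx)
    if (m < 2L) next
    lmax <- min(lag_max, m - 1L)
    cnt <- m - seq_len(lmax)
    den <- den + replace(numeric(lag_max), seq_len(lmax), cnt)
    for (x in chans) {
      num <- num + replace(numeric(lag_max), seq_len(lmax),
                           seg_sqdisp(x[idx], lmax))
    }
  }
  if (all(den == 0)) stop("no contiguous run supports any lag")
  msd <- ifelse(den > 0, num / den, NA_real_)
  structure(
    list(
      lags = c(0, seq_len(lag_max) / fs),
      msd = c(0, msd),
      dims = length(chans),
      short_window = short_window, long_window = long_window, fs = fs
    ),
    class = "diffusion_curve"
  )
}

# sum of squared displacements at lags 1..lmax for one contiguous series,
# via cumulative sums and an FFT autocorrelation
seg_sqdisp <- function(x, lmax) {
  m <- length(x)
  c2 <- cumsum(x^2)
  nfft <- stats::nextn(2L * m, 2)
  fx <- stats::fft(c(x, numeric(nfft - m)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE)) / nfft
  l <- seq_len(lmax)
  # Q(l) = sum_{i<=m-l} x_i^2 + sum_{i>l} x_i^2 ; A(l) = sum x_i x_{i+l}
  q <- c2[m - l] + (c2[m] - c2[l])
  q - 2 * ac[l + 1L]
}

#' @export
print.diffusion_curve <- function(x, ...) {
  cat(sprintf(
    "<diffusion_curve> %d lags to %.2f s (%dD), msd max %.3g\n",
    length(x$lags) - 1L, max(x$lags), x$dims, max(x$msd)
  ))
  invisible(x)
}

#' Short/long-term diffusion fits and the critical point
#'
#' Ordinary least squares fits of MSD against lag inside the short-term and
#' long-term windows (linear scale, for the diffusion coefficients) and of
#' log MSD against log lag (for the scaling exponents H). The critical
#' point is the intersection of the two linear fits. Diffusion coefficients
#' use `slope / (2 * dims)`: slope/2 per axis, slope/4 for the planar curve.
#'
#' @param curve A [msd_curve()] result.
#' @return List with `d_short`, `d_long` (diffusion coefficients),
#'   `h_short`, `h_long` (scaling exponents, slope of log-log fit / 2),
#'   `critical_time`, `critical_displacement`, `fractal_dimension`
#'   (`2 - h_short`), and the raw fit coefficients.
#' @export
diffusion_fits <- function(curve) {
  stopifnot(inherits(curve, "diffusion_curve"))
  fit_in <- function(win, loglog = FALSE) {
    sel <- which(curve$lags >= win[1] - 1e-12 & curve$lags <= win[2] + 1e-12 &
                   curve$lags > 0)
    if (length(sel) < 3L) {
      stop(sprintf("diffusion fit window [%g, %g] s has < 3 lag points",
                   win[1], win[2]))
    }
    t <- curve$lags[sel]
    y <- curve$msd[sel]
    if (loglog) {
      if (any(y <= 0)) return(c(NA_real_, NA_real_))
      t <- log(t); y <- log(y)
    }
    stats::coef(stats::lm.fit(cbind(1, t), y))
  }
  cs <- fit_in(curve$short_window)
  cl <- fit_in(curve$long_window)
  ls <- fit_in(curve$short_window, loglog = TRUE)
  ll <- fit_in(curve$long_window, loglog = TRUE)

  denom <- cs[2] - cl[2]
  if (is.finite(denom) && abs(denom) > 1e-12) {
    tc <- (cl[1] - cs[1]) / denom
    if (is.finite(tc) && tc > 0 && tc <= max(curve$lags) * 2) {
      dc <- cs[1] + cs[2] * tc
    } else {
      tc <- NA_real_; dc <- NA_real_
    }
  } else {
    tc <- NA_real_; dc <- NA_real_
  }
  h_short <- unname(ls[2] / 2)
  list(
    d_short = unname(cs[2]) / (2 * curve$dims),
    d_long = unname(cl[2]) / (2 * curve$dims),
    h_short = h_short,
    h_long = unname(ll[2] / 2),
    critical_time = unname(tc),
    critical_displacement = unname(dc),
    fractal_dimension = if (is.finite(h_short)) 2 - h_short else NA_real_,
    coef_short = cs, coef_long = cl
  )
}
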