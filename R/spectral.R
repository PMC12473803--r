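#' Welch power spectral density estimate
#'
#' Segmented averaged periodogram with a Hann window, 50% overlap and
#' per-segment mean detrending. The segment length defaults to
#' `min(256, floor(n/2))` samples. When the input trajectory contains
#' concatenation breaks, segments are drawn only from contiguous runs and
#' pooled, so no segment spans a discontinuity. The estimate is one-sided
#' and density-normalized: `sum(power) * df` equals the mean signal power
#' (Parseval, up to windowing).
#'
#' @param x Numeric signal, or a [cop_trajectory()] (in which case `axis`
#'   selects the channel and breaks are honoured).
#' @param fs Sampling rate in Hz (taken from the trajectory if given one).
#' @param axis For trajectory input: `"ml"` or `"ap"`.
#' @param nperseg Segment length in samples; default `min(256, floor(n/2))`.
#' @return An object of class `spectral_estimate`: `freq` (Hz, ascending
#'   from 0 to `fs/2`), `power` (non-negative PSD values), `nperseg`,
#'   `overlap`, `window`, `n_segments`.
#' @export
welch_psd <- function(x, fs = NULL, axis = c("ml", "ap"), nperseg = NULL) {
  breaks <- integer()
  if (inherits(x, "cop_trajectory")) {
    axis <- match.arg(axis)
    fs <- x$fs
    breaks <- x$breaks
    x <- x[[axis]]
  }
  stopifnot(is.numeric(x), !is.null(fs), fs > 0)
  n <- length(x)
  if (is.null(nperseg)) nperseg <- min(256L, floor(n / 2))
  nperseg <- as.integer(nperseg)
  if (nperseg < 8L) stop("trajectory too short for a PSD segment")
  step <- nperseg %/% 2L   # 50% overlap

  # contiguous runs
  cuts <- c(0L, breaks, n)
  runs <- lapply(seq_len(length(cuts) - 1L),
                 function(i) x[(cuts[i] + 1L):cuts[i + 1L]])

  w <- hann_window(nperseg)
  wnorm <- sum(w^2)
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  nseg <- 0L
  for (run in runs) {
    m <- length(run)
    if (m < nperseg) next
    starts <- seq(1L, m - nperseg + 1L, by = step)
    for (s in starts) {
      seg <- run[s:(s + nperseg - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- abs(stats::fft(seg)[seq_len(nfreq)])^2
      acc <- acc + sp
      nseg <- nseg + 1L
    }
  }
  if (nseg == 0L) stop("no contiguous run long enough for a PSD segment")
  # one-sided density scaling: double interior bins
  scale <- 1 / (fs * wnorm)
  p <- acc / nseg * scale
  if (nperseg %% 2L == 0L) {
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
  } else {
    p[2:nfreq] <- 2 * p[2:nfreq]
  }
  structure(
    list(
      freq = (seq_len(nfreq) - 1L) * fs / nperseg,
      power = p,
      nperseg = nperseg, overlap = 0.5, window = "hann", n_segments = nseg
    ),
    class = "spectral_estimate"
  )
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate> %d bins to %.1f Hz (%s window, nperseg=%d, %d segments)\n",
    length(x$freq), max(x$freq), x$window, x$nperseg, x$n_segments
  ))
  invisible(x)
}
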