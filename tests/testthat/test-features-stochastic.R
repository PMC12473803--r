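test_that("FFT mean squared displacement equals the naive loop oracle", {
  for (s in 1:5) {
    tr <- random_traj(s, n = 400L)
    mc <- msd_curve(tr, "ml", max_lag = 1.0)
    x <- tr$ml
    naive <- sapply(1:100, function(l) mean((x[(1 + l):400] - x[1:(400 - l)])^2))
    expect_equal(mc$msd[-1], naive, tolerance = 1e-12)
    # planar = ML + AP at equal pair counts
    mp <- msd_curve(tr, "planar", max_lag = 1.0)
    ma <- msd_curve(tr, "ap", max_lag = 1.0)
    expect_equal(mp$msd, mc$msd + ma$msd, tolerance = 1e-12)
  }
})

test_that("displacement pairs never bridge a concatenation break", {
  x <- c(seq(0, 0.05, length.out = 60), seq(0.3, 0.35, length.out = 60))
  tr <- cop_trajectory(x, rep(0, 120), fs = 100, breaks = 60L)
  mc <- msd_curve(tr, "ml", max_lag = 0.2)
  seg <- x[1:60]
  naive <- sapply(1:20, function(l) {
    d <- c(seg[(1 + l):60] - seg[1:(60 - l)],
           x[60 + (1 + l):60] - x[60 + 1:(60 - l)])
    mean(d^2)
  })
  expect_equal(mc$msd[2:21], naive, tolerance = 1e-12)
})

test_that("Brownian motion recovers its diffusion coefficient", {
  d_true <- 5e-5
  fs <- 100
  est <- sapply(1:20, function(s) {
    set.seed(s)
    x <- cumsum(rnorm(2000, sd = sqrt(2 * d_true / fs)))
    x <- pmin(pmax(x - mean(x), -0.49), 0.49)
    tr <- cop_trajectory(x, rep(0, 2000), fs = fs)
    diffusion_fits(msd_curve(tr, "ml"))$d_short
  })
  expect_lt(abs(mean(est) - d_true) / d_true, 0.15)
})

test_that("scaling exponents separate ballistic, diffusive and static regimes", {
  # constant-velocity line: MSD ~ dt^2, H -> 1, fractal dimension -> 1
  x <- seq(-0.4, 0.4, length.out = 1200)
  tr <- cop_trajectory(x, x / 2, fs = 100)
  f <- diffusion_fits(msd_curve(tr, "planar"))
  expect_equal(f$h_short, 1, tolerance = 0.05)
  expect_equal(f$fractal_dimension, 1, tolerance = 0.05)

  # white-noise position: flat MSD beyond one sample, H ~ 0
  set.seed(10)
  w <- pmin(pmax(rnorm(3000, sd = 0.05), -0.49), 0.49)
  trw <- cop_trajectory(w, rep(0, 3000), fs = 100)
  fw <- diffusion_fits(msd_curve(trw, "ml"))
  expect_lt(abs(fw$h_short), 0.1)
  expect_lt(abs(fw$h_long), 0.1)
})

test_that("the critical point is the intersection of the two fitted lines", {
  # synthetic piecewise-linear MSD: slope 4e-4 then 1e-4, crossing at 0.5 s
  lags <- seq(0, 3, by = 0.01)
  msd <- ifelse(lags <= 0.5, 4e-4 * lags, 1e-4 * lags + 1.5e-4)
  curve <- structure(
    list(lags = lags, msd = msd, dims = 1,
         short_window = c(0.02, 0.3), long_window = c(1.0, 2.5), fs = 100),
    class = "diffusion_curve"
  )
  f <- diffusion_fits(curve)
  expect_equal(f$critical_time, 0.5, tolerance = 1e-9)
  expect_equal(f$critical_displacement, 2e-4, tolerance = 1e-9)
  expect_equal(f$d_short, 2e-4, tolerance = 1e-9)
  expect_equal(f$d_long, 0.5e-4, tolerance = 1e-9)

  # too-narrow window errors
  curve$short_window <- c(0.02, 0.03)
  expect_error(diffusion_fits(curve), "< 3 lag points")
})
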