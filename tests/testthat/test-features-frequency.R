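test_that("a pure 1 Hz tone concentrates power in the mid band at its mode", {
  n <- 1500; fs <- 100
  t <- (0:(n - 1)) / fs
  tr <- cop_trajectory(0.3 * sin(2 * pi * 1.0 * t), rep(0, n), fs = fs)
  ff <- frequency_features(tr)
  bin <- fs / 256  # default segment length at this n
  expect_lte(abs(ff[["Mode of Power Spectrum Density ML"]] - 1.0), bin)
  expect_gte(ff[["Energy content 0.5-2 Hz (Power Spectrum Density) ML"]], 0.95)
  expect_lte(ff[["Energy content below 0.5 Hz (Power Spectrum Density) ML"]], 0.05)
  # zero-power AP channel reports missing spectral features
  expect_true(is.na(ff[["Total power (Power Spectrum Density) AP"]]))
})

test_that("band energies partition the spectrum and sum to one", {
  bands <- function(ax, ff) {
    sum(ff[sprintf(
      c("Energy content below 0.5 Hz (Power Spectrum Density) %s",
        "Energy content 0.5-2 Hz (Power Spectrum Density) %s",
        "Energy content above 2 Hz (Power Spectrum Density) %s"), ax)])
  }
  for (s in 1:10) {
    tr <- random_traj(s, n = 700L)
    ff <- frequency_features(tr)
    expect_equal(bands("ML", ff), 1, tolerance = 1e-9)
    expect_equal(bands("AP", ff), 1, tolerance = 1e-9)
  }
})

test_that("total Welch power approximates the signal variance (Parseval)", {
  set.seed(8)
  n <- 2000
  x <- 0.05 * sin(2 * pi * 0.8 * (0:(n - 1)) / 100) + rnorm(n, sd = 0.01)
  sp <- welch_psd(x, fs = 100)
  expect_equal(sum(sp$power) * sp$freq[2], var(x), tolerance = 0.1)
})

test_that("welch_psd agrees with a direct single-segment periodogram oracle", {
  set.seed(9)
  x <- rnorm(256)
  sp <- welch_psd(x, fs = 100, nperseg = 256L)   # exactly one segment
  w <- 0.5 - 0.5 * cos(2 * pi * (0:255) / 255)
  seg <- (x - mean(x)) * w
  raw <- abs(fft(seg)[1:129])^2 / (100 * sum(w^2))
  raw[2:128] <- 2 * raw[2:128]
  expect_equal(sp$power, raw, tolerance = 1e-12)
  expect_equal(sp$n_segments, 1L)
})

test_that("white-noise PSD modes spread across the whole band", {
  modes <- sapply(1:200, function(s) {
    set.seed(s)
    sp <- welch_psd(rnorm(512), fs = 100, nperseg = 128L)
    sp$freq[-1][which.max(sp$power[-1])]
  })
  # flat spectrum: the mode should be roughly uniform on (0, 50]
  expect_gt(suppressWarnings(ks.test(modes, "punif", 0, 50)$p.value), 0.001)
  expect_gt(diff(range(modes)), 40)
})

test_that("PSD segments never span the walking-scenario junction", {
  trial <- fixture_trial(31L, "PD")
  walk <- extract_scenario(trial, "walking")$left
  sp <- welch_psd(walk, axis = "ml")
  # 2 runs of 400 samples, 256-sample segments at 50% overlap: 2 per run
  expect_equal(sp$n_segments, 4L)
})
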