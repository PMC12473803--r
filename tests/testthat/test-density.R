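test_that("pooling concatenates all samples of a stratum", {
  cfg <- simulation_config(2, 2, seed = 20)
  coh <- simulate_cohort(cfg)
  pts <- pool_cop_samples(coh, "PD", "left")
  expect_equal(nrow(pts), 2L * length(coh$trials[[1]]$left$ml))
  expect_error(
    pool_cop_samples(simulate_cohort(simulation_config(0, 2, seed = 1)), "PD"),
    "no trials"
  )
})

test_that("a point cloud symmetric in ML yields a density symmetric in ML", {
  set.seed(4)
  x <- rnorm(400, sd = 0.08)
  y <- rnorm(400, sd = 0.05)
  pts <- cbind(c(x, -x), c(y, y))
  map <- compute_kde(pts, bandwidth = c(0.03, 0.03), gridsize = 101L)
  expect_lt(max(abs(map$density - map$density[101:1, ])), 1e-9)
})

test_that("the density integrates to ~1 and peaks at a tight cluster", {
  set.seed(5)
  pts <- cbind(rnorm(500, 0.1, 0.01), rnorm(500, -0.2, 0.01))
  map <- compute_kde(pts)
  int <- density_integral(map)
  expect_gte(int, 0.98)
  expect_lte(int, 1.0 + 1e-6)
  peak <- which(map$density == max(map$density), arr.ind = TRUE)
  expect_lt(abs(map$grid_ml[peak[1]] - 0.1), 0.02)
  expect_lt(abs(map$grid_ap[peak[2]] + 0.2), 0.02)
})

test_that("shifting the points shifts the density mode by the same amount", {
  set.seed(6)
  pts <- cbind(rnorm(300, 0, 0.02), rnorm(300, 0, 0.02))
  delta <- c(0.15, -0.1)
  m1 <- compute_kde(pts, bandwidth = c(0.02, 0.02))
  m2 <- compute_kde(sweep(pts, 2, -delta), bandwidth = c(0.02, 0.02))
  p1 <- which(m1$density == max(m1$density), arr.ind = TRUE)
  p2 <- which(m2$density == max(m2$density), arr.ind = TRUE)
  cell <- c(diff(m1$grid_ml[1:2]), diff(m1$grid_ap[1:2]))
  expect_lte(abs(m2$grid_ml[p2[1]] - m1$grid_ml[p1[1]] - delta[1]), cell[1] * 1.5)
  expect_lte(abs(m2$grid_ap[p2[2]] - m1$grid_ap[p1[2]] - delta[2]), cell[2] * 1.5)
})

test_that("cohort panels share one bandwidth and one grid; order does not matter", {
  cfg <- simulation_config(3, 3, seed = 21)
  coh <- simulate_cohort(cfg)
  maps <- cohort_density_maps(coh, gridsize = 80L)
  expect_named(maps, c("Control.left", "Control.right", "PD.left", "PD.right"))
  bw <- attr(maps, "bandwidth")
  for (m in maps) {
    expect_equal(m$bandwidth, bw)
    expect_equal(m$grid_ml, maps[[1]]$grid_ml)
    expect_equal(m$grid_ap, maps[[1]]$grid_ap)
  }
  # pooling order invariance
  pts <- pool_cop_samples(coh, "PD", "left")
  set.seed(7)
  shuffled <- pts[sample(nrow(pts)), ]
  m1 <- compute_kde(pts, bandwidth = bw, gridsize = 60L)
  m2 <- compute_kde(shuffled, bandwidth = bw, gridsize = 60L)
  expect_equal(m1$density, m2$density, tolerance = 1e-12)
})

test_that("degenerate clouds are rejected", {
  expect_error(compute_kde(cbind(rep(0.1, 5), rep(0.2, 5))), "degenerate")
  expect_error(compute_kde(cbind(0.1, 0.2)), "at least 2 points")
})
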