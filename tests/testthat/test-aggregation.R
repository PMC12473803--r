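test_that("average and asymmetry follow their closed forms", {
  expect_equal(average_feature(2, 4), 3)
  expect_equal(average_feature(7.3, 7.3), 7.3)
  expect_equal(average_feature(-1, 1), 0)

  expect_equal(asymmetry_feature(5, 5), 0)
  expect_equal(asymmetry_feature(3, 1), 0.5)
  expect_equal(asymmetry_feature(2, 0), 1)
  expect_equal(asymmetry_feature(0, 0), 0)
  expect_true(is.na(asymmetry_feature(1e-14, -1e-14)))
  expect_true(is.na(asymmetry_feature(NA, 1)))
  # signed variant for sensitivity analysis
  expect_equal(asymmetry_feature(3, 1, signed = TRUE), 0.5)
  expect_equal(asymmetry_feature(1, 3, signed = TRUE), -0.5)
})

test_that("asymmetry is side-exchange symmetric, scale-invariant and in [0, 1]", {
  set.seed(2)
  l <- rnorm(200); r <- rnorm(200)
  a <- asymmetry_feature(l, r)
  expect_equal(a, asymmetry_feature(r, l))
  expect_equal(a, asymmetry_feature(3.7 * l, 3.7 * r), tolerance = 1e-12)
  expect_true(all(a >= 0 & a <= 1))
})

test_that("average plus asymmetry reconstruct the pair up to side exchange", {
  set.seed(3)
  for (i in 1:50) {
    l <- runif(1, 0, 5); r <- runif(1, 0, 5)
    avg <- average_feature(l, r)
    asy <- asymmetry_feature(l, r)
    rec <- sort(c(avg * (1 + asy), avg * (1 - asy)))
    expect_equal(rec, sort(c(l, r)), tolerance = 1e-12)
  }
})

test_that("combine_feet yields the 144 named bilateral features", {
  trial <- fixture_trial(61L, "PD")
  fl <- extract_all(trial$left)
  fr <- extract_all(trial$right)
  both <- combine_feet(fl, fr)
  expect_length(both, 144L)
  expect_identical(names(both), scenario_feature_names())
  expect_equal(unname(both["Range ML—Average"]),
               unname((fl["Range ML"] + fr["Range ML"]) / 2))
  # identical feet: all asymmetry features 0
  same <- combine_feet(fl, fl)
  asym_cols <- grepl("—Asymmetry$", names(same))
  expect_true(all(same[asym_cols] == 0, na.rm = TRUE))
})

test_that("the scenario table has one row per participant and 144 feature columns", {
  cfg <- simulation_config(5, 4, seed = 15)
  coh <- simulate_cohort(cfg)
  tab <- cohort_feature_table(coh, "full_tug")
  expect_equal(dim(tab), c(9L, 3L + 144L))
  expect_identical(colnames(tab)[-(1:3)], scenario_feature_names())
  expect_identical(tab$group, coh$metadata$group)
  expect_true(all(tab$scenario == "full_tug"))
})

test_that("multiple trials per participant are feature-averaged; missing feet excluded", {
  trial <- fixture_trial(62L, "Control")
  fl <- extract_all(trial$left); fr <- extract_all(trial$right)
  f2 <- fl; f2[] <- as.numeric(fl) * 2
  pairs <- list(
    A = list(list(left = fl, right = fr), list(left = f2, right = fr)),
    B = list(left = fl, right = NULL)
  )
  expect_message(
    tab <- build_scenario_table(pairs, c("PD", "Control"), "full_tug"),
    "excluded"
  )
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$participant_id, "A")
  avg1 <- combine_feet(fl, fr); avg2 <- combine_feet(f2, fr)
  expect_equal(unname(unlist(tab[1, -(1:3)])),
               unname((avg1 + avg2) / 2), tolerance = 1e-12)
})
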