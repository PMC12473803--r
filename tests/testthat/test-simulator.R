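rms_sway <- function(traj) {
  cc <- traj_center(traj)
  sqrt(mean(cc$ml^2 + cc$ap^2))
}

test_that("identical config, group and seed reproduce a trial bit for bit", {
  cfg <- simulation_config(1, 1, seed = 1)
  a <- simulate_trial(cfg, "PD", 321L)
  b <- simulate_trial(cfg, "PD", 321L)
  expect_identical(a$left$ml, b$left$ml)
  expect_identical(a$right$ap, b$right$ap)
  c <- simulate_trial(cfg, "PD", 322L)
  expect_false(identical(a$left$ml, c$left$ml))
})

test_that("simulated CoP stays inside the normalized bounds under strong effects", {
  cfg <- simulation_config(
    1, 1,
    effect = effect_profile(sway_amplitude_ratio = 2, asymmetry_gain = 2.5,
                            lowfreq_power_shift = 0.8,
                            complexity_reduction = 0.6),
    seed = 1
  )
  b <- cop_bounds()
  for (s in 1:10) {
    tr <- simulate_trial(cfg, "PD", s)
    for (foot in c("left", "right")) {
      expect_true(all(tr[[foot]]$ml >= b$ml[1] & tr[[foot]]$ml <= b$ml[2]))
      expect_true(all(tr[[foot]]$ap >= b$ap[1] & tr[[foot]]$ap <= b$ap[2]))
    }
  }
})

test_that("phase structure follows the configured durations", {
  cfg <- simulation_config(1, 1, seed = 2)
  tr <- simulate_trial(cfg, "Control", 5L)
  tab <- table(tr$left$phase)
  expect_equal(as.integer(tab[c("sit_to_stand", "walk_out", "turn",
                                "walk_back", "turn_to_sit")]),
               c(200L, 400L, 200L, 400L, 300L))
  expect_error(simulation_config(1, 1, phase_durations = c(
    sit_to_stand = 0, walk_out = 4, turn = 2, walk_back = 4, turn_to_sit = 3
  )), "positive")
  expect_error(simulate_trial(cfg, "patient", 5L), "PD")
})

test_that("null effect profile gives PD and Control one generative law", {
  cfg <- simulation_config(1, 1, effect = effect_profile_zero(), seed = 3)
  rms_pd <- sapply(1:50, function(s) rms_sway(simulate_trial(cfg, "PD", s)$left))
  rms_ct <- sapply(51:100, function(s) rms_sway(simulate_trial(cfg, "Control", s)$left))
  expect_gt(wilcox.test(rms_pd, rms_ct)$p.value, 0.01)
})

test_that("asymmetry gain raises the left/right asymmetry of RMS sway", {
  asym_at <- function(gain) {
    cfg <- simulation_config(
      1, 1, effect = effect_profile(asymmetry_gain = gain), seed = 4
    )
    mean(sapply(1:50, function(s) {
      tr <- simulate_trial(cfg, "PD", s)
      asymmetry_feature(rms_sway(tr$left), rms_sway(tr$right))
    }))
  }
  expect_gt(asym_at(2.0), asym_at(1.0))
})

test_that("expected RMS sway grows with the sway amplitude ratio", {
  mean_rms_at <- function(ratio) {
    cfg <- simulation_config(
      1, 1, effect = effect_profile(sway_amplitude_ratio = ratio), seed = 5
    )
    mean(sapply(1:30, function(s) rms_sway(simulate_trial(cfg, "PD", s)$left)))
  }
  r <- sapply(c(1.0, 1.5, 2.0), mean_rms_at)
  expect_true(all(diff(r) > 0))
})

test_that("cohorts have the requested composition and are seed-deterministic", {
  cfg <- simulation_config(39, 38, seed = 6)
  coh <- simulate_cohort(cfg)
  expect_length(coh$trials, 77L)
  expect_equal(sum(coh$metadata$group == "PD") / 77, 39 / 77)
  expect_false(anyDuplicated(coh$metadata$participant_id) > 0)

  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$metadata, coh2$metadata)
  expect_identical(coh$trials[[40]]$left$ml, coh2$trials[[40]]$left$ml)

  small <- simulate_cohort(simulation_config(0, 5, seed = 7))
  expect_length(small$trials, 5L)
  expect_true(all(small$metadata$group == "Control"))
  expect_message(simulate_cohort(simulation_config(0, 0, seed = 8)), "zero")
})
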