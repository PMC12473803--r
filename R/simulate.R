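#' Group-effect profile for the synthetic TUG CoP generator
#'
#' Bundles the four group-level contrasts the simulator imposes on PD trials
#' relative to controls, mirroring the sway abnormalities reported for PD:
#' enlarged sway, lateralized left/right asymmetry, a shift of oscillatory
#' power into the low-frequency band, and reduced stochastic complexity
#' (smoother, more regular sway).
#'
#' @param sway_amplitude_ratio Multiplier (> 0) on the oscillatory and
#'   stochastic sway magnitude of PD trials. Default 1.3.
#' @param asymmetry_gain Multiplier (> 0) applied to the sway magnitude of
#'   one randomly lateralized foot in PD trials. Default 1.4.
#' @param lowfreq_power_shift Fraction in [0, 1] of the oscillatory power
#'   above 0.5 Hz that is moved below 0.5 Hz in PD trials. Default 0.3.
#' @param complexity_reduction Fraction in [0, 1) by which the innovation
#'   standard deviation of the autoregressive sway component is reduced in PD
#'   (its stationary variance is preserved, so the signal becomes smoother
#'   without changing magnitude). Default 0.3.
#' @return An object of class `effect_profile`.
#' @seealso [effect_profile_zero()] for the null (no group difference) profile.
#' @export
effect_profile <- function(sway_amplitude_ratio = 1.3,
                           asymmetry_gain = 1.4,
                           lowfreq_power_shift = 0.3,
                           complexity_reduction = 0.3) {
  stopifnot(
    sway_amplitude_ratio > 0, asymmetry_gain > 0,
    lowfreq_power_shift >= 0, lowfreq_power_shift <= 1,
    complexity_reduction >= 0, complexity_reduction < 1
  )
  structure(
    list(
      sway_amplitude_ratio = sway_amplitude_ratio,
      asymmetry_gain = asymmetry_gain,
      lowfreq_power_shift = lowfreq_power_shift,
      complexity_reduction = complexity_reduction
    ),
    class = "effect_profile"
  )
}

#' Null effect profile
#'
#' All effects at their neutral values: PD and control trials are drawn from
#' the identical generative law. Used for null-calibration of the pipeline.
#'
#' @return An `effect_profile` with ratios 1 and shifts 0.
#' @export
effect_profile_zero <- function() {
  effect_profile(
    sway_amplitude_ratio = 1, asymmetry_gain = 1,
    lowfreq_power_shift = 0, complexity_reduction = 0
  )
}

#' Simulation configuration for synthetic TUG cohorts
#'
#' @param n_pd,n_control Number of PD / control participants (>= 0).
#' @param sampling_rate Sampling rate in Hz (default 100, the insole rate).
#' @param phase_durations Named numeric vector of per-phase durations in
#'   seconds for the five TUG phases `sit_to_stand`, `walk_out`, `turn`,
#'   `walk_back`, `turn_to_sit`. All must be positive. Defaults 2/4/2/4/3 s,
#'   chosen so a trial is long enough for the stabilogram-diffusion and
#'   spectral fits to be well-posed.
#' @param effect An [effect_profile()] describing the PD-vs-control contrast.
#' @param seed Integer master seed for cohort generation.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_pd, n_control,
                              sampling_rate = 100,
                              phase_durations = c(
                                sit_to_stand = 2, walk_out = 4, turn = 2,
                                walk_back = 4, turn_to_sit = 3
                              ),
                              effect = effect_profile(),
                              seed = 1L) {
  stopifnot(
    n_pd >= 0, n_control >= 0, sampling_rate > 0,
    inherits(effect, "effect_profile")
  )
  required <- c("sit_to_stand", "walk_out", "turn", "walk_back", "turn_to_sit")
  if (!all(required %in% names(phase_durations))) {
    stop("`phase_durations` must name all five TUG phases")
  }
  phase_durations <- phase_durations[required]
  if (any(!is.finite(phase_durations)) || any(phase_durations <= 0)) {
    stop("all phase durations must be positive")
  }
  structure(
    list(
      n_pd = as.integer(n_pd), n_control = as.integer(n_control),
      sampling_rate = sampling_rate, phase_durations = phase_durations,
      effect = effect, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Deterministic phase-dependent CoP template shared by both feet:
# heel-to-toe AP progression during steps, a lateral excursion during the
# turn, smooth ramps during the sit/stand transitions.
tug_template <- function(config, f_step) {
  fs <- config$sampling_rate
  dur <- config$phase_durations
  out_ml <- out_ap <- out_phase <- vector("list", 5L)
  names_p <- names(dur)
  for (i in seq_along(dur)) {
    d <- dur[[i]]
    n <- max(1L, round(d * fs))
    t <- (seq_len(n) - 1L) / fs
    p <- names_p[i]
    if (p == "sit_to_stand") {
      ml <- rep(0, n)
      ap <- -0.15 + 0.15 * (1 - cos(pi * t / d)) / 2
    } else if (p %in% c("walk_out", "walk_back")) {
      ml <- 0.05 * sin(2 * pi * f_step * t)
      ap <- -0.18 + 0.28 * (0.5 - 0.5 * cos(2 * pi * f_step * t))
    } else if (p == "turn") {
      ml <- 0.12 * sin(pi * t / d)
      ap <- rep(-0.05, n)
    } else { # turn_to_sit
      ml <- rep(0, n)
      ap <- -0.12 * (1 - cos(pi * t / d)) / 2
    }
    out_ml[[i]] <- ml
    out_ap[[i]] <- ap
    out_phase[[i]] <- rep(p, n)
  }
  list(
    ml = unlist(out_ml), ap = unlist(out_ap),
    phase = unlist(out_phase)
  )
}

ar1_series <- function(n, phi, innov_sd) {
  as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                           method = "recursive"))
}

clamp <- function(x, rng) pmin(pmax(x, rng[1] + 1e-6), rng[2] - 1e-6)

#' Simulate one two-foot TUG trial
#'
#' Per-foot CoP is the sum of a deterministic phase template, a band-limited
#' oscillatory component (one tone below 0.5 Hz, one near 1.1 Hz, with the
#' power split between them controlled by the low-frequency fraction) and a
#' first-order autoregressive stochastic component. PD trials realize the
#' configured [effect_profile()]: a sway-magnitude multiplier, a gain on one
#' randomly lateralized foot, a shift of oscillatory power below 0.5 Hz and
#' a reduction of autoregressive innovation variance at preserved stationary
#' variance. Identical `(config, group, participant_seed)` reproduce the
#' trial bit for bit.
#'
#' @param config A [simulation_config()].
#' @param group `"PD"` or `"Control"`.
#' @param participant_seed Integer seed for this participant's random draws.
#' @param participant_id Identifier attached to the trial.
#' @return An object of class `tug_trial`: fields `left` and `right`
#'   ([cop_trajectory()]s with phase labels), `group_label`,
#'   `participant_id`.
#' @export
simulate_trial <- function(config, group, participant_seed,
                           participant_id = sprintf("P%d", participant_seed)) {
  stopifnot(inherits(config, "simulation_config"))
  if (!group %in% c("PD", "Control")) {
    stop("`group` must be \"PD\" or \"Control\"")
  }
  set.seed(as.integer(participant_seed))
  eff <- config$effect
  fs <- config$sampling_rate

  # participant-level draws (consumed identically for both groups so the
  # null profile yields one common generative law)
  amp_osc <- stats::rlnorm(1, log(0.035), 0.20)   # oscillatory amplitude
  sd_ar <- stats::rlnorm(1, log(0.012), 0.20)     # stationary AR sway sd
  f_step <- min(max(stats::rnorm(1, 0.9, 0.08), 0.6), 1.2)
  foot_nat <- exp(stats::rnorm(2, 0, 0.05))       # natural L/R variation
  asym_side <- sample(c("left", "right"), 1L)

  is_pd <- group == "PD"
  amp_mult <- if (is_pd) eff$sway_amplitude_ratio else 1
  low_frac0 <- 0.30                               # control low-freq fraction
  low_frac <- if (is_pd) {
    low_frac0 + eff$lowfreq_power_shift * (1 - low_frac0)
  } else {
    low_frac0
  }
  phi0 <- 0.95
  phi <- if (is_pd) {
    sqrt(1 - (1 - eff$complexity_reduction)^2 * (1 - phi0^2))
  } else {
    phi0
  }

  tmpl <- tug_template(config, f_step)
  n <- length(tmpl$ml)
  b <- cop_bounds()

  feet <- list()
  for (k in 1:2) {
    foot <- c("left", "right")[k]
    gain <- foot_nat[k] * amp_mult *
      (if (is_pd && foot == asym_side) eff$asymmetry_gain else 1)
    a_tot <- amp_osc * gain
    a_low <- a_tot * sqrt(low_frac)
    a_mid <- a_tot * sqrt(1 - low_frac)
    sd_stat <- sd_ar * gain
    innov <- sd_stat * sqrt(1 - phi^2)
    t <- (seq_len(n) - 1L) / fs
    ph <- stats::runif(4, 0, 2 * pi)
    osc_ml <- a_low * sin(2 * pi * 0.25 * t + ph[1]) +
      a_mid * sin(2 * pi * 1.1 * t + ph[2])
    osc_ap <- a_low * sin(2 * pi * 0.25 * t + ph[3]) +
      a_mid * sin(2 * pi * 1.1 * t + ph[4])
    ar_ml <- ar1_series(n, phi, innov)
    ar_ap <- ar1_series(n, phi, innov)
    feet[[foot]] <- cop_trajectory(
      ml = clamp(tmpl$ml + osc_ml + ar_ml, b$ml),
      ap = clamp(tmpl$ap + osc_ap + ar_ap, b$ap),
      fs = fs, phase = tmpl$phase
    )
  }

  structure(
    list(
      left = feet$left, right = feet$right,
      group_label = group, participant_id = participant_id
    ),
    class = "tug_trial"
  )
}

#' @export
print.tug_trial <- function(x, ...) {
  cat(sprintf(
    "<tug_trial> %s [%s], %d samples/foot @ %g Hz\n",
    x$participant_id, x$group_label, length(x$left$ml), x$left$fs
  ))
  invisible(x)
}

#' Simulate a cohort of TUG trials
#'
#' Generates `n_pd + n_control` participants with unique ids, deterministic
#' under the configuration seed: per-participant seeds are drawn once from
#' the master seed, so the same configuration reproduces the identical
#' cohort.
#'
#' @param config A [simulation_config()].
#' @return An object of class `tug_cohort`: `trials` (list of `tug_trial`)
#'   and `metadata` (data frame with `participant_id`, `group`, `seed`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_pd + config$n_control
  if (n == 0L) {
    message("simulate_cohort: zero-participant cohort requested")
    return(structure(
      list(trials = list(), metadata = data.frame(
        participant_id = character(), group = character(), seed = integer()
      )),
      class = "tug_cohort"
    ))
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- c(rep("PD", config$n_pd), rep("Control", config$n_control))
  ids <- sprintf("P%03d", seq_len(n))
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    trials[[i]] <- simulate_trial(config, groups[i], seeds[i], ids[i])
  }
  names(trials) <- ids
  structure(
    list(
      trials = trials,
      metadata = data.frame(
        participant_id = ids, group = groups, seed = seeds,
        stringsAsFactors = FALSE
      )
    ),
    class = "tug_cohort"
  )
}

#' @export
print.tug_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf(
    "<tug_cohort> %d participants (%s)\n", nrow(x$metadata),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")
  ))
  invisible(x)
}
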