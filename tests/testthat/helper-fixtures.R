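# Shared fixture builders. Everything is generated in code under fixed seeds.

# small circle trajectory within the normalized bounds
circle_traj <- function(r = 0.3, n = 1000L, fs = 100, omega = 2 * pi) {
  t <- (seq_len(n) - 1L) / fs
  cop_trajectory(ml = r * cos(omega * t), ap = r * sin(omega * t), fs = fs)
}

random_traj <- function(seed, n = 600L, fs = 100, sd = 0.002) {
  set.seed(seed)
  ml <- cumsum(rnorm(n, sd = sd))
  ap <- cumsum(rnorm(n, sd = sd))
  ml <- pmin(pmax(ml - mean(ml), -0.45), 0.45)
  ap <- pmin(pmax(ap - mean(ap), -0.52), 0.38)
  cop_trajectory(ml = ml, ap = ap, fs = fs)
}

# one default-effect simulated trial, cached per session
sim_fixture_env <- new.env()
fixture_trial <- function(seed = 101L, group = "PD") {
  key <- paste0(group, seed)
  if (is.null(sim_fixture_env[[key]])) {
    cfg <- simulation_config(1, 1, seed = seed)
    sim_fixture_env[[key]] <- simulate_trial(cfg, group, seed)
  }
  sim_fixture_env[[key]]
}

# tiny labelled feature table with planted signal in chosen columns
toy_feature_table <- function(n_per_class = 12L, informative = 1L,
                              effect = 3, seed = 1L, duplicate = FALSE) {
  set.seed(seed)
  nm <- scenario_feature_names()
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * length(nm)), n, length(nm))
  y <- rep(c("Control", "PD"), each = n_per_class)
  for (j in informative) X[y == "PD", j] <- X[y == "PD", j] + effect
  if (duplicate) X[, informative[1] + 1L] <- X[, informative[1]]
  out <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = y, scenario = "full_tug",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  cbind(out, as.data.frame(X, check.names = FALSE) |>
          stats::setNames(nm))
}
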