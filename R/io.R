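#' Write a TUG trial to CSV
#'
#' One row per sample, UTF-8, '.' decimal separator, header columns `time`,
#' `ml_left`, `ap_left`, `ml_right`, `ap_right` and, when present, `phase`.
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the doubles exactly.
#'
#' @param trial A `tug_trial` (see [simulate_trial()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "tug_trial"))
  df <- data.frame(
    time = fmt17(trial$left$time),
    ml_left = fmt17(trial$left$ml),
    ap_left = fmt17(trial$left$ap),
    ml_right = fmt17(trial$right$ml),
    ap_right = fmt17(trial$right$ap),
    stringsAsFactors = FALSE
  )
  if (!is.null(trial$left$phase)) df$phase <- trial$left$phase
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g", width = 1)

#' Read a TUG trial from CSV
#'
#' Accepts the dialect written by [write_trial()]: mandatory columns `time`,
#' `ml_left`, `ap_left`, `ml_right`, `ap_right`, optional `phase`, and
#' optional 32 per-sensor force columns `f01_left` .. `f16_left`,
#' `f01_right` .. `f16_right`. When force columns are present and CoP
#' columns are absent -- or `recompute_cop = TRUE` -- the CoP is computed
#' from the forces via [compute_cop_series()]; otherwise the exported CoP
#' columns take precedence. Malformed rows are reported with their line
#' numbers; coordinates outside the normalized bounds and non-uniform
#' timestamps (tolerance 1e-6 s) are rejected.
#'
#' @param path CSV file path.
#' @param recompute_cop Force CoP recomputation from sensor columns.
#' @param layout Sensor geometry for recomputation, see [sensor_layout()].
#' @return A `tug_trial` with `group_label = NA` (labels live in cohort
#'   metadata, not in trial files).
#' @export
read_trial <- function(path, recompute_cop = FALSE, layout = sensor_layout()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  sensor_cols <- function(side) sprintf("f%02d_%s", 1:16, side)
  have_sensors <- all(c(sensor_cols("left"), sensor_cols("right")) %in% names(df))
  cop_cols <- c("ml_left", "ap_left", "ml_right", "ap_right")
  have_cop <- all(cop_cols %in% names(df))

  if (!"time" %in% names(df)) stop("missing mandatory column `time`")
  if (!have_cop && !have_sensors) {
    missing <- setdiff(cop_cols, names(df))
    stop(sprintf(
      "missing mandatory column(s): %s (and no complete sensor-force columns)",
      paste(missing, collapse = ", ")
    ))
  }

  num <- function(col) {
    x <- df[[col]]
    if (is.character(x)) {
      xx <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xx) & !is.na(x))
      if (length(bad)) {
        stop(sprintf(
          "column `%s`: malformed value %s at line %d",
          col, dQuote(x[bad[1]]), bad[1] + 1L
        ), call. = FALSE)
      }
      x <- xx
    }
    bad <- which(is.na(x))
    if (length(bad)) {
      stop(sprintf("column `%s`: missing value at line %d", col, bad[1] + 1L),
           call. = FALSE)
    }
    as.numeric(x)
  }

  time <- num("time")
  if (length(time) < 2L) stop("trial must contain at least 2 samples")
  dt <- diff(time)
  fs <- 1 / stats::median(dt)
  bad_dt <- which(abs(dt - 1 / fs) > 1e-6)
  if (length(bad_dt)) {
    stop(sprintf(
      "non-uniform timestamps: step at line %d deviates by %.3g s (tolerance 1e-6 s)",
      bad_dt[1] + 2L, abs(dt[bad_dt[1]] - 1 / fs)
    ))
  }

  if (have_cop && !recompute_cop) {
    ml_l <- num("ml_left"); ap_l <- num("ap_left")
    ml_r <- num("ml_right"); ap_r <- num("ap_right")
  } else {
    if (!have_sensors) stop("CoP recomputation requested but sensor columns absent")
    fl <- sapply(sensor_cols("left"), num)
    fr <- sapply(sensor_cols("right"), num)
    cl <- compute_cop_series(fl, layout)
    cr <- compute_cop_series(fr, layout)
    ml_l <- cl$x; ap_l <- cl$y; ml_r <- cr$x; ap_r <- cr$y
  }

  b <- cop_bounds()
  rows <- seq_along(ml_l) + 1L  # header is line 1
  check_bounds_vec(ml_l, b$ml, "ml_left", rows)
  check_bounds_vec(ap_l, b$ap, "ap_left", rows)
  check_bounds_vec(ml_r, b$ml, "ml_right", rows)
  check_bounds_vec(ap_r, b$ap, "ap_right", rows)

  phase <- if ("phase" %in% names(df)) as.character(df$phase) else NULL
  structure(
    list(
      left = cop_trajectory(ml_l, ap_l, fs, phase),
      right = cop_trajectory(ml_r, ap_r, fs, phase),
      group_label = NA_character_,
      participant_id = tools::file_path_sans_ext(basename(path))
    ),
    class = "tug_trial"
  )
}

#' Extract an analysis scenario from a trial
#'
#' Scenario `"full_tug"` is the whole recording. Scenario `"walking"` keeps
#' only the 3 m walking segments (walk-out and walk-back), concatenated in
#' time order; the junction between the two sub-walks is recorded as a break
#' so that velocity differences, Welch segments and diffusion displacement
#' pairs never bridge it.
#'
#' @param trial A `tug_trial` with per-sample phase labels (required for the
#'   walking scenario).
#' @param scenario `"full_tug"` or `"walking"`.
#' @return List with elements `left` and `right` ([cop_trajectory()]s).
#' @export
extract_scenario <- function(trial, scenario = c("full_tug", "walking")) {
  stopifnot(inherits(trial, "tug_trial"))
  scenario <- match.arg(scenario)
  if (scenario == "full_tug") {
    return(list(left = trial$left, right = trial$right))
  }
  if (is.null(trial$left$phase)) {
    stop("walking scenario requires per-sample phase annotations")
  }
  subset_foot <- function(traj) {
    idx <- which(traj$phase %in% c("walk_out", "walk_back"))
    if (!length(idx)) stop("no walking samples in trial")
    breaks <- which(diff(idx) > 1L)
    cop_trajectory(
      ml = traj$ml[idx], ap = traj$ap[idx], fs = traj$fs,
      phase = traj$phase[idx], breaks = breaks
    )
  }
  list(left = subset_foot(trial$left), right = subset_foot(trial$right))
}
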