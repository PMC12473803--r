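#' Bilateral average of a feature
#'
#' Arithmetic mean of the left- and right-foot values, `(L + R) / 2`.
#' Missingness on either side propagates. Vectorized.
#'
#' @param left,right Numeric feature value(s).
#' @return `(left + right) / 2`.
#' @export
average_feature <- function(left, right) {
  (left + right) / 2
}

#' Bilateral asymmetry index of a feature
#'
#' Normalized absolute left/right difference, `|L - R| / (|L| + |R|)`,
#' guaranteed to lie in [0, 1]; it quantifies lateralized imbalance. When
#' both sides are exactly zero the index is defined as 0 (perfect symmetry
#' at null magnitude). When the denominator is below `1e-12` with unequal
#' sides -- a difference at floating-noise level -- the result is `NA`.
#' A signed variant `(L - R) / (L + R)` is available for sensitivity
#' analysis.
#'
#' @param left,right Numeric feature value(s).
#' @param signed Use the signed variant (default `FALSE`).
#' @return Asymmetry index (vectorized).
#' @export
asymmetry_feature <- function(left, right, signed = FALSE) {
  if (signed) {
    den <- left + right
    out <- ifelse(abs(den) > 1e-12, (left - right) / den, NA_real_)
    out[left == 0 & right == 0] <- 0
    return(out)
  }
  den <- abs(left) + abs(right)
  out <- ifelse(den > 1e-12, abs(left - right) / den, NA_real_)
  out[left == 0 & right == 0] <- 0
  out
}

#' Combine a left/right feature pair into the 144 bilateral features
#'
#' @param left,right Length-72 named feature vectors over the identical
#'   registry (see [extract_all()]).
#' @param signed Passed to [asymmetry_feature()].
#' @return Named numeric vector of length 144: all 72 `"<name>\u2014Average"`
#'   columns followed by all 72 `"<name>\u2014Asymmetry"` columns.
#' @export
combine_feet <- function(left, right, signed = FALSE) {
  if (!identical(names(left), names(right))) {
    stop("left and right feature vectors must share the identical registry order")
  }
  reg <- feature_registry()
  if (!identical(names(left), reg$name)) {
    stop("feature vectors must follow the registry order")
  }
  avg <- average_feature(as.numeric(left), as.numeric(right))
  asy <- asymmetry_feature(as.numeric(left), as.numeric(right), signed = signed)
  stats::setNames(c(avg, asy), scenario_feature_names())
}

#' Bilateral feature column names
#'
#' @return Character vector of the 144 scenario feature column names
#'   (72 averages then 72 asymmetries).
#' @export
scenario_feature_names <- function() {
  reg <- feature_registry()
  c(paste0(reg$name, "\u2014Average"), paste0(reg$name, "\u2014Asymmetry"))
}

#' Build the participants-by-144 scenario feature table
#'
#' @param pairs Named list (one element per participant) of lists with
#'   elements `left` and `right`, each a length-72 feature vector; or a list
#'   of such pair lists per participant when several trials are available,
#'   in which case feature values are averaged across trials.
#' @param labels Character vector of group labels (`"PD"`/`"Control"`),
#'   aligned with `pairs`.
#' @param scenario Scenario tag, `"full_tug"` or `"walking"`.
#' @param signed Passed to [asymmetry_feature()].
#' @return Data frame: `participant_id`, `group`, `scenario`, then the 144
#'   feature columns in fixed order (averages, then asymmetries).
#' @export
build_scenario_table <- function(pairs, labels,
                                 scenario = c("full_tug", "walking"),
                                 signed = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(length(pairs) == length(labels))
  ids <- names(pairs)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_along(pairs))

  one_participant <- function(p, id) {
    # single pair or list of per-trial pairs
    if (any(c("left", "right") %in% names(p))) p <- list(p)
    ok <- vapply(p, function(q) !is.null(q$left) && !is.null(q$right), logical(1))
    if (!all(ok)) {
      message(sprintf(
        "participant %s: %d trial(s) missing a foot, excluded", id, sum(!ok)
      ))
      p <- p[ok]
    }
    if (!length(p)) return(NULL)
    rows <- do.call(rbind, lapply(p, function(q) {
      combine_feet(q$left, q$right, signed = signed)
    }))
    colMeans(rows)
  }

  feats <- Map(one_participant, pairs, ids)
  keep <- !vapply(feats, is.null, logical(1))
  if (any(!keep)) {
    message(sprintf("%d participant(s) excluded (missing a foot)", sum(!keep)))
  }
  mat <- do.call(rbind, feats[keep])
  out <- data.frame(
    participant_id = ids[keep],
    group = labels[keep],
    scenario = scenario,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  out <- cbind(out, as.data.frame(mat, check.names = FALSE))
  rownames(out) <- NULL
  stopifnot(identical(colnames(out)[-(1:3)], scenario_feature_names()))
  out
}

#' Extract the scenario feature table for a simulated cohort
#'
#' Runs [extract_scenario()] and [extract_all()] for every participant's
#' trial(s) and assembles the 144-column table.
#'
#' @param cohort A `tug_cohort` from [simulate_cohort()].
#' @param scenario `"full_tug"` or `"walking"`.
#' @param signed Passed to [asymmetry_feature()].
#' @return See [build_scenario_table()].
#' @export
cohort_feature_table <- function(cohort, scenario = c("full_tug", "walking"),
                                 signed = FALSE) {
  stopifnot(inherits(cohort, "tug_cohort"))
  scenario <- match.arg(scenario)
  pairs <- lapply(cohort$trials, function(trial) {
    sc <- extract_scenario(trial, scenario)
    list(left = extract_all(sc$left), right = extract_all(sc$right))
  })
  build_scenario_table(pairs, cohort$metadata$group, scenario, signed = signed)
}
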