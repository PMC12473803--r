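#' The frozen 72-feature CoP registry
#'
#' Canonical ordered list of the 72 per-foot CoP sway features across the
#' four domains, following the Quijoux/Prieto posturographic taxonomy:
#' 14 positional, 17 dynamic, 20 frequency (10 per axis) and 21 stochastic
#' (7 per ML / AP / planar component). Feature names are the field's
#' conventional names with axis suffixes `ML`, `AP` and `ML-AP` (planar /
#' resultant). Every name is unique and the count of 72 is asserted at load
#' time; downstream code addresses features by registry name, never by
#' position.
#'
#' @return Data frame with columns `name`, `domain`
#'   (`positional`/`dynamic`/`frequency`/`stochastic`) and `axis`
#'   (`ML`, `AP`, `ML-AP`, `planar`).
#' @export
feature_registry <- function() {
  .tugcop_registry
}

make_registry <- function() {
  row <- function(name, domain, axis) {
    data.frame(name = name, domain = domain, axis = axis,
               stringsAsFactors = FALSE)
  }
  positional <- rbind(
    row("Mean distance ML", "positional", "ML"),
    row("Mean distance AP", "positional", "AP"),
    row("Mean distance ML-AP", "positional", "ML-AP"),
    row("RMS sway ML", "positional", "ML"),
    row("RMS sway AP", "positional", "AP"),
    row("RMS sway ML-AP", "positional", "ML-AP"),
    row("Maximal distance ML", "positional", "ML"),
    row("Maximal distance AP", "positional", "AP"),
    row("Maximal distance (Radius)", "positional", "ML-AP"),
    row("Range ML", "positional", "ML"),
    row("Range AP", "positional", "AP"),
    row("Range ML-AP", "positional", "ML-AP"),
    row("95% confidence ellipse area", "positional", "planar"),
    row("Principal sway direction", "positional", "planar")
  )
  dynamic <- rbind(
    row("Sway path length ML-AP", "dynamic", "ML-AP"),
    row("Mean Velocity ML", "dynamic", "ML"),
    row("Mean Velocity AP", "dynamic", "AP"),
    row("Mean Velocity ML-AP", "dynamic", "ML-AP"),
    row("Mean positive peak velocity ML", "dynamic", "ML"),
    row("Mean positive peak velocity AP", "dynamic", "AP"),
    row("Mean negative peak velocity ML", "dynamic", "ML"),
    row("Mean negative peak velocity AP", "dynamic", "AP"),
    row("Velocity standard deviation ML", "dynamic", "ML"),
    row("Velocity standard deviation AP", "dynamic", "AP"),
    row("Velocity standard deviation ML-AP", "dynamic", "ML-AP"),
    row("Sway area per second ML-AP", "dynamic", "ML-AP"),
    row("Phase plane parameter ML", "dynamic", "ML"),
    row("Phase plane parameter AP", "dynamic", "AP"),
    row("Mean frequency ML", "dynamic", "ML"),
    row("Mean frequency AP", "dynamic", "AP"),
    row("Mean frequency ML-AP", "dynamic", "ML-AP")
  )
  freq_axis <- function(axis) rbind(
    row(sprintf("Total power (Power Spectrum Density) %s", axis), "frequency", axis),
    row(sprintf("Mean frequency (Power Spectrum Density) %s", axis), "frequency", axis),
    row(sprintf("Centroidal frequency (Power Spectrum Density) %s", axis), "frequency", axis),
    row(sprintf("Mode of Power Spectrum Density %s", axis), "frequency", axis),
    row(sprintf("50%% Power Frequency %s", axis), "frequency", axis),
    row(sprintf("95%% Power Frequency %s", axis), "frequency", axis),
    row(sprintf("Frequency Quotient Power Spectrum Density %s", axis), "frequency", axis),
    row(sprintf("Energy content below 0.5 Hz (Power Spectrum Density) %s", axis), "frequency", axis),
    row(sprintf("Energy content 0.5-2 Hz (Power Spectrum Density) %s", axis), "frequency", axis),
    row(sprintf("Energy content above 2 Hz (Power Spectrum Density) %s", axis), "frequency", axis)
  )
  stoch_axis <- function(axis) rbind(
    row(sprintf("Short-term diffusion coefficient %s", axis), "stochastic", axis),
    row(sprintf("Long-term diffusion coefficient %s", axis), "stochastic", axis),
    row(sprintf("Critical time %s", axis), "stochastic", axis),
    row(sprintf("Critical displacement %s", axis), "stochastic", axis),
    row(sprintf("Short-term scaling exponent %s", axis), "stochastic", axis),
    row(sprintf("Long-term scaling exponent %s", axis), "stochastic", axis),
    row(sprintf("Fractal dimension %s", axis), "stochastic", axis)
  )
  reg <- rbind(
    positional, dynamic,
    freq_axis("ML"), freq_axis("AP"),
    stoch_axis("ML"), stoch_axis("AP"), stoch_axis("ML-AP")
  )
  stopifnot(nrow(reg) == 72L, !anyDuplicated(reg$name))
  reg
}

.tugcop_registry <- make_registry()

#' Look up registry features by name
#'
#' @param names Character vector of feature names.
#' @return The matching registry rows, in the order given; errors on any
#'   name that does not resolve.
#' @export
registry_lookup <- function(names) {
  reg <- feature_registry()
  idx <- match(names, reg$name)
  if (anyNA(idx)) {
    stop(sprintf(
      "unknown feature name(s): %s",
      paste(names[is.na(idx)], collapse = "; ")
    ))
  }
  reg[idx, , drop = FALSE]
}
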