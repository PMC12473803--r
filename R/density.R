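#' Pool CoP samples for one group and foot
#'
#' Concatenates the (ML, AP) samples of every trial in the given
#' group/foot stratum of a cohort.
#'
#' @param cohort A `tug_cohort` (see [simulate_cohort()]), or a plain list
#'   of `tug_trial`s plus a `groups` vector.
#' @param group `"PD"` or `"Control"`.
#' @param foot `"left"` or `"right"`.
#' @return Two-column matrix (`ml`, `ap`) of pooled samples.
#' @export
pool_cop_samples <- function(cohort, group, foot = c("left", "right")) {
  foot <- match.arg(foot)
  stopifnot(inherits(cohort, "tug_cohort"))
  sel <- which(cohort$metadata$group == group)
  if (!length(sel)) stop(sprintf("no trials in stratum (%s, %s)", group, foot))
  pts <- lapply(cohort$trials[sel], function(tr) {
    cbind(ml = tr[[foot]]$ml, ap = tr[[foot]]$ap)
  })
  do.call(rbind, pts)
}

#' Scott's-rule bandwidths for a 2-D point cloud
#'
#' Per-axis Gaussian kernel standard deviations `sigma_j * n^(-1/6)`.
#'
#' @param points Two-column matrix of (ml, ap) samples.
#' @return Length-2 numeric vector of bandwidths (ML, AP).
#' @export
scott_bandwidth <- function(points) {
  n <- nrow(points)
  c(stats::sd(points[, 1]), stats::sd(points[, 2])) * n^(-1 / 6)
}

#' Two-dimensional Gaussian KDE occupancy map
#'
#' Evaluates a Gaussian-kernel density estimate of pooled CoP samples on a
#' fixed lattice over the normalized coordinate ranges (via
#' [MASS::kde2d()]). A comparison set of maps (e.g. the four group-by-foot
#' panels) must share one bandwidth, grid and axis limits; see
#' [cohort_density_maps()] which enforces this by construction.
#'
#' @param points Two-column matrix of (ml, ap) samples (>= 2 distinct
#'   points).
#' @param bandwidth Length-2 Gaussian kernel standard deviations (ML, AP);
#'   default: Scott's rule on `points`.
#' @param gridsize Number of lattice points per axis (default 200).
#' @param lims Axis limits, defaults to the normalized coordinate bounds.
#' @param source Optional `(group, foot)` tag carried in the result.
#' @return An object of class `density_map`: `grid_ml`, `grid_ap`,
#'   `density` (matrix, ml x ap), `bandwidth`, `source`.
#' @export
compute_kde <- function(points, bandwidth = NULL, gridsize = 200L,
                        lims = NULL, source = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("KDE requires at least 2 points")
  if (nrow(unique(points)) < 2L) {
    stop("degenerate point cloud: all points identical")
  }
  if (is.null(bandwidth)) bandwidth <- scott_bandwidth(points)
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0)) {
    stop("bandwidth must be positive and finite")
  }
  b <- cop_bounds()
  if (is.null(lims)) lims <- c(b$ml, b$ap)
  # MASS::kde2d uses h/4 as the Gaussian sd, so pass 4 * sd
  k <- MASS::kde2d(points[, 1], points[, 2], h = 4 * bandwidth,
                   n = gridsize, lims = lims)
  structure(
    list(
      grid_ml = k$x, grid_ap = k$y, density = k$z,
      bandwidth = bandwidth, source = source
    ),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %dx%d grid, bandwidth (%.4g, %.4g)%s\n",
    length(x$grid_ml), length(x$grid_ap), x$bandwidth[1], x$bandwidth[2],
    if (!is.null(x$source)) paste0(", ", paste(x$source, collapse = "/")) else ""
  ))
  invisible(x)
}

#' Numerical integral of a density map
#'
#' Trapezoidal quadrature over the evaluation lattice; approximately 1 for
#' a well-resolved map whose support lies inside the grid.
#'
#' @param map A `density_map`.
#' @return Scalar integral estimate.
#' @export
density_integral <- function(map) {
  trap_w <- function(g) {
    d <- diff(g)
    c(d[1] / 2, (d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  }
  wx <- trap_w(map$grid_ml)
  wy <- trap_w(map$grid_ap)
  as.numeric(wx %*% map$density %*% wy)
}

#' Group-by-foot CoP occupancy maps for a cohort
#'
#' Builds the four comparison panels (Control/PD x left/right) with one
#' shared bandwidth -- Scott's rule computed once on the pooled Control-left
#' stratum and frozen for all panels -- and one shared grid, so the maps are
#' directly comparable.
#'
#' @param cohort A `tug_cohort`.
#' @param gridsize Lattice points per axis.
#' @return Named list of four `density_map`s
#'   (`Control.left`, `Control.right`, `PD.left`, `PD.right`), with the
#'   shared bandwidth as attribute `bandwidth`.
#' @export
cohort_density_maps <- function(cohort, gridsize = 200L) {
  ref <- pool_cop_samples(cohort, "Control", "left")
  bw <- scott_bandwidth(ref)
  out <- list()
  for (g in c("Control", "PD")) {
    for (f in c("left", "right")) {
      out[[paste(g, f, sep = ".")]] <- compute_kde(
        pool_cop_samples(cohort, g, f),
        bandwidth = bw, gridsize = gridsize, source = c(g, f)
      )
    }
  }
  attr(out, "bandwidth") <- bw
  out
}

#' Export a density map as a long-format data frame
#'
#' @param map A `density_map`.
#' @return Data frame with columns `ml`, `ap`, `density`.
#' @export
density_to_df <- function(map) {
  data.frame(
    ml = rep(map$grid_ml, times = length(map$grid_ap)),
    ap = rep(map$grid_ap, each = length(map$grid_ml)),
    density = as.vector(map$density)
  )
}
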