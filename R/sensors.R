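#' Synthetic 16-sensor insole layout
#'
#' Approximate normalized (ML, AP) positions of the 16 capacitive pressure
#' sensors of a pressure-sensing insole: 4 heel, 4 midfoot, 5 metatarsal and
#' 3 toe sensors. The geometry is synthetic -- a plausible anatomical layout
#' inside the normalized coordinate bounds, used for force-to-CoP computation
#' and for distributing CoP-consistent test forces. It is not the vendor's
#' calibrated sensor map.
#'
#' @return Data frame with columns `sensor` (1..16), `dx` (ML position) and
#'   `dy` (AP position), in normalized units.
#' @export
sensor_layout <- function() {
  data.frame(
    sensor = 1:16,
    dx = c(
      -0.15, 0.15, -0.18, 0.18,            # heel
      -0.20, 0.20, -0.16, 0.16,            # midfoot
      -0.28, -0.14, 0.00, 0.14, 0.28,      # metatarsal
      -0.18, 0.00, 0.18                    # toes
    ),
    dy = c(
      -0.52, -0.52, -0.42, -0.42,
      -0.25, -0.25, -0.10, -0.10,
      0.10, 0.13, 0.15, 0.13, 0.10,
      0.32, 0.36, 0.32
    )
  )
}

#' Compute the center of pressure of one sensor frame
#'
#' The CoP is the force-weighted average location of all ground reaction
#' forces acting on the plantar surface:
#' \deqn{CoP_x = \sum_i d_{xi} F_i / \sum_i F_i,\qquad
#'       CoP_y = \sum_i d_{yi} F_i / \sum_i F_i.}
#'
#' An all-zero frame is a swing-phase (no ground contact) sample: it is
#' flagged, not treated as a fatal error, so a full gait sequence can be
#' processed frame by frame.
#'
#' @param forces Numeric vector of non-negative per-sensor forces.
#' @param layout Sensor coordinate table as from [sensor_layout()]; must have
#'   as many rows as `forces` has entries (16 for this device).
#' @return List with `x`, `y` (normalized CoP coordinates, `NA` for a
#'   no-contact frame) and `contact` (logical).
#' @export
compute_cop <- function(forces, layout = sensor_layout()) {
  forces <- as.numeric(forces)
  if (length(forces) != nrow(layout)) {
    stop(sprintf(
      "expected %d per-sensor forces, got %d", nrow(layout), length(forces)
    ))
  }
  if (anyNA(forces) || any(forces < 0)) {
    stop("sensor forces must be non-negative and non-missing")
  }
  s <- sum(forces)
  if (s <= 0) {
    return(list(x = NA_real_, y = NA_real_, contact = FALSE))
  }
  list(
    x = sum(layout$dx * forces) / s,
    y = sum(layout$dy * forces) / s,
    contact = TRUE
  )
}

#' Compute CoP for a matrix of sensor frames
#'
#' @param force_matrix Numeric matrix, one row per time sample, one column
#'   per sensor.
#' @inheritParams compute_cop
#' @return Data frame with columns `x`, `y`, `contact`.
#' @export
compute_cop_series <- function(force_matrix, layout = sensor_layout()) {
  force_matrix <- as.matrix(force_matrix)
  if (ncol(force_matrix) != nrow(layout)) {
    stop("force matrix must have one column per sensor")
  }
  if (anyNA(force_matrix) || any(force_matrix < 0)) {
    stop("sensor forces must be non-negative and non-missing")
  }
  s <- rowSums(force_matrix)
  contact <- s > 0
  x <- ifelse(contact, as.vector(force_matrix %*% layout$dx) / s, NA_real_)
  y <- ifelse(contact, as.vector(force_matrix %*% layout$dy) / s, NA_real_)
  data.frame(x = x, y = y, contact = contact)
}

#' Distribute a total force over sensors consistently with a target CoP
#'
#' Finds three sensors whose triangle contains the target point and assigns
#' barycentric weights, so that [compute_cop()] recovers the target exactly
#' (to floating precision). Intended for generating raw-sensor test frames.
#'
#' @param cop_x,cop_y Target CoP in normalized coordinates; must lie inside
#'   the convex hull of the sensor positions.
#' @param total_force Total force to distribute (> 0).
#' @inheritParams compute_cop
#' @return Numeric vector of per-sensor forces (mostly zeros).
#' @export
distribute_forces <- function(cop_x, cop_y, total_force = 1, layout = sensor_layout()) {
  stopifnot(is.finite(cop_x), is.finite(cop_y), total_force > 0)
  pts <- cbind(layout$dx, layout$dy)
  d2 <- (pts[, 1] - cop_x)^2 + (pts[, 2] - cop_y)^2
  ord <- order(d2)
  combos <- utils::combn(ord, 3L)
  # prefer triangles of nearby sensors: order combinations by summed distance
  csum <- colSums(matrix(d2[combos], nrow = 3L))
  combos <- combos[, order(csum), drop = FALSE]
  for (j in seq_len(ncol(combos))) {
    tri <- combos[, j]
    w <- barycentric(pts[tri, , drop = FALSE], c(cop_x, cop_y))
    if (!is.null(w) && all(w >= -1e-12)) {
      f <- numeric(nrow(layout))
      f[tri] <- pmax(w, 0) * total_force
      return(f)
    }
  }
  stop("target CoP lies outside the convex hull of the sensor layout")
}

barycentric <- function(tri, p) {
  m <- cbind(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
  det_m <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (abs(det_m) < 1e-14) return(NULL)   # degenerate triangle
  rhs <- p - tri[1, ]
  l2 <- (rhs[1] * m[2, 2] - rhs[2] * m[1, 2]) / det_m
  l3 <- (m[1, 1] * rhs[2] - m[2, 1] * rhs[1]) / det_m
  c(1 - l2 - l3, l2, l3)
}
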