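# Axon population grids around the lead, per-axon activation thresholds by
# bisection, current-distance curves, active-axon counts and activation
# volumes.

#' Axon grid specification
#'
#' A planar grid of straight axons perpendicular to the lead, centered on
#' the active contact: radial distances log-spaced between `r_min` and
#' `r_max`, several axial offsets, and copies of the grid rotated around
#' the lead at the given azimuths (relative to the active contact's
#' azimuth). Axons run tangentially (perpendicular to both the lead axis
#' and the radial direction).
#'
#' @param r_min,r_max Radial range from the lead axis (mm); `r_min` must
#'   clear the encapsulation sheath.
#' @param n_radii Number of log-spaced radii.
#' @param offsets Axial offsets from the contact center (mm).
#' @param azimuths Rotation azimuths (degrees) of the rotated subset,
#'   relative to the active contact azimuth.
#' @return An object of class `axon_grid_spec`.
#' @export
axon_grid_spec <- function(r_min = 1.5, r_max = 8, n_radii = 10,
                           offsets = seq(-3, 3, length.out = 5),
                           azimuths = seq(0, 330, by = 30)) {
  stopifnot(r_min > 0, r_max > r_min, n_radii >= 2, length(offsets) >= 1,
            length(azimuths) >= 1)
  structure(list(r_min = r_min, r_max = r_max, n_radii = as.integer(n_radii),
                 offsets = offsets, azimuths = azimuths),
            class = "axon_grid_spec")
}

#' Build the axon population grid
#'
#' @param grid An [axon_grid_spec()].
#' @param lead A [lead_spec()].
#' @param domain A [domain_spec()] (for the encapsulation clearance check).
#' @param active_contact Active contact id or label; the grid is centered
#'   on its axial center and its azimuth defines rotation zero.
#' @return A data.frame of class `axon_grid`: one row per axon with radius,
#'   offset, azimuth, center coordinates, tangential direction and distance
#'   to the contact center. The `facing` column marks the subset at the
#'   contact azimuth.
#' @export
build_grid <- function(grid = axon_grid_spec(), lead = lead_spec(),
                       domain = domain_spec(), active_contact = "d1a") {
  stopifnot(inherits(grid, "axon_grid_spec"))
  k <- contact_id(active_contact)
  rmin_ok <- lead$lead_radius + domain$encapsulation_thickness
  if (grid$r_min <= rmin_ok)
    stop(sprintf("r_min (%g mm) must clear the lead and encapsulation (> %g mm)",
                 grid$r_min, rmin_ok))
  lay <- contact_layout(lead)
  az0 <- if (is.na(lay$azimuth[k])) 0 else lay$azimuth[k]
  zc <- (lay$z0[k] + lay$z1[k]) / 2
  radii <- grid$r_min * (grid$r_max / grid$r_min)^
    (seq(0, 1, length.out = grid$n_radii))
  g <- expand.grid(r = radii, offset = grid$offsets, azimuth = grid$azimuths,
                   KEEP.OUT.ATTRS = FALSE)
  azr <- (az0 + g$azimuth) * pi / 180
  out <- data.frame(axon = seq_len(nrow(g)),
                    r = g$r, offset = g$offset, azimuth = g$azimuth,
                    x = g$r * cos(azr), y = g$r * sin(azr),
                    z = zc + g$offset,
                    ux = -sin(azr), uy = cos(azr), uz = 0,
                    facing = abs(g$azimuth %% 360) < 1e-9)
  ctr <- contact_center(lead, k)
  out$distance <- sqrt((out$x - ctr[1])^2 + (out$y - ctr[2])^2 +
                         (out$z - ctr[3])^2)
  attr(out, "spec") <- grid
  attr(out, "active_contact") <- k
  attr(out, "lead") <- lead
  attr(out, "center_z") <- zc
  class(out) <- c("axon_grid", "data.frame")
  out
}

# axon instances for every grid row; shared fiber
grid_axons <- function(grid, fiber) {
  lapply(seq_len(nrow(grid)), function(i) {
    ctr <- c(grid$x[i], grid$y[i], grid$z[i])
    u <- c(grid$ux[i], grid$uy[i], grid$uz[i])
    span <- ((fiber$n_nodes - 1) * fiber$internode_length +
               fiber$node_length) * 1e-3
    build_axon(fiber, start_point = ctr - u * span / 2, direction = u)
  })
}

#' Activation threshold by bisection
#'
#' Bisects the stimulus amplitude between the search bounds until the
#' bracket's relative width reaches `tol`; the threshold is the bracket
#' midpoint. Reported unconverged (with reason) when the axon already
#' fires at the lower bound or does not fire at the upper bound.
#'
#' @param axon Axon with `Ve_static` attached.
#' @param waveform A [stimulus_waveform()].
#' @param range Search range for the amplitude magnitude (mA).
#' @param tol Relative bracket width at convergence.
#' @param dt Integration step (ms).
#' @return An object of class `threshold_result`: `threshold` (mA),
#'   `converged`, `reason`, `bracket`, `n_evals`.
#' @export
find_threshold <- function(axon, waveform = stimulus_waveform(),
                           range = c(0.05, 10), tol = 0.01, dt = 0.002) {
  act <- function(a) simulate_axon(axon, waveform, amplitude = a,
                                   dt = dt)$activated
  lo <- range[1]; hi <- range[2]
  n <- 2L
  a_lo <- act(lo); a_hi <- act(hi)
  if (a_lo && !a_hi)
    stop("anomalous bracket: activation at the lower but not the upper bound")
  if (a_lo)
    return(structure(list(threshold = lo, converged = FALSE,
                          reason = "lower bound already activating",
                          bracket = c(NA, lo), n_evals = n),
                     class = "threshold_result"))
  if (!a_hi)
    return(structure(list(threshold = NA_real_, converged = FALSE,
                          reason = "upper bound not activating",
                          bracket = c(hi, NA), n_evals = n),
                     class = "threshold_result"))
  while ((hi - lo) / ((hi + lo) / 2) > tol) {
    mid <- (hi + lo) / 2
    n <- n + 1L
    a_mid <- act(mid)
    if (a_mid) hi <- mid else lo <- mid
    if (n > 60L) break
  }
  structure(list(threshold = (hi + lo) / 2, converged = TRUE,
                 reason = "converged", bracket = c(lo, hi),
                 n_evals = n),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$converged)
    cat(sprintf("threshold %.4g mA (bracket [%.4g, %.4g], %d evaluations)\n",
                x$threshold, x$bracket[1], x$bracket[2], x$n_evals))
  else cat(sprintf("unconverged: %s\n", x$reason))
  invisible(x)
}

#' Brute-force amplitude sweep
#'
#' Evaluates activation on a fixed amplitude ladder; the sweep threshold is
#' the lowest activating amplitude. Used as the oracle against bisection.
#'
#' @param axon Axon with `Ve_static` attached.
#' @param waveform A [stimulus_waveform()].
#' @param amplitudes Ascending amplitude ladder (mA).
#' @param dt Integration step (ms).
#' @return List with `threshold` (NA if none activate) and the logical
#'   `activated` vector.
#' @export
amplitude_sweep <- function(axon, waveform = stimulus_waveform(),
                            amplitudes, dt = 0.002) {
  act <- vapply(amplitudes, function(a)
    simulate_axon(axon, waveform, amplitude = a, dt = dt)$activated,
    logical(1))
  thr <- if (any(act)) amplitudes[which(act)[1]] else NA_real_
  list(threshold = thr, activated = act)
}

#' Thresholds for a whole axon grid
#'
#' Attaches the solved field to every axon of the grid (one shared
#' interpolation pass) and bisects each activation threshold.
#'
#' @param sol A `field_solution` (or analytic field function).
#' @param grid An [build_grid()] result.
#' @param fiber A [fiber_spec()].
#' @param waveform A [stimulus_waveform()].
#' @param range,tol,dt See [find_threshold()].
#' @param axons,W Optional precomputed axon instances and interpolation
#'   operator (reused across variants by [run_matrix()]).
#' @return Data.frame of class `population_thresholds`: grid columns plus
#'   `threshold`, `converged`, `reason`.
#' @export
population_thresholds <- function(sol, grid, fiber = fiber_spec(),
                                  waveform = stimulus_waveform(),
                                  range = c(0.05, 10), tol = 0.01,
                                  dt = 0.002, axons = NULL, W = NULL) {
  stopifnot(inherits(grid, "axon_grid"))
  if (is.null(axons)) axons <- grid_axons(grid, fiber)
  ve <- grid_potentials(sol, axons, W)
  I_ref <- if (inherits(sol, c("field_solution", "sphere_solution")))
    sol$current else if (!is.null(attr(sol, "I"))) attr(sol, "I") else -1
  out <- grid
  out$threshold <- NA_real_
  out$converged <- FALSE
  out$reason <- NA_character_
  for (i in seq_along(axons)) {
    ax <- axons[[i]]
    ax$Ve_static <- ve[, i]
    ax$I_ref <- I_ref
    tr <- find_threshold(ax, waveform, range = range, tol = tol, dt = dt)
    out$threshold[i] <- tr$threshold
    out$converged[i] <- tr$converged
    out$reason[i] <- tr$reason
  }
  class(out) <- c("population_thresholds", class(grid))
  out
}

# matrix of Ve (V) per compartment (rows) x axon (cols)
grid_potentials <- function(sol, axons, W = NULL) {
  if (!is.null(W) && inherits(sol, c("field_solution", "sphere_solution")))
    return(matrix(as.vector(W %*% sol$V), ncol = length(axons)))
  pts <- do.call(rbind, lapply(axons, function(a) a$coords))
  if (inherits(sol, c("field_solution", "sphere_solution"))) {
    v <- field_at(sol, pts)
  } else if (is.function(sol)) {
    v <- sol(pts)
  } else stop("sol must be a field solution or a field function")
  matrix(v, ncol = length(axons))
}

#' Current-distance relationship
#'
#' Threshold versus distance to the active contact center, with the
#' Spearman rank correlation of the facing-azimuth subset (thresholds are
#' expected to increase with distance).
#'
#' @param thresholds A [population_thresholds()] result.
#' @return Data.frame of class `current_distance` sorted by distance
#'   (converged axons only), with attributes `spearman_facing` and
#'   `spearman_all`.
#' @export
current_distance_curve <- function(thresholds) {
  stopifnot(inherits(thresholds, "population_thresholds"))
  ok <- thresholds$converged
  if (sum(ok) < 2) stop("need at least 2 converged thresholds")
  d <- thresholds[ok, c("axon", "r", "offset", "azimuth", "facing",
                        "distance", "threshold")]
  d <- d[order(d$distance), ]
  fac <- d$facing & d$offset == 0
  if (sum(fac) < 3) fac <- d$facing
  attr(d, "spearman_facing") <- if (sum(fac) >= 3)
    stats::cor(d$distance[fac], d$threshold[fac], method = "spearman")
  else NA_real_
  attr(d, "spearman_all") <- stats::cor(d$distance, d$threshold,
                                        method = "spearman")
  class(d) <- c("current_distance", "data.frame")
  d
}

#' @export
plot.current_distance <- function(x, ...) {
  plot(x$distance, x$threshold, log = "xy",
       xlab = "distance to contact center (mm)",
       ylab = "activation threshold (mA)",
       pch = ifelse(x$facing, 19, 1), ...)
  graphics::legend("topleft", pch = c(19, 1),
                   legend = c("facing azimuth", "other azimuths"), bty = "n")
  invisible(x)
}

#' Active-axon count and activation volume at a stimulus amplitude
#'
#' Counts axons with threshold at or below the amplitude and estimates the
#' activation volume by revolving the per-azimuth, per-offset maximal
#' activated radius: each (azimuth, offset) sector contributes
#' `0.5 * dtheta * r_max^2 * dz`. Axons whose threshold search stopped at
#' the lower bound ("already activating") count as active.
#'
#' @param thresholds A [population_thresholds()] result over the rotated
#'   grid.
#' @param amplitude Stimulus amplitude magnitude (mA).
#' @return An object of class `activation_summary`: `amplitude`,
#'   `n_active`, `volume_mm3`.
#' @export
activation_summary <- function(thresholds, amplitude = 1) {
  stopifnot(inherits(thresholds, "population_thresholds"))
  active <- (thresholds$converged & thresholds$threshold <= amplitude) |
    (!thresholds$converged &
       thresholds$reason == "lower bound already activating" &
       thresholds$threshold <= amplitude)
  az <- sort(unique(thresholds$azimuth))
  off <- sort(unique(thresholds$offset))
  dtheta <- if (length(az) > 1) diff(az)[1] * pi / 180 else 2 * pi
  dz <- if (length(off) > 1) diff(off)[1] else NA_real_
  vol <- NA_real_
  if (!is.na(dz)) {
    vol <- 0
    for (a in az) for (o in off) {
      sel <- thresholds$azimuth == a & thresholds$offset == o & active
      rmax <- if (any(sel)) max(thresholds$r[sel]) else 0
      vol <- vol + 0.5 * dtheta * rmax^2 * dz
    }
  }
  structure(list(amplitude = amplitude, n_active = sum(active),
                 n_axons = nrow(thresholds), volume_mm3 = vol),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf("activation at %.3g mA: %d / %d axons, volume %.3g mm^3\n",
              x$amplitude, x$n_active, x$n_axons, x$volume_mm3))
  invisible(x)
}
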