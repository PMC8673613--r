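# Full 15-variant comparison matrix: voltage-difference maps, per-axon
# threshold errors and population activation errors relative to the
# reference variant (model #1), plus per-stage timing logs.

#' Voltage-difference map between two field solutions
#'
#' Signed per-probe difference (other minus reference) and the percentage
#' relative to the reference, on a shared probe grid. Probes within two
#' local element diameters of a point-source vertex are excluded (FEM
#' point loads are not pointwise convergent at the source).
#'
#' @param ref,other `field_solution` objects from the same lead geometry.
#' @param pts n x 3 probe points in tissue (mm).
#' @param normalize If `TRUE`, `other` is rescaled to the reference
#'   commanded current; if `FALSE` a current mismatch is an error.
#' @param W Optional precomputed interpolation operator for `pts`.
#' @return Data.frame of class `voltage_diff`: probe coordinates, `v_ref`,
#'   `v_other` (volts), `dv`, `rel_pct`, `excluded`; summary statistics in
#'   attributes.
#' @export
voltage_difference_map <- function(ref, other, pts, normalize = FALSE,
                                   W = NULL) {
  stopifnot(inherits(ref, "field_solution"), inherits(other, "field_solution"))
  if (!isTRUE(all.equal(unclass(ref$model$mesh$lead),
                        unclass(other$model$mesh$lead))))
    stop("solutions come from different lead geometries")
  scale <- 1
  if (abs(ref$current - other$current) > 1e-12) {
    if (!normalize)
      stop("commanded currents differ (", other$current, " vs ",
           ref$current, " mA); set normalize = TRUE to rescale")
    scale <- ref$current / other$current
  }
  pts <- as_points(pts)
  if (is.null(W)) W <- interpolation_matrix(ref$model$mesh, pts)
  v_ref <- as.vector(W %*% ref$V)
  v_other <- as.vector(W %*% other$V) * scale
  excl <- rep(FALSE, nrow(pts))
  for (sol in list(ref, other)) {
    if (!is.null(sol$source$vertex)) {
      vx <- sol$model$mesh$vertices[sol$source$vertex, ]
      h <- point_source_exclusion_radius(sol$model$mesh, sol$source$vertex)
      d <- sqrt(rowSums(sweep(pts, 2L, vx)^2))
      excl <- excl | d < h
    }
  }
  dv <- v_other - v_ref
  rel <- 100 * dv / abs(v_ref)
  dv[excl] <- NA; rel[excl] <- NA
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    v_ref = v_ref, v_other = v_other,
                    dv = dv, rel_pct = rel, excluded = excl)
  ok <- !excl
  attr(out, "summary") <- c(min_pct = min(rel[ok]), mean_pct = mean(rel[ok]),
                            max_pct = max(rel[ok]),
                            rms_v = sqrt(mean(dv[ok]^2)))
  attr(out, "n_excluded") <- sum(excl)
  class(out) <- c("voltage_diff", "data.frame")
  out
}

# two local element diameters around a vertex
point_source_exclusion_radius <- function(mesh, vertex) {
  touch <- which(rowSums(mesh$tets == vertex) > 0)
  vids <- unique(as.vector(mesh$tets[touch, ]))
  d <- sqrt(rowSums(sweep(mesh$vertices[vids, , drop = FALSE], 2L,
                          mesh$vertices[vertex, ])^2))
  2 * max(d)
}

#' Per-axon threshold error against the reference variant
#'
#' `100 * (T_variant - T_ref) / T_ref` for every axon converged in both
#' sets.
#'
#' @param ref,variant `population_thresholds` for the same grid.
#' @return Data.frame with `axon`, `distance`, `error_pct`; attribute
#'   `range` holds the min/max error.
#' @export
threshold_error <- function(ref, variant) {
  stopifnot(inherits(ref, "population_thresholds"),
            inherits(variant, "population_thresholds"))
  if (!identical(ref$axon, variant$axon))
    stop("threshold sets are for different axon grids")
  ok <- ref$converged & variant$converged
  err <- 100 * (variant$threshold[ok] - ref$threshold[ok]) / ref$threshold[ok]
  out <- data.frame(axon = ref$axon[ok], distance = ref$distance[ok],
                    error_pct = err)
  attr(out, "range") <- range(err)
  out
}

#' Run the variant comparison matrix
#'
#' Builds the shared parent mesh and axon grid once, then for each variant
#' assembles, solves, interpolates the field onto the axons, bisects all
#' activation thresholds, and accumulates the comparison metrics relative
#' to the reference variant: voltage differences on the axon compartments,
#' per-axon threshold errors, active-axon count and activation volume
#' errors, and per-stage timing (informational only). A failing variant is
#' recorded and the matrix continues.
#'
#' @param lead,domain,sigma,settings Geometry, conductivities and mesh
#'   sizing shared by all variants.
#' @param variants Integer model ids to run (subset of 1:15).
#' @param reference Reference model id (must be in `variants`).
#' @param active_contact Contact id or label, active in every variant.
#' @param current Commanded current (mA, cathodic negative).
#' @param grid,fiber,waveform Axon population definition.
#' @param amplitude Amplitude (mA) at which counts/volumes are evaluated.
#' @param range,tol,dt Threshold search controls.
#' @param mesh Optionally a prebuilt parent mesh (skips meshing).
#' @param verbose Print progress.
#' @return An object of class `vc_comparison`.
#' @export
run_matrix <- function(lead = lead_spec(), domain = domain_spec(),
                       sigma = conductivity_map(),
                       settings = mesh_settings(),
                       variants = 1:15, reference = 1,
                       active_contact = "d1a", current = -1,
                       grid = axon_grid_spec(), fiber = fiber_spec(),
                       waveform = stimulus_waveform(), amplitude = 1,
                       range = c(0.05, 10), tol = 0.01, dt = 0.002,
                       mesh = NULL, verbose = interactive()) {
  if (!reference %in% variants)
    stop("the reference variant must be part of the matrix")
  t_mesh <- system.time(
    if (is.null(mesh)) mesh <- build_lead_mesh(lead, domain, settings)
  )[["elapsed"]]
  gr <- build_grid(grid, mesh$lead, mesh$domain, active_contact)
  axons_all <- grid_axons(gr, fiber)
  W_all <- interpolation_matrix(
    mesh, do.call(rbind, lapply(axons_all, function(a) a$coords)))
  ids <- unique(as.integer(variants))
  ids <- c(reference, setdiff(ids, reference))   # reference first
  runs <- list()
  timing <- data.frame(model_id = integer(), build = numeric(),
                       solve = numeric(), thresholds = numeric(),
                       failed = logical())
  for (mid in ids) {
    if (verbose) message("variant #", mid)
    rec <- tryCatch({
      tb <- system.time(model <- vc_model(
        mesh, variant_spec(mid, active_contact = active_contact),
        sigma))[["elapsed"]]
      ts <- system.time(sol <- solve_vc(model, current = current))[["elapsed"]]
      tt <- system.time(thr <- population_thresholds(
        sol, gr, fiber, waveform, range = range, tol = tol,
        dt = dt, axons = axons_all, W = W_all))[["elapsed"]]
      list(model_id = mid, sol = sol, thresholds = thr,
           times = c(build = tb, solve = ts, thresholds = tt),
           failed = FALSE, error = NULL)
    }, error = function(e)
      list(model_id = mid, sol = NULL, thresholds = NULL,
           times = c(build = NA, solve = NA, thresholds = NA),
           failed = TRUE, error = conditionMessage(e)))
    runs[[as.character(mid)]] <- rec
    timing <- rbind(timing,
                    data.frame(model_id = mid, build = rec$times[["build"]],
                               solve = rec$times[["solve"]],
                               thresholds = rec$times[["thresholds"]],
                               failed = rec$failed))
  }
  refrun <- runs[[as.character(reference)]]
  if (refrun$failed)
    stop("reference variant failed: ", refrun$error)
  # probe points: compartments of the facing-plane axons
  face_sel <- which(gr$facing)
  ncomp <- nrow(axons_all[[1]]$coords)
  probe_rows <- as.vector(outer(seq_len(ncomp), (face_sel - 1L) * ncomp, `+`))
  probe <- do.call(rbind,
                   lapply(axons_all[face_sel], function(a) a$coords))
  W_probe <- W_all[probe_rows, , drop = FALSE]
  ref_sum <- activation_summary(refrun$thresholds, amplitude)
  rows <- list()
  for (mid in ids) {
    rec <- runs[[as.character(mid)]]
    if (rec$failed) {
      rows[[as.character(mid)]] <- data.frame(
        model_id = mid, failed = TRUE, thr_err_min = NA, thr_err_max = NA,
        n_active = NA, volume_mm3 = NA, n_active_err_pct = NA,
        volume_err_pct = NA, dv_rms_V = NA, dv_max_pct = NA,
        dv_min_pct = NA)
      next
    }
    te <- threshold_error(refrun$thresholds, rec$thresholds)
    su <- activation_summary(rec$thresholds, amplitude)
    vd <- voltage_difference_map(refrun$sol, rec$sol, probe, W = W_probe)
    vs <- attr(vd, "summary")
    rows[[as.character(mid)]] <- data.frame(
      model_id = mid, failed = FALSE,
      thr_err_min = attr(te, "range")[1], thr_err_max = attr(te, "range")[2],
      n_active = su$n_active, volume_mm3 = su$volume_mm3,
      n_active_err_pct = 100 * (su$n_active - ref_sum$n_active) /
        ref_sum$n_active,
      volume_err_pct = 100 * (su$volume_mm3 - ref_sum$volume_mm3) /
        ref_sum$volume_mm3,
      dv_rms_V = vs[["rms_v"]], dv_max_pct = vs[["max_pct"]],
      dv_min_pct = vs[["min_pct"]])
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  out <- list(summary = summary_df, runs = runs, timing = timing,
              grid = gr, reference = reference, amplitude = amplitude,
              active_contact = contact_id(active_contact),
              contact_type = contact_layout(lead)$type[
                contact_id(active_contact)],
              mesh_seconds = t_mesh, mesh = mesh)
  class(out) <- "vc_comparison"
  out
}

#' @export
print.vc_comparison <- function(x, ...) {
  cat(sprintf("vc_comparison: %d variants vs model #%d (%s contact, %.3g mA eval)\n",
              nrow(x$summary), x$reference, x$contact_type, x$amplitude))
  print(x$summary[, c("model_id", "thr_err_min", "thr_err_max",
                      "n_active", "volume_mm3", "n_active_err_pct",
                      "volume_err_pct")], digits = 3)
  invisible(x)
}

#' @export
summary.vc_comparison <- function(object, ...) {
  s <- object$summary[!object$summary$failed &
                        object$summary$model_id != object$reference, ]
  list(
    max_abs_individual_error = max(abs(c(s$thr_err_min, s$thr_err_max))),
    max_abs_population_error = max(abs(c(s$n_active_err_pct,
                                         s$volume_err_pct))),
    individual_error_range = range(c(s$thr_err_min, s$thr_err_max)),
    n_failed = sum(object$summary$failed),
    timing = object$timing)
}
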