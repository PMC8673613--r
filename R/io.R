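# Configuration (YAML), standard-format export (Gmsh MSH 4.1, VTU, CSV)
# and programmatic fixture generation.

default_config <- function() {
  list(
    lead = list(lead_radius = 0.65, tip_contact_length = 1.5,
                ring_contact_length = 1.5, inter_contact_gap = 0.5,
                segment_arc = 90, segments_per_row = 3L, n_rows = 2L,
                contact_thickness = 0.1, shaft_length = 40),
    domain = list(encapsulation_thickness = 0.5, brain_radius = 50,
                  ground_radius = 10),
    conductivity = list(brain = 0.2, encapsulation = 0.13,
                        contact = 5.3e6, shaft = 1e-16),
    variant = list(model_id = 1L, active_contact = "d1a"),
    source = list(current = -1, seed_voltage = 1),
    mesh = list(z_fine = 0.5, theta_step = 15, radial_growth = 1.35,
                z_growth = 1.45, core_rings = 2L, encap_rings = 2L,
                refine = 1L),
    fiber = list(fiber_diameter = 5.7, n_nodes = 21L,
                 internode_segments = 3L, temperature = 37),
    waveform = list(pulse_width = 60, amplitude = 1, onset_delay = 100,
                    t_total = 3),
    grid = list(r_min = 1.5, r_max = 8, n_radii = 10L,
                offsets = c(-3, -1.5, 0, 1.5, 3),
                azimuths = seq(0, 330, by = 30)),
    threshold = list(range = c(0.05, 10), tol = 0.01, dt = 0.002),
    comparison = list(variants = 1:15, reference = 1L, amplitude = 1),
    seed = 1L,
    output_dir = "output")
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("config section '", path, "' must be a mapping")
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown config key", if (length(extra) > 1) "s" else "", ": ",
         paste0(if (nzchar(path)) paste0(path, ".") else "", extra,
                collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(if (nzchar(path))
                                       paste0(path, ".") else "", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML configuration, fills defaults for every omitted key,
#' rejects unknown keys, and constructs the validated specification
#' objects. An empty file yields the full default configuration
#' (model #1, -1 mA, 60 us pulse).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return An object of class `run_config`: validated spec objects plus
#'   scalar settings, and `$raw` with the merged raw values.
#' @export
load_config <- function(path = NULL) {
  user <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
  }
  raw <- merge_config(default_config(), user)
  overrides <- character()
  if (!is.null(user))
    overrides <- unlist(lapply(names(user), function(s)
      paste0(s, ".", names(user[[s]]))))
  cfg <- list(
    lead = do.call(lead_spec, raw$lead),
    domain = do.call(domain_spec, raw$domain),
    sigma = do.call(conductivity_map, raw$conductivity),
    variant = variant_spec(raw$variant$model_id,
                           active_contact = raw$variant$active_contact),
    settings = do.call(mesh_settings, raw$mesh),
    fiber = do.call(fiber_spec, raw$fiber),
    waveform = do.call(stimulus_waveform, raw$waveform),
    grid = do.call(axon_grid_spec, raw$grid),
    source = raw$source,
    threshold = raw$threshold,
    comparison = raw$comparison,
    seed = as.integer(raw$seed),
    output_dir = raw$output_dir,
    overrides = overrides,
    raw = raw)
  class(cfg) <- "run_config"
  cfg
}

#' Save a run configuration
#'
#' Writes the raw (merged) configuration back to YAML;
#' `load_config(save_config(cfg, f))` reproduces `cfg`.
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(cfg$raw, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: variant #", x$variant$model_id, ", contact ",
      x$variant$active_contact, ", ", x$source$current, " mA, ",
      x$waveform$pulse_width, " us\n", sep = "")
  if (length(x$overrides))
    cat("  overridden keys:", paste(x$overrides, collapse = ", "), "\n")
  invisible(x)
}

#' Export a mesh in Gmsh MSH 4.1 format
#'
#' ASCII MSH v4.1 with one volume entity per labeled region (entity tag =
#' region code) and tetrahedral elements.
#'
#' @param mesh A `vc_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  stopifnot(inherits(mesh, "vc_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat"), con)
  regions <- sort(unique(mesh$region))
  writeLines("$Entities", con)
  writeLines(sprintf("0 0 0 %d", length(regions)), con)
  for (r in regions)
    writeLines(sprintf("%d 0 0 0 0 0 0 1 %d 0", r, r), con)
  writeLines("$EndEntities", con)
  writeLines("$Nodes", con)
  writeLines(sprintf("1 %d 1 %d", nv, nv), con)
  writeLines(sprintf("3 %d 0 %d", regions[1], nv), con)
  writeLines(format(seq_len(nv)), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines("$EndNodes", con)
  writeLines("$Elements", con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("%d %d 1 %d", length(regions), m, m), con)
  eid <- 0L
  for (r in regions) {
    sel <- which(mesh$region == r)
    writeLines(sprintf("3 %d 4 %d", r, length(sel)), con)
    writeLines(sprintf("%d %d %d %d %d", eid + seq_along(sel),
                       mesh$tets[sel, 1], mesh$tets[sel, 2],
                       mesh$tets[sel, 3], mesh$tets[sel, 4]), con)
    eid <- eid + length(sel)
  }
  writeLines("$EndElements", con)
  invisible(path)
}

#' Export a mesh (with optional fields) as ASCII VTU
#'
#' XML VTK unstructured grid with integer region labels as cell data and
#' any point/cell data supplied (e.g. the solved potential).
#'
#' @param mesh A `vc_mesh`.
#' @param path Output file.
#' @param point_data Named list of per-vertex numeric vectors.
#' @param cell_data Named list of per-tet numeric vectors; the region
#'   label is always included.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "vc_mesh"))
  nv <- nrow(mesh$vertices); m <- nrow(mesh$tets)
  cell_data <- c(list(region = mesh$region), cell_data)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nv, m))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(sprintf("%d %d %d %d", mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                     mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(format(seq_len(m) * 4L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('</DataArray></Cells>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(sprintf("%.10g", point_data[[nm]]), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('<CellData>')
  for (nm in names(cell_data)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    w('</DataArray>')
  }
  w('</CellData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Export a field solution as VTU
#'
#' @param sol A `field_solution`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_solution_vtu <- function(sol, path) {
  stopifnot(inherits(sol, "field_solution"))
  mesh <- sol$model$mesh
  gr <- per_tet_gradient(mesh, sol$V, seq_len(nrow(mesh$tets)))
  jmag <- sol$model$sigma_tet * sqrt(rowSums(gr^2)) * 1e3 * 1e-3  # mA/mm^2
  jmag[!sol$model$active_tet] <- 0
  write_vtu(mesh, path, point_data = list(V_e = sol$V),
            cell_data = list(j_mag = jmag,
                             active = as.numeric(sol$model$active_tet)))
}

#' Export contact-current diagnostics as CSV
#'
#' @param sol A `field_solution`.
#' @param path Output file.
#' @return The data.frame written, invisibly.
#' @export
write_contact_currents_csv <- function(sol, path) {
  stopifnot(inherits(sol, "field_solution"))
  lay <- contact_layout(sol$model$mesh$lead)
  df <- data.frame(contact = lay$contact, label = lay$label,
                   type = lay$type,
                   current_mA = as.numeric(sol$contact_currents),
                   active = lay$contact == sol$model$variant$active_contact)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export an axon with attached potentials as CSV
#'
#' Columns: compartment index, x, y, z (mm), type, Ve (V).
#' @param axon An axon with `Ve_static`.
#' @param path Output file.
#' @return The data.frame written, invisibly.
#' @export
write_axon_csv <- function(axon, path) {
  stopifnot(inherits(axon, "axon_instance"))
  df <- data.frame(compartment = seq_len(nrow(axon$coords)),
                   x = axon$coords[, 1], y = axon$coords[, 2],
                   z = axon$coords[, 3], type = axon$type,
                   Ve = if (is.null(axon$Ve_static)) NA else axon$Ve_static)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Generate small test fixtures
#'
#' Programmatic fixtures used by the test-suite and examples:
#' `"sphere"` -- a small lead-free grounded sphere for the analytic
#' point-source oracle; `"variant_pair"` -- a coarse parent mesh with
#' models #1 and #15 assembled on it (equal active-contact surface
#' signatures by construction); `"axon_bundle"` -- three axons at
#' increasing radii with an analytic point-source field attached, written
#' as CSV when `dir` is given.
#'
#' @param kind `"sphere"`, `"variant_pair"` or `"axon_bundle"`.
#' @param seed RNG seed (the generators are deterministic; the seed is set
#'   for reproducibility of any downstream sampling).
#' @param dir Optional output directory for the file forms.
#' @return The fixture object(s).
#' @export
generate_fixtures <- function(kind = c("sphere", "variant_pair",
                                       "axon_bundle"),
                              seed = 1, dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (kind == "sphere") {
    mesh <- sphere_mesh(radius = 200, n_sub = 2, r_inner = 1,
                        growth = 1.3, r_switch = 30, growth_far = 1.5)
    if (!is.null(dir)) write_msh(mesh, file.path(dir, "sphere.msh"))
    return(mesh)
  }
  if (kind == "variant_pair") {
    mesh <- build_lead_mesh(lead_spec(), domain_spec(brain_radius = 30),
                            mesh_settings(z_fine = 0.75, radial_growth = 1.7,
                                          z_growth = 1.8))
    m1 <- vc_model(mesh, variant_spec(1))
    m15 <- vc_model(mesh, variant_spec(15))
    if (!is.null(dir)) write_msh(mesh, file.path(dir, "variant_pair.msh"))
    return(list(mesh = mesh, model_1 = m1, model_15 = m15))
  }
  # axon_bundle
  fib <- fiber_spec()
  fld <- point_source_field(I = -1, sigma = 0.2)
  axons <- lapply(c(2, 3, 4), function(r) {
    ax <- build_axon(fib, start_point = c(-5, r, 0), direction = c(1, 0, 0))
    attach_field(ax, fld)
  })
  if (!is.null(dir))
    for (i in seq_along(axons))
      write_axon_csv(axons[[i]], file.path(dir,
                                           sprintf("axon_%d.csv", i)))
  axons
}
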