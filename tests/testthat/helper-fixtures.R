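# Shared, lazily built fixtures. Heavy objects (meshes, solves) are built
# once per test run and cached; coarse settings keep the unit tests fast,
# the acceptance tests use the default study-scale mesh.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

coarse_settings <- function()
  mesh_settings(z_fine = 0.75, radial_growth = 1.6, z_growth = 1.7)

coarse_mesh <- function()
  memo("coarse_mesh", build_lead_mesh(lead_spec(), domain_spec(),
                                      coarse_settings()))

default_mesh <- function()
  memo("default_mesh", build_lead_mesh())

coarse_solution <- function(model_id) {
  memo(paste0("coarse_sol_", model_id), {
    solve_vc(vc_model(coarse_mesh(), variant_spec(model_id)))
  })
}

default_solution <- function(model_id) {
  memo(paste0("default_sol_", model_id), {
    solve_vc(vc_model(default_mesh(), variant_spec(model_id)))
  })
}

oracle_sphere_solution <- function() {
  memo("oracle_sphere", {
    mesh <- sphere_mesh()
    solve_sphere_point_source(mesh, current = -1, sigma = 0.2)
  })
}

# axon at 2 mm from an analytic cathodic point source, field attached
analytic_axon <- function(r = 2) {
  memo(paste0("axon_r", r), {
    ax <- build_axon(fiber_spec(), start_point = c(-5, r, 0),
                     direction = c(1, 0, 0))
    attach_field(ax, point_source_field(I = -1, sigma = 0.2))
  })
}

# reduced-scale 15-variant comparison on the default mesh, shared by the
# acceptance checks
acceptance_matrix <- function() {
  memo("acceptance_matrix", {
    run_matrix(mesh = default_mesh(),
               grid = axon_grid_spec(n_radii = 8,
                                     offsets = c(-1.5, 0, 1.5),
                                     azimuths = seq(0, 300, by = 60)),
               verbose = FALSE)
  })
}
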