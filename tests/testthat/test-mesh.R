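test_that("every tetrahedron carries exactly one region label and positive volume", {
  mesh <- coarse_mesh()
  expect_equal(length(mesh$region), nrow(mesh$tets))
  expect_true(all(mesh$region %in% c(1:4, 11:18)))
  expect_true(all(mesh$geom$vol > 0))
  # total volume matches the polygonal (24-gon) cylinder domain exactly
  R <- mesh$domain$brain_radius
  h <- diff(range(mesh$z_levels))
  th <- 2 * pi / mesh$n_th
  poly <- 0.5 * mesh$n_th * R^2 * sin(th)      # inscribed polygon area
  expect_equal(sum(mesh$geom$vol) / (poly * h), 1, tolerance = 1e-6)
})

test_that("mesh construction is deterministic", {
  m1 <- build_lead_mesh(lead_spec(), domain_spec(), coarse_settings())
  m2 <- build_lead_mesh(lead_spec(), domain_spec(), coarse_settings())
  expect_identical(m1$tets, m2$tets)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$region, m2$region)
  expect_identical(contact_surface_signature(m1, 2),
                   contact_surface_signature(m2, 2))
})

test_that("directional contact surface area matches the analytic band area within 1%", {
  mesh <- default_mesh()
  lead <- mesh$lead
  analytic <- lead$lead_radius * (lead$segment_arc * pi / 180) *
    lead$ring_contact_length
  for (k in 2:7)
    expect_equal(sum(mesh$surfaces[[k]]$area), analytic, tolerance = 0.01)
  # ring contact: full-circumference band
  ring <- 2 * pi * lead$lead_radius * lead$ring_contact_length
  expect_equal(sum(mesh$surfaces[[8]]$area), ring, tolerance = 0.01)
})

test_that("contact surfaces are watertight facet sets adjacent to tissue", {
  mesh <- coarse_mesh()
  for (k in 1:8) {
    s <- mesh$surfaces[[k]]
    expect_gt(nrow(s$facets), 0)
    # each facet pairs one contact-shell tet with one encapsulation tet
    expect_true(all(mesh$region[s$tet_a] == 10 + k))
    expect_true(all(mesh$region[s$tet_b] == 2))
    # normals are unit and point into tissue (outward radially for bands)
    expect_equal(rowSums(s$normal^2), rep(1, nrow(s$normal)))
  }
  # directional band: outward normal has positive radial component
  s <- mesh$surfaces[[3]]
  rad <- s$centroid[, 1:2] / sqrt(rowSums(s$centroid[, 1:2]^2))
  expect_true(all(rowSums(s$normal[, 1:2] * rad) > 0.9))
})

test_that("contact surface signature is identical across all 15 variants and stable under volume-only coarsening", {
  mesh <- coarse_mesh()
  # the parent mesh is shared: the signature is a property of the mesh,
  # equal for any variant assembled on it
  sig <- contact_surface_signature(mesh, 2)
  for (mid in c(1, 7, 15)) {
    model <- vc_model(mesh, variant_spec(mid))
    expect_identical(contact_surface_signature(model$mesh, 2), sig)
  }
  # brain-region growth does not touch the contact-surface discretization
  m2 <- build_lead_mesh(lead_spec(), domain_spec(),
                        mesh_settings(z_fine = 0.75, radial_growth = 1.9,
                                      z_growth = 1.7))
  expect_identical(contact_surface_signature(m2, 2), sig)
  # refining the azimuthal/axial seeding does change it
  m3 <- build_lead_mesh(lead_spec(), domain_spec(),
                        mesh_settings(z_fine = 0.5, radial_growth = 1.6,
                                      z_growth = 1.7))
  expect_false(identical(contact_surface_signature(m3, 2), sig))
})

test_that("point location and interpolation reproduce a linear field exactly", {
  mesh <- coarse_mesh()
  set.seed(42)
  # random tissue points: radius outside the lead, inside the domain
  n <- 200
  r <- runif(n, 1.3, 20); th <- runif(n, 0, 2 * pi)
  pts <- cbind(r * cos(th), r * sin(th), runif(n, -15, 20))
  W <- interpolation_matrix(mesh, pts)
  vlin <- 0.3 * mesh$vertices[, 1] - 0.2 * mesh$vertices[, 2] +
    0.05 * mesh$vertices[, 3] + 1
  expect_equal(as.vector(W %*% vlin),
               0.3 * pts[, 1] - 0.2 * pts[, 2] + 0.05 * pts[, 3] + 1,
               tolerance = 1e-10)
  # points inside the lead are rejected as non-tissue
  expect_error(interpolation_matrix(mesh, rbind(c(0, 0, 5))),
               "inside the lead")
  expect_error(interpolation_matrix(mesh, rbind(c(500, 0, 0))),
               "outside the mesh")
})

test_that("mesh refinement changes the solution by a bounded relative amount and huge elements are flagged", {
  sol1 <- coarse_solution(15)
  sol2 <- default_solution(15)
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  probe <- rbind(cbind(3 * cos(th), 3 * sin(th), 2.75),
                 cbind(6 * cos(th), 6 * sin(th), 2.75))
  cc <- convergence_check(sol1, sol2, probe)
  expect_lt(cc$max_rel, 0.10)      # coarse vs default: bounded change
  expect_gt(cc$max_rel, 0)
  # identical solutions: zero change
  cc0 <- convergence_check(sol2, sol2, probe)
  expect_equal(cc0$max_rel, 0)
  expect_equal(cc0$rms_rel, 0)
  # a deliberately crude mesh fails a 2% acceptance threshold
  crude <- solve_vc(vc_model(
    build_lead_mesh(lead_spec(), domain_spec(),
                    mesh_settings(z_fine = 1.5, radial_growth = 2.2,
                                  z_growth = 2.2, core_rings = 1,
                                  encap_rings = 1)),
    variant_spec(15)))
  ccc <- convergence_check(crude, sol2, probe)
  expect_gt(ccc$max_rel, 0.02)
})
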