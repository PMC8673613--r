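# Solver-level properties on the coarse shared mesh: conservation,
# linearity, equipotentiality, analytic and equivalence oracles.

test_that("every source implementation delivers the commanded current within 1% (consistent flux)", {
  for (mid in c(1, 4, 7, 11, 15)) {
    sol <- coarse_solution(mid)
    I <- integrate_contact_current(sol, 2)$current_mA
    expect_equal(I, -1, tolerance = 0.01,
                 label = sprintf("model %d active current", mid))
    # global conservation: contacts + ground sum to zero
    expect_lt(abs(sum(sol$contact_currents) + sol$ground_current), 1e-6)
  }
})

test_that("inactive contacts carry zero net current", {
  for (mid in c(1, 15)) {
    sol <- coarse_solution(mid)
    inact <- sol$contact_currents[-2]
    expect_lt(max(abs(inact)), 1e-3,
              label = sprintf("model %d inactive currents", mid))
  }
})

test_that("the solution is linear in the commanded current and zero on the ground patch", {
  mesh <- coarse_mesh()
  model <- vc_model(mesh, variant_spec(15))
  s1 <- coarse_solution(15)
  s2 <- solve_vc(model, current = -2.5)
  expect_equal(max(abs(s2$V - 2.5 * s1$V)) / max(abs(s2$V)), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(s1$V[mesh$ground_nodes])), 0)
})

test_that("the two-solve electric-potential source delivers the target and equals the scaled seed solve", {
  sol <- coarse_solution(11)
  expect_equal(sol$contact_currents[[2]], -1, tolerance = 0.01)
  # pointwise: second solve is the seed solve rescaled by I_target / I_1
  sc <- sol$source$scaled_voltage / sol$source$seed_voltage
  expect_equal(max(abs(sol$V - sol$source$V_seed * sc)) / max(abs(sol$V)),
               0, tolerance = 1e-8)
  # a different seed voltage cancels out of the final solution
  s2 <- solve_vc(vc_model(coarse_mesh(), variant_spec(11)), seed_voltage = 2)
  expect_equal(max(abs(s2$V - sol$V)) / max(abs(sol$V)), 0,
               tolerance = 1e-8)
})

test_that("the floating-potential contact is equipotential and matches the scaled-Dirichlet solution", {
  mesh <- coarse_mesh()
  s15 <- coarse_solution(15)
  nodes <- unique(as.vector(mesh$surfaces[[2]]$facets))
  expect_equal(diff(range(s15$V[nodes])), 0, tolerance = 1e-12)
  expect_equal(s15$floating_values[["contact_2"]],
               s15$V[nodes[1]])
  # equivalence oracle: same equipotential + total-current physics as the
  # two-solve Dirichlet source
  s11 <- coarse_solution(11)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  probe <- cbind(3 * cos(th), 3 * sin(th), 2.75)
  v15 <- field_at(s15, probe); v11 <- field_at(s11, probe)
  expect_lt(sqrt(mean((v15 - v11)^2)) / sqrt(mean(v11^2)), 0.01)
})

test_that("the point current source load snaps to a contact-domain vertex and conserves current", {
  sol <- coarse_solution(1)
  mesh <- coarse_mesh()
  touching <- mesh$region[which(rowSums(mesh$tets == sol$source$vertex) > 0)]
  expect_true(any(touching %in% 11:18))
  expect_lt(sol$source$snap_offset, 0.5)
  # total applied load is the commanded current at one vertex
  expect_equal(sol$contact_currents[[2]], -1, tolerance = 0.01)
})

test_that("uniform-flux sources impose I/A and their integrated jump equals I", {
  sol <- coarse_solution(7)
  A <- sum(coarse_mesh()$surfaces[[2]]$area)
  expect_equal(sol$source$imposed_density, -1 / A)
  mp <- surface_current_density_map(sol, 2)
  expect_equal(unique(mp$jn_tissue), -1 / A)
  expect_equal(sum(mp$jn_tissue * mp$area), -1, tolerance = 1e-9)
})

test_that("far-field potential decays monotonically along rays into the brain", {
  sol <- coarse_solution(15)
  for (ang in c(0, 90, 200)) {
    u <- c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
    r <- seq(1.5, 40, by = 0.7)
    ray <- cbind(r * u[1], r * u[2], 2.75 + r * 0)
    v <- field_at(sol, ray)
    expect_true(all(diff(abs(v)) < 0),
                label = sprintf("monotone decay at azimuth %d", ang))
  }
})

test_that("FEM potential of a central point source matches the analytic solution", {
  sol <- oracle_sphere_solution()
  mesh <- sol$mesh
  r <- sqrt(rowSums(mesh$vertices^2))
  sel <- which(r >= 2 & r <= 25)
  # exact bounded-domain closed form (pure FEM error)
  R <- max(mesh$shells)
  vex <- (-1e-3) / (4 * pi * 0.2) * (1 / (r[sel] * 1e-3) - 1 / (R * 1e-3))
  expect_lt(max(abs(sol$V[sel] - vex) / abs(vex)), 0.02)
  # infinite-medium formula I/(4 pi sigma r) within 2% over 2-25 mm
  vinf <- (-1e-3) / (4 * pi * 0.2 * (r[sel] * 1e-3))
  expect_lt(max(abs(sol$V[sel] - vinf) / abs(vinf)), 0.02)
  # interpolated off-vertex agreement
  set.seed(7)
  rr <- runif(40, 2, 25); th <- runif(40, 0, 2 * pi)
  ph <- acos(runif(40) * 2 - 1)
  pp <- cbind(rr * sin(ph) * cos(th), rr * sin(ph) * sin(th), rr * cos(ph))
  expect_equal(field_at(sol, pp), point_source_field(-1, 0.2)(pp),
               tolerance = 0.03)
})

test_that("consistent and quadrature contact-current integration agree in sign, quadrature carries discretization error", {
  sol <- coarse_solution(15)
  ic <- integrate_contact_current(sol, 2, "consistent")$current_mA
  iq <- integrate_contact_current(sol, 2, "quadrature")$current_mA
  expect_lt(ic, 0); expect_lt(iq, 0)
  expect_equal(ic, -1, tolerance = 0.01)
  # the one-sided facet-gradient estimate is the crude diagnostic
  expect_gt(abs(iq), 0.1)
  expect_lt(abs(iq), 2)
})

test_that("assembling a variant requires a grounded mesh", {
  mesh <- coarse_mesh()
  broken <- mesh
  broken$ground_nodes <- integer(0)
  expect_error(vc_model(broken, variant_spec(1)), "ground")
})
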