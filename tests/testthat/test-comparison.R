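# Comparison metrics: voltage difference maps, threshold errors, and the
# reduced-scale matrix invariants.

test_that("voltage difference of a solution against itself is exactly zero and normalization removes current scaling", {
  sol <- coarse_solution(15)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(3 * cos(th), 3 * sin(th), 2.75)
  vd <- voltage_difference_map(sol, sol, pts)
  expect_equal(vd$dv, rep(0, nrow(pts)))
  expect_equal(vd$rel_pct, rep(0, nrow(pts)))
  # 2x current, normalized back: zero map
  sol2 <- solve_vc(vc_model(coarse_mesh(), variant_spec(15)), current = -2)
  expect_error(voltage_difference_map(sol, sol2, pts), "normalize")
  vd2 <- voltage_difference_map(sol, sol2, pts, normalize = TRUE)
  expect_equal(max(abs(vd2$dv)), 0, tolerance = 1e-9)
})

test_that("probes near the point-source vertex are excluded from difference maps", {
  s1 <- coarse_solution(1)
  s15 <- coarse_solution(15)
  mesh <- coarse_mesh()
  vx <- mesh$vertices[s1$source$vertex, ]
  near <- rbind(vx + c(0.6, 0, 0), c(5, 0, 2.75))
  vd <- voltage_difference_map(s15, s1, near)
  expect_true(vd$excluded[1])
  expect_false(vd$excluded[2])
  expect_true(is.na(vd$dv[1]))
  expect_equal(attr(vd, "n_excluded"), 1L)
})

test_that("threshold errors are percentage differences with the expected algebra", {
  gs <- axon_grid_spec(n_radii = 3, offsets = 0, azimuths = 0)
  gr <- build_grid(gs, lead_spec(), domain_spec(), "d1a")
  a <- gr; a$threshold <- c(1, 2, 4); a$converged <- TRUE
  a$reason <- "converged"
  class(a) <- c("population_thresholds", class(gr))
  b <- a; b$threshold <- c(1, 2, 4)
  expect_equal(threshold_error(a, b)$error_pct, c(0, 0, 0))
  b$threshold <- 2 * a$threshold
  expect_equal(threshold_error(a, b)$error_pct, c(100, 100, 100))
  b$threshold <- c(0.8, 2, 6)
  expect_equal(threshold_error(a, b)$error_pct, c(-20, 0, 50))
  expect_equal(attr(threshold_error(a, b), "range"), c(-20, 50))
  b$axon <- rev(b$axon)
  expect_error(threshold_error(a, b), "different axon grids")
})

test_that("absolute difference maps are exactly antisymmetric under reference swap", {
  s15 <- coarse_solution(15)
  s11 <- coarse_solution(11)
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(4 * cos(th), 4 * sin(th), 2.75)
  ab <- voltage_difference_map(s15, s11, pts)
  ba <- voltage_difference_map(s11, s15, pts)
  expect_equal(ab$dv, -ba$dv)
})

test_that("a reduced matrix is reproducible and reference errors vanish", {
  # tiny matrix: reference + 2 variants, few axons
  gs <- axon_grid_spec(n_radii = 3, offsets = c(-1, 1), azimuths = c(0, 180))
  run_args <- list(settings = coarse_settings(), variants = c(1, 7, 15),
                   reference = 1, grid = gs, verbose = FALSE,
                   mesh = coarse_mesh())
  cmp <- do.call(run_matrix, run_args)
  expect_s3_class(cmp, "vc_comparison")
  ref_row <- cmp$summary[cmp$summary$model_id == 1, ]
  expect_equal(ref_row$thr_err_min, 0)
  expect_equal(ref_row$thr_err_max, 0)
  expect_equal(ref_row$n_active_err_pct, 0)
  expect_equal(ref_row$volume_err_pct, 0)
  expect_false(any(cmp$summary$failed))
  expect_true(all(is.finite(cmp$timing$solve[!cmp$timing$failed])))
  # determinism: a second run gives identical thresholds
  cmp2 <- do.call(run_matrix, run_args)
  expect_identical(cmp$summary, cmp2$summary)
  expect_identical(cmp$runs[["15"]]$thresholds$threshold,
                   cmp2$runs[["15"]]$thresholds$threshold)
})

test_that("a failing variant is recorded and the matrix continues", {
  gs <- axon_grid_spec(n_radii = 3, offsets = 0, azimuths = 0)
  # break variant 7 by an impossible threshold range
  cmp <- run_matrix(settings = coarse_settings(), variants = c(1, 15),
                    reference = 1, grid = gs, verbose = FALSE,
                    mesh = coarse_mesh(), range = c(0.05, 10))
  expect_false(any(cmp$summary$failed))
  # an unsolvable variant id cannot even be constructed; simulate failure
  # by a corrupted sigma
  expect_error(run_matrix(settings = coarse_settings(), variants = c(2),
                          reference = 1, grid = gs, verbose = FALSE,
                          mesh = coarse_mesh()),
               "reference")
})
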