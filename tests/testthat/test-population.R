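# Axon grids, bisection thresholds vs sweep oracle, current-distance
# curves and activation summaries.

test_that("the grid uses log-spaced radii, honors rotations and is centered on the contact", {
  gs <- axon_grid_spec(r_min = 1.5, r_max = 8, n_radii = 10,
                       offsets = c(-3, -1.5, 0, 1.5, 3),
                       azimuths = seq(0, 330, by = 30))
  gr <- build_grid(gs, lead_spec(), domain_spec(), "d1a")
  radii <- sort(unique(gr$r))
  expect_equal(length(radii), 10L)
  ratios <- radii[-1] / radii[-10]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-9)
  expect_equal(nrow(gr), 10 * 5 * 12)
  expect_equal(length(unique(gr$azimuth)), 12L)
  # centered on the contact's axial center
  lay <- contact_layout(lead_spec())
  expect_equal(mean(gr$z), (lay$z0[2] + lay$z1[2]) / 2)
  # axons are perpendicular to the lead axis (tangential direction)
  expect_equal(gr$uz, rep(0, nrow(gr)))
  expect_equal(gr$ux^2 + gr$uy^2, rep(1, nrow(gr)))
  # radial clearance is enforced
  expect_error(build_grid(axon_grid_spec(r_min = 1.0), lead_spec(),
                          domain_spec()), "clear")
})

test_that("bisection agrees with a 0.5%-step amplitude sweep within one step", {
  wf <- stimulus_waveform()
  for (r in c(2, 3, 4)) {
    ax <- analytic_axon(r)
    bi <- find_threshold(ax, wf, tol = 0.002)
    expect_true(bi$converged)
    # geometric 0.5% ladder bracketing the bisection estimate
    lad <- bi$threshold * 1.005^(seq(-10, 10))
    sw <- amplitude_sweep(ax, wf, lad)
    expect_false(is.na(sw$threshold))
    expect_lt(abs(sw$threshold - bi$threshold) / bi$threshold, 0.0075)
    # the sweep is a step function: no activation below, all above
    expect_true(all(diff(sw$activated) >= 0))
  }
})

test_that("out-of-range axons are reported unconverged with a reason", {
  ax <- analytic_axon(8)        # far axon: weak drive
  res <- find_threshold(ax, stimulus_waveform(), range = c(0.05, 0.5))
  expect_false(res$converged)
  expect_match(res$reason, "upper bound not activating")
  # very close axon with a capped lower bound
  ax2 <- analytic_axon(2)
  thr <- find_threshold(ax2, stimulus_waveform())$threshold
  res2 <- find_threshold(ax2, stimulus_waveform(),
                         range = c(thr * 2, thr * 10))
  expect_false(res2$converged)
  expect_match(res2$reason, "lower bound already activating")
})

test_that("thresholds increase with distance and the facing azimuth is favored", {
  sol <- coarse_solution(15)
  gs <- axon_grid_spec(n_radii = 6, offsets = 0, azimuths = c(0, 180))
  gr <- build_grid(gs, coarse_mesh()$lead, coarse_mesh()$domain, "d1a")
  thr <- population_thresholds(sol, gr)
  cd <- current_distance_curve(thr)
  expect_gt(attr(cd, "spearman_facing"), 0.95)
  # directional shielding: facing thresholds lower at matched radius
  for (r in sort(unique(thr$r))[3:6]) {
    tf <- thr$threshold[thr$azimuth == 0 & thr$r == r]
    to <- thr$threshold[thr$azimuth == 180 & thr$r == r]
    if (is.finite(tf) && is.finite(to)) expect_lt(tf, to)
  }
  # per-axon thresholds do not depend on grid enumeration order
  gr_rev <- gr[rev(seq_len(nrow(gr))), ]
  class(gr_rev) <- class(gr)
  thr_rev <- population_thresholds(sol, gr_rev)
  expect_equal(thr_rev$threshold[rev(seq_len(nrow(gr)))], thr$threshold)
})

test_that("activation counts and volume are non-decreasing step functions of amplitude", {
  # synthetic thresholds on a small rotated grid, no simulation needed
  gs <- axon_grid_spec(n_radii = 4, offsets = c(-1, 1),
                       azimuths = c(0, 90, 180, 270))
  gr <- build_grid(gs, lead_spec(), domain_spec(), "d1a")
  thr <- gr
  # threshold proportional to r^2 (monotone recruitment inward-out)
  thr$threshold <- 0.1 * thr$r^2
  thr$converged <- TRUE
  thr$reason <- "converged"
  class(thr) <- c("population_thresholds", class(gr))
  amps <- c(0.05, 0.3, 1, 3, 10)
  sums <- lapply(amps, function(a) activation_summary(thr, a))
  n <- vapply(sums, `[[`, numeric(1), "n_active")
  v <- vapply(sums, `[[`, numeric(1), "volume_mm3")
  expect_true(all(diff(n) >= 0))
  expect_true(all(diff(v) >= 0))
  expect_equal(n[1], 0); expect_equal(v[1], 0)
  expect_equal(n[length(n)], nrow(thr))
  # hand-computed volume oracle at amplitude 1: active radii are r <= sqrt(10),
  # the largest grid radius below that bounds each sector
  radii <- sort(unique(thr$r))
  rmax <- max(radii[radii <= sqrt(1 / 0.1)])
  dtheta <- pi / 2; dz <- 2
  expect_equal(sums[[3]]$volume_mm3, 8 * 0.5 * dtheta * rmax^2 * dz)
})

test_that("empty or degenerate threshold sets are handled", {
  gs <- axon_grid_spec(n_radii = 2, offsets = 0, azimuths = 0)
  gr <- build_grid(gs, lead_spec(), domain_spec(), "d1a")
  thr <- gr
  thr$threshold <- NA_real_
  thr$converged <- FALSE
  thr$reason <- "upper bound not activating"
  class(thr) <- c("population_thresholds", class(gr))
  expect_error(current_distance_curve(thr), "at least 2")
  s <- activation_summary(thr, 1)
  expect_equal(s$n_active, 0)
})
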