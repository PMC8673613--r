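# Myelinated axon cable model of the MRG class: nodes of Ranvier carry fast
# Na+, persistent Na+, slow K+ and leak channels; internodes are reduced
# single-cable passive RC compartments (axolemma and myelin lamellae lumped
# in series). Straight fibers, extracellular drive from a static potential
# profile scaled by the stimulus waveform.

#' Fiber-diameter geometry table of the myelinated axon model family
#'
#' Published relationship between fiber diameter and internode length,
#' axon/node caliber and myelin lamella count used by [fiber_spec()].
#' Lengths in um.
#'
#' @return A data.frame with one row per supported fiber diameter.
#' @export
mrg_geometry_table <- function() {
  data.frame(
    fiber_diameter = c(5.7, 7.3, 8.7, 10, 11.5, 12.8, 14, 15, 16),
    internode_length = c(500, 750, 1000, 1150, 1250, 1350, 1400, 1450, 1500),
    axon_diameter = c(3.4, 4.6, 5.8, 6.9, 8.1, 9.2, 10.4, 11.5, 12.7),
    node_diameter = c(1.9, 2.4, 2.8, 3.3, 3.7, 4.2, 4.7, 5.0, 5.5),
    lamellae = c(80, 100, 110, 120, 130, 135, 140, 145, 150))
}

#' Myelinated fiber specification
#'
#' MRG-class myelinated axon. Node compartments carry fast Na+, persistent
#' Na+, slow K+ and leak conductances; internodes are passive single-cable
#' RC compartments whose specific conductance and capacitance lump the
#' axolemma in series with `2 * lamellae` myelin membranes. Fiber diameter
#' selects internode length, axon/node caliber and lamella count from the
#' published diameter table ([mrg_geometry_table()]).
#'
#' @param fiber_diameter Fiber diameter in um (one of the table entries).
#' @param n_nodes Number of nodes of Ranvier (odd).
#' @param internode_segments Passive segments per internode.
#' @param axial_resistivity Axoplasmic resistivity (Ohm cm).
#' @param temperature Model temperature (deg C); gating rates are Q10-scaled
#'   from their 36 deg C reference.
#' @param gnaf,gnap,gks,gl Nodal maximal conductances (mS/cm^2).
#' @param ena,ek,el Reversal potentials (mV).
#' @param cm_node Nodal specific capacitance (uF/cm^2).
#' @param v_rest Resting potential (mV). The nodal leak reversal is
#'   balanced so the fiber rests exactly here (the published value for the
#'   model family); `el` is retained as the nominal leak reversal.
#' @param g_axolemma Internodal axolemma conductance (mS/cm^2).
#' @param c_axolemma Internodal axolemma capacitance (uF/cm^2).
#' @param g_myelin,c_myelin Per-membrane myelin conductance (mS/cm^2) and
#'   capacitance (uF/cm^2).
#' @param node_length Node length (um).
#' @return An object of class `fiber_spec`.
#' @export
fiber_spec <- function(fiber_diameter = 5.7, n_nodes = 21,
                       internode_segments = 3,
                       axial_resistivity = 70, temperature = 37,
                       gnaf = 3000, gnap = 10, gks = 80, gl = 7,
                       ena = 50, ek = -90, el = -90, cm_node = 2,
                       v_rest = -80,
                       g_axolemma = 0.1, c_axolemma = 2,
                       g_myelin = 1, c_myelin = 0.1,
                       node_length = 1) {
  tab <- mrg_geometry_table()
  i <- match(fiber_diameter, tab$fiber_diameter)
  if (is.na(i))
    stop("fiber_diameter must be one of: ",
         paste(tab$fiber_diameter, collapse = ", "), " um")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 3L || n_nodes %% 2L == 0L)
    stop("n_nodes must be odd and >= 3 (fiber symmetric about its center)")
  stopifnot(internode_segments >= 1, axial_resistivity > 0,
            gnaf >= 0, gnap >= 0, gks >= 0, gl >= 0)
  nl <- tab$lamellae[i]
  n_memb <- 2 * nl
  g_int <- 1 / (1 / g_axolemma + n_memb / g_myelin)   # mS/cm^2, series
  c_int <- 1 / (1 / c_axolemma + n_memb / c_myelin)   # uF/cm^2, series
  out <- list(fiber_diameter = fiber_diameter,
              internode_length = tab$internode_length[i],
              axon_diameter = tab$axon_diameter[i],
              node_diameter = tab$node_diameter[i],
              lamellae = nl,
              n_nodes = n_nodes,
              internode_segments = as.integer(internode_segments),
              axial_resistivity = axial_resistivity,
              temperature = temperature,
              gnaf = gnaf, gnap = gnap, gks = gks, gl = gl,
              ena = ena, ek = ek, el = el, cm_node = cm_node,
              v_rest = v_rest,
              g_internode = g_int, c_internode = c_int,
              node_length = node_length)
  class(out) <- "fiber_spec"
  out
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("MRG-class fiber: %.3g um, %d nodes, internode %.4g um (%d segments)\n",
              x$fiber_diameter, x$n_nodes, x$internode_length,
              x$internode_segments))
  cat(sprintf("  node gNaf/gNap/gKs/gL = %g/%g/%g/%g mS/cm^2, T = %g C\n",
              x$gnaf, x$gnap, x$gks, x$gl, x$temperature))
  invisible(x)
}

# Q10 factors relative to the 36 C reference of the published kinetics
fiber_q10 <- function(fiber) {
  dT <- (fiber$temperature - 36) / 10
  c(q1 = 2.2^dT, q2 = 2.9^dT, q3 = 3.0^dT)
}

# Nodal steady-state current at clamped potential v (per unit area, gates
# at their infinity values); used to find the resting potential.
node_steady_current <- function(v, fiber) {
  g <- gate_inf(v)
  fiber$gnaf * g["m"]^3 * g["h"] * (v - fiber$ena) +
    fiber$gnap * g["p"]^3 * (v - fiber$ena) +
    fiber$gks * g["s"] * (v - fiber$ek) +
    fiber$gl * (v - fiber$el)
}

gate_inf <- function(v) {
  f1 <- function(x, y) ifelse(abs(x / y) < 1e-7, y, x / (1 - exp(-x / y)))
  f2 <- function(x, y) ifelse(abs(x / y) < 1e-7, y, x / (exp(x / y) - 1))
  am <- 6.57 * f1(v + 20.4, 10.3);  bm <- 0.304 * f2(v + 25.7, 9.16)
  ah <- 0.34 * f2(v + 114, 11);     bh <- 12.6 / (1 + exp(-(v + 31.8) / 13.4))
  ap <- 0.0353 * f1(v + 27, 10.2);  bp <- 0.000883 * f2(v + 34, 10)
  as_ <- 0.3 / (1 + exp(-(v + 53) / 5))
  bs <- 0.03 / (1 + exp(-(v + 90) / 1))
  c(m = am / (am + bm), h = ah / (ah + bh), p = ap / (ap + bp),
    s = as_ / (as_ + bs))
}

#' Resting potential of the fiber
#'
#' The fiber rests at `fiber$v_rest`: the nodal leak reversal is balanced
#' (see [balanced_leak_reversal()]) and internodal leak reversals equal the
#' resting potential, so the resting state is a uniform equilibrium.
#'
#' @param fiber A [fiber_spec()].
#' @return Resting potential in mV.
#' @export
resting_potential <- function(fiber) fiber$v_rest

#' Balanced nodal leak reversal
#'
#' Leak reversal potential that makes the nodal membrane current vanish at
#' the resting potential with gates at steady state; used in place of the
#' nominal `el` so the reduced fiber rests exactly at `v_rest`.
#'
#' @param fiber A [fiber_spec()].
#' @return Leak reversal in mV.
#' @export
balanced_leak_reversal <- function(fiber) {
  v <- fiber$v_rest
  g <- gate_inf(v)
  i_chan <- fiber$gnaf * g[["m"]]^3 * g[["h"]] * (v - fiber$ena) +
    fiber$gnap * g[["p"]]^3 * (v - fiber$ena) +
    fiber$gks * g[["s"]] * (v - fiber$ek)
  v + i_chan / fiber$gl
}

#' Build a straight axon
#'
#' Places the compartment chain (nodes of Ranvier separated by
#' `internode_segments` passive internodal compartments) on a straight
#' line. The chain is centered within the requested span.
#'
#' @param fiber A [fiber_spec()].
#' @param start_point Line origin (mm).
#' @param direction Direction vector (normalized internally).
#' @param length Available span along the line (mm); must cover the fiber
#'   (`(n_nodes - 1) * internode_length`). Default: exactly the fiber span.
#' @return An object of class `axon_instance` with compartment coordinates
#'   (mm), types, lengths and diameters (um).
#' @export
build_axon <- function(fiber, start_point = c(0, 0, 0),
                       direction = c(1, 0, 0), length = NULL) {
  stopifnot(inherits(fiber, "fiber_spec"))
  nrm <- sqrt(sum(direction^2))
  if (nrm <= 0) stop("direction must be a nonzero vector")
  u <- direction / nrm
  span_um <- (fiber$n_nodes - 1) * fiber$internode_length + fiber$node_length
  span <- span_um * 1e-3                      # mm
  if (is.null(length)) length <- span
  if (length <= 0) stop("axon length must be positive")
  if (length < span - 1e-9)
    stop(sprintf("length %.3g mm too short: %d nodes of this fiber span %.3g mm",
                 length, fiber$n_nodes, span))
  ns <- fiber$internode_segments
  Lnode <- fiber$node_length                  # um
  Lint <- (fiber$internode_length - Lnode) / ns
  seg_len <- c(rep(c(Lnode, rep(Lint, ns)), fiber$n_nodes - 1L), Lnode)
  seg_type <- c(rep(c("node", rep("internode", ns)), fiber$n_nodes - 1L),
                "node")
  s_end <- cumsum(seg_len)
  s_mid <- (s_end - seg_len / 2) * 1e-3       # mm along the chain
  offset <- (length - span) / 2
  coords <- matrix(rep(start_point, each = length(s_mid)), ncol = 3L) +
    outer(offset + s_mid, u)
  diam <- ifelse(seg_type == "node", fiber$node_diameter,
                 fiber$axon_diameter)
  out <- list(fiber = fiber,
              coords = coords,
              type = seg_type,
              seg_length = seg_len,           # um
              diameter = diam,                # um
              direction = u,
              Ve_static = NULL, I_ref = NULL)
  class(out) <- "axon_instance"
  out
}

#' @export
print.axon_instance <- function(x, ...) {
  cat(sprintf("axon_instance: %d compartments (%d nodes), %.3g um fiber\n",
              nrow(x$coords), sum(x$type == "node"), x$fiber$fiber_diameter))
  cat(sprintf("  from (%.2f, %.2f, %.2f) along (%.2f, %.2f, %.2f) mm\n",
              x$coords[1, 1], x$coords[1, 2], x$coords[1, 3],
              x$direction[1], x$direction[2], x$direction[3]))
  if (!is.null(x$Ve_static))
    cat(sprintf("  Ve_static attached: [%.4g, %.4g] V at I_ref = %g mA\n",
                min(x$Ve_static), max(x$Ve_static), x$I_ref))
  invisible(x)
}

#' Attach extracellular potentials to an axon
#'
#' Interpolates a solved (or analytic) extracellular field at the
#' compartment centers and stores it as the static potential profile at the
#' reference stimulus current. During simulation the profile is scaled by
#' `amplitude / |I_ref|` and the stimulus waveform.
#'
#' @param axon An [build_axon()] result.
#' @param field A `field_solution`, an `analytic_field`, or any function
#'   mapping an n x 3 matrix (mm) to potentials (V).
#' @param I_ref Reference current (mA) that generated the field; defaults
#'   to the solution's commanded current (or -1 mA for analytic fields).
#' @return The axon with `Ve_static` (V) attached.
#' @export
attach_field <- function(axon, field, I_ref = NULL) {
  stopifnot(inherits(axon, "axon_instance"))
  if (inherits(field, c("field_solution", "sphere_solution"))) {
    if (is.null(I_ref)) I_ref <- field$current
    ve <- field_at(field, axon$coords)
  } else if (is.function(field)) {
    if (is.null(I_ref)) I_ref <- attr(field, "I")
    if (is.null(I_ref)) I_ref <- -1
    ve <- field(axon$coords)
  } else stop("field must be a field_solution or a function of points")
  if (any(!is.finite(ve)))
    stop("non-finite extracellular potentials along the axon")
  axon$Ve_static <- as.numeric(ve)
  axon$I_ref <- I_ref
  axon
}

# Absolute electrical parameters of the compartment chain (areas in cm^2,
# capacitances uF, conductances mS).
axon_electrics <- function(axon) {
  f <- axon$fiber
  area <- pi * (axon$diameter * 1e-4) * (axon$seg_length * 1e-4)  # cm^2
  is_node <- axon$type == "node"
  cm <- ifelse(is_node, f$cm_node, f$c_internode) * area           # uF
  gl <- ifelse(is_node, f$gl, f$g_internode) * area                # mS
  gnaf <- ifelse(is_node, f$gnaf, 0) * area
  gnap <- ifelse(is_node, f$gnap, 0) * area
  gks <- ifelse(is_node, f$gks, 0) * area
  # axial: series half-segment resistances, rho in Ohm cm
  ax_area <- pi * (ifelse(is_node, f$node_diameter, f$axon_diameter) *
                     1e-4)^2 / 4                                   # cm^2
  rhalf <- f$axial_resistivity * (axon$seg_length * 1e-4 / 2) / ax_area  # Ohm
  n <- length(area)
  ga <- 1000 / (rhalf[-n] + rhalf[-1])                             # mS
  list(cm = cm, ga = ga, is_node = is_node,
       gnaf = gnaf, gnap = gnap, gks = gks, gl = gl)
}

#' Simulate the extracellular stimulation of an axon
#'
#' Integrates the cable equation with a semi-implicit (Crank-Nicolson)
#' scheme and Rush-Larsen gate updates; the extracellular drive enters as
#' `waveform(t) * amplitude / |I_ref| * Ve_static`. Action potentials are
#' detected at the 2nd node from each end (0 mV crossing after pulse
#' onset); the axon counts as activated only when the spike reaches both
#' detectors (propagation through the fiber).
#'
#' @param axon Axon with `Ve_static` attached (see [attach_field()]).
#' @param waveform A [stimulus_waveform()].
#' @param amplitude Stimulus amplitude magnitude in mA; default from the
#'   waveform.
#' @param dt Time step (ms).
#' @param record `"none"`, `"detectors"` or `"all"` membrane traces.
#' @return An object of class `axon_sim`: `activated`, detector spike
#'   times (ms), and optionally traces.
#' @export
simulate_axon <- function(axon, waveform = stimulus_waveform(),
                          amplitude = NULL, dt = 0.002,
                          record = c("none", "detectors", "all")) {
  stopifnot(inherits(axon, "axon_instance"),
            inherits(waveform, "stimulus_waveform"))
  record <- match.arg(record)
  if (is.null(axon$Ve_static)) stop("attach a field before simulating")
  if (is.null(amplitude)) amplitude <- waveform$amplitude
  el <- axon_electrics(axon)
  f <- axon$fiber
  vrest <- resting_potential(f)
  epas <- ifelse(el$is_node, balanced_leak_reversal(f), vrest)
  q <- fiber_q10(f)
  n <- length(el$cm)
  node_idx <- which(el$is_node)
  det <- c(node_idx[2L], node_idx[length(node_idx) - 1L])
  ve_mV <- axon$Ve_static * 1000 * amplitude / abs(axon$I_ref)
  nsteps <- ceiling(waveform$t_total / dt)
  i_on <- round(waveform$onset_delay / 1000 / dt)
  i_off <- round((waveform$onset_delay + waveform$pulse_width) / 1000 / dt)
  if (i_off <= i_on) i_off <- i_on + 1L
  res <- cable_run(el$cm, el$ga, el$is_node, el$gnaf, el$gnap, el$gks,
                   el$gl, epas, f$ena, f$ek, vrest, ve_mV, dt,
                   as.integer(nsteps), as.integer(i_on), as.integer(i_off),
                   q[["q1"]], q[["q2"]], q[["q3"]],
                   as.integer(det - 1L), 0,
                   match(record, c("none", "detectors", "all")) - 1L)
  if (any(!is.finite(res$v_final)))
    stop("cable integration unstable (non-finite membrane potential), dt = ",
         dt, " ms")
  out <- list(activated = res$activated,
              spike_times = res$cross_times,   # NA when no crossing
              detectors = det,
              v_rest = vrest,
              vmax = res$vmax,
              v_final = res$v_final,
              dt = dt, amplitude = amplitude,
              waveform = waveform,
              times = if (record != "none") seq(0, by = dt,
                                                length.out = res$n_rec) else NULL,
              traces = res$traces)
  class(out) <- "axon_sim"
  out
}

#' @export
print.axon_sim <- function(x, ...) {
  cat(sprintf("axon_sim: amplitude %.4g mA -> %s\n", x$amplitude,
              if (x$activated) "ACTIVATED (AP at both detectors)" else
                "not activated"))
  if (any(is.finite(x$spike_times)))
    cat(sprintf("  detector crossings at %s ms\n",
                paste(sprintf("%.3f", x$spike_times), collapse = ", ")))
  invisible(x)
}

#' Propagating action potential criterion
#'
#' An axon counts as activated when the membrane potential crosses the
#' detection level at both terminal detector nodes after stimulus onset --
#' an AP at one end only (blocked propagation) does not count.
#'
#' @param times Time vector (ms).
#' @param traces Matrix of membrane potentials (time x detectors).
#' @param level Detection level (mV).
#' @param after Only crossings after this time (ms) count.
#' @return Logical.
#' @export
detect_propagation <- function(times, traces, level = 0, after = 0) {
  traces <- as.matrix(traces)
  stopifnot(length(times) == nrow(traces))
  ok <- vapply(seq_len(ncol(traces)), function(j) {
    v <- traces[, j]
    cross <- which(v[-1] >= level & v[-length(v)] < level)
    any(times[cross + 1L] > after)
  }, logical(1))
  all(ok)
}
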