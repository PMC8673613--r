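# Structured tetrahedral mesh of the lead-in-brain geometry.
#
# The grid is a tensor product of a 2D annular cross-section (radial rings
# aligned to the material radii: contact shell, encapsulation, graded brain)
# and axial layers aligned to the contact bands. Hexahedral/wedge cells are
# split into tetrahedra with a global-index rule so the mesh is conforming.
# One parent mesh carries every lead component as a labeled region; model
# variants select cell subsets, which guarantees the active-contact surface
# discretization is identical across all variants.

#' Mesh sizing controls
#'
#' @param z_fine Axial element size in the contact region (mm).
#' @param theta_step Azimuthal step (degrees); must divide the segment arc
#'   and the inter-segment gap.
#' @param radial_growth Geometric growth of radial rings into the brain.
#' @param z_growth Geometric growth of axial layers away from the contacts.
#' @param core_rings Radial intervals inside the lead core.
#' @param encap_rings Radial intervals across the encapsulation sheath.
#' @param refine Integer refinement factor; `refine = 2` halves the element
#'   sizes in every direction (used for mesh-convergence checks).
#' @return An object of class `mesh_settings`.
#' @export
mesh_settings <- function(z_fine = 0.5, theta_step = 15, radial_growth = 1.35,
                          z_growth = 1.45, core_rings = 2, encap_rings = 2,
                          refine = 1) {
  stopifnot(z_fine > 0, theta_step > 0, radial_growth > 1, z_growth > 1,
            core_rings >= 1, encap_rings >= 1, refine >= 1)
  refine <- as.integer(refine)
  structure(list(z_fine = z_fine / refine,
                 theta_step = theta_step / refine,
                 radial_growth = radial_growth^(1 / refine),
                 z_growth = z_growth^(1 / refine),
                 core_rings = as.integer(core_rings) * refine,
                 encap_rings = as.integer(encap_rings) * refine,
                 refine = refine),
            class = "mesh_settings")
}

# Geometric break sequence from `from` to `to` (excluding `from`), first
# step ~h0, steps growing by `ratio`, rescaled so the last break is `to`.
geom_breaks <- function(from, to, h0, ratio) {
  stopifnot(to > from, h0 > 0, ratio >= 1)
  steps <- h0 * ratio^(0:400)
  cs <- cumsum(steps)
  n <- which(cs >= (to - from) * (1 - 1e-12))[1]
  if (is.na(n)) stop("geom_breaks: growth too slow")
  s <- steps[seq_len(n)] * (to - from) / cs[n]
  from + cumsum(s)
}

subdiv_breaks <- function(anchors, h) {
  # subdivide each anchor interval into equal steps no larger than h
  out <- anchors[1]
  for (i in seq_len(length(anchors) - 1L)) {
    n <- max(1L, ceiling((anchors[i + 1L] - anchors[i]) / h - 1e-9))
    out <- c(out, anchors[i] + (anchors[i + 1L] - anchors[i]) * seq_len(n) / n)
  }
  out
}

#' Build the parent tetrahedral mesh of the lead-in-brain geometry
#'
#' Meshes the full geometry once with every lead component (core, shaft
#' shell, 8 contact shells, encapsulation, brain) as a labeled region.
#' Model variants are applied afterwards by selecting cell subsets
#' ([vc_model()]), so the active-contact surface mesh is shared across all
#' 15 variants by construction.
#'
#' @param lead A [lead_spec()].
#' @param domain A [domain_spec()].
#' @param settings A [mesh_settings()].
#' @return An object of class `vc_mesh` (kind `"lead"`).
#' @export
build_lead_mesh <- function(lead = lead_spec(), domain = domain_spec(),
                            settings = mesh_settings()) {
  stopifnot(inherits(lead, "lead_spec"), inherits(domain, "domain_spec"))
  if (domain$brain_radius < 25 * lead$lead_radius)
    stop("brain_radius must be at least 25 lead radii ",
         "(grounded boundary must be far-field)")
  a <- lead$lead_radius
  t_sh <- lead$contact_thickness
  et <- domain$encapsulation_thickness
  R <- domain$brain_radius
  lay <- contact_layout(lead)
  arc <- lead$segment_arc
  gap <- (360 - lead$segments_per_row * arc) / lead$segments_per_row
  step <- settings$theta_step
  if (abs(arc / step - round(arc / step)) > 1e-9 ||
      abs(gap / step - round(gap / step)) > 1e-9)
    stop("theta_step must divide both the segment arc (", arc,
         ") and the gap (", gap, ")")

  ## --- azimuthal sectors ------------------------------------------------
  theta0 <- -arc / 2                      # segment "a" centered at azimuth 0
  n_th <- as.integer(round(360 / step))
  th_breaks <- theta0 + step * (0:n_th)
  th_mid <- (th_breaks[-1] + th_breaks[-(n_th + 1)]) / 2
  az_centers <- c(0, 120, 240)
  dang <- function(x, c0) abs(((x - c0 + 180) %% 360) - 180)
  sector_col <- integer(n_th)             # 0 = gap, 1..3 = segment column
  for (k in 1:3)
    sector_col[dang(th_mid, az_centers[k]) < arc / 2 - 1e-9] <- k

  ## --- radial rings -----------------------------------------------------
  r_core <- seq(0, a - t_sh, length.out = settings$core_rings + 1L)
  r_shell <- seq(a - t_sh, a, length.out = settings$refine + 1L)[-1]
  r_enc <- seq(a, a + et, length.out = settings$encap_rings + 1L)[-1]
  h0 <- (et / settings$encap_rings) * settings$radial_growth
  r_brain <- geom_breaks(a + et, R, h0, settings$radial_growth)
  r_breaks <- c(r_core, r_shell, r_enc, r_brain)
  n_r <- length(r_breaks) - 1L            # radial intervals

  ## --- axial layers -----------------------------------------------------
  z_ring_top <- max(lay$z1)
  z_fine_top <- z_ring_top + settings$z_fine
  anchors <- sort(unique(c(-et, 0, lay$z0, lay$z1, z_fine_top)))
  z_fine <- subdiv_breaks(anchors, settings$z_fine)
  z_top <- z_ring_top + lead$shaft_length
  z_bot <- -R
  z_below <- -rev(geom_breaks(et, R, settings$z_fine * settings$z_growth,
                              settings$z_growth))
  z_above <- geom_breaks(z_fine_top, z_top,
                         settings$z_fine * settings$z_growth,
                         settings$z_growth)
  z_levels <- sort(unique(c(z_below, z_fine, z_above)))
  n_z <- length(z_levels) - 1L

  ## --- 2D cross-section triangulation -----------------------------------
  # vertex 1 = center; ring i (radius r_breaks[i+1], i = 1..n_r) has n_th
  # vertices at th_breaks[1..n_th]
  vid2 <- function(i, j) {               # ring i >= 1, sector node j (wraps)
    j <- ((j - 1L) %% n_th) + 1L
    1L + (i - 1L) * n_th + j
  }
  n2 <- 1L + n_r * n_th
  th <- th_breaks[seq_len(n_th)]
  v2r <- c(0, rep(r_breaks[-1], each = n_th))
  v2th <- c(0, rep(th, n_r))
  tri <- matrix(0L, n_th + (n_r - 1L) * n_th * 2L, 3L)
  tri_rint <- integer(nrow(tri)); tri_sec <- integer(nrow(tri))
  idx <- 0L
  for (j in seq_len(n_th)) {             # center fan, radial interval 1
    idx <- idx + 1L
    tri[idx, ] <- c(1L, vid2(1L, j), vid2(1L, j + 1L))
    tri_rint[idx] <- 1L; tri_sec[idx] <- j
  }
  for (i in seq_len(n_r - 1L)) {         # annulus between ring i and i+1
    for (j in seq_len(n_th)) {
      A <- vid2(i, j); B <- vid2(i + 1L, j)
      C <- vid2(i + 1L, j + 1L); D <- vid2(i, j + 1L)
      if (min(A, C) < min(B, D)) {
        tr <- rbind(c(A, B, C), c(A, C, D))
      } else {
        tr <- rbind(c(B, C, D), c(B, D, A))
      }
      tri[idx + 1:2, ] <- tr
      tri_rint[idx + 1:2] <- i + 1L
      tri_sec[idx + 1:2] <- j
      idx <- idx + 2L
    }
  }

  ## --- extrusion to tetrahedra ------------------------------------------
  # 3D vertex id of 2D vertex v at z level k
  nzl <- n_z + 1L
  vid3 <- function(v, k) (k - 1L) * n2 + v
  xy <- cbind(v2r * cospi(v2th / 180), v2r * sinpi(v2th / 180))
  vertices <- cbind(xy[rep(seq_len(n2), nzl), , drop = FALSE],
                    rep(z_levels, each = n2))
  ntri <- nrow(tri)
  # sort each triangle's columns by 2D index (prism diagonal rule)
  tsort <- sort3_rows(tri)
  m <- ntri * n_z * 3L
  tets <- matrix(0L, m, 4L)
  tet_tri <- integer(m); tet_layer <- integer(m)
  row0 <- 0L
  for (k in seq_len(n_z)) {
    b1 <- vid3(tsort[, 1], k);  b2 <- vid3(tsort[, 2], k)
    b3 <- vid3(tsort[, 3], k)
    t1 <- vid3(tsort[, 1], k + 1L); t2 <- vid3(tsort[, 2], k + 1L)
    t3 <- vid3(tsort[, 3], k + 1L)
    rows <- row0 + seq_len(3L * ntri)
    tets[rows, ] <- rbind(cbind(b1, b2, b3, t3),
                          cbind(b1, b2, t3, t2),
                          cbind(b1, t2, t3, t1))
    tet_tri[rows] <- rep.int(seq_len(ntri), 3L)
    tet_layer[rows] <- k
    row0 <- row0 + 3L * ntri
  }
  tet_rint <- tri_rint[tet_tri]
  tet_sec <- tri_sec[tet_tri]

  ## --- region labels -----------------------------------------------------
  eps <- 1e-9
  r_hi <- r_breaks[tet_rint + 1L]
  r_lo <- r_breaks[tet_rint]
  z_lo <- z_levels[tet_layer]
  z_hi <- z_levels[tet_layer + 1L]
  zm <- (z_lo + z_hi) / 2
  ring_class <- ifelse(r_hi <= a - t_sh + eps, "core",
                ifelse(r_hi <= a + eps, "shell",
                ifelse(r_hi <= a + et + eps, "encap", "brain")))
  # contact band per layer (0 = none): 1 tip, 2 row1, 3 row2, 4 ring
  band <- integer(length(zm))
  band[zm > lay$z0[1] & zm < lay$z1[1]] <- 1L
  band[zm > lay$z0[2] & zm < lay$z1[2]] <- 2L
  band[zm > lay$z0[5] & zm < lay$z1[5]] <- 3L
  band[zm > lay$z0[8] & zm < lay$z1[8]] <- 4L
  col <- sector_col[tet_sec]
  region <- rep(REG_BRAIN, length(zm))
  in_lead_z <- z_lo >= -eps
  under_encap <- !in_lead_z & z_lo >= -et - eps
  # tissue below the tip: encapsulation cap within the sheath radius
  region[under_encap & r_hi <= a + et + eps] <- REG_ENCAP
  # lead-height cells
  region[in_lead_z & ring_class == "core"] <- REG_CORE
  region[in_lead_z & ring_class == "encap"] <- REG_ENCAP
  sh <- in_lead_z & ring_class == "shell"
  region[sh] <- REG_SHAFT
  region[sh & band == 1L] <- REG_CONTACT0 + 1L
  region[sh & band == 4L] <- REG_CONTACT0 + 8L
  for (cc in 1:3) {
    region[sh & band == 2L & col == cc] <- REG_CONTACT0 + 1L + cc
    region[sh & band == 3L & col == cc] <- REG_CONTACT0 + 4L + cc
  }

  mesh <- list(kind = "lead",
               vertices = vertices, tets = tets, region = region,
               rint = tet_rint, sector = tet_sec, layer = tet_layer,
               r_breaks = r_breaks, theta0 = theta0, theta_step = step,
               n_th = n_th, z_levels = z_levels, n2 = n2,
               lead = lead, domain = domain, settings = settings)
  mesh$geom <- tet_geometry(vertices, tets)
  # locator: cell id over (rint, sector, layer)
  cell <- ((tet_layer - 1L) * n_th + (tet_sec - 1L)) * n_r + tet_rint
  mesh$n_cells <- n_z * n_th * n_r
  mesh$cell_index <- build_cell_index(cell, mesh$n_cells)

  ## --- surfaces and ground patch ----------------------------------------
  mesh$surfaces <- vector("list", 8L)
  for (k in 1:8) {
    s <- region_interface(mesh, REG_CONTACT0 + k, REG_ENCAP)
    if (is.null(s)) stop("contact ", k, " has no tissue interface")
    s$edge <- facet_on_patch_edge(s$facets)
    ctr <- contact_center(lead, k)
    d <- sweep(s$centroid, 2L, ctr)
    s$dist_center <- sqrt(rowSums(d * d))
    mesh$surfaces[[k]] <- s
  }
  vr <- sqrt(vertices[, 1]^2 + vertices[, 2]^2)
  mesh$ground_nodes <- which(abs(vertices[, 3] - z_bot) < 1e-9 &
                               vr <= domain$ground_radius + 1e-9)
  if (!length(mesh$ground_nodes)) stop("mesh has no ground patch nodes")
  class(mesh) <- "vc_mesh"
  mesh
}

#' Geometric center of a contact
#'
#' Center of the contact surface: for directional segments the point at the
#' lead surface at the segment's azimuth center and axial mid-band; for tip
#' and ring contacts the on-axis axial mid-band point.
#' @param lead A [lead_spec()].
#' @param contact Contact id or label.
#' @return Length-3 numeric (mm).
#' @export
contact_center <- function(lead, contact) {
  k <- contact_id(contact)
  lay <- contact_layout(lead)
  zc <- (lay$z0[k] + lay$z1[k]) / 2
  if (is.na(lay$azimuth[k])) return(c(0, 0, zc))
  azr <- lay$azimuth[k] * pi / 180
  c(lead$lead_radius * cos(azr), lead$lead_radius * sin(azr), zc)
}

locator_cells_lead <- function(mesh, pts, widen = FALSE) {
  n_r <- length(mesh$r_breaks) - 1L
  n_z <- length(mesh$z_levels) - 1L
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  th <- atan2(pts[, 2], pts[, 1]) * 180 / pi
  th <- (th - mesh$theta0) %% 360
  sec <- pmin(floor(th / mesh$theta_step) + 1L, mesh$n_th)
  ri <- findInterval(r, mesh$r_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  ri[r > mesh$r_breaks[n_r + 1L] + 1e-9] <- NA_integer_
  zi <- findInterval(pts[, 3], mesh$z_levels, rightmost.closed = TRUE)
  zi[zi < 1L | zi > n_z] <- NA_integer_
  cell_of <- function(ri, si, zi) {
    si <- ((si - 1L) %% mesh$n_th) + 1L
    ((zi - 1L) * mesh$n_th + (si - 1L)) * n_r + ri
  }
  npt <- nrow(pts)
  if (!widen) {
    # vectorized CSR expansion of each point's single candidate cell
    valid <- !is.na(ri) & !is.na(zi)
    cid <- rep(NA_integer_, npt)
    cid[valid] <- cell_of(ri[valid], sec[valid], zi[valid])
    off <- mesh$cell_index$offsets
    starts <- rep(1L, npt); lens <- rep(0L, npt)
    ok <- !is.na(cid)
    starts[ok] <- off[cid[ok]] + 1L
    lens[ok] <- off[cid[ok] + 1L] - off[cid[ok]]
    idx <- sequence(lens) + rep(starts - 1L, lens)
    tets <- mesh$cell_index$order[idx]
    return(split(tets, factor(rep.int(seq_len(npt), lens),
                              levels = seq_len(npt))))
  }
  out <- vector("list", npt)
  for (i in seq_len(npt)) {
    if (is.na(ri[i]) || is.na(zi[i])) { out[[i]] <- integer(0); next }
    rr <- unique(pmax(1L, pmin(n_r, ri[i] + (-1:1))))
    ss <- sec[i] + (-1:1)
    zz <- unique(pmax(1L, pmin(n_z, zi[i] + (-1:1))))
    g <- expand.grid(rr = rr, ss = ss, zz = zz)
    cells <- unique(cell_of(g$rr, g$ss, g$zz))
    out[[i]] <- unlist(cell_tets(mesh$cell_index, cells), use.names = FALSE)
  }
  out
}

#' Discretization signature of a contact surface
#'
#' A stable hash of the contact-surface facet geometry (vertex coordinates
#' of every facet, order-independent). Model variants built from the same
#' parent mesh share the signature for every contact by construction; the
#' signature changes when the surface discretization changes.
#'
#' @param mesh A `vc_mesh` (kind `"lead"`).
#' @param contact Contact id or label.
#' @return A character md5 string.
#' @export
contact_surface_signature <- function(mesh, contact) {
  k <- contact_id(contact)
  s <- mesh$surfaces[[k]]
  co <- mesh$vertices
  tri <- array(0, dim = c(nrow(s$facets), 3L, 3L))
  for (j in 1:3) tri[, j, ] <- co[s$facets[, j], , drop = FALSE]
  # canonical: vertices within facet sorted lexicographically, then facets
  flat <- t(apply(tri, 1L, function(m) {
    m <- round(m, 8)
    as.vector(t(m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]))
  }))
  o <- do.call(order, as.data.frame(flat))
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(apply(format(flat[o, , drop = FALSE], digits = 10, trim = TRUE),
                   1L, paste, collapse = " "), tf)
  unname(tools::md5sum(tf))
}

#' Relative change between two field solutions on probe points
#'
#' Mesh-convergence statistic: interpolates two solutions of the same
#' geometry (e.g. at `refine = 1` and `refine = 2`) on shared probe points
#' and reports the maximum and RMS relative voltage change.
#'
#' @param sol_coarse,sol_fine `field_solution` objects for the same lead,
#'   domain and variant at two mesh resolutions.
#' @param probe_pts n x 3 matrix of tissue probe points (mm).
#' @return List with `max_rel`, `rms_rel`, `n`.
#' @export
convergence_check <- function(sol_coarse, sol_fine, probe_pts) {
  stopifnot(inherits(sol_coarse, "field_solution"),
            inherits(sol_fine, "field_solution"))
  g1 <- sol_coarse$model$mesh$lead; g2 <- sol_fine$model$mesh$lead
  if (!isTRUE(all.equal(unclass(g1), unclass(g2))))
    stop("solutions come from different lead geometries")
  v1 <- field_at(sol_coarse, probe_pts)
  v2 <- field_at(sol_fine, probe_pts)
  ref <- pmax(abs(v2), max(abs(v2)) * 1e-6)
  rel <- abs(v2 - v1) / ref
  list(max_rel = max(rel), rms_rel = sqrt(mean(rel^2)), n = length(rel))
}
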