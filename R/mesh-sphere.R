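# Lead-free spherical control mesh for the analytic point-source oracle:
# a point current source at the center of a fully grounded sphere has the
# closed-form potential V(r) = I/(4 pi sigma) (1/r - 1/R). The default
# radius is much larger than the probe range so V is also within a fraction
# of a percent of the infinite-medium I/(4 pi sigma r) there.
#
# Construction: an octahedron-based geodesic triangulation of the unit
# sphere, replicated on geometrically graded radial shells; the innermost
# shell is joined to the center vertex by a tetrahedral fan, consecutive
# shells by prisms split with the same global-index rule as the lead mesh.

octa_sphere <- function(n_sub) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(n_sub)) {
    nv <- nrow(v)
    ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    key <- (ed[, 1] - 1) * nv + ed[, 2]
    uk <- unique(key)
    mid_id <- match(key, uk) + nv
    uidx <- match(uk, key)
    mids <- (v[ed[uidx, 1], , drop = FALSE] + v[ed[uidx, 2], , drop = FALSE])
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m13 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m13),
               cbind(m12, f[, 2], m23),
               cbind(m13, m23, f[, 3]),
               cbind(m12, m23, m13))
  }
  list(v = v, f = f)
}

#' Spherical control mesh with a central point source location
#'
#' @param radius Outer (grounded) radius in mm. The default is large so the
#'   bounded-domain solution matches the infinite-medium formula to within
#'   a fraction of a percent over the probe range of a few tens of mm.
#' @param n_sub Octahedron subdivision level of the angular triangulation.
#' @param r_inner Radius of the first shell around the center vertex (mm).
#' @param growth Radial shell growth ratio in the near field.
#' @param r_switch Radius beyond which shells grow by `growth_far`.
#' @param growth_far Far-field shell growth ratio.
#' @return A `vc_mesh` (kind `"sphere"`), all-brain region, grounded on the
#'   outer shell.
#' @export
sphere_mesh <- function(radius = 4000, n_sub = 4, r_inner = 0.5,
                        growth = 1.12, r_switch = 60, growth_far = 1.25) {
  stopifnot(radius > r_switch, r_switch > r_inner, r_inner > 0)
  surf <- octa_sphere(n_sub)
  ns <- nrow(surf$v)
  shells <- c(r_inner,
              geom_breaks(r_inner, r_switch, r_inner * (growth - 1), growth),
              geom_breaks(r_switch, radius, r_switch * (growth_far - 1),
                          growth_far))
  shells <- sort(unique(shells))
  nsh <- length(shells)
  vertices <- rbind(c(0, 0, 0),
                    surf$v[rep(seq_len(ns), nsh), , drop = FALSE] *
                      rep(shells, each = ns))
  vid <- function(v, k) 1L + (k - 1L) * ns + v
  ntri <- nrow(surf$f)
  tsort <- sort3_rows(surf$f)
  m <- ntri + ntri * (nsh - 1L) * 3L
  tets <- matrix(0L, m, 4L)
  tet_tri <- integer(m); tet_shell <- integer(m)
  tets[seq_len(ntri), ] <- cbind(1L, vid(tsort[, 1], 1L),
                                 vid(tsort[, 2], 1L), vid(tsort[, 3], 1L))
  tet_tri[seq_len(ntri)] <- seq_len(ntri)
  tet_shell[seq_len(ntri)] <- 1L
  row0 <- ntri
  for (k in seq_len(nsh - 1L)) {
    b1 <- vid(tsort[, 1], k);  b2 <- vid(tsort[, 2], k)
    b3 <- vid(tsort[, 3], k)
    t1 <- vid(tsort[, 1], k + 1L); t2 <- vid(tsort[, 2], k + 1L)
    t3 <- vid(tsort[, 3], k + 1L)
    rows <- row0 + seq_len(3L * ntri)
    tets[rows, ] <- rbind(cbind(b1, b2, b3, t3),
                          cbind(b1, b2, t3, t2),
                          cbind(b1, t2, t3, t1))
    tet_tri[rows] <- rep.int(seq_len(ntri), 3L)
    tet_shell[rows] <- k + 1L
    row0 <- row0 + 3L * ntri
  }
  mesh <- list(kind = "sphere",
               vertices = vertices, tets = tets,
               region = rep(REG_BRAIN, m),
               shells = shells, surf = surf, ns = ns,
               tet_tri = tet_tri, tet_shell = tet_shell,
               center_vertex = 1L)
  mesh$geom <- tet_geometry(vertices, tets)
  cell <- (tet_shell - 1L) * ntri + tet_tri
  mesh$n_cells <- nsh * ntri
  mesh$cell_index <- build_cell_index(cell, mesh$n_cells)
  # spherical-triangle edge planes for the angular locator
  va <- surf$v[surf$f[, 1], , drop = FALSE]
  vb <- surf$v[surf$f[, 2], , drop = FALSE]
  vc_ <- surf$v[surf$f[, 3], , drop = FALSE]
  n1 <- vcross(va, vb); n1 <- n1 * sign(rowSums(n1 * vc_))
  n2 <- vcross(vb, vc_); n2 <- n2 * sign(rowSums(n2 * va))
  n3 <- vcross(vc_, va); n3 <- n3 * sign(rowSums(n3 * vb))
  mesh$edge_planes <- list(n1, n2, n3)
  mesh$ground_nodes <- 1L + (nsh - 1L) * ns + seq_len(ns)
  mesh$surfaces <- NULL
  class(mesh) <- "vc_mesh"
  mesh
}

locator_cells_sphere <- function(mesh, pts, widen = FALSE) {
  ntri <- nrow(mesh$surf$f)
  nsh <- length(mesh$shells)
  r <- sqrt(rowSums(pts^2))
  shell <- findInterval(r, c(0, mesh$shells), rightmost.closed = TRUE)
  shell[r > mesh$shells[nsh] + 1e-9] <- NA_integer_
  out <- vector("list", nrow(pts))
  ep <- mesh$edge_planes
  for (i in seq_len(nrow(pts))) {
    if (is.na(shell[i])) { out[[i]] <- integer(0); next }
    if (r[i] < 1e-12) {
      tris <- seq_len(ntri)
    } else {
      d <- pts[i, ] / r[i]
      tol <- if (widen) 1e-6 else 1e-9
      ok <- (ep[[1]] %*% d) >= -tol & (ep[[2]] %*% d) >= -tol &
        (ep[[3]] %*% d) >= -tol
      tris <- which(ok[, 1])
    }
    sh <- shell[i]
    if (widen) sh <- unique(pmax(1L, pmin(nsh, sh + (-1:1))))
    cells <- as.vector(outer(tris, (sh - 1L) * ntri, `+`))
    out[[i]] <- unlist(cell_tets(mesh$cell_index, cells), use.names = FALSE)
  }
  out
}

#' Analytic potential of a point current source in a homogeneous medium
#'
#' Infinite-medium potential `V(r) = I / (4 pi sigma r)`, optionally with
#' the grounded-sphere correction `- I / (4 pi sigma R)`.
#'
#' @param I Source current in mA (cathodic negative).
#' @param sigma Conductivity in S/m.
#' @param center Source location (mm).
#' @param ground_radius Optional grounded-sphere radius (mm); if given the
#'   bounded-domain closed form is used.
#' @return An object of class `analytic_field`: call it on an n x 3 matrix
#'   of points (mm) to get potentials in volts.
#' @export
point_source_field <- function(I = -1, sigma = 0.2, center = c(0, 0, 0),
                               ground_radius = NULL) {
  force(I); force(sigma); force(center); force(ground_radius)
  f <- function(pts) {
    pts <- as_points(pts)
    d <- sweep(pts, 2L, center)
    r_m <- sqrt(rowSums(d * d)) * 1e-3
    v <- (I * 1e-3) / (4 * pi * sigma * r_m)
    if (!is.null(ground_radius))
      v <- v - (I * 1e-3) / (4 * pi * sigma * (ground_radius * 1e-3))
    v
  }
  structure(f, class = c("analytic_field", "function"),
            I = I, sigma = sigma, center = center)
}

#' Solve the point-source control problem on a sphere mesh
#'
#' Dirac current load at the central vertex of a [sphere_mesh()], grounded
#' outer shell, homogeneous conductivity. The exact solution is
#' `V(r) = I/(4 pi sigma) (1/r - 1/R)`.
#'
#' @param mesh A `vc_mesh` of kind `"sphere"`.
#' @param current Source current in mA (cathodic negative).
#' @param sigma Conductivity in S/m.
#' @return An object of class `sphere_solution` with vertex potentials `V`
#'   (volts); works with [field_at()] and [attach_field()].
#' @export
solve_sphere_point_source <- function(mesh, current = -1, sigma = 0.2) {
  stopifnot(inherits(mesh, "vc_mesh"), mesh$kind == "sphere")
  n <- nrow(mesh$vertices)
  K <- assemble_stiffness(mesh, seq_len(nrow(mesh$tets)),
                          rep(sigma, nrow(mesh$tets)))
  f <- numeric(n)
  f[mesh$center_vertex] <- current * 1e-3
  s <- solve_tied(K, f, n, list(),
                  list(nodes = mesh$ground_nodes,
                       values = rep(0, length(mesh$ground_nodes))))
  structure(list(V = s$V, mesh = mesh, current = current, sigma = sigma,
                 rel_residual = s$rel_res),
            class = "sphere_solution")
}

#' @export
print.sphere_solution <- function(x, ...) {
  cat(sprintf("sphere_solution: point source %g mA, sigma %g S/m, R %g mm\n",
              x$current, x$sigma, max(x$mesh$shells)))
  invisible(x)
}
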