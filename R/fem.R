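# P1 finite-element solver for Laplace's equation div(sigma grad V) = 0 on
# the labeled tetrahedral mesh, with the five current-source implementations
# and the explicit/boundary contact representations of the model matrix.
#
# Internally SI units (m, S, A, V); mesh coordinates are mm, hence the 1e-3
# factor in the stiffness (grad in 1/mm squared times volume in mm^3).

assemble_stiffness <- function(mesh, tet_idx, sigma_tet) {
  G <- mesh$geom$G[tet_idx, , drop = FALSE]
  vol <- mesh$geom$vol[tet_idx]
  TT <- mesh$tets[tet_idx, , drop = FALSE]
  n <- nrow(mesh$vertices)
  scal <- sigma_tet * vol * 1e-3
  ilist <- vector("list", 16L); jlist <- ilist; xlist <- ilist
  p <- 0L
  for (i in 1:4) {
    gi <- G[, (i - 1L) * 3L + 1:3, drop = FALSE]
    for (j in 1:4) {
      gj <- G[, (j - 1L) * 3L + 1:3, drop = FALSE]
      p <- p + 1L
      ilist[[p]] <- TT[, i]; jlist[[p]] <- TT[, j]
      xlist[[p]] <- scal * rowSums(gi * gj)
    }
  }
  Matrix::sparseMatrix(i = unlist(ilist), j = unlist(jlist),
                       x = unlist(xlist), dims = c(n, n))
}

#' Assemble a volume-conductor model for one variant
#'
#' Selects the cell subset of the parent mesh that the variant's
#' explicit/boundary choices imply, assigns conductivities, and assembles
#' the stiffness operators. Boundary-represented components are excluded
#' from the finite-element domain, leaving their tissue interfaces as
#' boundary surfaces; inactive contacts in boundary representation become
#' floating equipotential conductors (all surface nodes tied to one
#' unknown with zero net current), while explicit inactive contacts rely on
#' the platinum conductivity.
#'
#' @param mesh Parent `vc_mesh` from [build_lead_mesh()].
#' @param variant A [variant_spec()].
#' @param sigma A [conductivity_map()].
#' @return An object of class `vc_model`.
#' @export
vc_model <- function(mesh, variant, sigma = conductivity_map()) {
  stopifnot(inherits(mesh, "vc_mesh"), inherits(variant, "variant_spec"),
            inherits(sigma, "conductivity_map"))
  if (mesh$kind != "lead") stop("vc_model needs a lead mesh")
  if (!length(mesh$ground_nodes)) stop("mesh has no grounded patch")
  reg <- mesh$region
  sigma_tet <- numeric(length(reg))
  sigma_tet[reg == REG_BRAIN] <- sigma$brain
  sigma_tet[reg == REG_ENCAP] <- sigma$encapsulation
  sigma_tet[reg %in% c(REG_CORE, REG_SHAFT)] <- sigma$shaft
  sigma_tet[reg > REG_CONTACT0] <- sigma$contact
  ak <- variant$active_contact
  active <- reg %in% c(REG_BRAIN, REG_ENCAP)
  if (variant$shaft_rep == "explicit")
    active <- active | reg %in% c(REG_CORE, REG_SHAFT)
  for (k in 1:8) {
    rep_k <- if (k == ak) variant$active_contact_rep else
      variant$inactive_contacts_rep
    if (rep_k == "explicit") active <- active | reg == (REG_CONTACT0 + k)
  }
  ties <- list()
  if (variant$inactive_contacts_rep == "boundary") {
    for (k in setdiff(1:8, ak))
      ties[[paste0("contact_", k)]] <-
        sort(unique(as.vector(mesh$surfaces[[k]]$facets)))
  }
  if (variant$source_type == "floating_potential")
    ties[[paste0("contact_", ak)]] <-
      sort(unique(as.vector(mesh$surfaces[[ak]]$facets)))
  tidx <- which(active)
  K <- assemble_stiffness(mesh, tidx, sigma_tet[tidx])
  tis <- which(reg %in% c(REG_BRAIN, REG_ENCAP))
  K_t <- assemble_stiffness(mesh, tis, sigma_tet[tis])
  out <- list(mesh = mesh, variant = variant, sigma = sigma,
              sigma_tet = sigma_tet, active_tet = active,
              K = K, K_t = K_t, ties = ties,
              ground_nodes = mesh$ground_nodes)
  class(out) <- "vc_model"
  out
}

#' @export
print.vc_model <- function(x, ...) {
  print(x$variant)
  cat(sprintf("  %d active tets of %d; %d floating conductor constraints\n",
              sum(x$active_tet), length(x$active_tet), length(x$ties)))
  invisible(x)
}

# Reduced-system solve with node ties (DOF condensation) and Dirichlet data.
# ties: list of node index vectors merged into single DOFs.
# dirichlet: list(nodes=, values=).
solve_tied <- function(K, f, n, ties, dirichlet,
                       solver = c("pcg", "direct"),
                       tol = 1e-12, maxit = 20000L) {
  solver <- match.arg(solver)
  dof <- seq_len(n)
  for (s in ties) dof[s] <- min(s)
  umap <- match(dof, unique(dof))
  ndof <- max(umap)
  T <- Matrix::sparseMatrix(i = seq_len(n), j = umap, x = 1, dims = c(n, ndof))
  Kd <- Matrix::t(T) %*% K %*% T
  fd <- as.vector(Matrix::t(T) %*% f)
  vfix <- rep(NA_real_, ndof)
  # vertices without active elements (excluded lead interior) are inert
  dK <- Matrix::diag(Kd)
  vfix[dK == 0] <- 0
  if (length(dirichlet$nodes)) {
    dn <- umap[dirichlet$nodes]
    vfix[dn] <- dirichlet$values   # tied Dirichlet nodes must agree in value
  }
  fixed <- which(!is.na(vfix))
  free <- setdiff(seq_len(ndof), fixed)
  rhs <- fd[free]
  if (length(fixed))
    rhs <- rhs - as.vector(Kd[free, fixed, drop = FALSE] %*% vfix[fixed])
  Kff <- Kd[free, free, drop = FALSE]
  vd <- numeric(ndof)
  vd[fixed] <- vfix[fixed]
  if (solver == "pcg") {
    Kg <- methods::as(methods::as(Kff, "CsparseMatrix"), "generalMatrix")
    pc <- sparse_pcg(Kg@p, Kg@i, Kg@x, rhs, tol, as.integer(maxit))
    if (!pc$converged)
      stop(sprintf("linear solver did not converge: relative residual %.3g after %d iterations",
                   pc$rel_res, pc$iters))
    vd[free] <- pc$x
  } else {
    vd[free] <- as.vector(Matrix::solve(Matrix::forceSymmetric(Kff), rhs))
  }
  res <- as.vector(Kd[free, , drop = FALSE] %*% vd) - fd[free]
  scale <- max(sqrt(sum(fd^2)), sqrt(sum(as.vector(Kd %*% vd)^2)))
  rel_res <- sqrt(sum(res^2)) / max(scale, 1e-300)
  list(V = as.vector(T %*% vd), vd = vd, umap = umap, rel_res = rel_res)
}

surface_load <- function(mesh, contact, I_A) {
  s <- mesh$surfaces[[contact]]
  n <- nrow(mesh$vertices)
  A_tot <- sum(s$area)
  f <- numeric(n)
  w <- I_A * s$area / A_tot / 3
  for (j in 1:3) {
    agg <- rowsum(w, s$facets[, j])
    f[as.integer(rownames(agg))] <- f[as.integer(rownames(agg))] + agg[, 1]
  }
  f
}

point_source_vertex <- function(mesh, contact) {
  k <- contact_id(contact)
  lead <- mesh$lead
  lay <- contact_layout(lead)
  zc <- (lay$z0[k] + lay$z1[k]) / 2
  azr <- if (is.na(lay$azimuth[k])) 0 else lay$azimuth[k] * pi / 180
  rmid <- lead$lead_radius - lead$contact_thickness / 2
  target <- c(rmid * cos(azr), rmid * sin(azr), zc)
  cand <- sort(unique(as.vector(
    mesh$tets[mesh$region == REG_CONTACT0 + k, , drop = FALSE])))
  d2 <- rowSums(sweep(mesh$vertices[cand, , drop = FALSE], 2L, target)^2)
  v <- cand[which.min(d2)]          # which.min is the lowest-index tie-break
  list(vertex = v, offset = sqrt(min(d2)), target = target)
}

#' Solve the volume-conductor model
#'
#' Applies the variant's current source, the grounded patch, and the
#' floating-conductor constraints, and solves the Laplace system. The
#' electric-potential source performs its two-solve procedure: a Dirichlet
#' seed solve whose delivered current is measured, then a solve with the
#' seed rescaled by commanded/measured current.
#'
#' @param model A [vc_model()].
#' @param current Commanded stimulus current in mA (cathodic negative;
#'   default -1 mA).
#' @param seed_voltage Dirichlet seed (V) for the electric-potential source.
#' @return An object of class `field_solution` with node potentials (V),
#'   per-contact integrated currents (mA), floating-conductor values, and
#'   source diagnostics.
#' @export
solve_vc <- function(model, current = -1, seed_voltage = 1) {
  stopifnot(inherits(model, "vc_model"))
  if (current == 0) stop("commanded current must be nonzero")
  mesh <- model$mesh
  n <- nrow(mesh$vertices)
  I_A <- current * 1e-3
  v <- model$variant
  ak <- v$active_contact
  src <- list(type = v$source_type)
  t0 <- proc.time()[["elapsed"]]
  dirichlet <- list(nodes = model$ground_nodes,
                    values = rep(0, length(model$ground_nodes)))
  f <- numeric(n)
  if (v$source_type == "point_current") {
    if (v$active_contact_rep != "explicit")
      stop("point current source requires an explicit active contact domain")
    ps <- point_source_vertex(mesh, ak)
    f[ps$vertex] <- I_A
    src$vertex <- ps$vertex; src$snap_offset <- ps$offset
  } else if (v$source_type %in% c("boundary_current", "current_density")) {
    if (v$source_type == "boundary_current" &&
        v$active_contact_rep != "explicit")
      stop("boundary current source requires an explicit active contact")
    if (v$source_type == "current_density" &&
        v$active_contact_rep != "boundary")
      stop("current density source applies only to exterior boundaries")
    A_tot <- sum(mesh$surfaces[[ak]]$area)
    if (A_tot <= 0) stop("active contact surface has zero area")
    f <- surface_load(mesh, ak, I_A)
    src$area_mm2 <- A_tot
    src$imposed_density <- current / A_tot      # mA / mm^2
  } else if (v$source_type == "floating_potential") {
    rep_node <- min(model$ties[[paste0("contact_", ak)]])
    f[rep_node] <- I_A
  } else if (v$source_type == "electric_potential") {
    snodes <- sort(unique(as.vector(mesh$surfaces[[ak]]$facets)))
    d1 <- list(nodes = c(dirichlet$nodes, snodes),
               values = c(dirichlet$values, rep(seed_voltage, length(snodes))))
    s1 <- solve_tied(model$K, f, n, model$ties, d1)
    I1 <- contact_flux(model, s1$V, ak)
    if (abs(I1) < 1e-12)
      stop("degenerate geometry: seed solve delivers no current")
    u2 <- seed_voltage * current / I1
    d2 <- list(nodes = d1$nodes,
               values = c(dirichlet$values, rep(u2, length(snodes))))
    s2 <- solve_tied(model$K, f, n, model$ties, d2)
    src$seed_voltage <- seed_voltage; src$I1_mA <- I1
    src$scaled_voltage <- u2
    src$V_seed <- s1$V
    out <- finish_solution(model, s2, current, src,
                           t0 = t0)
    return(out)
  } else stop("unknown source type")
  s <- solve_tied(model$K, f, n, model$ties, dirichlet)
  finish_solution(model, s, current, src, t0 = t0)
}

# tissue-side consistent (reaction) flux through contact k, in mA; positive
# current leaves the contact into tissue
contact_flux <- function(model, V, k, KtV = NULL) {
  if (is.null(KtV)) KtV <- as.vector(model$K_t %*% V)
  nodes <- unique(as.vector(model$mesh$surfaces[[k]]$facets))
  sum(KtV[nodes]) * 1e3
}

finish_solution <- function(model, s, current, src, t0) {
  mesh <- model$mesh
  KtV <- as.vector(model$K_t %*% s$V)
  cc <- vapply(1:8, function(k) contact_flux(model, s$V, k, KtV), numeric(1))
  names(cc) <- contact_layout(mesh$lead)$label
  ground <- sum(KtV[model$ground_nodes]) * 1e3
  fl <- vapply(model$ties, function(nds) s$V[min(nds)], numeric(1))
  out <- list(V = s$V, model = model, current = current,
              source = src, contact_currents = cc,
              ground_current = ground,
              floating_values = fl,
              rel_residual = s$rel_res,
              solve_seconds = proc.time()[["elapsed"]] - t0)
  class(out) <- "field_solution"
  out
}

#' @export
print.field_solution <- function(x, ...) {
  v <- x$model$variant
  cat(sprintf("field_solution: variant #%d (%s), %g mA on contact %d\n",
              v$model_id, v$source_type, x$current, v$active_contact))
  cat(sprintf("  active contact current %.6g mA; ground %.6g mA\n",
              x$contact_currents[v$active_contact], x$ground_current))
  inact <- x$contact_currents[-v$active_contact]
  cat(sprintf("  max |inactive contact current| %.3g mA\n", max(abs(inact))))
  if (length(x$floating_values))
    cat(sprintf("  floating values [V]: %s\n",
                paste(sprintf("%.4g", x$floating_values), collapse = ", ")))
  cat(sprintf("  relative residual %.2e (%.2f s)\n", x$rel_residual,
              x$solve_seconds))
  invisible(x)
}

#' Interpolate a field solution at points
#'
#' @param sol A `field_solution`.
#' @param pts n x 3 matrix of tissue points (mm).
#' @return Potentials in volts.
#' @export
field_at <- function(sol, pts) {
  stopifnot(inherits(sol, c("field_solution", "sphere_solution")))
  mesh <- if (!is.null(sol$model)) sol$model$mesh else sol$mesh
  W <- interpolation_matrix(mesh, pts)
  as.vector(W %*% sol$V)
}

per_tet_gradient <- function(mesh, V, tet_idx) {
  # grad V in V/mm for the given tets (n_idx x 3)
  G <- mesh$geom$G[tet_idx, , drop = FALSE]
  TT <- mesh$tets[tet_idx, , drop = FALSE]
  gx <- gy <- gz <- numeric(length(tet_idx))
  for (i in 1:4) {
    vi <- V[TT[, i]]
    gx <- gx + vi * G[, (i - 1L) * 3L + 1L]
    gy <- gy + vi * G[, (i - 1L) * 3L + 2L]
    gz <- gz + vi * G[, (i - 1L) * 3L + 3L]
  }
  cbind(gx, gy, gz)
}

#' Integrated current through a contact surface
#'
#' Integrates the normal component of the current density over the contact
#' surface. The default `"consistent"` method assembles the discrete
#' reaction flux over tissue-side elements -- the flux-difference form (for
#' an interior boundary this is the jump seen from the tissue, never the
#' two-sided average). `"quadrature"` evaluates the tissue-side element
#' gradient on each facet directly and is kept as a diagnostic; it carries
#' the usual O(h) consistency error at edge singularities. For the point
#' current source the contact-tissue interface is the only conducting exit
#' of the contact domain (all other faces border the insulating shaft or
#' the excluded lead interior), so the open surface is equivalent to a
#' closed surface around the contact domain up to the insulator leak.
#'
#' @param sol A `field_solution`.
#' @param contact Contact id or label.
#' @param method `"consistent"` (default) or `"quadrature"`.
#' @return An object of class `contact_current`: current in mA, positive
#'   when leaving the contact into the tissue.
#' @export
integrate_contact_current <- function(sol, contact,
                                      method = c("consistent", "quadrature")) {
  stopifnot(inherits(sol, "field_solution"))
  method <- match.arg(method)
  k <- contact_id(contact)
  s <- sol$model$mesh$surfaces[[k]]
  if (method == "consistent") {
    I <- contact_flux(sol$model, sol$V, k)
  } else {
    gr <- per_tet_gradient(sol$model$mesh, sol$V, s$tet_b)   # V/mm
    sig <- sol$model$sigma_tet[s$tet_b]
    jn <- -sig * rowSums(gr * s$normal) * 1e3                # A/m^2, into tissue
    I <- sum(jn * s$area * 1e-6) * 1e3                       # mA
  }
  structure(list(contact = k, current_mA = I, method = method,
                 n_facets = nrow(s$facets), area_mm2 = sum(s$area)),
            class = "contact_current")
}

#' @export
print.contact_current <- function(x, ...) {
  cat(sprintf("contact %d: %.6g mA (%s; %d facets, %.3g mm^2)\n",
              x$contact, x$current_mA, x$method, x$n_facets, x$area_mm2))
  invisible(x)
}

#' Per-facet current density on a contact surface
#'
#' Facet-wise current density on the active (or any) contact surface:
#' the tissue-side normal component, the tissue-side magnitude, and -- for
#' explicit contacts -- the contact-side magnitude, which near a point
#' current source carries the weld-point convergence current.
#'
#' @param sol A `field_solution`.
#' @param contact Contact id or label.
#' @return A data.frame with one row per facet: centroid coordinates, area
#'   (mm^2), `edge` flag (facet on the contact perimeter), distance to the
#'   contact center, `jn_tissue` and `jmag_tissue` (mA/mm^2), and
#'   `jmag_contact` (NA when the contact has no explicit domain in the
#'   solved variant).
#' @export
surface_current_density_map <- function(sol, contact) {
  stopifnot(inherits(sol, "field_solution"))
  k <- contact_id(contact)
  model <- sol$model
  s <- model$mesh$surfaces[[k]]
  gr_t <- per_tet_gradient(model$mesh, sol$V, s$tet_b)
  sig_t <- model$sigma_tet[s$tet_b]
  jn <- -sig_t * rowSums(gr_t * s$normal) * 1e3 * 1e-3      # mA/mm^2
  # for the pure Neumann (current density) source the normal trace on the
  # active surface is the imposed boundary value itself; the broken
  # element gradient is only an O(h) shadow of it
  if (model$variant$source_type == "current_density" &&
      k == model$variant$active_contact)
    jn <- rep(sol$source$imposed_density, length(jn))
  # tangential component from the in-plane gradient of the facet's own
  # nodal potentials (exact for the P1 trace; avoids normal smearing)
  mver <- model$mesh$vertices
  e1 <- mver[s$facets[, 2], , drop = FALSE] - mver[s$facets[, 1], , drop = FALSE]
  e2 <- mver[s$facets[, 3], , drop = FALSE] - mver[s$facets[, 1], , drop = FALSE]
  dv1 <- sol$V[s$facets[, 2]] - sol$V[s$facets[, 1]]
  dv2 <- sol$V[s$facets[, 3]] - sol$V[s$facets[, 1]]
  g11 <- rowSums(e1 * e1); g12 <- rowSums(e1 * e2); g22 <- rowSums(e2 * e2)
  det <- g11 * g22 - g12^2
  a1 <- (g22 * dv1 - g12 * dv2) / det
  a2 <- (g11 * dv2 - g12 * dv1) / det
  gt2 <- a1^2 * g11 + 2 * a1 * a2 * g12 + a2^2 * g22       # |grad_t V|^2, (V/mm)^2
  jt <- sig_t * sqrt(pmax(gt2, 0)) * 1e3 * 1e-3
  jmag_t <- sqrt(jn^2 + jt^2)
  jmag_c <- rep(NA_real_, nrow(s$facets))
  if (all(model$active_tet[s$tet_a])) {
    gr_c <- per_tet_gradient(model$mesh, sol$V, s$tet_a)
    jmag_c <- model$sigma_tet[s$tet_a] * sqrt(rowSums(gr_c^2)) * 1e3 * 1e-3
  }
  out <- data.frame(x = s$centroid[, 1], y = s$centroid[, 2],
                    z = s$centroid[, 3], area = s$area, edge = s$edge,
                    dist_center = s$dist_center,
                    jn_tissue = jn, jmag_tissue = jmag_t,
                    jmag_contact = jmag_c)
  attr(out, "contact") <- k
  attr(out, "imposed_density") <- sol$source$imposed_density
  class(out) <- c("contact_density_map", "data.frame")
  out
}

#' Edge-vs-center current density ratio of a contact map
#'
#' Mean tissue-side current density magnitude over perimeter (edge/corner)
#' facets divided by the mean over interior (center) facets. Values above 1
#' reproduce the edge enhancement of distributed sources.
#'
#' @param map Result of [surface_current_density_map()].
#' @return A single ratio.
#' @export
edge_center_ratio <- function(map) {
  stopifnot(inherits(map, "contact_density_map"))
  inner <- !map$edge
  if (!any(inner)) inner <- rank(map$dist_center) <= 3
  mean(map$jmag_tissue[map$edge]) / mean(map$jmag_tissue[inner])
}

#' Center-peak ratio of a contact current density map
#'
#' For the point current source: ratio of the contact-side current density
#' magnitude on the facets nearest the contact center (over the weld point)
#' to the median over the remaining interior facets. Uses the contact-side
#' magnitude because the convergence current toward the source lives inside
#' the conductor; an ideal conductor's tissue-side density has no center
#' structure.
#'
#' @param map Result of [surface_current_density_map()].
#' @param n_center Number of central facets forming the peak region.
#' @return A single ratio (NA when the variant has no explicit contact).
#' @export
center_peak_ratio <- function(map, n_center = 4) {
  stopifnot(inherits(map, "contact_density_map"))
  if (all(is.na(map$jmag_contact))) return(NA_real_)
  ctr <- rank(map$dist_center, ties.method = "first") <= n_center
  rest <- !ctr & !map$edge
  if (!any(rest)) rest <- !ctr
  mean(map$jmag_contact[ctr]) / stats::median(map$jmag_contact[rest])
}
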