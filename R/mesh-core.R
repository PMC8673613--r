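# Shared tetrahedral-mesh internals: element geometry, face adjacency,
# point location and P1 interpolation. Units: coordinates in mm.

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Per-tet P1 geometry: signed volume, basis gradients (1/mm) and the affine
# offsets lam0 such that lambda_i(x) = lam0[,i] + G[,i] . x
tet_geometry <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE]
  c3 <- vertices[tets[, 3], , drop = FALSE]
  d <- vertices[tets[, 4], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a; e3 <- d - a
  cr23 <- vcross(e2, e3)
  det <- rowSums(e1 * cr23)            # 6 * signed volume
  if (any(abs(det) < 1e-12))
    stop("degenerate tetrahedra in mesh (zero volume)")
  g2 <- cr23 / det
  g3 <- vcross(e3, e1) / det
  g4 <- vcross(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  G <- cbind(g1, g2, g3, g4)           # m x 12: (gx,gy,gz) per basis
  lam0 <- cbind(1 - rowSums(g1 * a), -rowSums(g2 * a),
                -rowSums(g3 * a), -rowSums(g4 * a))
  list(vol = abs(det) / 6,
       G = G,
       lam0 = lam0,
       centroid = (a + b + c3 + d) / 4)
}

sort3_rows <- function(f) {
  lo <- pmin(f[, 1], f[, 2]); hi <- pmax(f[, 1], f[, 2])
  s1 <- pmin(lo, f[, 3]); s3 <- pmax(hi, f[, 3])
  cbind(s1, f[, 1] + f[, 2] + f[, 3] - s1 - s3, s3)
}

# Encode sorted vertex triples as a single double (exact below 2^53)
face_key <- function(f, nv) {
  f <- sort3_rows(f)
  (f[, 1] - 1) * nv * nv + (f[, 2] - 1) * nv + f[, 3]
}

# All 4 faces of every tet; returns face vertex matrix, owning tet, local face
tet_faces <- function(tets) {
  m <- nrow(tets)
  loc <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  faces <- matrix(0L, 4L * m, 3L)
  for (k in 1:4)
    faces[seq.int(k, by = 4L, length.out = m), ] <- tets[, loc[k, ]]
  list(faces = faces, tet = rep(seq_len(m), each = 4L))
}

# Interior faces between two element-region groups; returns per-facet vertex
# ids, the adjacent tet on each side, area (mm^2) and the unit normal
# pointing from side_a into side_b.
region_interface <- function(mesh, region_a, region_b) {
  tf <- tet_faces(mesh$tets)
  keys <- face_key(tf$faces, nrow(mesh$vertices))
  o <- order(keys)
  k <- keys[o]
  dup <- which(k[-1] == k[-length(k)])
  t1 <- tf$tet[o][dup]; t2 <- tf$tet[o][dup + 1L]
  r1 <- mesh$region[t1]; r2 <- mesh$region[t2]
  sel_ab <- r1 %in% region_a & r2 %in% region_b
  sel_ba <- r1 %in% region_b & r2 %in% region_a
  ta <- c(t1[sel_ab], t2[sel_ba])
  tb <- c(t2[sel_ab], t1[sel_ba])
  fidx <- o[dup][sel_ab | sel_ba]      # index into tf rows (a or b side)
  fv <- tf$faces[c(o[dup][sel_ab], (o[dup + 1L])[sel_ba]), , drop = FALSE]
  if (nrow(fv) == 0L)
    return(NULL)
  v1 <- mesh$vertices[fv[, 1], , drop = FALSE]
  v2 <- mesh$vertices[fv[, 2], , drop = FALSE]
  v3 <- mesh$vertices[fv[, 3], , drop = FALSE]
  cr <- vcross(v2 - v1, v3 - v1)
  area <- sqrt(rowSums(cr * cr)) / 2
  n <- cr / (2 * area)
  fc <- (v1 + v2 + v3) / 3
  # orient from side a (contact) into side b (tissue)
  flip <- rowSums(n * (mesh$geom$centroid[tb, , drop = FALSE] - fc)) < 0
  n[flip, ] <- -n[flip, ]
  list(facets = fv, tet_a = ta, tet_b = tb, area = area,
       normal = n, centroid = fc)
}

# Mark facets on the boundary of a surface patch (facets owning an edge that
# appears only once within the patch).
facet_on_patch_edge <- function(facets) {
  ed <- rbind(facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(1, 3)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  key <- (ed[, 1] - 1) * (max(ed) + 1) + ed[, 2]
  cnt <- table(key)
  single <- as.numeric(names(cnt))[cnt == 1L]
  onb <- matrix(key %in% single, ncol = 3L)
  rowSums(onb) > 0L
}

# Candidate tets per locator cell, CSR layout over an integer cell id per tet
build_cell_index <- function(cell_id, n_cells) {
  o <- order(cell_id)
  counts <- tabulate(cell_id, nbins = n_cells)
  list(order = o, offsets = c(0L, cumsum(counts)))
}

cell_tets <- function(index, cells) {
  # returns list mapping each requested cell to tet ids
  lapply(cells, function(cid) {
    if (cid < 1L || cid > length(index$offsets) - 1L) return(integer(0))
    a <- index$offsets[cid] + 1L
    b <- index$offsets[cid + 1L]
    if (b < a) integer(0) else index$order[a:b]
  })
}

# Evaluate barycentric coordinates of points in candidate tets (vectorized
# over point/tet pairs); returns the containing tet and weights.
match_tets <- function(mesh, pts, cand, tol = 1e-7) {
  npt <- nrow(pts)
  reps <- lengths(cand)
  pi_ <- rep.int(seq_len(npt), reps)
  ti <- unlist(cand, use.names = FALSE)
  if (length(ti) == 0L)
    return(list(tet = rep(NA_integer_, npt), bary = matrix(NA_real_, npt, 4)))
  G <- mesh$geom$G; lam0 <- mesh$geom$lam0
  x <- pts[pi_, 1]; y <- pts[pi_, 2]; z <- pts[pi_, 3]
  lam <- matrix(0, length(ti), 4L)
  for (i in 1:4) {
    cidx <- (i - 1L) * 3L
    lam[, i] <- lam0[ti, i] + G[ti, cidx + 1L] * x +
      G[ti, cidx + 2L] * y + G[ti, cidx + 3L] * z
  }
  ok <- lam[, 1] >= -tol & lam[, 2] >= -tol & lam[, 3] >= -tol &
    lam[, 4] >= -tol
  tet <- rep(NA_integer_, npt)
  bary <- matrix(NA_real_, npt, 4L)
  hit <- which(ok)
  if (length(hit)) {
    first <- hit[!duplicated(pi_[hit])]
    tet[pi_[first]] <- ti[first]
    bary[pi_[first], ] <- lam[first, , drop = FALSE]
  }
  list(tet = tet, bary = bary)
}

#' Locate points in a volume-conductor mesh
#'
#' Finds for each query point the containing tetrahedron and its barycentric
#' weights, using the structured-grid accelerator of the mesh.
#'
#' @param mesh A `vc_mesh`.
#' @param pts Numeric matrix (n x 3) of coordinates in mm.
#' @return List with integer vector `tet` (NA when outside the mesh) and an
#'   n x 4 matrix `bary` of weights.
#' @export
locate_points <- function(mesh, pts) {
  pts <- as_points(pts)
  cand <- locator_cells(mesh, pts)
  res <- match_tets(mesh, pts, cand)
  miss <- which(is.na(res$tet))
  if (length(miss)) {        # retry with neighborhood cells (roundoff at faces)
    cand2 <- locator_cells(mesh, pts[miss, , drop = FALSE], widen = TRUE)
    res2 <- match_tets(mesh, pts[miss, , drop = FALSE], cand2, tol = 1e-6)
    res$tet[miss] <- res2$tet
    res$bary[miss, ] <- res2$bary
  }
  res
}

as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(pts) <- "double"
  pts
}

# dispatch on mesh kind
locator_cells <- function(mesh, pts, widen = FALSE) {
  switch(mesh$kind,
         lead = locator_cells_lead(mesh, pts, widen),
         sphere = locator_cells_sphere(mesh, pts, widen),
         stop("unknown mesh kind"))
}

#' P1 interpolation operator for fixed probe points
#'
#' Builds the sparse matrix `W` such that `W %*% V` interpolates vertex
#' values `V` at the probe points. Probe points must lie inside the mesh;
#' by default they must lie in tissue (brain or encapsulation), the region
#' where extracellular potentials are defined.
#'
#' @param mesh A `vc_mesh`.
#' @param pts n x 3 matrix of points (mm).
#' @param tissue_only Require all points inside tissue regions.
#' @return A `dgCMatrix` of dimension n x n_vertices.
#' @export
interpolation_matrix <- function(mesh, pts, tissue_only = TRUE) {
  pts <- as_points(pts)
  loc <- locate_points(mesh, pts)
  bad <- which(is.na(loc$tet))
  if (length(bad))
    stop("points outside the mesh: indices ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  if (tissue_only) {
    reg <- mesh$region[loc$tet]
    bad <- which(!(reg %in% c(REG_BRAIN, REG_ENCAP)))
    if (length(bad))
      stop("points inside the lead geometry (not in tissue): indices ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) " ..." else "")
  }
  n <- nrow(pts)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), 4L),
    j = as.vector(mesh$tets[loc$tet, ]),
    x = as.vector(loc$bary),
    dims = c(n, nrow(mesh$vertices)))
}

#' @export
print.vc_mesh <- function(x, ...) {
  cat(sprintf("vc_mesh (%s): %d vertices, %d tetrahedra\n",
              x$kind, nrow(x$vertices), nrow(x$tets)))
  tb <- table(region_name(x$region))
  cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
  if (!is.null(x$surfaces)) {
    ns <- vapply(x$surfaces, function(s) if (is.null(s)) 0L else nrow(s$facets),
                 integer(1))
    cat("  contact surface facets:", paste(ns, collapse = "/"), "\n")
  }
  cat(sprintf("  ground patch nodes: %d\n", length(x$ground_nodes)))
  invisible(x)
}

REG_BRAIN <- 1L
REG_ENCAP <- 2L
REG_CORE  <- 3L
REG_SHAFT <- 4L
REG_CONTACT0 <- 10L   # contact k has code 10 + k

region_name <- function(code) {
  nm <- character(length(code))
  nm[code == REG_BRAIN] <- "brain"
  nm[code == REG_ENCAP] <- "encapsulation"
  nm[code == REG_CORE] <- "core"
  nm[code == REG_SHAFT] <- "shaft"
  ct <- code > REG_CONTACT0
  nm[ct] <- paste0("contact_", code[ct] - REG_CONTACT0)
  nm
}
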