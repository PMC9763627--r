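#' Triangulated surface mesh with reference (resting) geometry
#'
#' Constructs a `tri_mesh` from vertex positions and a triangle index matrix.
#' Edge and dihedral connectivity is derived once; the geometry at
#' construction time is recorded as the stress-free reference state used by
#' the membrane force model (rest edge lengths, rest dihedral angles, rest
#' triangle areas, rest total area and volume).
#'
#' For a closed mesh every edge must be shared by exactly two consistently
#' oriented triangles (Euler characteristic 2); orientation is flipped
#' globally if the signed volume is negative so that normals point outward.
#' Open meshes (flat test patches) are allowed with `closed = FALSE`.
#'
#' @param vertices n x 3 numeric matrix of positions (m).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param closed logical; require (and verify) a closed oriented surface.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, triangles, closed = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  nv <- nrow(vertices)
  nt <- nrow(triangles)
  if (ncol(vertices) != 3L || ncol(triangles) != 3L)
    stop("vertices must be n x 3 and triangles m x 3")
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle indices out of range")

  # directed edge table
  de_from <- c(triangles[, 1], triangles[, 2], triangles[, 3])
  de_to <- c(triangles[, 2], triangles[, 3], triangles[, 1])
  de_tri <- rep.int(seq_len(nt), 3L)
  key <- paste(pmin(de_from, de_to), pmax(de_from, de_to))
  mult <- table(key)
  if (closed) {
    if (any(mult != 2L))
      stop("mesh is not closed: every edge must be shared by exactly 2 triangles")
    dir_key <- paste(de_from, de_to)
    if (anyDuplicated(dir_key))
      stop("mesh orientation is inconsistent (duplicated directed edge)")
  } else if (any(mult > 2L)) {
    stop("non-manifold edge detected")
  }

  first <- !duplicated(key)
  E <- cbind(pmin(de_from, de_to)[first], pmax(de_from, de_to)[first])

  # ensure outward orientation (positive enclosed volume) for closed meshes
  geom <- cpp_vertex_geometry(vertices, triangles)
  if (closed && geom$total_volume < 0) {
    triangles <- triangles[, c(1L, 3L, 2L), drop = FALSE]
    de_from <- c(triangles[, 1], triangles[, 2], triangles[, 3])
    de_to <- c(triangles[, 2], triangles[, 3], triangles[, 1])
    de_tri <- rep.int(seq_len(nt), 3L)
    geom <- cpp_vertex_geometry(vertices, triangles)
  }
  if (any(geom$tri_areas <= 0))
    stop("geometry error: degenerate triangle ",
         which(geom$tri_areas <= 0)[1])
  if (closed) {
    ne <- nrow(E)
    if (nv - ne + nt != 2L)
      stop("mesh is not genus-0: Euler characteristic is ", nv - ne + nt)
  }

  # dihedral quads (i, j, k, l): k completes triangle containing directed
  # edge i->j, l completes the triangle containing j->i
  third <- c(triangles[, 3], triangles[, 1], triangles[, 2])
  dirmap <- paste(de_from, de_to)
  idx_ij <- match(paste(E[, 1], E[, 2]), dirmap)
  idx_ji <- match(paste(E[, 2], E[, 1]), dirmap)
  interior <- !is.na(idx_ij) & !is.na(idx_ji)
  Q <- cbind(E[interior, 1], E[interior, 2],
             third[idx_ij[interior]], third[idx_ji[interior]])
  storage.mode(E) <- "integer"
  storage.mode(Q) <- "integer"

  rest_len <- sqrt(rowSums((vertices[E[, 2], , drop = FALSE] -
                            vertices[E[, 1], , drop = FALSE])^2))
  mesh <- structure(list(
    vertex_positions = vertices,
    triangles = triangles,
    edges = E,
    dihedral_quads = Q,
    n_vertices = nv,
    closed = closed,
    rest_edge_lengths = rest_len,
    rest_dihedral_angles = .dihedral_angles(vertices, Q),
    rest_tri_areas = geom$tri_areas,
    rest_total_area = geom$total_area,
    rest_total_volume = if (closed) geom$total_volume else 0
  ), class = "tri_mesh")
  mesh
}

# signed dihedral angles across interior edges, vectorised; 0 when flat
.dihedral_angles <- function(V, Q) {
  if (nrow(Q) == 0L) return(numeric(0))
  xi <- V[Q[, 1], , drop = FALSE]; xj <- V[Q[, 2], , drop = FALSE]
  xk <- V[Q[, 3], , drop = FALSE]; xl <- V[Q[, 4], , drop = FALSE]
  e <- xj - xi
  n1 <- .rowcross(e, xk - xi)
  n2 <- .rowcross(xi - xj, xl - xj)
  ln1 <- sqrt(rowSums(n1^2)); ln2 <- sqrt(rowSums(n2^2))
  le <- sqrt(rowSums(e^2))
  s <- rowSums(.rowcross(n1, n2) * e) / (ln1 * ln2 * le)
  cth <- rowSums(n1 * n2) / (ln1 * ln2)
  atan2(s, cth)
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "tri_mesh: %d vertices, %d triangles, %d edges (%s)\n",
    x$n_vertices, nrow(x$triangles), nrow(x$edges),
    if (x$closed) "closed" else "open"))
  cat(sprintf("  area %.4g um^2, volume %.4g um^3, mean spacing %.1f nm\n",
              x$rest_total_area * 1e12, x$rest_total_volume * 1e18,
              mean(x$rest_edge_lengths) * 1e9))
  invisible(x)
}

# ------------------------------------------------------------------ builders

# Mesh a surface of revolution given a meridian profile psi -> (r, z),
# psi in [0, pi]. Rings are placed at equal meridian arc length; each ring
# carries a point count proportional to its circumference, so triangles are
# near-equilateral. Deterministic zigzag triangulation between rings.
.revolution_mesh <- function(profile, n_vertices) {
  if (n_vertices < 12L)
    stop("configuration error: n_vertices must be at least 12")
  psi <- seq(0, pi, length.out = 4001L)
  rz <- profile(psi)
  seg <- sqrt(diff(rz[, 1])^2 + diff(rz[, 2])^2)
  s <- c(0, cumsum(seg))
  L <- s[length(s)]

  count_for <- function(delta) {
    K <- max(3L, round(L / delta))
    sj <- seq(0, L, length.out = K + 1L)
    rj <- approx(s, rz[, 1], xout = sj)$y
    m <- pmax(3L, round(2 * pi * rj[-c(1L, K + 1L)] / delta))
    2L + sum(m)
  }
  # bisection on the target spacing
  lo <- L / (4 * sqrt(n_vertices)); hi <- 4 * L / sqrt(n_vertices)
  for (it in 1:60) {
    mid <- 0.5 * (lo + hi)
    if (count_for(mid) > n_vertices) lo <- mid else hi <- mid
  }
  delta <- 0.5 * (lo + hi)

  K <- max(3L, round(L / delta))
  sj <- seq(0, L, length.out = K + 1L)
  rj <- approx(s, rz[, 1], xout = sj)$y
  zj <- approx(s, rz[, 2], xout = sj)$y
  m <- c(1L, pmax(3L, round(2 * pi * rj[-c(1L, K + 1L)] / delta)), 1L)

  verts <- matrix(0, sum(m), 3)
  ring_start <- cumsum(c(0L, m[-length(m)])) + 1L
  offs <- numeric(K + 1L)
  for (j in seq_len(K + 1L)) {
    if (m[j] == 1L) {
      verts[ring_start[j], ] <- c(0, 0, zj[j])
    } else {
      offs[j] <- 0.5 * (j %% 2L)
      phi <- 2 * pi * (seq_len(m[j]) - 1L + offs[j]) / m[j]
      idx <- ring_start[j] + seq_len(m[j]) - 1L
      verts[idx, ] <- cbind(rj[j] * cos(phi), rj[j] * sin(phi), zj[j])
    }
  }

  tris <- vector("list", K)
  # north fan
  r1 <- ring_start[2L] + seq_len(m[2L]) - 1L
  tris[[1L]] <- cbind(ring_start[1L], r1, c(r1[-1L], r1[1L]))
  # bands
  for (j in 2:(K - 1L)) {
    A <- ring_start[j] + seq_len(m[j]) - 1L
    B <- ring_start[j + 1L] + seq_len(m[j + 1L]) - 1L
    tris[[j]] <- .zigzag_band(A, B, offs[j], offs[j + 1L])
  }
  # south fan (reversed winding)
  rl <- ring_start[K] + seq_len(m[K]) - 1L
  tris[[K]] <- cbind(ring_start[K + 1L], c(rl[-1L], rl[1L]), rl)
  T <- do.call(rbind, tris)
  list(vertices = verts, triangles = T)
}

# deterministic zigzag triangulation between two rings of point counts
# length(A), length(B); advances the ring whose next vertex has the smaller
# azimuth (ties to A), producing a consistent orientation
.zigzag_band <- function(A, B, offA, offB) {
  ma <- length(A); mb <- length(B)
  out <- matrix(0L, ma + mb, 3L)
  ia <- 0L; ib <- 0L; r <- 0L
  while (ia < ma || ib < mb) {
    nextA <- 2 * pi * (ia + 1L + offA) / ma
    nextB <- 2 * pi * (ib + 1L + offB) / mb
    r <- r + 1L
    if (ib >= mb || (ia < ma && nextA <= nextB)) {
      out[r, ] <- c(A[ia %% ma + 1L], B[ib %% mb + 1L], A[(ia + 1L) %% ma + 1L])
      ia <- ia + 1L
    } else {
      out[r, ] <- c(A[ia %% ma + 1L], B[ib %% mb + 1L], B[(ib + 1L) %% mb + 1L])
      ib <- ib + 1L
    }
  }
  out[seq_len(r), , drop = FALSE]
}

#' Build a biconcave discocyte RBC mesh
#'
#' Generates a closed genus-0 triangulated mesh of the classic biconcave
#' surface of revolution (Evans-Fung form). With the default coefficients
#' and a 7.8 um diameter the surface has ~135 um^2 area and ~94 um^3 volume;
#' at ~5000 vertices the mean inter-vertex spacing is ~200 nm, matching the
#' fibrinogen-receptor-density-based spacing of the adhesion model.
#'
#' The thickness profile is `T(rho) = diameter * sqrt(1 - rho^2) *
#' (c0 + c2 rho^2 + c4 rho^4)` with `rho` the fractional cylindrical radius;
#' the surface is `z = +/- T/2`.
#'
#' @param n_vertices target vertex count (>= 12; achieved within ~5%).
#' @param cell_diameter cell diameter in m (default 7.8 um).
#' @param shape_coefs the (c0, c2, c4) thickness coefficients.
#' @return a [tri_mesh()].
#' @export
build_discocyte_mesh <- function(n_vertices = 5000,
                                 cell_diameter = 7.8e-6,
                                 shape_coefs = c(0.1036, 1.0013, -0.5614)) {
  if (n_vertices < 12L)
    stop("configuration error: n_vertices must be at least 12")
  R <- cell_diameter / 2
  c0 <- shape_coefs[1]; c2 <- shape_coefs[2]; c4 <- shape_coefs[3]
  profile <- function(psi) {
    rho <- sin(psi)
    thick <- cell_diameter * sqrt(pmax(0, 1 - rho^2)) *
      (c0 + c2 * rho^2 + c4 * rho^4)
    cbind(R * rho, sign(cos(psi)) * thick / 2)
  }
  g <- .revolution_mesh(profile, n_vertices)
  tri_mesh(g$vertices, g$triangles, closed = TRUE)
}

#' Build a triangulated sphere mesh
#'
#' Near-uniform ring-based triangulation of a sphere; used for convergence
#' checks against the analytic area 4 pi r^2 and for contact-query fixtures.
#'
#' @param n_vertices target vertex count.
#' @param radius sphere radius (m).
#' @return a [tri_mesh()].
#' @export
build_sphere_mesh <- function(n_vertices = 500, radius = 1e-6) {
  profile <- function(psi) cbind(radius * sin(psi), radius * cos(psi))
  g <- .revolution_mesh(profile, n_vertices)
  tri_mesh(g$vertices, g$triangles, closed = TRUE)
}

#' Build a flat triangulated patch
#'
#' Regular equilateral-row triangulation of a rectangle in the z = 0 plane
#' (open mesh). Used as a fixture with known analytic areas and as the
#' domain for transport-equation oracles.
#'
#' @param nx,ny number of vertices per row / number of rows.
#' @param spacing lattice spacing (m).
#' @return a [tri_mesh()] with `closed = FALSE`.
#' @export
build_flat_patch <- function(nx = 20, ny = 20, spacing = 1e-7) {
  ix <- rep(seq_len(nx) - 1L, ny)
  iy <- rep(seq_len(ny) - 1L, each = nx)
  V <- cbind((ix + 0.5 * (iy %% 2L)) * spacing,
             iy * spacing * sqrt(3) / 2, 0)
  id <- function(i, j) (j - 1L) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1L)) {
    i <- seq_len(nx - 1L)
    if (j %% 2L == 1L) {
      tris[[length(tris) + 1L]] <- cbind(id(i, j), id(i + 1L, j), id(i, j + 1L))
      tris[[length(tris) + 1L]] <- cbind(id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
    } else {
      tris[[length(tris) + 1L]] <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L))
      tris[[length(tris) + 1L]] <- cbind(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L))
    }
  }
  tri_mesh(V, do.call(rbind, tris), closed = FALSE)
}

# ----------------------------------------------------------------- geometry

#' Median-dual control-volume areas
#'
#' Per-vertex areas of the median-dual cells (connect triangle barycenters
#' with edge midpoints): each vertex receives exactly one third of every
#' incident triangle's area, so the dual areas partition the total surface
#' area exactly.
#'
#' @param mesh a [tri_mesh()].
#' @param vertices optional deformed positions (defaults to the mesh's own).
#' @return numeric vector of per-vertex areas (m^2).
#' @export
median_dual_areas <- function(mesh, vertices = mesh$vertex_positions) {
  g <- cpp_vertex_geometry(vertices, mesh$triangles)
  if (any(g$tri_areas <= 0))
    stop("geometry error: degenerate triangle ", which(g$tri_areas <= 0)[1])
  g$dual_areas
}

#' Unit outward vertex normals (area-weighted)
#' @inheritParams median_dual_areas
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh, vertices = mesh$vertex_positions) {
  cpp_vertex_geometry(vertices, mesh$triangles)$normals
}

#' Total surface area of a mesh (m^2)
#' @inheritParams median_dual_areas
#' @export
mesh_area <- function(mesh, vertices = mesh$vertex_positions) {
  cpp_vertex_geometry(vertices, mesh$triangles)$total_area
}

#' Enclosed volume of a closed mesh (m^3)
#' @inheritParams median_dual_areas
#' @export
mesh_volume <- function(mesh, vertices = mesh$vertex_positions) {
  cpp_vertex_geometry(vertices, mesh$triangles)$total_volume
}

#' Mean inter-vertex spacing (mean edge length, m)
#' @param mesh a [tri_mesh()].
#' @param vertices optional deformed positions.
#' @export
mean_vertex_spacing <- function(mesh, vertices = mesh$vertex_positions) {
  E <- mesh$edges
  mean(sqrt(rowSums((vertices[E[, 2], , drop = FALSE] -
                     vertices[E[, 1], , drop = FALSE])^2)))
}
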