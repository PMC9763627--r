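test_that("discocyte meshes are closed, genus-0, and near the target size", {
  for (n in c(12, 150, 1000)) {
    m <- build_discocyte_mesh(n)
    nv <- m$n_vertices
    ne <- nrow(m$edges)
    nt <- nrow(m$triangles)
    expect_equal(nv - ne + nt, 2)            # Euler characteristic
    expect_equal(nrow(m$dihedral_quads), ne) # every edge interior
    expect_true(abs(nv - n) <= max(2, 0.05 * n))
    expect_true(all(m$rest_tri_areas > 0))
    expect_gt(m$rest_total_volume, 0)
  }
  expect_error(build_discocyte_mesh(6), "at least 12")
})

test_that("a ~5000-vertex discocyte has ~200 nm adhesion-vertex spacing", {
  m <- fx_5000 <- build_discocyte_mesh(5000)
  expect_true(abs(m$n_vertices - 5000) <= 250)
  sp <- mean_vertex_spacing(m)
  expect_gt(sp, 150e-9)
  expect_lt(sp, 250e-9)
  # shape sanity: canonical human RBC area/volume at 7.8 um diameter
  expect_true(abs(m$rest_total_area - 134e-12) < 8e-12)
  expect_true(abs(m$rest_total_volume - 93e-18) < 8e-18)
})

test_that("median-dual areas partition the surface exactly", {
  m <- fx_coarse_discocyte()
  Ai <- median_dual_areas(m)
  expect_true(all(Ai > 0))
  expect_lt(abs(sum(Ai) - m$rest_total_area) / m$rest_total_area, 1e-10)
  expect_lt(abs(sum(Ai) - sum(m$rest_tri_areas)) / sum(m$rest_tri_areas),
            1e-10)
  # interior vertex of a uniform patch receives 1/3 of incident triangle area
  p <- fx_patch()
  Ap <- median_dual_areas(p)
  geo <- cpp_vertex_geometry(p$vertex_positions, p$triangles)
  i <- 12 * 5 + 6  # interior vertex
  inc <- which(apply(p$triangles == i, 1, any))
  expect_equal(Ap[i], sum(geo$tri_areas[inc]) / 3, tolerance = 1e-12)
})

test_that("sphere mesh area and volume converge to the analytic values", {
  errs <- sapply(c(200, 800, 3200), function(n) {
    s <- build_sphere_mesh(n, 1e-6)
    abs(s$rest_total_area - 4 * pi * 1e-12) / (4 * pi * 1e-12)
  })
  expect_true(all(diff(errs) < 0))  # refinement reduces the error
  expect_lt(errs[3], 2e-3)
})

test_that("vertex normals are unit and outward on a sphere", {
  s <- build_sphere_mesh(400, 1e-6)
  nrm <- vertex_normals(s)
  expect_equal(sqrt(rowSums(nrm^2)), rep(1, s$n_vertices), tolerance = 1e-12)
  # outward: normal . radial direction > 0
  rad <- s$vertex_positions / sqrt(rowSums(s$vertex_positions^2))
  expect_true(all(rowSums(nrm * rad) > 0.9))
})

test_that("mean vertex spacing halves under 4x refinement and is exact on a
           uniform patch", {
  m1 <- build_discocyte_mesh(250)
  m2 <- build_discocyte_mesh(1000)
  ratio <- mean_vertex_spacing(m2) / mean_vertex_spacing(m1)
  expect_true(abs(ratio - 0.5) < 0.08)
  p <- fx_patch(spacing = 1e-7)
  expect_equal(mean_vertex_spacing(p), 1e-7, tolerance = 1e-12)
})

test_that("VTS contact query matches an exhaustive point-triangle oracle", {
  set.seed(42)
  m1 <- build_sphere_mesh(80, 1e-6)
  for (rep in 1:3) {
    V2 <- build_sphere_mesh(70, 0.8e-6)$vertex_positions
    V2 <- V2 + matrix(rnorm(length(V2), sd = 5e-8), ncol = 3)
    shift <- c(rnorm(2, sd = 2e-7), 1.9e-6 + rep * 1e-7)
    V2 <- sweep(V2, 2, shift, "+")
    m2 <- build_sphere_mesh(70, 0.8e-6)
    b1 <- rbc_body(m1); b2 <- rbc_body(m2)
    b2$vertex_positions <- V2
    cm <- contact_query(b1, b2, 6e-6, "VTS")
    idx <- which(cm$within_cutoff)
    idx <- idx[seq(1, length(idx), length.out = min(12, length(idx)))]
    for (i in idx) {
      p <- b1$vertex_positions[i, ]
      dd <- apply(m2$triangles, 1, function(tr)
        pt_tri_dist_oracle(p, V2[tr[1], ], V2[tr[2], ], V2[tr[3], ]))
      expect_lt(abs(cm$dist[i] - min(dd)) / min(dd), 1e-12)
    }
  }
})

test_that("contact behaves on parallel flat patches and beyond cutoff", {
  p <- fx_patch(12, 12, 1e-7)
  b1 <- rbc_body(p)
  b2 <- rbc_body(p)
  d <- 60e-9
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + d
  cm <- contact_query(b1, b2, 100e-9, "VTS")
  # interior vertices all matched at exactly the plane separation
  interior <- which(
    b1$vertex_positions[, 1] > 2e-7 & b1$vertex_positions[, 1] < 9e-7 &
    b1$vertex_positions[, 2] > 2e-7 & b1$vertex_positions[, 2] < 9e-7)
  expect_true(all(cm$within_cutoff[interior]))
  expect_equal(cm$dist[interior], rep(d, length(interior)), tolerance = 1e-12)
  # far apart: empty map
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 1e-6
  cm2 <- contact_query(b1, b2, 100e-9, "VTS")
  expect_false(any(cm2$within_cutoff))
  cm3 <- contact_query(b1, b2, 100e-9, "VTV")
  expect_false(any(cm3$within_cutoff))
})

test_that("VTV pairing finds nearest vertices within the cutoff", {
  p <- fx_patch(8, 8, 1e-7)
  b1 <- rbc_body(p)
  b2 <- rbc_body(p)
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 40e-9
  cm <- contact_query(b1, b2, 100e-9, "VTV")
  expect_true(all(cm$within_cutoff))
  expect_equal(cm$partner, seq_len(p$n_vertices))  # aligned lattices
  expect_equal(cm$dist, rep(40e-9, p$n_vertices), tolerance = 1e-12)
})
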