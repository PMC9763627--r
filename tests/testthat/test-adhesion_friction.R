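test_that("affinity composition follows the cross-bridge sum", {
  uJ <- 1e-6
  p <- adhesion_params(gamma_ifgr = 0, gamma_ifg = 1 * uJ, gamma_mfg = 0.25 * uJ)
  expect_equal(total_affinity(p, 1, 1), 1.5 * uJ)
  p0 <- adhesion_params(gamma_ifg = 1e-30)  # all-zero limit (validated > 0 r0)
  expect_equal(total_affinity(adhesion_params(), 0, 0), 0)
  # UAM limit: gamma_mfg = 0 makes the density irrelevant
  pu <- adhesion_params(gamma_ifgr = 0.5 * uJ, gamma_ifg = 1 * uJ)
  expect_equal(total_affinity(pu, 3, 7), 1.5 * uJ)
  expect_error(total_affinity(p, -1, 0), "negative")
})

test_that("pathophysiological composition reproduces the reference scalings", {
  uJ <- 1e-6
  healthy <- pathophys_affinity(pathophys_params(n_star = 1.25, gamma_star = 1),
                                gamma_ifg = 1 * uJ)
  expect_equal(healthy$gamma_affin, 1.625 * uJ)
  expect_equal(healthy$n_ave_t0, 2.5)
  sle <- pathophys_affinity(pathophys_params(n_star = 1.5, gamma_star = 2),
                            gamma_ifg = 1 * uJ)
  expect_equal(sle$gamma_affin, 2.5 * uJ)
  expect_equal(sle$n_ave_t0, 3)
  # healthy reference (multipliers 1) matches the plain composition
  ref <- pathophys_affinity(pathophys_params(), gamma_ifg = 1 * uJ)
  p <- adhesion_params(gamma_ifg = 1 * uJ, gamma_mfg = 0.25 * uJ)
  expect_equal(ref$gamma_affin, total_affinity(p, 1, 1))
})

test_that("Morse energy has its minimum at r0 and vanishes beyond cutoff", {
  g <- 1e-6; beta <- 5e7; r0 <- 20e-9; rc <- 100e-9; ai <- 4e-14
  expect_equal(morse_energy(r0, g, beta, r0, rc, ai), -g * ai)
  expect_equal(morse_energy(rc * 1.0001, g, beta, r0, rc, ai), 0)
  rr <- seq(0, rc, length.out = 4001)
  U <- morse_energy(rr, g, beta, r0, rc, ai)
  expect_equal(rr[which.min(U)], r0, tolerance = 1e-3)
  expect_true(all(U >= -g * ai * (1 + 1e-9)))
})

test_that("Morse force is the negative radial derivative of the energy", {
  g <- 1e-6; beta <- 5e7; r0 <- 20e-9; rc <- 100e-9; ai <- 4e-14
  # zero at the zero-force separation and beyond the cutoff
  expect_equal(morse_force(r0, g, beta, r0, rc, ai), 0)
  expect_equal(morse_force(rc * 1.01, g, beta, r0, rc, ai), 0)
  h <- 1e-13
  for (r in c(5e-9, 15e-9, 30e-9, 60e-9, 95e-9)) {
    fd <- -(morse_energy(r + h, g, beta, r0, rc, ai) -
            morse_energy(r - h, g, beta, r0, rc, ai)) / (2 * h)
    f <- morse_force(r, g, beta, r0, rc, ai)
    # force magnitude along decreasing r: -dU/dr projected on approach
    expect_lt(abs(-fd - f) / max(abs(f), 1e-30), 1e-6)
  }
  # attraction beyond r0, repulsion below
  expect_gt(morse_force(30e-9, g, beta, r0, rc, ai), 0)
  expect_lt(morse_force(10e-9, g, beta, r0, rc, ai), 0)
})

test_that("pairwise adhesion forces respect the scheme contracts", {
  p <- fx_patch(10, 10, 2e-7)
  b1 <- rbc_body(p); b2 <- rbc_body(p)
  r0 <- 20e-9
  uJ <- 1e-6
  # exactly at r0: all forces vanish
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + r0
  prm <- adhesion_params(gamma_ifg = 1 * uJ, gamma_mfg = 0.25 * uJ)
  res <- adhesion_forces(b1, b2, prm)
  expect_lt(max(abs(res$F_a)), 1e-25)
  # at r > r0 the source is attracted toward the target (+z here)
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 20e-9
  res2 <- adhesion_forces(b1, b2, prm)
  interior <- which(median_dual_areas(p) > 0.9 * max(median_dual_areas(p)))
  expect_true(all(res2$F_a[interior, 3] > 0))
  # momentum conservation across the pair
  expect_lt(max(abs(colSums(res2$F_a) + colSums(res2$F_b))),
            1e-12 * max(abs(res2$F_a)))
  # mobile term is linear in the gap density
  prm_m <- adhesion_params(gamma_mfg = 0.25 * uJ)
  r_a <- adhesion_forces(b1, b2, prm_m)
  b1$n_mfg <- b1$n_mfg * 2; b2$n_mfg <- b2$n_mfg * 2
  r_b <- adhesion_forces(b1, b2, prm_m)
  expect_equal(r_b$F_a, 2 * r_a$F_a, tolerance = 1e-12)
})

test_that("with gamma_mfg = 0 the pipeline reduces to the UAM bit-for-bit", {
  p <- fx_patch(10, 10, 2e-7)
  b1 <- rbc_body(p); b2 <- rbc_body(p)
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 45e-9
  uJ <- 1e-6
  uam <- adhesion_params(gamma_ifg = 1.5 * uJ, gamma_mfg = 0)
  cbmm_zero_density <- adhesion_params(gamma_ifg = 1.5 * uJ,
                                       gamma_mfg = 0.25 * uJ)
  b1z <- b1; b2z <- b2
  b1z$n_mfg[] <- 0; b2z$n_mfg[] <- 0
  f_uam <- adhesion_forces(b1, b2, uam)
  f_cbmm <- adhesion_forces(b1z, b2z, cbmm_zero_density)
  expect_identical(f_uam$F_a, f_cbmm$F_a)
  expect_identical(f_uam$F_b, f_cbmm$F_b)
})

test_that("Couette friction opposes tangential sliding with the Couette law", {
  p <- fx_patch(10, 10, 2e-7)
  b1 <- rbc_body(p); b2 <- rbc_body(p)
  gap <- 40e-9
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + gap
  prm <- adhesion_params(mu_gap = 3.6e-3, r_glyco = 5e-9)
  # purely normal approach: no friction
  b1$velocities[, 3] <- 1e-6
  resN <- friction_forces(b1, b2, prm)
  expect_lt(max(abs(resN$F_a)), 1e-24)
  # tangential sliding at speed s
  s <- 1e-6
  b1$velocities[] <- 0; b1$velocities[, 1] <- s
  res <- friction_forces(b1, b2, prm)
  Ai <- median_dual_areas(p)
  interior <- which(Ai > 0.9 * max(Ai))
  expected <- -prm$mu_gap * s * Ai[interior] / (gap - 2 * prm$r_glyco)
  expect_equal(res$F_a[interior, 1], expected, tolerance = 1e-9)
  # halved effective gap doubles the force (above the clamp)
  b2h <- b2
  b2h$vertex_positions[, 3] <- b1$vertex_positions[, 3] + 25e-9
  resH <- friction_forces(b1, b2h, prm)
  expect_equal(resH$F_a[interior, 1] / res$F_a[interior, 1],
               rep((gap - 10e-9) / (25e-9 - 10e-9), length(interior)),
               tolerance = 1e-6)
  # friction power against the tangential relative motion is non-positive
  expect_lt(sum(res$F_a * b1$velocities), 0)
})

test_that("VTV bridging cannot span gaps wider than the cutoff", {
  # vertex spacing far above r_cutoff: only the aligned partner interacts;
  # a laterally shifted lattice has no partner in range at all
  p <- fx_patch(8, 8, 6e-7)
  b1 <- rbc_body(p); b2 <- rbc_body(p)
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 30e-9
  b2$vertex_positions[, 1] <- b2$vertex_positions[, 1] + 3e-7  # half spacing
  cm <- contact_query(b1, b2, 100e-9, "VTV")
  expect_false(any(cm$within_cutoff))
})
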