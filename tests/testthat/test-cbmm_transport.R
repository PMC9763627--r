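test_that("drift velocity follows the gap-weighted Couette entrainment", {
  p <- fx_patch(10, 10, 2e-7)
  b1 <- rbc_body(p); b2 <- rbc_body(p)
  tp <- transport_params(delta_fg = 45e-9)
  rg <- 5e-9
  w <- c(1e-6, 0, 0)
  b2$velocities <- matrix(rep(w, each = p$n_vertices), ncol = 3)
  Ai <- median_dual_areas(p)
  interior <- which(Ai > 0.9 * max(Ai))
  # delta_gap >= delta_fg: no drift
  b2$vertex_positions[, 3] <- b1$vertex_positions[, 3] + 45e-9 + 2 * rg + 1e-9
  cm <- contact_query(b1, b2, 200e-9, "VTS")
  d0 <- drift_velocity(b1, b2, cm, tp, rg)
  expect_equal(max(abs(d0)), 0)
  # delta_gap = 0: drift = half the relative surface velocity (tangential)
  b2$vertex_positions[, 3] <- b1$vertex_positions[, 3] + 2 * rg
  cm <- contact_query(b1, b2, 200e-9, "VTS")
  d1 <- drift_velocity(b1, b2, cm, tp, rg)
  expect_equal(d1[interior, 1], rep(0.5 * w[1], length(interior)),
               tolerance = 1e-9)
  # delta_gap = delta_fg / 2: quarter of the relative velocity
  b2$vertex_positions[, 3] <- b1$vertex_positions[, 3] + 2 * rg + 45e-9 / 2
  cm <- contact_query(b1, b2, 200e-9, "VTS")
  d2 <- drift_velocity(b1, b2, cm, tp, rg)
  expect_equal(d2[interior, 1], rep(0.25 * w[1], length(interior)),
               tolerance = 1e-9)
})

test_that("adsorption source balances at equilibrium and has the right
           signs and gating", {
  tp <- transport_params(adsorption = TRUE, phi0 = 0.001, n0 = 1,
                         delta_fg = 45e-9)
  n <- c(1, 1, 0.5, 2)
  S_open <- adsorption_source(n, NULL, tp)
  expect_equal(S_open[1:2], c(0, 0))                 # N = N0: exact balance
  expect_gt(S_open[3], 0)                            # depleted: replenished
  expect_lt(S_open[4], 0)                            # enriched: lost to bulk
  # tight gap (rsep < delta_fg): source suppressed regardless of N
  p <- fx_patch(6, 6, 2e-7)
  b1 <- rbc_body(p, n_mfg = 0.5); b2 <- rbc_body(p)
  b2$vertex_positions[, 3] <- b1$vertex_positions[, 3] + 20e-9
  cm <- contact_query(b1, b2, 100e-9, "VTS")
  S_gap <- adsorption_source(b1$n_mfg, cm, tp)
  expect_equal(S_gap[cm$within_cutoff], rep(0, sum(cm$within_cutoff)))
  expect_error(adsorption_source(n, NULL, transport_params()), "adsorption")
})

test_that("pure diffusion reproduces the planar heat kernel", {
  patch <- build_flat_patch(41, 47, 1e-7)
  b <- rbc_body(patch)
  V <- patch$vertex_positions
  ctr <- colMeans(V)
  i0 <- which.min(rowSums(sweep(V, 2, ctr)^2))
  Ai <- median_dual_areas(patch)
  b$n_mfg <- rep(0, nrow(V)); b$n_mfg[i0] <- 1 / Ai[i0]
  tp <- transport_params(d_mfg = 1e-15)
  tt <- 5
  for (s in 1:250) b <- transport_step(b, dt = tt / 250, params = tp)
  w <- b$n_mfg * Ai; w <- w / sum(w)
  mu <- colSums(w * V)
  v <- sum(w * rowSums(sweep(V, 2, mu)^2))
  expect_lt(abs(v - 4 * tp$d_mfg * tt) / (4 * tp$d_mfg * tt), 0.05)
})

test_that("uniform drift translates a profile at the drift speed", {
  patch <- build_flat_patch(41, 47, 1e-7)
  b <- rbc_body(patch)
  V <- patch$vertex_positions
  ctr <- colMeans(V)
  b$n_mfg <- exp(-rowSums(sweep(V, 2, ctr)^2) / (2 * (3e-7)^2))
  Ai <- median_dual_areas(patch)
  a0 <- sum(b$n_mfg * Ai)
  u <- 1e-7
  drift <- matrix(rep(c(u, 0, 0), each = nrow(V)), ncol = 3)
  tp <- transport_params(d_mfg = 0)
  tt <- 10
  for (s in 1:200) b <- transport_step(b, drift = drift, dt = tt / 200,
                                       params = tp)
  w <- b$n_mfg * Ai; w <- w / sum(w)
  mu <- colSums(w * V)
  expect_lt(abs((mu[1] - ctr[1]) - u * tt) / (u * tt), 0.05)
  expect_lt(abs(mu[2] - ctr[2]), 0.02 * u * tt)
  expect_equal(sum(b$n_mfg * Ai), a0, tolerance = 1e-12)  # conservative
  expect_true(all(b$n_mfg >= 0))                          # upwind positivity
})

test_that("amount is conserved and the maximum principle holds on a closed
           surface", {
  sm <- build_sphere_mesh(300, 1e-6)
  b <- rbc_body(sm)
  set.seed(3)
  b$n_mfg <- runif(sm$n_vertices, 0.5, 2)
  Ai <- median_dual_areas(sm)
  a0 <- sum(b$n_mfg * Ai)
  rng0 <- range(b$n_mfg)
  tp <- transport_params(d_mfg = 1e-13)
  for (s in 1:1000) b <- transport_step(b, dt = 0.01, params = tp)
  expect_lt(abs(sum(b$n_mfg * Ai) - a0) / a0, 1e-8)
  expect_gte(min(b$n_mfg), rng0[1] - 1e-12)
  expect_lte(max(b$n_mfg), rng0[2] + 1e-12)
  # long-time limit: uniform at the area-weighted mean
  expect_lt(diff(range(b$n_mfg)) / mean(b$n_mfg), 0.05)
})

test_that("average gap density composes both surfaces' contributions", {
  p <- fx_patch(8, 8, 2e-7)
  b1 <- rbc_body(p, n_mfg = 1); b2 <- rbc_body(p, n_mfg = 1)
  b2$vertex_positions[, 3] <- b1$vertex_positions[, 3] + 30e-9
  cma <- contact_query(b1, b2, 100e-9, "VTS")
  cmb <- contact_query(b2, b1, 100e-9, "VTS")
  expect_equal(average_gap_density(b1, b2, cma, cmb), 2, tolerance = 1e-9)
  # pathophysiological initialization: N* per surface -> starting Nave 2 N*
  b1$n_mfg[] <- 1.5; b2$n_mfg[] <- 1.5
  expect_equal(average_gap_density(b1, b2, cma, cmb), 3, tolerance = 1e-9)
  # one surface zeroed: mean of the other's in-contact densities
  b1$n_mfg[] <- 0; b2$n_mfg[] <- 1
  expect_equal(average_gap_density(b1, b2, cma, cmb), 1, tolerance = 1e-9)
  # empty contact: flagged NA, not an exception
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 1
  cma <- contact_query(b1, b2, 100e-9, "VTS")
  cmb <- contact_query(b2, b1, 100e-9, "VTS")
  expect_true(is.na(average_gap_density(b1, b2, cma, cmb)))
})
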