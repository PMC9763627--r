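test_that("formation rate recovers a synthetic linear growth exactly", {
  g <- 0.3e-6
  traj <- data.frame(time = seq(0, 10, by = 0.1))
  traj$overlap <- g * traj$time
  expect_equal(formation_rate(traj), g, tolerance = 1e-12)
  # constant overlap: zero with the no-growth flag
  traj$overlap <- rep(2e-6, nrow(traj))
  r <- formation_rate(traj)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "no_growth"))
  # growth measured from the initial geometric overlap
  traj$overlap <- 1e-6 + g * traj$time
  expect_equal(formation_rate(traj), g, tolerance = 1e-12)
})

test_that("stage segmentation splits tension curves at the smoothed peak", {
  d <- seq(0, 6e-6, length.out = 121)
  dstar <- 2e-6
  f <- ifelse(d < dstar, d / dstar, pmax(0, 1 - (d - dstar) / 4e-6)) * 2e-11
  traj <- data.frame(displacement = d, f_ot = f)
  seg <- stage_segmentation(traj)
  expect_equal(seg$disp_at_peak, dstar, tolerance = 0.05 * dstar)
  expect_false(seg$single_stage)
  expect_equal(seg$peak_tension, max(f))
  # monotone rising curve: single stage
  traj2 <- data.frame(displacement = d, f_ot = d * 5e-6)
  expect_true(stage_segmentation(traj2)$single_stage)
  expect_error(stage_segmentation(data.frame(displacement = 0, f_ot = 0)),
               "no pulling")
})

test_that("contact area reproduces a fully engaged flat patch", {
  p <- fx_patch(12, 12, 2e-7)
  b1 <- rbc_body(p); b2 <- rbc_body(p)
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 40e-9
  a <- contact_area(b1, b2, r_cutoff = 100e-9)
  expect_lt(abs(a - p$rest_total_area) / p$rest_total_area, 0.05)
  b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + 1e-5
  expect_equal(contact_area(b1, b2, r_cutoff = 100e-9), 0)
})

test_that("overlap length is the projected silhouette overlap", {
  m <- fx_coarse_discocyte()
  b1 <- rbc_body(m); b2 <- rbc_body(m)
  diam <- max(m$vertex_positions[, 1]) - min(m$vertex_positions[, 1])
  b2$vertex_positions[, 1] <- b2$vertex_positions[, 1] + 0.75 * diam
  expect_equal(overlap_length(b1, b2), 0.25 * diam, tolerance = 1e-9)
  b2$vertex_positions[, 1] <- b2$vertex_positions[, 1] + diam
  expect_equal(overlap_length(b1, b2), 0)
})

test_that("doublet placement reaches the requested surface gap", {
  m <- fx_coarse_discocyte(300)
  for (off in c(0.8, 0.5)) {
    pos <- place_doublet(m, off, 20e-9, "VTS")
    cm <- cpp_contact_vts(pos$x1, pos$x2, m$triangles, 5e-6)
    expect_equal(min(cm$dist[cm$tri > 0]), 20e-9, tolerance = 0.05)
    dx <- mean(pos$x2[, 1]) - mean(pos$x1[, 1])
    diam <- max(m$vertex_positions[, 1]) - min(m$vertex_positions[, 1])
    expect_equal(dx, off * diam, tolerance = 1e-6)
  }
})

test_that("identical configuration and seed give bit-identical trajectories", {
  pr <- cbmm_preset("table2.groupA.1.0")
  cfg <- pr$protocol
  cfg$duration <- 0.3
  mesh <- fx_coarse_discocyte(150)
  run <- function() run_doublet_formation(cfg, pr$membrane, pr$adhesion,
                                          pr$transport, mesh = mesh,
                                          n_init = pr$n_init)
  t1 <- run()
  t2 <- run()
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})
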