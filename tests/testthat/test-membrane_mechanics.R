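test_that("membrane parameter invariants are enforced at load time", {
  p <- membrane_params()
  expect_equal(2 * p$es0 + p$ka + p$kd, p$k0, tolerance = 1e-3)
  expect_equal(p$eta_c, p$eta_t / 3)
  expect_equal(p$eta_t, 12 * p$eta_m / (13 * sqrt(3)))
  expect_error(membrane_params(ka = 0.3), "k0 must equal")
})

test_that("elastic forces vanish at rest and are translation invariant", {
  m <- fx_coarse_discocyte()
  b <- rbc_body(m)
  F0 <- elastic_forces(b)
  # the rest geometry is the energy minimum by construction
  scale <- max(abs(elastic_forces(
    b, b$vertex_positions + matrix(rnorm(3 * m$n_vertices, sd = 1e-8), ncol = 3))))
  expect_lt(max(abs(F0)), 1e-9 * scale)
  # uniform translation leaves forces identically zero
  Vt <- sweep(b$vertex_positions, 2, c(1e-6, -2e-6, 3e-6), "+")
  expect_lt(max(abs(elastic_forces(b, Vt))), 1e-9 * scale)
})

test_that("every elastic energy term matches its finite-difference gradient", {
  set.seed(7)
  m <- fx_coarse_discocyte()
  V <- m$vertex_positions + matrix(rnorm(3 * m$n_vertices, sd = 2e-8), ncol = 3)
  idx <- c(1, 17, 60, 101, 149)
  terms <- list(
    shear = mp_only(es0 = 6.54e-6),
    bend = mp_only(eb = 2.4e-19),
    area = mp_only(ka = 0.288, kd = 0.144),
    volume = mp_only(kv = 220))
  for (nm in names(terms)) {
    b <- rbc_body(m, terms[[nm]])
    F <- elastic_forces(b, V)
    fd <- -fd_gradient(function(x) membrane_energy(b, x)$total, V, idx)
    expect_lt(max(abs(fd - F[idx, ])) / max(abs(F[idx, ])), 1e-5,
              label = paste("FD gradient of", nm, "term"))
  }
  # and the combined model
  b <- rbc_body(m, membrane_params())
  F <- elastic_forces(b, V)
  fd <- -fd_gradient(function(x) membrane_energy(b, x)$total, V, idx)
  expect_lt(max(abs(fd - F[idx, ])) / max(abs(F[idx, ])), 1e-5)
})

test_that("viscous forces dissipate, conserve momentum, and follow the
           pairwise law", {
  m <- fx_coarse_discocyte()
  b <- rbc_body(m)
  # rigid translation: no relative velocity, no force
  b$velocities <- matrix(rep(c(1e-6, 2e-6, -1e-6), each = m$n_vertices), ncol = 3)
  expect_equal(max(abs(viscous_forces(b))), 0)
  # random velocities: momentum conserved, power non-positive
  set.seed(8)
  b$velocities <- matrix(rnorm(3 * m$n_vertices, sd = 1e-6), ncol = 3)
  Fv <- viscous_forces(b)
  expect_lt(max(abs(colSums(Fv))), 1e-20)
  expect_lt(sum(Fv * b$velocities), 0)
  # two-vertex closure: relative speed s along the edge gives (etaT+etaC)*s
  p <- b$params
  tri <- matrix(c(1L, 2L, 3L), 1)
  mesh2 <- tri_mesh(rbind(c(0, 0, 0), c(1e-6, 0, 0), c(0.5e-6, 1e-6, 0)),
                    tri, closed = FALSE)
  b2 <- rbc_body(mesh2, membrane_params())
  b2$velocities <- rbind(c(1e-6, 0, 0), c(-1e-6, 0, 0), c(0, 0, 0))
  Fv2 <- viscous_forces(b2)
  # edge (1,2): v_rel = 2e-6 along the edge, closing
  expect_equal(Fv2[1, 1], -(p$eta_t + p$eta_c) * 2e-6, tolerance = 1e-10)
})

test_that("semi-implicit integration follows its discrete closed forms", {
  m <- fx_coarse_discocyte()
  b <- rbc_body(m, mp_only(eta_m = 0))  # no elastic stiffness, no viscosity
  v0 <- 1e-6
  b$velocities[, 1] <- v0
  dt <- 1e-4
  out <- integrate_step(list(b), NULL, dt)[[1]]
  expect_equal(out$vertex_positions[, 1], b$vertex_positions[, 1] + v0 * dt,
               tolerance = 1e-12)
  # constant external force: after n steps v = F*n*dt/m exactly
  f0 <- 1e-12
  ext <- list(matrix(c(rep(f0, m$n_vertices), rep(0, 2 * m$n_vertices)),
                     ncol = 3))
  bb <- rbc_body(m, mp_only(eta_m = 0))
  for (k in 1:5) bb <- integrate_step(list(bb), ext, dt)[[1]]
  mi <- bb$params$mass_total / m$n_vertices
  expect_equal(bb$velocities[, 1], rep(f0 * 5 * dt / mi, m$n_vertices),
               tolerance = 1e-12)
  expect_error(integrate_step(list(b), NULL, 0), "dt must be")
})

test_that("stable_dt scales as a spring-mass bound and holds a rest mesh", {
  m <- fx_coarse_discocyte()
  # pure-spring parameterizations so the spring term dominates the bound
  b1 <- rbc_body(m, mp_only(es0 = 6.54e-6, eta_m = 1e-9))
  b4 <- rbc_body(m, mp_only(es0 = 4 * 6.54e-6, eta_m = 1e-9))
  expect_equal(stable_dt(b4) / stable_dt(b1), 0.5, tolerance = 0.01)
  bm <- rbc_body(m, membrane_params(mass_total = 4e-5))
  b0 <- rbc_body(m, membrane_params())
  expect_equal(stable_dt(bm) / stable_dt(b0), 2, tolerance = 0.01)
  # stability smoke test: 1e4 steps at stable_dt leave the rest mesh in place
  b <- rbc_body(m, membrane_params())
  dt <- stable_dt(b)
  mesh_l <- rbcbridge:::.mesh_list(m)
  mech_l <- rbcbridge:::.mech_list(b)
  nv <- m$n_vertices
  st <- list(x1 = m$vertex_positions, v1 = matrix(0, nv, 3), n1 = rep(1, nv),
             x2 = m$vertex_positions + 5e-5, v2 = matrix(0, nv, 3),
             n2 = rep(1, nv))
  phys <- c(unclass(adhesion_params()),
            list(d_mfg = 0, delta_fg = 45e-9, phi0 = 1, n0 = 1,
                 adsorption = FALSE, transport_on = FALSE))
  ctrl <- list(dt = dt, t_end = 1e4 * dt, settle_t = 0, record_dt = 1e4 * dt,
               pull_rate = 0, t_ramp = 0.25, escape_f = Inf, stop_on_sep = FALSE,
               trap1 = integer(0), trap2 = integer(0))
  sim <- rbcbridge:::cpp_simulate(mesh_l, mech_l, mesh_l, mech_l, st, phys, ctrl)
  drift <- sqrt(rowSums((sim$final$body1$x - m$vertex_positions)^2))
  expect_lt(max(drift), 1e-9)
})

test_that("a perturbed free cell relaxes: strain energy decreases", {
  set.seed(11)
  m <- fx_coarse_discocyte()
  b <- rbc_body(m, membrane_params())
  V <- m$vertex_positions * 1.01  # small inflation
  dt <- stable_dt(b)
  b$vertex_positions <- V
  e0 <- membrane_energy(b, V)$total
  mesh_l <- rbcbridge:::.mesh_list(m)
  mech_l <- rbcbridge:::.mech_list(b)
  nv <- m$n_vertices
  st <- list(x1 = V, v1 = matrix(0, nv, 3), n1 = rep(1, nv),
             x2 = V + 1e-4, v2 = matrix(0, nv, 3), n2 = rep(1, nv))
  phys <- c(unclass(adhesion_params()),
            list(d_mfg = 0, delta_fg = 45e-9, phi0 = 1, n0 = 1,
                 adsorption = FALSE, transport_on = FALSE))
  ctrl <- list(dt = dt, t_end = 4000 * dt, settle_t = 0, record_dt = 2000 * dt,
               pull_rate = 0, t_ramp = 0.25, escape_f = Inf, stop_on_sep = FALSE,
               trap1 = integer(0), trap2 = integer(0))
  sim <- rbcbridge:::cpp_simulate(mesh_l, mech_l, mesh_l, mech_l, st, phys, ctrl)
  e1 <- membrane_energy(b, sim$final$body1$x)$total
  expect_lt(e1, e0)
})
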