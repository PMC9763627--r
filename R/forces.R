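#' Elastic membrane forces
#'
#' Negative gradient of the total membrane strain energy (cytoskeleton
#' shear springs + dihedral bending + global/local area penalties + volume
#' penalty) at every vertex, evaluated at the body's current positions.
#' The net force over a closed surface sums to zero (translation
#' invariance) and vanishes identically at the rest geometry.
#'
#' @param body an [rbc_body()].
#' @param vertices optional deformed positions (defaults to the body's).
#' @return n x 3 matrix of forces (N).
#' @export
elastic_forces <- function(body, vertices = body$vertex_positions) {
  if (any(!is.finite(vertices))) stop("state error: non-finite positions")
  cpp_elastic_forces(vertices, .mesh_list(body$mesh), .mech_list(body))
}

#' Membrane strain energy, by component
#'
#' @inheritParams elastic_forces
#' @return list with `shear`, `bend`, `area_global`, `area_local`,
#'   `volume`, `total` (J).
#' @export
membrane_energy <- function(body, vertices = body$vertex_positions) {
  cpp_membrane_energy(vertices, .mesh_list(body$mesh), .mech_list(body))
}

#' Dissipative membrane-viscosity forces
#'
#' Pairwise dissipative force on every cytoskeleton edge (i, j):
#' `F_ij = -eta_t * v_ij - eta_c * (v_ij . e_ij) e_ij` applied to `i` with
#' the opposite reaction on `j`, so momentum is conserved exactly and the
#' instantaneous dissipated power is non-positive.
#'
#' @param body an [rbc_body()] with velocities.
#' @param vertices,velocities optional state overrides.
#' @return n x 3 matrix of forces (N).
#' @export
viscous_forces <- function(body, vertices = body$vertex_positions,
                           velocities = body$velocities) {
  cpp_viscous_forces(vertices, velocities, .mesh_list(body$mesh),
                     body$params$eta_t, body$params$eta_c)
}

#' Cross-bridge adhesion forces between two bodies
#'
#' Evaluates the Morse-type adhesion forces on every source vertex within
#' the cutoff: the specific term along the VTV direction, the immobile and
#' mobile non-specific terms along the VTS direction, with the mobile term
#' scaled by the local gap density `n_src(i) + n_tgt(nearest)`. The
#' reaction is distributed to the nearest target element by barycentric
#' weights (VTS) or applied to the partner vertex (VTV), conserving linear
#' momentum exactly.
#'
#' @param body_a,body_b source and target [rbc_body()] objects.
#' @param contact optional precomputed VTS [contact_query()] map.
#' @param params an [adhesion_params()].
#' @return list with `F_a` (forces on source vertices), `F_b` (reactions on
#'   target vertices) and `f_sum_a` (net adhesion force vector on A).
#' @export
adhesion_forces <- function(body_a, body_b, params,
                            contact = NULL) {
  Ai <- median_dual_areas(body_a$mesh, body_a$vertex_positions)
  vts <- list(); vtv <- list()
  if (params$gamma_ifg > 0 || params$gamma_mfg > 0) {
    cm <- if (!is.null(contact) && contact$mode == "VTS") contact else
      contact_query(body_a, body_b, params$r_cutoff, "VTS")
    vts <- list(tri = ifelse(is.na(cm$tri), 0L, cm$tri), dist = cm$dist,
                dir = cm$dir, bary = cm$bary)
  }
  if (params$gamma_ifgr > 0) {
    cm <- if (!is.null(contact) && contact$mode == "VTV") contact else
      contact_query(body_a, body_b, params$r_cutoff, "VTV")
    vtv <- list(idx = ifelse(is.na(cm$partner), 0L, cm$partner),
                dist = cm$dist, dir = cm$dir)
  }
  res <- cpp_adhesion_forces(Ai, body_a$n_mfg, body_b$n_mfg, vts, vtv,
                             body_b$mesh$triangles, body_b$mesh$n_vertices,
                             unclass(params))
  list(F_a = res$F_src, F_b = res$F_tgt, f_sum_a = res$f_sum_src)
}

#' Intercellular Couette friction forces
#'
#' At every source vertex within the cutoff of the pairing surface, the
#' tangential relative velocity is opposed by the Couette shear stress
#' `mu_gap * v_t / (r_sep - 2 r_glyco)` converted to a nodal force by the
#' median-dual area; the gap denominator is clamped below at `eps_gap`.
#' The reaction is distributed barycentrically to the nearest target
#' element.
#'
#' @inheritParams adhesion_forces
#' @return list with `F_a` and `F_b`.
#' @export
friction_forces <- function(body_a, body_b, params, contact = NULL) {
  if (is.null(contact) || contact$mode != "VTS")
    contact <- contact_query(body_a, body_b, params$r_cutoff, "VTS")
  Ai <- median_dual_areas(body_a$mesh, body_a$vertex_positions)
  nrm <- vertex_normals(body_a$mesh, body_a$vertex_positions)
  vts <- list(tri = ifelse(is.na(contact$tri), 0L, contact$tri),
              dist = contact$dist, dir = contact$dir, bary = contact$bary)
  res <- cpp_friction_forces(Ai, nrm, body_a$velocities, body_b$velocities,
                             vts, body_b$mesh$triangles,
                             body_b$mesh$n_vertices, unclass(params))
  list(F_a = res$F_src, F_b = res$F_tgt)
}

#' Conservative explicit time-step bound
#'
#' Stability bound for the semi-implicit Euler integrator, from the
#' stiffest local restoring coefficient (edge springs, local/global area
#' penalties and the Morse curvature bound) and the per-vertex drag:
#' `dt = safety * min(2 sqrt(m/k_max), m/c_max)`.
#'
#' @param body an [rbc_body()].
#' @param adhesion optional [adhesion_params()] whose stiffness and gap
#'   friction are included in the bound.
#' @param n_mfg_max largest expected gap density (scales the Morse term).
#' @param safety safety factor.
#' @return time step in s.
#' @export
stable_dt <- function(body, adhesion = NULL, n_mfg_max = 6, safety = 0.3) {
  p <- body$params
  sp <- body$spring
  l0 <- body$mesh$rest_edge_lengths
  x0 <- l0 / sp$lmax
  k_edge <- sp$kbtp * (0.5 / (1 - x0)^3 + 1) / sp$lmax + 2 * sp$kpow / l0^3
  # per-vertex: ~6 incident edges; in-plane area stiffness ~ 4 (ka + kd)
  k_area <- 4 * (p$ka + p$kd)
  k_adh <- 0
  c_gap <- 0
  if (!is.null(adhesion)) {
    Ai_max <- max(median_dual_areas(body$mesh))
    gmax <- adhesion$gamma_ifgr + adhesion$gamma_ifg +
      n_mfg_max * adhesion$gamma_mfg
    # Morse curvature at full compression ~ 2 Gamma beta^2 Ai e^{2 beta r0}
    k_adh <- 2 * gmax * adhesion$beta^2 * Ai_max *
      exp(2 * adhesion$beta * adhesion$r0)
    c_gap <- adhesion$mu_gap * Ai_max / adhesion$eps_gap
  }
  k_max <- 6 * max(k_edge) + k_area + k_adh
  c_max <- 8 * (p$eta_t + p$eta_c) + c_gap
  m <- p$mass_total / body$mesh$n_vertices
  safety * min(2 * sqrt(m / k_max), m / c_max)
}

#' Advance bodies one semi-implicit Euler step
#'
#' Velocity update from the total force (elastic + viscous + any external
#' per-vertex forces supplied), then position update with the new velocity.
#' This is the reference R-level integrator; the protocol drivers use the
#' same update order inside the compiled simulation loop.
#'
#' @param bodies list of [rbc_body()] objects.
#' @param external_forces list of n x 3 matrices (or NULL entries).
#' @param dt time step (s); must not exceed [stable_dt()].
#' @return the updated list of bodies.
#' @export
integrate_step <- function(bodies, external_forces = NULL, dt) {
  if (dt <= 0) stop("configuration error: dt must be > 0")
  for (i in seq_along(bodies)) {
    b <- bodies[[i]]
    f <- elastic_forces(b) + viscous_forces(b)
    if (!is.null(external_forces) && !is.null(external_forces[[i]]))
      f <- f + external_forces[[i]]
    if (any(!is.finite(f))) stop("state error: non-finite force")
    m <- b$params$mass_total / b$mesh$n_vertices
    b$velocities <- b$velocities + f / m * dt
    b$vertex_positions <- b$vertex_positions + b$velocities * dt
    bodies[[i]] <- b
  }
  bodies
}
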