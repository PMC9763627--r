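#' Friction-induced drift velocity of adsorbed mobile fibrinogen
#'
#' Where the intercellular gap `delta_gap = r_sep - 2 r_glyco` is narrower
#' than the hydrodynamic size `delta_fg` of the adsorbed mobile Fg, the
#' bridging molecules are dragged by the Couette shear and slide relative
#' to their adsorption surface with velocity
#' `0.5 * (v_neighbor - v_rbc) * (delta_fg - delta_gap) / delta_fg`,
#' projected on the local tangent plane; zero for wider gaps and outside
#' the contact.
#'
#' @param body the adsorption-surface [rbc_body()].
#' @param neighbor the pairing [rbc_body()].
#' @param contact a VTS [contact_query()] map from `body` to `neighbor`.
#' @param params a [transport_params()].
#' @param r_glyco glycocalyx height (m).
#' @return n x 3 matrix of tangential drift velocities (m/s).
#' @export
drift_velocity <- function(body, neighbor, contact, params, r_glyco = 5e-9) {
  stopifnot(contact$mode == "VTS")
  nrm <- vertex_normals(body$mesh, body$vertex_positions)
  vts <- list(tri = ifelse(is.na(contact$tri), 0L, contact$tri),
              dist = contact$dist, bary = contact$bary)
  cpp_drift_velocity(body$velocities, neighbor$velocities, nrm, vts,
                     neighbor$mesh$triangles, params$delta_fg,
                     si_value(r_glyco, "r_glyco"))
}

#' Bulk adsorption source/sink of mobile fibrinogen
#'
#' Net normal flux onto the surface layer: a constant recruitment term plus
#' a diffusive term following the bulk-to-surface concentration gradient,
#' `J_const = D n0 (phi0 - 1) / (phi0 (1.4 delta_fg)^2)` and
#' `J_diff = -D (N phi0 - n0) / (phi0 (1.4 delta_fg)^2)`. The two cancel at
#' the equilibrium density `N = n0` (zero net adsorption), and the source
#' is applied only on exposed surface (`r_sep >= delta_fg`); it vanishes in
#' the tight gap.
#'
#' @param n per-vertex normalized density.
#' @param contact a VTS [contact_query()] map (or NULL: all exposed).
#' @param params a [transport_params()] with `adsorption = TRUE`.
#' @return per-vertex rate (1/s).
#' @export
adsorption_source <- function(n, contact = NULL, params) {
  if (!params$adsorption)
    stop("configuration error: adsorption_source requires adsorption = TRUE")
  if (params$phi0 <= 0) stop("configuration error: phi0 must be > 0")
  rsep <- rep(Inf, length(n))
  if (!is.null(contact)) {
    rsep[contact$within_cutoff] <- contact$dist[contact$within_cutoff]
  }
  cpp_adsorption_source(n, rsep, unclass(params))
}

#' Advance the mobile-Fg density one transport step
#'
#' Finite-volume update of the convection-diffusion equation on the
#' median-dual control volumes of the (possibly deformed) surface:
#' cotangent-weighted Laplacian for diffusion, first-order upwind face
#' fluxes for the drift convection, explicit source term. The update
#' operates on the transported amount `N * Ai`, so the total amount is
#' conserved exactly when the source is off; sub-stepping is engaged
#' automatically when the diffusion/CFL bound requires it. Density stays
#' non-negative (upwinding).
#'
#' @param body an [rbc_body()].
#' @param drift n x 3 drift-velocity matrix (m/s), e.g. [drift_velocity()].
#' @param source per-vertex rate (1/s), e.g. [adsorption_source()].
#' @param dt time step (s).
#' @param params a [transport_params()].
#' @return the body with updated `n_mfg`.
#' @export
transport_step <- function(body, drift = NULL, source = NULL, dt, params) {
  nv <- body$mesh$n_vertices
  if (is.null(drift)) drift <- matrix(0, nv, 3)
  if (is.null(source)) source <- numeric(nv)
  body$n_mfg <- cpp_transport_step(body$vertex_positions,
                                   .mesh_list(body$mesh), body$n_mfg,
                                   drift, source, params$d_mfg, dt)
  body
}

#' Average bridge density in the intercellular gap
#'
#' Area-weighted mean, over in-contact vertices of both bodies, of the
#' local gap density `n_self(i) + n_other(nearest point)`; `NA` when the
#' contact is empty.
#'
#' @param body_a,body_b the two [rbc_body()] objects.
#' @param contact_a,contact_b VTS [contact_query()] maps a->b and b->a.
#' @return scalar average density (dimensionless), or `NA`.
#' @export
average_gap_density <- function(body_a, body_b, contact_a, contact_b) {
  acc_w <- 0; acc_n <- 0
  pair <- list(list(body_a, body_b, contact_a),
               list(body_b, body_a, contact_b))
  for (p in pair) {
    src <- p[[1]]; tgt <- p[[2]]; cm <- p[[3]]
    ok <- which(cm$within_cutoff)
    if (!length(ok)) next
    Ai <- median_dual_areas(src$mesh, src$vertex_positions)
    tv <- tgt$mesh$triangles[cm$tri[ok], , drop = FALSE]
    n_t <- cm$bary[ok, 1] * tgt$n_mfg[tv[, 1]] +
      cm$bary[ok, 2] * tgt$n_mfg[tv[, 2]] +
      cm$bary[ok, 3] * tgt$n_mfg[tv[, 3]]
    acc_w <- acc_w + sum(Ai[ok])
    acc_n <- acc_n + sum(Ai[ok] * (src$n_mfg[ok] + n_t))
  }
  if (acc_w == 0) return(NA_real_)
  acc_n / acc_w
}
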