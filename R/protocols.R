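#' Place two cells as a doublet with a prescribed surface gap
#'
#' Body 1 is centred at the origin with its face normal along z; body 2 is
#' shifted along x by `offset_frac * diameter` and lowered along z until
#' the minimum inter-surface (VTS) distance equals `gap`. The vertical
#' placement is solved by a few fixed-point iterations of the contact
#' query, which is robust for smooth convex-rim shapes.
#'
#' @param mesh a discocyte [tri_mesh()] (used for both cells).
#' @param offset_frac lateral center offset as a fraction of the diameter.
#' @param gap target minimum surface separation (m).
#' @param mode "VTS" (surface gap) or "VTV" (nearest-vertex gap).
#' @return list of two vertex-position matrices `x1`, `x2`.
#' @keywords internal
place_doublet <- function(mesh, offset_frac, gap, mode = "VTS") {
  V <- mesh$vertex_positions
  diam <- max(V[, 1]) - min(V[, 1])
  x1 <- V
  dx <- offset_frac * diam
  span <- max(V[, 3]) - min(V[, 3])
  zoff <- span + 10 * gap
  x2 <- V
  x2[, 1] <- x2[, 1] + dx
  x2[, 3] <- x2[, 3] + zoff
  big <- 4 * span + diam
  for (it in 1:12) {
    if (mode == "VTS") {
      cm <- cpp_contact_vts(x1, x2, mesh$triangles, big)
      d <- suppressWarnings(min(cm$dist[cm$tri > 0L]))
    } else {
      cm <- cpp_contact_vtv(x1, x2, big)
      d <- suppressWarnings(min(cm$dist[cm$idx > 0L]))
    }
    if (!is.finite(d)) stop("placement failed: surfaces out of range")
    shift <- d - gap
    if (abs(shift) < 0.02 * gap) break
    x2[, 3] <- x2[, 3] - shift
  }
  list(x1 = x1, x2 = x2)
}

# distal trap patch: vertices at the far end along `direction`*x covering
# `frac` of the cell surface area (by median-dual area)
.trap_patch <- function(mesh, vertices, frac, direction) {
  Ai <- median_dual_areas(mesh, vertices)
  x <- vertices[, 1] * direction
  ord <- order(x, decreasing = TRUE)
  csum <- cumsum(Ai[ord])
  keep <- ord[csum <= frac * sum(Ai)]
  if (!length(keep)) keep <- ord[1L]
  sort(keep)
}

.as_trajectory <- function(sim, config, params) {
  df <- as.data.frame(sim$trajectory)
  structure(df,
            class = c("cbmm_trajectory", "data.frame"),
            config = config, params = params,
            final = sim$final, peak_fot = sim$peak_fot,
            disp_at_peak = sim$disp_at_peak,
            escaped = sim$escaped, separated = sim$separated,
            t_end = sim$t_end)
}

#' @export
print.cbmm_trajectory <- function(x, ...) {
  cat(sprintf("cbmm_trajectory: %d samples, t = [%.3g, %.3g] s\n",
              nrow(x), x$time[1], x$time[nrow(x)]))
  cat(sprintf("  peak trap tension %.3g pN%s%s\n",
              attr(x, "peak_fot") * 1e12,
              if (isTRUE(attr(x, "escaped"))) " [escaped]" else "",
              if (isTRUE(attr(x, "separated"))) " [separated]" else ""))
  invisible(x)
}

# Resolution scaling for desk-scale meshes: the cross-bridge interaction
# lengths (1/beta, r0, r_cutoff, r_glyco, delta_fg) are defined relative to
# the ~200 nm adhesion-vertex spacing of the full-resolution model. On a
# coarser mesh they are stretched by s = spacing / 200 nm so that the
# contact zone stays resolved; mu_gap is scaled by s as well, which keeps
# both the adhesion energy per unit area and the Couette shear stress at
# the (scaled) zero-force gap unchanged.
.resolution_scale <- function(mesh, reference_spacing = 200e-9) {
  max(1, mean_vertex_spacing(mesh) / reference_spacing)
}

.scale_adhesion <- function(adhesion, s) {
  if (s == 1) return(adhesion)
  adhesion_params(gamma_ifgr = adhesion$gamma_ifgr,
                  gamma_ifg = adhesion$gamma_ifg,
                  gamma_mfg = adhesion$gamma_mfg,
                  beta = adhesion$beta / s,
                  r0 = adhesion$r0 * s,
                  r_cutoff = adhesion$r_cutoff * s,
                  r_glyco = adhesion$r_glyco * s,
                  mu_gap = adhesion$mu_gap * s,
                  eps_gap = adhesion$eps_gap)
}

# shared driver around the compiled simulation loop
.run_protocol <- function(mesh, membrane, adhesion, transport, config,
                          n_init, with_trap, length_scale = NULL) {
  body <- rbc_body(mesh, membrane, n_mfg = n_init)
  if (is.null(length_scale)) length_scale <- .resolution_scale(mesh)
  adhesion <- .scale_adhesion(adhesion, length_scale)
  transport <- transport_params(d_mfg = transport$d_mfg,
                                delta_fg = transport$delta_fg * length_scale,
                                adsorption = transport$adsorption,
                                phi0 = transport$phi0, n0 = transport$n0)
  dt <- config$dt
  if (is.null(dt)) dt <- stable_dt(body, adhesion)
  else if (dt > stable_dt(body, adhesion, safety = 1))
    stop("configuration error: dt exceeds the stability bound")

  mode0 <- if (adhesion$gamma_ifg > 0 || adhesion$gamma_mfg > 0) "VTS" else "VTV"
  pos <- place_doublet(mesh, config$initial_offset_frac, adhesion$r0, mode0)
  if (config$jitter > 0) {
    set.seed(config$rng_seed)
    pos$x1 <- pos$x1 + matrix(rnorm(length(pos$x1), sd = config$jitter),
                              ncol = 3)
    pos$x2 <- pos$x2 + matrix(rnorm(length(pos$x2), sd = config$jitter),
                              ncol = 3)
  }
  nv <- mesh$n_vertices
  state <- list(x1 = pos$x1, v1 = matrix(0, nv, 3),
                n1 = rep(n_init, length.out = nv),
                x2 = pos$x2, v2 = matrix(0, nv, 3),
                n2 = rep(n_init, length.out = nv))
  trap1 <- integer(0); trap2 <- integer(0)
  if (with_trap) {
    trap1 <- .trap_patch(mesh, pos$x1, config$trap_frac, -1)
    trap2i <- .trap_patch(mesh, pos$x2, config$trap_frac, +1)
    trap2 <- trap2i
  }
  transport_on <- adhesion$gamma_mfg > 0
  phys <- c(unclass(adhesion),
            list(d_mfg = transport$d_mfg, delta_fg = transport$delta_fg,
                 phi0 = transport$phi0, n0 = transport$n0,
                 adsorption = transport$adsorption,
                 transport_on = transport_on))
  ctrl <- list(dt = dt,
               t_end = if (with_trap) config$settle_time + config$duration
                       else config$duration,
               settle_t = if (with_trap) config$settle_time else 0,
               record_dt = config$snapshot_interval,
               pull_rate = if (with_trap) config$pulling_rate else 0,
               t_ramp = 0.25,
               escape_f = if (with_trap) config$escape_threshold else Inf,
               stop_on_sep = with_trap,
               trap1 = trap1, trap2 = trap2)
  sim <- cpp_simulate(.mesh_list(mesh), .mech_list(body),
                      .mesh_list(mesh), .mech_list(body),
                      state, phys, ctrl)
  .as_trajectory(sim, config,
                 list(membrane = membrane, adhesion = adhesion,
                      transport = transport, dt = dt,
                      n_vertices = nv, length_scale = length_scale,
                      trap1 = trap1, trap2 = trap2))
}

#' Run the doublet-formation protocol
#'
#' Two discocytes are initialized at point contact (minimum surface
#' separation `r0` at an ~0.8-diameter lateral offset, first touch at the
#' face-plateau margin) with no external
#' load and evolved for the configured duration. Non-specific VTS adhesion
#' drives spontaneous sliding growth of the contact; pure-VTV (specific
#' bridge) parameter sets remain locked at the initial point contact
#' because the inter-vertex spacing exceeds the interaction cutoff.
#'
#' @param config a [protocol_config()] with `protocol = "formation"`.
#' @param membrane a [membrane_params()].
#' @param adhesion an [adhesion_params()] (e.g. one formation preset row).
#' @param transport a [transport_params()].
#' @param mesh optional prebuilt discocyte [tri_mesh()]; default builds one
#'   with `n_vertices`.
#' @param n_vertices mesh resolution when `mesh` is NULL.
#' @param n_init initial normalized mobile-Fg density per surface.
#' @return a `cbmm_trajectory` (time, overlap, contact area, `n_ave`, ...).
#' @export
run_doublet_formation <- function(config = protocol_config("formation"),
                                  membrane = membrane_params(),
                                  adhesion = adhesion_params(),
                                  transport = transport_params(),
                                  mesh = NULL, n_vertices = 750,
                                  n_init = 1, length_scale = NULL) {
  if (config$protocol != "formation")
    stop("configuration error: config$protocol must be 'formation'")
  if (is.null(mesh)) mesh <- build_discocyte_mesh(n_vertices)
  .run_protocol(mesh, membrane, adhesion, transport, config, n_init,
                with_trap = FALSE, length_scale = length_scale)
}

#' Run the optical-tweezers disaggregation protocol
#'
#' An equilibrium doublet in crescent overlap (default 50% of the
#' diameter, surface gap `r0`, uniform mobile-Fg density) is first allowed
#' to conform during `settle_time` with the distal patches held, then the
#' patches (~2% of each cell's area at the far poles) are displaced in
#' opposite directions at the pulling rate. The recorded trap tension
#' `f_ot` is the reaction force required to enforce the motion; the run
#' ends at complete separation or when `f_ot` crosses the escape
#' threshold.
#'
#' @inheritParams run_doublet_formation
#' @param config a [protocol_config()] with `protocol = "disaggregation"`.
#' @return a `cbmm_trajectory`.
#' @export
run_ot_disaggregation <- function(config = protocol_config("disaggregation"),
                                  membrane = membrane_params(),
                                  adhesion = adhesion_params(),
                                  transport = transport_params(),
                                  mesh = NULL, n_vertices = 750,
                                  n_init = 1, length_scale = NULL) {
  if (config$protocol != "disaggregation")
    stop("configuration error: config$protocol must be 'disaggregation'")
  if (is.null(mesh)) mesh <- build_discocyte_mesh(n_vertices)
  .run_protocol(mesh, membrane, adhesion, transport, config, n_init,
                with_trap = TRUE, length_scale = length_scale)
}

#' Average doublet formation rate (to 80% of final overlap)
#'
#' Average rate of overlap-length growth up to the 80% point: the overlap
#' grown at 80% of the final grown overlap, divided by the time taken to
#' reach it. Growth is measured from the initial (geometric) overlap of
#' the point-contacted pair, so the metric reflects formed contact, not
#' the starting configuration. Returns 0 (with attribute
#' `no_growth = TRUE`) when the overlap never grows.
#'
#' @param traj a formation `cbmm_trajectory` (needs `time` and `overlap`).
#' @return speed in m/s.
#' @export
formation_rate <- function(traj) {
  ov <- traj$overlap - traj$overlap[1]
  tt <- traj$time
  final <- ov[length(ov)]
  if (!is.finite(final) || final <= 1e-9) {
    out <- 0
    attr(out, "no_growth") <- TRUE
    return(out)
  }
  i80 <- which(ov >= 0.8 * final)[1]
  if (i80 == 1L || tt[i80] <= 0) {
    out <- 0
    attr(out, "no_growth") <- TRUE
    return(out)
  }
  ov[i80] / tt[i80]
}

#' Adhesive contact area of a doublet
#'
#' Sum of the median-dual areas of vertices within the interaction cutoff
#' of the pairing surface, per cell, averaged over the two cells.
#'
#' @param body_a,body_b the two [rbc_body()] objects.
#' @param contact_a,contact_b VTS [contact_query()] maps (recomputed when
#'   NULL).
#' @param r_cutoff cutoff used when recomputing.
#' @return area in m^2.
#' @export
contact_area <- function(body_a, body_b, contact_a = NULL, contact_b = NULL,
                         r_cutoff = 100e-9) {
  if (is.null(contact_a))
    contact_a <- contact_query(body_a, body_b, r_cutoff, "VTS")
  if (is.null(contact_b))
    contact_b <- contact_query(body_b, body_a, r_cutoff, "VTS")
  a1 <- sum(median_dual_areas(body_a$mesh, body_a$vertex_positions)[
    contact_a$within_cutoff])
  a2 <- sum(median_dual_areas(body_b$mesh, body_b$vertex_positions)[
    contact_b$within_cutoff])
  0.5 * (a1 + a2)
}

#' Projected overlap length of the doublet silhouettes
#'
#' Overlap of the two cells' extents along the sliding/pulling axis (x);
#' 0 when the silhouettes are disjoint.
#'
#' @param body_a,body_b the two [rbc_body()] objects.
#' @return length in m.
#' @export
overlap_length <- function(body_a, body_b) {
  x1 <- body_a$vertex_positions[, 1]
  x2 <- body_b$vertex_positions[, 1]
  max(0, min(max(x1), max(x2)) - max(min(x1), min(x2)))
}

#' Segment a disaggregation tension curve into stages
#'
#' Splits the trap-tension-versus-displacement curve at its smoothed global
#' maximum into stage I (rising tension: adhesion-interface reorientation)
#' and stage II (declining tension: contact-area loss dominates). A curve
#' that is still rising at its end (e.g. a low-diffusivity CBMM run that
#' escapes the trap) is reported as single-stage.
#'
#' @param traj a disaggregation `cbmm_trajectory`.
#' @param smooth_window running-mean window (samples, made odd).
#' @return list with `peak_tension` (N), `disp_at_peak` (m),
#'   `stage_boundary` (row index), `single_stage` (logical).
#' @export
stage_segmentation <- function(traj, smooth_window = 9) {
  sel <- traj$displacement > 0
  if (!any(sel)) stop("state error: no pulling phase in trajectory")
  f <- traj$f_ot[sel]
  d <- traj$displacement[sel]
  k <- max(3L, as.integer(smooth_window))
  if (k %% 2L == 0L) k <- k + 1L
  if (length(f) > k) {
    fs <- stats::filter(f, rep(1 / k, k), sides = 2)
    fs[is.na(fs)] <- f[is.na(fs)]
  } else fs <- f
  ipk <- which.max(fs)
  tail_lo <- fs[length(fs)] >= 0.95 * fs[ipk]
  single <- ipk >= length(fs) - max(1L, k %/% 2L) || tail_lo
  list(peak_tension = max(f),
       disp_at_peak = d[which.max(f)],
       stage_boundary = ipk,
       single_stage = single)
}
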