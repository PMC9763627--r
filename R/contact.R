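#' Proximity query between two cell surfaces
#'
#' For every vertex of `source`, finds the nearest point of the `target`
#' surface within `r_cutoff`. In VTS mode the nearest point on the target
#' triangulation is returned (distance `r_vts`, unit direction `e_vts` from
#' the vertex toward that point, nearest triangle and its barycentric
#' coordinates); in VTV mode the nearest target vertex. Ties between
#' equidistant triangles/vertices break to the lowest index, and pairings
#' are recomputed per query (no persistent bonds). The velocity of the
#' nearest surface point is interpolated barycentrically so that relative
#' velocities `v_ij` are available for friction and drift.
#'
#' @param source,target [rbc_body()] objects (or lists with
#'   `vertex_positions`, `velocities` and a `mesh`).
#' @param r_cutoff interaction cutoff (m).
#' @param mode "VTS" or "VTV".
#' @return object of class `contact_map`: a list with per-source-vertex
#'   fields `within_cutoff`, `dist`, `dir`, `v_target`, `v_rel` and, for
#'   VTS, `tri` + `bary`, for VTV, `partner`.
#' @export
contact_query <- function(source, target, r_cutoff, mode = c("VTS", "VTV")) {
  mode <- match.arg(mode)
  if (r_cutoff <= 0) stop("configuration error: r_cutoff must be > 0")
  Xs <- source$vertex_positions
  Xt <- target$vertex_positions
  Vs <- source$velocities
  Vt <- target$velocities
  ns <- nrow(Xs)
  if (mode == "VTS") {
    raw <- cpp_contact_vts(Xs, Xt, target$mesh$triangles, r_cutoff)
    ok <- raw$tri > 0L
    vtg <- matrix(0, ns, 3)
    if (any(ok)) {
      tv <- target$mesh$triangles[pmax(raw$tri, 1L), , drop = FALSE]
      for (k in 1:3) {
        vtg[ok, ] <- vtg[ok, ] + raw$bary[ok, k] * Vt[tv[ok, k], , drop = FALSE]
      }
    }
    out <- list(mode = "VTS", within_cutoff = ok, dist = raw$dist,
                dir = raw$dir, tri = ifelse(ok, raw$tri, NA_integer_),
                bary = raw$bary, v_target = vtg, v_rel = Vs - vtg,
                r_cutoff = r_cutoff)
  } else {
    raw <- cpp_contact_vtv(Xs, Xt, r_cutoff)
    ok <- raw$idx > 0L
    vtg <- matrix(0, ns, 3)
    vtg[ok, ] <- Vt[raw$idx[ok], , drop = FALSE]
    out <- list(mode = "VTV", within_cutoff = ok, dist = raw$dist,
                dir = raw$dir, partner = ifelse(ok, raw$idx, NA_integer_),
                v_target = vtg, v_rel = Vs - vtg, r_cutoff = r_cutoff)
  }
  structure(out, class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map (%s): %d / %d vertices within %.3g nm cutoff\n",
              x$mode, sum(x$within_cutoff), length(x$within_cutoff),
              x$r_cutoff * 1e9))
  invisible(x)
}
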