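#' Create an RBC body: mesh + velocities + mobile-Fg density + mechanics
#'
#' Binds a [tri_mesh()] to membrane mechanical parameters, per-vertex
#' velocities and the normalized mobile-fibrinogen surface density field
#' (initialized uniform, representing a doublet equilibrated for a long
#' time). The cytoskeleton edge springs are calibrated per edge so that the
#' generated mesh is the stress-free reference state and the network shear
#' modulus equals `es0`:
#' a worm-like-chain attraction with `x0 = l0/lmax = 1/2.2` balanced at the
#' rest length by a power-law repulsion `kp / l^2`.
#'
#' @param mesh a [tri_mesh()].
#' @param params a [membrane_params()].
#' @param n_mfg initial normalized mobile-Fg density (scalar or per vertex).
#' @param velocities optional n x 3 matrix (m/s), default zero.
#' @return object of class `rbc_body`.
#' @export
rbc_body <- function(mesh, params = membrane_params(), n_mfg = 1,
                     velocities = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(params, "membrane_params"))
  nv <- mesh$n_vertices
  if (is.null(velocities)) velocities <- matrix(0, nv, 3)
  n_mfg <- rep_len(n_mfg, nv)
  if (any(n_mfg < 0)) stop("state error: negative mobile-Fg density")
  spring <- .calibrate_springs(mesh$rest_edge_lengths, params$es0)
  structure(list(mesh = mesh,
                 vertex_positions = mesh$vertex_positions,
                 velocities = velocities,
                 n_mfg = n_mfg,
                 params = params,
                 spring = spring),
            class = "rbc_body")
}

# WLC + power-law (m = 2) edge springs calibrated to the network shear
# modulus mu0 = es0 at each edge's own rest length (zero rest tension):
#   kBT/p = 4 l0 mu0 / (sqrt(3) (a + 3 b)),  kp = (kBT/p) b l0^2
# with x0 = 1/2.2,
#   a = x0/(2(1-x0)^3) - 1/(4(1-x0)^2) + 1/4
#   b = 1/(4(1-x0)^2) - 1/4 + x0
.calibrate_springs <- function(l0, es0, x0 = 1 / 2.2) {
  om <- 1 - x0
  a <- x0 / (2 * om^3) - 1 / (4 * om^2) + 0.25
  b <- 1 / (4 * om^2) - 0.25 + x0
  kbtp <- 4 * l0 * es0 / (sqrt(3) * (a + 3 * b))
  list(kbtp = kbtp, lmax = l0 / x0, kpow = kbtp * b * l0^2)
}

# flatten body + params into the list layout the C++ kernels expect
.mech_list <- function(body) {
  p <- body$params
  list(spring_kbtp = body$spring$kbtp,
       spring_lmax = body$spring$lmax,
       spring_kpow = body$spring$kpow,
       kb = 2 * p$eb / sqrt(3),
       ka = p$ka, kd = p$kd, kv = p$k_omega,
       eta_t = p$eta_t, eta_c = p$eta_c,
       mass_vertex = p$mass_total / body$mesh$n_vertices)
}

.mesh_list <- function(mesh) {
  list(triangles = mesh$triangles, edges = mesh$edges,
       dihedral_quads = mesh$dihedral_quads,
       n_vertices = mesh$n_vertices,
       rest_edge_lengths = mesh$rest_edge_lengths,
       rest_dihedral_angles = mesh$rest_dihedral_angles,
       rest_tri_areas = mesh$rest_tri_areas,
       rest_total_area = mesh$rest_total_area,
       rest_total_volume = mesh$rest_total_volume)
}

#' @export
print.rbc_body <- function(x, ...) {
  cat(sprintf("rbc_body: %d vertices, mean n_mfg %.3f\n",
              x$mesh$n_vertices, mean(x$n_mfg)))
  invisible(x)
}
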