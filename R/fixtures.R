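#' Deterministic small geometries for unit tests
#'
#' * `"flat_patch"`: planar triangulated sheet with known analytic areas
#'   (arguments `nx`, `ny`, `spacing`).
#' * `"sphere_pair"`: two spheres with a prescribed pole-to-pole `gap`
#'   (arguments `n`, `radius`, `gap`); the minimum VTS distance equals the
#'   gap at the facing poles.
#' * `"coarse_discocyte_pair"`: two coarse discocytes placed at point
#'   contact (arguments `n`, `gap`, `offset_frac`).
#'
#' @param kind fixture type.
#' @param ... fixture-specific arguments, see above.
#' @return for `"flat_patch"` a [tri_mesh()]; for the pair fixtures a list
#'   of two [rbc_body()] objects.
#' @export
make_fixture <- function(kind = c("flat_patch", "sphere_pair",
                                  "coarse_discocyte_pair"), ...) {
  kind <- match.arg(kind)
  args <- list(...)
  if (kind == "flat_patch") {
    return(build_flat_patch(nx = args$nx %||% 20L, ny = args$ny %||% 20L,
                            spacing = args$spacing %||% 1e-7))
  }
  if (kind == "sphere_pair") {
    n <- args$n %||% 300L
    radius <- args$radius %||% 1e-6
    gap <- args$gap %||% 20e-9
    mesh <- build_sphere_mesh(n, radius)
    b1 <- rbc_body(mesh, membrane_params())
    b2 <- rbc_body(mesh, membrane_params())
    shift <- 2 * radius + gap
    b2$vertex_positions[, 3] <- b2$vertex_positions[, 3] + shift
    return(list(b1, b2))
  }
  n <- args$n %||% 300L
  gap <- args$gap %||% 20e-9
  offset <- args$offset_frac %||% 0.95
  mesh <- build_discocyte_mesh(n)
  pos <- place_doublet(mesh, offset, gap, "VTS")
  b1 <- rbc_body(mesh, membrane_params())
  b2 <- rbc_body(mesh, membrane_params())
  b1$vertex_positions <- pos$x1
  b2$vertex_positions <- pos$x2
  list(b1, b2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
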