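# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

fx_coarse_discocyte <- function(n = 150) {
  key <- paste0("disc", n)
  if (is.null(.fx[[key]])) .fx[[key]] <- build_discocyte_mesh(n)
  .fx[[key]]
}

fx_patch <- function(nx = 12, ny = 12, spacing = 1e-7) {
  key <- paste("patch", nx, ny, spacing)
  if (is.null(.fx[[key]])) .fx[[key]] <- build_flat_patch(nx, ny, spacing)
  .fx[[key]]
}

# independent point-triangle closest distance: plane projection + closed-form
# segment distances (different algorithm than the package's kernel)
pt_tri_dist_oracle <- function(p, a, b, c) {
  n <- pracma_cross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  seg <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(1, max(0, t))
    sqrt(sum((u + t * d - p)^2))
  }
  if (nn > 0) {
    nh <- n / nn
    q <- p - sum((p - a) * nh) * nh
    # barycentric test of the projection
    v0 <- b - a; v1 <- c - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1) return(abs(sum((p - a) * nh)))
  }
  min(seg(p, a, b), seg(p, b, c), seg(p, c, a))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# membrane parameter set with only selected energy terms active (the k0
# identity is kept consistent)
mp_only <- function(es0 = 0, eb = 0, ka = 0, kd = 0, kv = 0, eta_m = 0.7e-6) {
  membrane_params(es0 = max(es0, 1e-12), eb = eb, ka = ka, kd = kd,
                  k0 = 2 * max(es0, 1e-12) + ka + kd, k_omega = kv,
                  eta_m = eta_m)
}

# central finite difference of a scalar energy functional
fd_gradient <- function(fun, V, idx, h = 1e-11) {
  g <- matrix(0, length(idx), 3)
  for (r in seq_along(idx)) for (k in 1:3) {
    Vp <- V; Vp[idx[r], k] <- Vp[idx[r], k] + h
    Vm <- V; Vm[idx[r], k] <- Vm[idx[r], k] - h
    g[r, k] <- (fun(Vp) - fun(Vm)) / (2 * h)
  }
  g
}
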