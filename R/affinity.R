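#' Total cross-bridge adhesion affinity
#'
#' Composes the adhesion affinity from the three bridge populations:
#' `gamma_ifgr + gamma_ifg + (n1 + n2) * gamma_mfg`, where `n1`, `n2` are
#' the normalized mobile-Fg densities contributed by the two cell surfaces
#' in the gap. With `gamma_mfg = 0` this reduces to the uniform affinity
#' model (UAM).
#'
#' @param params an [adhesion_params()].
#' @param n1,n2 normalized mobile-Fg densities (>= 0), vectorized.
#' @return affinity in J/m^2.
#' @export
total_affinity <- function(params, n1 = 0, n2 = 0) {
  if (any(n1 < 0) || any(n2 < 0))
    stop("state error: negative mobile-Fg density")
  params$gamma_ifgr + params$gamma_ifg + (n1 + n2) * params$gamma_mfg
}

#' Pathophysiological affinity composition
#'
#' Initial total affinity under pathophysiological scaling:
#' `gamma_ifg + n_star * (n_b1 + n_b2) * gamma_star * gamma_mfg_b`, together
#' with the corresponding starting gap density
#' `n_ave_t0 = n_star * (n_b1 + n_b2)` used to initialize the per-surface
#' density fields of a protocol run.
#'
#' @param p a [pathophys_params()].
#' @param gamma_ifg immobile non-specific affinity (J/m^2).
#' @return list with `gamma_affin` (J/m^2) and `n_ave_t0`.
#' @export
pathophys_affinity <- function(p, gamma_ifg = 1e-6) {
  gamma_ifg <- si_value(gamma_ifg, "gamma_ifg")
  list(gamma_affin = gamma_ifg +
         p$n_star * (p$n_b1 + p$n_b2) * p$gamma_star * p$gamma_mfg_b,
       n_ave_t0 = p$n_star * (p$n_b1 + p$n_b2))
}

#' Morse-type cross-bridge interaction energy
#'
#' `U = Gamma * (exp(2 beta (r0 - r)) - 2 exp(beta (r0 - r))) * Ai` for
#' `r <= r_cutoff`, 0 beyond. The minimum is `-Gamma * Ai` at `r = r0`.
#'
#' @param rsep separation distance(s) (m).
#' @param gamma adhesion affinity (J/m^2).
#' @param beta spatial decay coefficient (1/m).
#' @param r0 zero-force separation (m).
#' @param r_cutoff cutoff separation (m).
#' @param ai local adhesion area (m^2).
#' @return energy in J (vectorized over `rsep`).
#' @export
morse_energy <- function(rsep, gamma, beta, r0, r_cutoff, ai) {
  stopifnot(all(rsep >= 0))
  y <- beta * (r0 - rsep)
  ifelse(rsep > r_cutoff, 0, gamma * (exp(2 * y) - 2 * exp(y)) * ai)
}

#' Morse-type cross-bridge force magnitude
#'
#' Negative radial derivative of [morse_energy()]:
#' `F = Gamma * Ai * (2 beta exp(beta (r0 - r)) - 2 beta exp(2 beta (r0 - r)))`,
#' positive = attraction (directed toward the pairing surface), zero at
#' `r = r0` and beyond `r_cutoff`.
#'
#' @inheritParams morse_energy
#' @return force magnitude in N (vectorized over `rsep`).
#' @export
morse_force <- function(rsep, gamma, beta, r0, r_cutoff, ai) {
  y <- beta * (r0 - rsep)
  ifelse(rsep > r_cutoff, 0, gamma * ai * 2 * beta * (exp(y) - exp(2 * y)))
}
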