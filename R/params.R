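#' Membrane mechanical parameters
#'
#' Coarse-grained particle model constants of the RBC membrane. The
#' effective area compressibility `k0` must satisfy `k0 = 2*es0 + ka + kd`
#' (checked at construction to 1e-3 relative). The membrane viscosity
#' `eta_m` maps to the pairwise dissipative coefficients via
#' `eta_t = 12*eta_m/(13*sqrt(3))`, `eta_c = eta_t/3`.
#'
#' The per-vertex mass is a fictitious numerical mass (`mass_total /
#' n_vertices`) chosen so that the dynamics are overdamped and quasi-static
#' at the micrometre-per-second loading rates of the protocols; inertial
#' forces are then negligible against the piconewton-scale adhesion forces.
#'
#' @param es0 resting shear elastic modulus (N/m).
#' @param eb bending modulus (J).
#' @param ka global area compressibility coefficient (N/m).
#' @param kd local area compressibility coefficient (N/m).
#' @param k0 effective area compressibility modulus (N/m).
#' @param k_omega volume penalty coefficient (J/m^3).
#' @param eta_m membrane viscosity (N s/m).
#' @param mass_total total fictitious membrane mass (kg).
#' @return object of class `membrane_params`.
#' @export
membrane_params <- function(es0 = 6.54e-6,
                            eb = 2.4e-19,
                            ka = 0.288,
                            kd = 0.144,
                            k0 = 0.432,
                            k_omega = 220,
                            eta_m = 0.7e-6,
                            mass_total = 1e-5) {
  es0 <- si_value(es0, "es0"); eb <- si_value(eb, "eb")
  ka <- si_value(ka, "ka"); kd <- si_value(kd, "kd")
  k0 <- si_value(k0, "k0"); k_omega <- si_value(k_omega, "k_omega")
  eta_m <- si_value(eta_m, "eta_m"); mass_total <- si_value(mass_total, "mass_total")
  if (abs(2 * es0 + ka + kd - k0) > 1e-3 * k0)
    stop("configuration error: k0 must equal 2*es0 + ka + kd (got ",
         format(2 * es0 + ka + kd), " vs k0 = ", format(k0), ")")
  eta_t <- 12 * eta_m / (13 * sqrt(3))
  structure(list(es0 = es0, eb = eb, ka = ka, kd = kd, k0 = k0,
                 k_omega = k_omega, eta_m = eta_m,
                 eta_t = eta_t, eta_c = eta_t / 3,
                 mass_total = mass_total),
            class = "membrane_params")
}

#' Cross-bridge adhesion and intercellular friction parameters
#'
#' Affinities are adhesion energies per unit area (J/m^2): `gamma_ifgr`
#' for specific receptor-bound bridges (VTV scheme), `gamma_ifg` for
#' immobile non-specific bridges (VTS scheme) and `gamma_mfg` for mobile
#' non-specific bridges per unit normalized density (VTS scheme).
#'
#' @param gamma_ifgr specific-bridge affinity (J/m^2), VTV.
#' @param gamma_ifg immobile non-specific affinity (J/m^2), VTS.
#' @param gamma_mfg mobile non-specific affinity per unit density (J/m^2).
#' @param beta Morse spatial decay coefficient (1/m).
#' @param r0 zero-force separation distance (m).
#' @param r_cutoff cutoff separation distance (m).
#' @param r_glyco glycocalyx height (m).
#' @param mu_gap intercellular gap plasma viscosity (Pa s).
#' @param eps_gap lower clamp on the effective Couette gap (m).
#' @return object of class `adhesion_params`.
#' @export
adhesion_params <- function(gamma_ifgr = 0,
                            gamma_ifg = 0,
                            gamma_mfg = 0,
                            beta = 5e7,
                            r0 = 20e-9,
                            r_cutoff = 100e-9,
                            r_glyco = 5e-9,
                            mu_gap = 3.6e-3,
                            eps_gap = 1e-9) {
  p <- list(gamma_ifgr = si_value(gamma_ifgr, "gamma_ifgr"),
            gamma_ifg = si_value(gamma_ifg, "gamma_ifg"),
            gamma_mfg = si_value(gamma_mfg, "gamma_mfg"),
            beta = si_value(beta, "beta"),
            r0 = si_value(r0, "r0"),
            r_cutoff = si_value(r_cutoff, "r_cutoff"),
            r_glyco = si_value(r_glyco, "r_glyco"),
            mu_gap = si_value(mu_gap, "mu_gap"),
            eps_gap = si_value(eps_gap, "eps_gap"))
  if (p$r0 <= 0 || p$r_cutoff <= p$r0)
    stop("configuration error: need 0 < r0 < r_cutoff")
  if (p$beta <= 0) stop("configuration error: beta must be > 0")
  if (min(p$gamma_ifgr, p$gamma_ifg, p$gamma_mfg) < 0)
    stop("configuration error: affinities must be >= 0")
  structure(p, class = "adhesion_params")
}

#' Mobile-bridge surface transport parameters
#'
#' @param d_mfg surface diffusivity of mobile fibrinogen (m^2/s).
#' @param delta_fg hydrodynamic size of the adsorbed mobile Fg (m).
#' @param adsorption logical; enable the bulk adsorption source/sink.
#' @param phi0 surface-to-bulk concentration ratio at equilibrium.
#' @param n0 initial (equilibrium) normalized surface density per cell.
#' @return object of class `transport_params`.
#' @export
transport_params <- function(d_mfg = 1e-15,
                             delta_fg = 45e-9,
                             adsorption = FALSE,
                             phi0 = 1,
                             n0 = 1) {
  p <- list(d_mfg = si_value(d_mfg, "d_mfg"),
            delta_fg = si_value(delta_fg, "delta_fg"),
            adsorption = isTRUE(adsorption),
            phi0 = si_value(phi0, "phi0"),
            n0 = si_value(n0, "n0"))
  if (p$d_mfg < 0) stop("configuration error: d_mfg must be >= 0")
  if (p$delta_fg <= 0) stop("configuration error: delta_fg must be > 0")
  if (p$adsorption && p$phi0 <= 0)
    stop("configuration error: phi0 must be > 0 when adsorption is on")
  structure(p, class = "transport_params")
}

#' Pathophysiological scaling parameters
#'
#' Multipliers applied to the baseline mobile-bridge state: `n_star` scales
#' the equilibrium surface concentration of adsorbed fibrinogen and
#' `gamma_star` scales the mobile-bridge affinity, representing the clinical
#' span from healthy plasma (`n_star = 1..1.5`, `gamma_star = 1`) to SLE
#' hyper-aggregation (`n_star = 1.5`, `gamma_star = 2`).
#'
#' @param n_star surface concentration multiplier (> 0).
#' @param gamma_star affinity multiplier (> 0).
#' @param n_b1,n_b2 baseline normalized surface densities of the two cells.
#' @param gamma_mfg_b baseline mobile affinity (J/m^2).
#' @return object of class `pathophys_params`.
#' @export
pathophys_params <- function(n_star = 1, gamma_star = 1,
                             n_b1 = 1, n_b2 = 1,
                             gamma_mfg_b = 0.25e-6) {
  if (n_star <= 0 || gamma_star <= 0)
    stop("configuration error: n_star and gamma_star must be > 0")
  structure(list(n_star = n_star, gamma_star = gamma_star,
                 n_b1 = n_b1, n_b2 = n_b2,
                 gamma_mfg_b = si_value(gamma_mfg_b, "gamma_mfg_b")),
            class = "pathophys_params")
}

#' Protocol settings for the doublet experiments
#'
#' @param protocol "formation" or "disaggregation".
#' @param duration simulated physical time after any settling phase (s).
#' @param dt mechanics time step (s); `NULL` = use [stable_dt()].
#' @param pulling_rate optical-trap displacement rate per cell end (m/s).
#' @param trap_frac fraction of cell surface area held in each distal patch.
#' @param escape_threshold trap escape tension (N); the run stops when the
#'   trap reaction force exceeds it.
#' @param settle_time initial trap-free phase letting the doublet relax to its
#'   own adhesion equilibrium before the traps engage (s).
#' @param initial_offset_frac center-to-center lateral offset as a fraction
#'   of the cell diameter (formation start: ~0.8 = point contact at the face plateau margin;
#'   disaggregation start: ~0.5 = crescent overlap).
#' @param snapshot_interval trajectory recording interval (s).
#' @param rng_seed seed for the optional initial vertex jitter.
#' @param jitter amplitude of the optional initial perturbation (m).
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(protocol = c("formation", "disaggregation"),
                            duration = 40,
                            dt = NULL,
                            pulling_rate = 0.15e-6,
                            trap_frac = 0.02,
                            escape_threshold = 32e-12,
                            settle_time = 4,
                            initial_offset_frac = NULL,
                            snapshot_interval = 0.05,
                            rng_seed = 1L,
                            jitter = 0) {
  protocol <- match.arg(protocol)
  if (is.null(initial_offset_frac))
    initial_offset_frac <- if (protocol == "formation") 0.8 else 0.5
  duration <- si_value(duration, "duration")
  pulling_rate <- si_value(pulling_rate, "pulling_rate")
  if (duration <= 0) stop("configuration error: duration must be > 0")
  if (pulling_rate < 0) stop("configuration error: pulling_rate must be >= 0")
  structure(list(protocol = protocol, duration = duration, dt = dt,
                 pulling_rate = pulling_rate, trap_frac = trap_frac,
                 escape_threshold = si_value(escape_threshold, "escape_threshold"),
                 settle_time = si_value(settle_time, "settle_time"),
                 initial_offset_frac = initial_offset_frac,
                 snapshot_interval = si_value(snapshot_interval, "snapshot_interval"),
                 rng_seed = as.integer(rng_seed), jitter = si_value(jitter, "jitter")),
            class = "protocol_config")
}
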