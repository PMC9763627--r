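#' Named parameter presets for the published simulation sets
#'
#' Returns a complete run configuration (membrane + adhesion + transport +
#' pathophysiology + protocol) for the named simulation row:
#'
#' * `"table2.groupA.0.5"` / `".1.0"` / `".1.5"` -- pure mobile
#'   non-specific bridging (mFgB, VTS), friction-optimized, formation.
#' * `"table2.groupB.*"` -- immobile non-specific (iFgB, VTS) formation.
#' * `"table2.groupC.*"` -- mixed mobile VTS + specific VTV.
#' * `"table2.groupD.*"` -- mixed immobile VTS + specific VTV.
#' * `"table2.groupE.*"` -- pure specific bridging (iFgRB, VTV).
#' * `"table2.low_friction"`, `"table2.long_range"` -- friction variants.
#' * `"table3.uam.0.5" ... "table3.uam.5.0"` -- UAM disaggregation.
#' * `"table3.cbmm.highD"` / `".modD"` / `".lowD"` -- CBMM disaggregation
#'   at mobile-Fg diffusivity 1.8e-11 / 1e-14 / 1e-15 m^2/s.
#' * `"table3.cbmm.phi0.001"` / `".phi0.01"` / `".phi0.1"` / `".phi2"` /
#'   `".phi10"` -- CBMM with the bulk adsorption source on.
#' * `"table4.healthy_lower"` / `".healthy_median"` / `".healthy_upper"` /
#'   `".nstar2"` / `".sle_median"` -- pathophysiological scaling
#'   (`n_star`, `gamma_star`) of the baseline CBMM.
#'
#' Affinities are in uJ/m^2 in the names; all values are stored in SI.
#'
#' @param name preset name (see above).
#' @return list with `membrane`, `adhesion`, `transport`, `pathophys`,
#'   `protocol`, `n_init` and `label`.
#' @export
cbmm_preset <- function(name) {
  tab <- .preset_table()
  row <- tab[[name]]
  if (is.null(row))
    stop("configuration error: unknown preset '", name, "'; see ?cbmm_preset")
  row
}

#' @rdname cbmm_preset
#' @export
cbmm_preset_names <- function() names(.preset_table())

.preset_table <- function() {
  uJ <- 1e-6
  base_adh <- function(ifgr = 0, ifg = 0, mfg = 0, r0 = 20e-9,
                       rcut = 100e-9, rgly = 5e-9, mugap = 3.6e-3)
    adhesion_params(gamma_ifgr = ifgr * uJ, gamma_ifg = ifg * uJ,
                    gamma_mfg = mfg * uJ, beta = 5e7, r0 = r0,
                    r_cutoff = rcut, r_glyco = rgly, mu_gap = mugap)
  form <- function(adh, d = 1e-15, n_init = 1, label) {
    list(membrane = membrane_params(), adhesion = adh,
         transport = transport_params(d_mfg = d, adsorption = FALSE),
         pathophys = pathophys_params(),
         protocol = protocol_config("formation"),
         n_init = n_init, label = label)
  }
  disagg <- function(adh, d = 1e-15, ads = FALSE, phi0 = 1, n_init = 1,
                     label) {
    list(membrane = membrane_params(), adhesion = adh,
         transport = transport_params(d_mfg = d, adsorption = ads,
                                      phi0 = phi0, n0 = n_init),
         pathophys = pathophys_params(),
         protocol = protocol_config("disaggregation"),
         n_init = n_init, label = label)
  }
  out <- list()
  # ---- formation groups (table2.*), three affinity levels each
  lv <- c("0.5" = 0.5, "1.0" = 1, "1.5" = 1.5)
  for (nm in names(lv)) {
    g <- lv[[nm]]
    out[[paste0("table2.groupA.", nm)]] <-
      form(base_adh(mfg = g / 2), label = paste0("Group A ", nm))
    out[[paste0("table2.groupB.", nm)]] <-
      form(base_adh(ifg = g), label = paste0("Group B ", nm))
    out[[paste0("table2.groupC.", nm)]] <-
      form(base_adh(ifgr = if (g == 1.5) 0.5 else g / 2,
                    mfg = if (g == 1.5) 0.5 else g / 4),
           label = paste0("Group C ", nm))
    out[[paste0("table2.groupD.", nm)]] <-
      form(base_adh(ifgr = if (g == 1.5) 0.5 else g / 2,
                    ifg = if (g == 1.5) 1 else g / 2),
           label = paste0("Group D ", nm))
    out[[paste0("table2.groupE.", nm)]] <-
      form(base_adh(ifgr = g), label = paste0("Group E ", nm))
  }
  out[["table2.low_friction"]] <-
    form(base_adh(ifg = 1, rgly = 0, mugap = 1.8e-3), label = "low friction")
  out[["table2.long_range"]] <-
    form(base_adh(ifg = 1, r0 = 500e-9, rcut = 2000e-9, rgly = 0,
                  mugap = 1.8e-3), label = "long-range MP")
  # ---- disaggregation rows (table3.*)
  for (g in c(0.5, 1, 1.5, 2, 3.5, 5)) {
    out[[sprintf("table3.uam.%.1f", g)]] <-
      disagg(base_adh(ifg = g), label = sprintf("UAM %.1f uJ/m^2", g))
  }
  out[["table3.cbmm.highD"]] <-
    disagg(base_adh(ifg = 1, mfg = 0.25), d = 1.8e-11, label = "CBMM high D")
  out[["table3.cbmm.modD"]] <-
    disagg(base_adh(ifg = 1, mfg = 0.25), d = 1e-14, label = "CBMM moderate D")
  out[["table3.cbmm.lowD"]] <-
    disagg(base_adh(ifg = 1, mfg = 0.25), d = 1e-15, label = "CBMM low D")
  for (ph in c(0.001, 0.01, 0.1, 2, 10)) {
    out[[paste0("table3.cbmm.phi", sub("^0\\.", "0.", format(ph)))]] <-
      disagg(base_adh(ifg = 1, mfg = 0.25), d = 1e-15, ads = TRUE,
             phi0 = ph, label = paste0("CBMM phi0 = ", ph))
  }
  # ---- pathophysiology rows (table4.*; baseline CBMM, adsorption on, phi0 0.001)
  patho <- function(nstar, gstar, label) {
    pp <- pathophys_params(n_star = nstar, gamma_star = gstar)
    cfg <- disagg(base_adh(ifg = 1, mfg = 0.25 * gstar), d = 1e-15,
                  ads = TRUE, phi0 = 0.001, n_init = nstar, label = label)
    cfg$pathophys <- pp
    cfg
  }
  out[["table4.healthy_lower"]] <- patho(1, 1, "healthy lower (N*=1)")
  out[["table4.healthy_median"]] <- patho(1.25, 1, "healthy median (N*=1.25)")
  out[["table4.healthy_upper"]] <- patho(1.5, 1, "healthy upper (N*=1.5)")
  out[["table4.nstar2"]] <- patho(2, 1, "N*=2")
  out[["table4.sle_median"]] <- patho(1.5, 2, "SLE median (N*=1.5, G*=2)")
  out
}
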