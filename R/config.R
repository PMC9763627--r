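#' Load and validate a run configuration file
#'
#' YAML configuration with sections `membrane`, `adhesion`, `transport`,
#' `pathophys` and `protocol`; every physical quantity may carry an
#' explicit unit suffix ("20 nm", "3.6 cP", "6.54 uN/m") and is converted
#' to SI on load. Alternatively a single `preset: <name>` key resolves a
#' named parameter-table preset (see [cbmm_preset()]), with any further
#' keys overriding the preset. Unknown keys are rejected; the
#' relation `k0 = 2 es0 + ka + kd` is enforced at load time.
#'
#' @param path YAML file.
#' @return list with validated `membrane`, `adhesion`, `transport`,
#'   `pathophys`, `protocol` parameter objects (plus `n_init`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

#' @rdname load_config
#' @param raw a nested list as parsed from YAML.
#' @export
build_run_config <- function(raw) {
  known_sections <- c("preset", "membrane", "adhesion", "transport",
                      "pathophys", "protocol", "n_init", "output", "log_level")
  bad <- setdiff(names(raw), known_sections)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "))
  cfg <- if (!is.null(raw$preset)) cbmm_preset(raw$preset) else
    list(membrane = membrane_params(), adhesion = adhesion_params(),
         transport = transport_params(), pathophys = pathophys_params(),
         protocol = protocol_config("formation"), n_init = 1)
  apply_over <- function(builder, current, over, section) {
    if (is.null(over)) return(current)
    allowed <- names(formals(builder))
    bad <- setdiff(names(over), allowed)
    if (length(bad))
      stop("configuration error at '", section, "': unknown key(s): ",
           paste(bad, collapse = ", "))
    args <- modifyList(lapply(unclass(current), identity)[
      intersect(names(current), allowed)], over)
    do.call(builder, args)
  }
  cfg$membrane <- apply_over(membrane_params, cfg$membrane, raw$membrane,
                             "membrane")
  cfg$adhesion <- apply_over(adhesion_params, cfg$adhesion, raw$adhesion,
                             "adhesion")
  cfg$transport <- apply_over(transport_params, cfg$transport, raw$transport,
                              "transport")
  cfg$pathophys <- apply_over(pathophys_params, cfg$pathophys, raw$pathophys,
                              "pathophys")
  cfg$protocol <- apply_over(protocol_config, cfg$protocol, raw$protocol,
                             "protocol")
  if (!is.null(raw$n_init)) cfg$n_init <- si_value(raw$n_init, "n_init")
  cfg$output <- raw$output
  cfg
}
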