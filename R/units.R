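#' Convert a unit-suffixed quantity to SI
#'
#' Configuration files carry explicit unit suffixes ("20 nm", "3.6 cP",
#' "6.54 uN/m"). This parses such strings into plain SI numbers; bare
#' numerics are passed through unchanged (assumed SI already).
#'
#' @param x a numeric, or a string "value unit".
#' @param what optional key path used in error messages.
#' @return numeric scalar in SI units.
#' @examples
#' si_value("100 nm")   # 1e-7
#' si_value("3.6 cP")   # 3.6e-3
#' @export
si_value <- function(x, what = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("configuration error at '", what, "': expected number or 'value unit' string")
  parts <- strsplit(trimws(x), "\\s+")[[1]]
  if (length(parts) == 1L) {
    val <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(val))
      stop("configuration error at '", what, "': unit missing or value unparseable in '", x, "'")
    return(val)
  }
  val <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(val))
    stop("configuration error at '", what, "': cannot parse numeric part of '", x, "'")
  unit <- paste(parts[-1], collapse = "")
  fac <- .si_unit_table[[unit]]
  if (is.null(fac))
    stop("configuration error at '", what, "': unknown unit '", unit, "'")
  val * fac
}

.si_unit_table <- list(
  # length
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  # time
  "s" = 1, "ms" = 1e-3,
  # inverse length
  "1/nm" = 1e9, "nm^-1" = 1e9, "1/m" = 1, "m^-1" = 1,
  # viscosity
  "Pa.s" = 1, "Pa*s" = 1, "mPa.s" = 1e-3, "cP" = 1e-3,
  # force
  "N" = 1, "mN" = 1e-3, "uN" = 1e-6, "nN" = 1e-9, "pN" = 1e-12,
  # tension / membrane moduli
  "N/m" = 1, "mN/m" = 1e-3, "uN/m" = 1e-6, "nN/m" = 1e-9,
  # viscosity (surface)
  "N.s/m" = 1, "uN.s/m" = 1e-6,
  # energy
  "J" = 1, "uJ" = 1e-6,
  # surface energy / affinity
  "J/m^2" = 1, "uJ/m^2" = 1e-6, "mJ/m^2" = 1e-3,
  # diffusivity
  "m^2/s" = 1, "um^2/s" = 1e-12,
  # volume penalty (pressure-like)
  "J/m^3" = 1, "N/m^2" = 1, "Pa" = 1, "N/m^3" = 1,
  # mass
  "kg" = 1, "g" = 1e-3,
  # velocity
  "m/s" = 1, "um/s" = 1e-6, "nm/s" = 1e-9,
  # area
  "m^2" = 1, "um^2" = 1e-12
)
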