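#' Physical constants used throughout the package
#'
#' Bundles the thermal energy and the reference dimensions of bare DNA used
#' by the polymer, helix and AFM modules. The thermal energy defaults to
#' 4.11 pN nm (298 K) and is configurable for other temperatures.
#'
#' @param kBT Thermal energy in pN nm. Default 4.11 (298 K).
#' @param dsdna_rise Axial rise of B-form dsDNA in nm per bp. Default 0.34.
#' @param dsdna_radius Radius of the dsDNA helix in nm. Default 1.0.
#' @param ssdna_contour_per_nt Contour length of bare ssDNA in nm per nt.
#'   Default 0.56.
#'
#' @return A list of class `sm_constants` with the four constants.
#' @examples
#' const <- sm_constants()
#' const$kBT
#' @export
sm_constants <- function(kBT = 4.11, dsdna_rise = 0.34, dsdna_radius = 1.0,
                         ssdna_contour_per_nt = 0.56) {
  vals <- c(kBT = kBT, dsdna_rise = dsdna_rise, dsdna_radius = dsdna_radius,
            ssdna_contour_per_nt = ssdna_contour_per_nt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("all physical constants must be finite and positive")
  }
  structure(as.list(vals), class = "sm_constants")
}
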