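# Mutation of the exoenzyme allocation trait at cell division.

#' Mutate an allocation trait value
#'
#' With probability `p_mut` the daughter's trait is drawn from a normal
#' distribution centred on the maternal value with standard deviation
#' `sigma_mut`, constrained to `[0, 1]` by rejection sampling (draws outside
#' the interval are redrawn rather than clipped, so no probability mass
#' accumulates at the boundaries); otherwise the maternal value is inherited
#' unchanged.
#'
#' @param phi_parent maternal trait value in `[0, 1]`.
#' @param params a [soil_params()] object (uses `p_mut`, `sigma_mut`).
#' @return the daughter's trait value.
#' @examples
#' p <- soil_params(p_mut = 1, sigma_mut = 0.05)
#' mutate_trait(0.5, p)
#' @export
mutate_trait <- function(phi_parent, params) {
  if (phi_parent < 0 || phi_parent > 1) stop("phi_parent must lie in [0, 1]")
  if (params$p_mut <= 0 || stats::runif(1) >= params$p_mut) return(phi_parent)
  if (params$sigma_mut <= 0) return(phi_parent)
  repeat {
    v <- stats::rnorm(1, phi_parent, params$sigma_mut)
    if (v >= 0 && v <= 1) return(v)
  }
}
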