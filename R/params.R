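# Model parameters: defaults, validation, system-size rescaling.

# Unit-volume (k = 1) defaults. The volume-dependent parameters I_C, I_D,
# K_m and theta are expressed per unit soil volume V (the volume expected to
# hold a single cell); soil_params() rescales them to the requested system
# size k before returning.
.unit_defaults <- list(
  V          = 1e-9,    # cm^3, unit soil volume of one cell
  k          = 1,       # system size (unit volumes per microsite)
  L          = 10,      # lattice side length (microsites)
  phi        = 0.5,     # exoenzyme allocation fraction (evolving trait)
  gamma_M    = 0.3,     # microbial carbon production fraction (growth efficiency)
  gamma_Z    = 0.4,     # enzyme carbon production fraction
  omega_M    = 1e-9,    # mg, carbon mass of one cell
  omega_Z    = 1e-16,   # mg, carbon mass of one enzyme molecule
  omega_C    = 1e-16,   # mg, carbon mass of one SOC molecule
  omega_D    = 1e-19,   # mg, carbon mass of one DOC molecule
  alpha      = 1e10,    # structural cost of one cell (DOC molecules)
  alpha_prime = 2.33e10, # energetic cost of one cell (DOC molecules)
  beta       = 1e3,     # structural cost of one SOC molecule (DOC molecules)
  rho        = 1e3,     # structural cost of one enzyme molecule (DOC molecules)
  rho_prime  = 1.5e3,   # energetic cost of one enzyme molecule (DOC molecules)
  d_M        = 2e-4,    # 1/h, cell death rate
  d_Z        = 2e-3,    # 1/h, enzyme deactivation rate
  V_max      = 0.42,    # 1/h, maximum uptake rate
  theta      = 7e5,     # 1/(mg h), encounter probability x decomposition rate
  K_m        = 3e-10,   # mg, uptake half-saturation constant
  I_C        = 5e-13,   # mg/h, external SOC input
  I_D        = 0,       # mg/h, external DOC input
  l_C        = 1e-6,    # 1/h, SOC leaching rate
  l_D        = 1e-6,    # 1/h, DOC leaching rate
  l          = 0,       # leached fraction of dead-cell / deactivated-enzyme carbon
  p          = 0.5,     # fraction of recycled dead carbon routed to SOC
  T_max      = 1e6,     # h, simulation horizon
  p_disp     = 0.3,     # newborn dispersal probability
  p_open     = 0.01,    # micro-disturbance probability on blocked dispersal
  p_mut      = 0.1,     # mutation probability per division
  sigma_mut  = 0.05,    # sd of mutation effect (trait units)
  sigma_diff = 5e-6,    # DOC diffusion coefficient (enters the lattice update rule)
  tau_diff   = 1        # h, diffusion time step
)

.frac_fields <- c("phi", "l", "p", "p_disp", "p_open", "p_mut")
.nonneg_fields <- setdiff(names(.unit_defaults), .frac_fields)

#' Model parameter set
#'
#' Builds the full parameter set of the decomposition model. Defaults are the
#' standard biomass-model values at unit soil volume; the four
#' volume-dependent parameters (`I_C`, `I_D`, `K_m`, `theta`) are rescaled to
#' the requested system size `k` (the number of unit volumes per microsite):
#' inputs and half-saturation scale proportionally with `k`, the encounter
#' parameter `theta` inversely with `k`. Values supplied through `...` are
#' taken verbatim, i.e. as microsite-level values at the requested `k`.
#'
#' @param k system size (dimensionless, `>= 1`); default 10.
#' @param ... named overrides of any parameter field (see
#'   [validate_params()] for the field list); interpreted at system size `k`.
#' @return a validated object of class `soil_params` (a named list).
#' @examples
#' p <- soil_params()            # default microsite parameters at k = 10
#' p$I_C                         # 5e-12 mg/h per microsite
#' soil_params(k = 1)$I_C        # 5e-13 mg/h per unit volume
#' @export
soil_params <- function(k = 10, ...) {
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    stop("k must be a single number >= 1")
  p <- .unit_defaults
  p <- rescale_params(structure(p, class = "soil_params"), k)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(.unit_defaults))
    if (length(unknown))
      stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
    if ("k" %in% names(over))
      stop("set the system size through the k argument, not ...")
    p[names(over)] <- over
  }
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks range invariants (fractions in \[0, 1\], rates/masses/costs
#' non-negative, `k >= 1`, `L >= 1`) and the mass-consistency relations that
#' tie production fractions to molecular costs:
#' `gamma_M = omega_M / ((alpha + alpha') omega_D)`,
#' `gamma_Z = omega_Z / ((rho + rho') omega_D)` and
#' `omega_C = beta * omega_D`. The consistency relations are checked to a
#' relative tolerance of 1% (the default costs are printed to three
#' significant digits).
#'
#' @param params a `soil_params` object or named list with all fields present.
#' @return the parameter set, unchanged, invisibly classed as `soil_params`.
#' @export
validate_params <- function(params) {
  params <- unclass(params)
  missing <- setdiff(names(.unit_defaults), names(params))
  if (length(missing))
    stop("missing parameter field(s): ", paste(missing, collapse = ", "))
  errs <- character()
  for (f in .frac_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      errs <- c(errs, sprintf("range error: %s must lie in [0, 1] (got %s)",
                              f, format(params[[f]])))
  }
  for (f in .nonneg_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      errs <- c(errs, sprintf("range error: %s must be >= 0", f))
  }
  if (is.numeric(params$k) && length(params$k) == 1 && !is.na(params$k) &&
      params$k < 1)
    errs <- c(errs, "range error: k must be >= 1")
  if (is.numeric(params$L) && length(params$L) == 1 && !is.na(params$L) &&
      params$L < 1)
    errs <- c(errs, "range error: L must be >= 1")
  rel_ok <- function(a, b) {
    isTRUE(abs(a - b) <= 1e-2 * max(abs(a), abs(b), .Machine$double.xmin))
  }
  if (!length(errs)) {
    with(params, {
      if (!rel_ok(gamma_M, omega_M / ((alpha + alpha_prime) * omega_D)))
        errs <<- c(errs, "mass-consistency error: gamma_M != omega_M / ((alpha + alpha_prime) * omega_D)")
      if (!rel_ok(gamma_Z, omega_Z / ((rho + rho_prime) * omega_D)))
        errs <<- c(errs, "mass-consistency error: gamma_Z != omega_Z / ((rho + rho_prime) * omega_D)")
      if (!rel_ok(omega_C, beta * omega_D))
        errs <<- c(errs, "mass-consistency error: omega_C != beta * omega_D")
    })
  }
  if (length(errs)) stop(paste(errs, collapse = "\n  "))
  structure(params[names(.unit_defaults)], class = "soil_params")
}

#' Rescale a parameter set to a new system size
#'
#' Applies the volume scaling relations relative to the parameter set's
#' current `k`: `I_C`, `I_D` and `K_m` scale proportionally with the microsite
#' volume, the encounter parameter `theta` inversely. All other fields are
#' unchanged. Rescaling to the current `k` is the identity, and round trips
#' recover the original values to float tolerance.
#'
#' @param params a `soil_params` object.
#' @param k_new new system size (`>= 1`).
#' @return the rescaled `soil_params` object.
#' @export
rescale_params <- function(params, k_new) {
  if (!is.numeric(k_new) || length(k_new) != 1 || is.na(k_new) || k_new < 1)
    stop("k_new must be a single number >= 1")
  r <- k_new / params$k
  params$I_C   <- params$I_C * r
  params$I_D   <- params$I_D * r
  params$K_m   <- params$K_m * r
  params$theta <- params$theta / r
  params$k     <- k_new
  params
}

#' @export
print.soil_params <- function(x, ...) {
  cat(sprintf("<soil_params> microsite parameters at system size k = %g (volume %g cm^3)\n",
              x$k, x$V * x$k))
  df <- data.frame(value = vapply(unclass(x), format, ""))
  print(df)
  invisible(x)
}

# Effective diffusion step: the explicit Euler stencil is stable only when
# 4 * sigma_diff * tau / (V k)^(2/3) < 1; the simulators cap the step at half
# that limit so a user-level tau_diff never destabilises the scheme.
effective_tau <- function(params) {
  if (params$sigma_diff <= 0 || params$L < 2) return(params$tau_diff)
  tau_stab <- (params$V * params$k)^(2 / 3) / (4 * params$sigma_diff)
  min(params$tau_diff, 0.5 * tau_stab)
}
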