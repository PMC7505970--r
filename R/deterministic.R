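# Deterministic four-compartment (cdmz) approximation of a single microsite:
# SOC c, DOC d, cell biomass m, enzyme z, all in mg carbon.

#' Right-hand side of the deterministic cdmz model
#'
#' Mass-balance derivatives of the four-compartment microsite model. SOC is
#' supplied externally and decomposed by enzymes (`theta z c`); the resulting
#' DOC is taken up by cells with Michaelis-Menten kinetics; uptake is split
#' between biomass production (fraction `(1 - phi) gamma_M`), enzyme
#' production (`phi gamma_Z`) and respiration (the remainder). Dead biomass
#' and deactivated enzyme carbon are recycled after leaching of a fraction
#' `l`: a fraction `p` of recycled dead-cell carbon flows to SOC and the rest
#' to DOC, while deactivated enzymes return to DOC.
#'
#' @param state named numeric vector `c(c=, d=, m=, z=)`, all `>= 0` (mg).
#' @param params a [soil_params()] object.
#' @param phi enzyme allocation fraction; defaults to `params$phi`.
#' @return named derivative vector `(c, d, m, z)` in mg/h, with attribute
#'   `respiration` (mg/h of carbon respired as CO2) for budget checks.
#' @examples
#' p <- soil_params()
#' cdmz_rhs(c(c = 1e-7, d = 1e-11, m = 5e-9, z = 1e-10), p)
#' @export
cdmz_rhs <- function(state, params, phi = params$phi) {
  if (any(state < 0)) stop("negative state component")
  c_ <- state[["c"]]; d_ <- state[["d"]]; m_ <- state[["m"]]; z_ <- state[["z"]]
  pr <- unclass(params)
  u <- pr$V_max * d_ / (pr$K_m + d_)       # uptake per unit cell biomass (1/h)
  dc <- pr$I_C - pr$l_C * c_ - pr$theta * z_ * c_ + (1 - pr$l) * pr$p * pr$d_M * m_
  dd <- pr$I_D - pr$l_D * d_ + pr$theta * z_ * c_ + (1 - pr$l) * pr$d_Z * z_ +
    (1 - pr$l) * (1 - pr$p) * pr$d_M * m_ - u * m_
  dm <- (1 - phi) * pr$gamma_M * u * m_ - pr$d_M * m_
  dz <- phi * pr$gamma_Z * u * m_ - pr$d_Z * z_
  resp <- u * m_ * (1 - (1 - phi) * pr$gamma_M - phi * pr$gamma_Z)
  structure(c(c = dc, d = dd, m = dm, z = dz), respiration = resp)
}

#' Equilibrium of the cdmz model
#'
#' Computes the non-trivial (positive cell biomass) equilibrium when it
#' exists. The DOC component has the closed form `d* = K_m x / (1 - x)` with
#' `x = d_M / ((1 - phi) gamma_M V_max)`; the enzyme balance then fixes
#' `z* = phi gamma_Z u* m* / d_Z` and the SOC balance gives `c*` as a
#' function of `m*`, leaving a scalar root-find on the DOC balance for `m*`.
#' When no positive equilibrium exists (e.g. `x >= 1`, so growth cannot match
#' mortality at any DOC level) the extinction equilibrium is returned with
#' `viable = FALSE`.
#'
#' @param params a [soil_params()] object.
#' @param phi enzyme allocation fraction; defaults to `params$phi`.
#' @param tol relative residual tolerance on the returned equilibrium.
#' @return an object of class `cdmz_equilibrium`: list with `state`
#'   (named vector c, d, m, z), `cells` (`m / omega_M`), `phi`, `viable`,
#'   and `residual` (largest scaled derivative at the returned state).
#' @examples
#' eq <- steady_state(soil_params(), phi = 0.5)
#' eq$cells   # equilibrium cell number per microsite
#' @export
steady_state <- function(params, phi = params$phi, tol = 1e-9) {
  pr <- unclass(params)
  extinct <- function() {
    d0 <- if (pr$l_D > 0) pr$I_D / pr$l_D else 0
    c0 <- if (pr$l_C > 0) pr$I_C / pr$l_C else 0
    st <- c(c = c0, d = d0, m = 0, z = 0)
    structure(list(state = st, cells = 0, phi = phi, viable = FALSE,
                   residual = max(abs(cdmz_rhs(st, params, phi)))),
              class = "cdmz_equilibrium")
  }
  denom <- (1 - phi) * pr$gamma_M * pr$V_max
  if (denom <= 0) return(extinct())
  x <- pr$d_M / denom
  if (x >= 1) return(extinct())
  d_star <- pr$K_m * x / (1 - x)
  u <- pr$V_max * d_star / (pr$K_m + d_star)    # = d_M / ((1-phi) gamma_M)
  z_coef <- phi * pr$gamma_Z * u / pr$d_Z       # z* = z_coef * m*
  c_of <- function(m)
    (pr$I_C + (1 - pr$l) * pr$p * pr$d_M * m) / (pr$l_C + pr$theta * z_coef * m)
  g <- function(m)                               # DOC balance residual
    pr$I_D - pr$l_D * d_star + pr$theta * z_coef * m * c_of(m) +
      (1 - pr$l) * pr$d_Z * z_coef * m +
      (1 - pr$l) * (1 - pr$p) * pr$d_M * m - u * m
  resp_frac <- 1 - (1 - phi) * pr$gamma_M - phi * pr$gamma_Z
  m_max <- (pr$I_C + pr$I_D) / (u * resp_frac)   # respiration <= inputs
  if (!is.finite(m_max) || m_max <= 0) return(extinct())
  # g may have two roots (a repelling one near 0 and the positive
  # equilibrium); locate the maximum, then bracket the upper root.
  opt <- stats::optimize(g, c(0, m_max), maximum = TRUE, tol = m_max * 1e-12)
  if (opt$objective <= 0) return(extinct())
  hi <- m_max
  while (g(hi) > 0) hi <- hi * 2   # safety; g -> -inf for large m
  m_star <- stats::uniroot(g, c(opt$maximum, hi), tol = m_max * 1e-14)$root
  st <- c(c = c_of(m_star), d = d_star, m = m_star, z = z_coef * m_star)
  # residual scaled per equation by its gross (one-sided) carbon flux
  flux <- c(pr$I_C + pr$l_C * st[["c"]] + pr$theta * st[["z"]] * st[["c"]] +
              (1 - pr$l) * pr$p * pr$d_M * m_star,
            pr$I_D + pr$l_D * d_star + pr$theta * st[["z"]] * st[["c"]] +
              (1 - pr$l) * pr$d_Z * st[["z"]] +
              (1 - pr$l) * (1 - pr$p) * pr$d_M * m_star + u * m_star,
            (1 - phi) * pr$gamma_M * u * m_star + pr$d_M * m_star,
            phi * pr$gamma_Z * u * m_star + pr$d_Z * st[["z"]])
  res <- max(abs(cdmz_rhs(st, params, phi)) /
               pmax(flux, .Machine$double.xmin))
  if (res > tol)
    warning(sprintf("steady-state residual %.2e above tolerance %.2e", res, tol))
  structure(list(state = st, cells = m_star / pr$omega_M, phi = phi,
                 viable = TRUE, residual = res),
            class = "cdmz_equilibrium")
}

#' @export
print.cdmz_equilibrium <- function(x, ...) {
  cat(sprintf("<cdmz equilibrium> phi = %g, %s\n", x$phi,
              if (x$viable) "viable" else "extinction (no positive equilibrium)"))
  print(x$state)
  cat(sprintf("cells per microsite: %.4g\n", x$cells))
  invisible(x)
}

#' Growth rate of a rare mutant strain
#'
#' Long-term per-capita growth rate of a mutant with allocation `phi_mut`
#' experiencing a fixed DOC level `d_resident` (the environment set by the
#' resident): `(1 - phi') gamma_M V_max d / (K_m + d) - d_M`. At the
#' resident's own equilibrium DOC and `phi_mut` equal to the resident trait
#' this is exactly zero (resident neutrality).
#'
#' @param phi_mut mutant allocation fraction.
#' @param d_resident ambient DOC mass (mg), `>= 0`.
#' @param params a [soil_params()] object.
#' @return growth rate in 1/h.
#' @export
mutant_growth_rate <- function(phi_mut, d_resident, params) {
  if (any(d_resident < 0)) stop("d_resident must be >= 0")
  pr <- unclass(params)
  (1 - phi_mut) * pr$gamma_M * pr$V_max * d_resident / (pr$K_m + d_resident) -
    pr$d_M
}

#' Selection gradient of the allocation trait in a well-mixed microsite
#'
#' Derivative of the mutant growth rate with respect to the mutant trait,
#' evaluated at the resident trait and the resident's equilibrium DOC:
#' `-gamma_M V_max d* / (K_m + d*)`. It is negative whenever the resident
#' DOC is positive: in a well-mixed site, exoenzyme production is always
#' counter-selected.
#'
#' @param phi resident allocation fraction (must admit a positive equilibrium).
#' @param params a [soil_params()] object.
#' @param d optional DOC level; defaults to the resident equilibrium `d*`.
#' @return gradient in 1/h per trait unit.
#' @export
selection_gradient <- function(phi, params, d = NULL) {
  pr <- unclass(params)
  if (is.null(d)) {
    eq <- steady_state(params, phi)
    if (!eq$viable) stop("no positive resident equilibrium at phi = ", phi)
    d <- eq$state[["d"]]
  }
  -pr$gamma_M * pr$V_max * d / (pr$K_m + d)
}

#' Range of allocation values with a viable population
#'
#' Scans the trait interval and bisects both edges of the set of `phi` for
#' which [steady_state()] has strictly positive cell biomass. Viability
#' fails both at high `phi` (growth cannot match mortality) and at very low
#' `phi` (too little enzyme to generate DOC from SOC).
#'
#' @param params a [soil_params()] object.
#' @param n_grid number of scan points on \[0, 1\].
#' @param tol bisection tolerance on the bounds.
#' @return numeric vector `c(lower, upper)`, or `numeric(0)` (with a message)
#'   when no trait value is viable.
#' @export
viability_threshold <- function(params, n_grid = 201, tol = 1e-6) {
  viable <- function(phi) steady_state(params, phi)$viable
  grid <- seq(0, 1, length.out = n_grid)
  ok <- vapply(grid, viable, logical(1))
  if (!any(ok)) {
    message("no viable allocation value for these parameters")
    return(numeric(0))
  }
  i_lo <- min(which(ok)); i_hi <- max(which(ok))
  bisect <- function(bad, good) {
    for (it in 1:60) {
      if (abs(good - bad) < tol) break
      mid <- (bad + good) / 2
      if (viable(mid)) good <- mid else bad <- mid
    }
    good
  }
  lower <- if (i_lo == 1) grid[1] else bisect(grid[i_lo - 1], grid[i_lo])
  upper <- if (i_hi == n_grid) grid[n_grid] else bisect(grid[i_hi + 1], grid[i_hi])
  c(lower = lower, upper = upper)
}

#' Deterministic cdmz trajectory
#'
#' Integrates the cdmz system with `deSolve::ode` (lsoda). Used mainly to
#' compare hybrid stochastic trajectories against their deterministic limit.
#'
#' @param params a [soil_params()] object.
#' @param phi allocation fraction.
#' @param times output time points (h).
#' @param init initial state; defaults to the equilibrium of [steady_state()].
#' @return a data.frame with columns `time, c, d, m, z`.
#' @export
cdmz_trajectory <- function(params, phi = params$phi, times,
                            init = steady_state(params, phi)$state) {
  f <- function(t, y, parms) list(as.numeric(cdmz_rhs(y, params, phi)))
  out <- deSolve::ode(y = init, times = times, func = f, parms = NULL,
                      rtol = 1e-10, atol = 1e-25)
  as.data.frame(out)
}
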