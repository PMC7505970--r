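# Single-microsite operations of the hybrid model, in plain R. These mirror
# the compiled event loop used by simulate_site()/simulate_lattice() and are
# the reference implementation the tests cross-check it against.

#' Construct a microsite state
#'
#' @param c,d,z SOC, DOC and enzyme mass (mg), all `>= 0`.
#' @param cells data.frame with columns `phi` (trait), `S` (stored reserve,
#'   mg) and `strain` (positive integer label); zero-row for an empty site.
#' @return an object of class `microsite_state`.
#' @export
microsite_state <- function(c = 0, d = 0, z = 0, cells = empty_cells()) {
  if (any(c(c, d, z) < 0)) stop("c, d, z must be >= 0")
  stopifnot(is.data.frame(cells),
            all(c("phi", "S", "strain") %in% names(cells)))
  structure(list(c = c, d = d, z = z, cells = cells),
            class = "microsite_state")
}

#' @rdname microsite_state
#' @export
empty_cells <- function() {
  data.frame(phi = numeric(0), S = numeric(0), strain = integer(0))
}

#' @export
print.microsite_state <- function(x, ...) {
  cat(sprintf("<microsite> c = %.3e, d = %.3e, z = %.3e mg; M = %d cells\n",
              x$c, x$d, x$z, nrow(x$cells)))
  invisible(x)
}

#' Waiting time to the next death event
#'
#' One exponential clock for the whole population: rate `d_M * M_total`,
#' infinite when there are no cells.
#'
#' @param M_total total number of live cells (`>= 0`).
#' @param params a [soil_params()] object.
#' @return waiting time in hours (`Inf` when `M_total == 0`).
#' @export
draw_death_time <- function(M_total, params) {
  if (M_total < 0) stop("M_total must be >= 0")
  rate <- params$d_M * M_total
  if (rate == 0) return(Inf)
  stats::rexp(1, rate = rate)
}

# Adaptive explicit Euler over [0, dt] for one site, cell number frozen.
# Returns updated c,d,z, the per-cell uptake integral A (mg DOC per cell),
# and the interval's carbon ledger. Arithmetic matches the compiled core.
.euler_flows <- function(c_, d_, z_, m, sumphi, dt, pr) {
  rem <- dt
  h_min <- dt / 256
  A <- 0; input <- 0; leach <- 0; resp <- 0; discard <- 0; clips <- 0L
  while (rem > 0) {
    upt_f <- pr$V_max * d_ / (pr$K_m + d_)
    upt <- upt_f * pr$omega_M * m
    dec <- pr$theta * z_ * c_
    deact <- pr$d_Z * z_
    prodz <- pr$gamma_Z * upt_f * pr$omega_M * sumphi
    dc <- pr$I_C - pr$l_C * c_ - dec
    dd <- pr$I_D - pr$l_D * d_ + dec + (1 - pr$l) * deact - upt
    dz <- prodz - deact
    h <- rem
    if (dd < 0 && d_ > 0) h <- min(h, 0.01 * d_ / (-dd))
    if (dc < 0 && c_ > 0) h <- min(h, 0.5 * c_ / (-dc))
    if (dz < 0 && z_ > 0) h <- min(h, 0.5 * z_ / (-dz))
    if (h < h_min) h <- h_min
    if (h > rem) h <- rem
    res_gain <- pr$gamma_M * upt_f * pr$omega_M * (m - sumphi) * h
    c_ <- c_ + h * dc; d_ <- d_ + h * dd; z_ <- z_ + h * dz
    input <- input + h * (pr$I_C + pr$I_D)
    leach <- leach + h * (pr$l_C * (c_ - h * dc) + pr$l_D * (d_ - h * dd) +
                            pr$l * deact)
    resp <- resp + h * upt - h * prodz - res_gain
    if (m > 0) A <- A + h * upt_f * pr$omega_M
    if (c_ < 0) { discard <- discard + c_; c_ <- 0; clips <- clips + 1L }
    if (d_ < 0) { discard <- discard + d_; d_ <- 0; clips <- clips + 1L }
    if (z_ < 0) { discard <- discard + z_; z_ <- 0; clips <- clips + 1L }
    rem <- rem - h
  }
  list(c = c_, d = d_, z = z_, A = A,
       ledger = c(input = input, leach = leach, respiration = resp,
                  discard = discard), clips = clips)
}

#' Advance the deterministic flows of one microsite
#'
#' Integrates SOC, DOC and enzyme mass over `dt` with the cell count held
#' fixed, using an adaptive explicit Euler scheme (sub-steps chosen so the
#' relative DOC change per sub-step stays below 1%, with outflow caps so no
#' pool goes negative). Also returns the common storage increment earned by
#' each cell, per trait value: `Delta_j = (1 - phi_j) gamma_M A`, where `A`
#' is the integrated uptake per cell.
#'
#' @param site a [microsite_state()].
#' @param dt interval length (h), `> 0`.
#' @param params a [soil_params()] object.
#' @return list with `site` (flows advanced, reserves untouched), `Delta`
#'   (per-cell storage increments, aligned with `site$cells`), `A` (uptake
#'   integral per cell, mg) and `ledger` (input/leach/respiration/discard
#'   over the interval, mg).
#' @export
integrate_flows <- function(site, dt, params) {
  if (dt <= 0) stop("dt must be > 0")
  pr <- unclass(params)
  m <- nrow(site$cells)
  out <- .euler_flows(site$c, site$d, site$z, m, sum(site$cells$phi), dt, pr)
  site$c <- out$c; site$d <- out$d; site$z <- out$z
  list(site = site,
       Delta = (1 - site$cells$phi) * pr$gamma_M * out$A,
       A = out$A, ledger = out$ledger, clips = out$clips)
}

#' Apply threshold divisions in one microsite
#'
#' Adds the storage increments to each cell's reserve; every cell whose
#' reserve reaches the cell mass `omega_M` divides, mother and daughter each
#' keeping half of the excess `(S + Delta - omega_M) / 2` (or both reset to
#' zero under the `zero_reset` variant, which discards the excess). Daughters
#' inherit the maternal trait subject to mutation ([mutate_trait()]); a
#' mutated daughter founds a new strain. Placement of the newborns is the
#' lattice's job ([place_newborn()]).
#'
#' @param site a [microsite_state()].
#' @param Delta per-cell storage increments (mg) from [integrate_flows()].
#' @param params a [soil_params()] object.
#' @param zero_reset logical; reset both reserves to zero at division
#'   (does not conserve carbon; default `FALSE`).
#' @param next_strain next unused strain id for mutant daughters.
#' @return list with `site` (mothers updated), `newborns` (data.frame
#'   `phi, S, strain`) and `next_strain`.
#' @export
apply_divisions <- function(site, Delta, params, zero_reset = FALSE,
                            next_strain = max(c(0L, site$cells$strain)) + 1L) {
  if (any(Delta < 0)) stop("Delta must be >= 0")
  cells <- site$cells
  newborns <- empty_cells()
  if (nrow(cells)) {
    S_new <- cells$S + Delta
    div <- which(S_new >= params$omega_M)
    keep <- S_new
    for (j in div) {
      S_each <- if (zero_reset) 0 else (S_new[j] - params$omega_M) / 2
      keep[j] <- S_each
      phi_c <- mutate_trait(cells$phi[j], params)
      strain_c <- cells$strain[j]
      if (phi_c != cells$phi[j]) {
        strain_c <- next_strain
        next_strain <- next_strain + 1L
      }
      newborns <- rbind(newborns,
                        data.frame(phi = phi_c, S = S_each, strain = strain_c))
    }
    cells$S <- keep
    site$cells <- cells
  }
  list(site = site, newborns = newborns, next_strain = next_strain)
}

#' Remove one uniformly chosen cell and recycle its carbon
#'
#' The victim's structural mass `omega_M` plus its stored reserve is
#' recycled into the site after leaching of a fraction `l`: a fraction `p`
#' flows to SOC, the rest to DOC.
#'
#' @param site a [microsite_state()] with at least one cell.
#' @param params a [soil_params()] object.
#' @param route_p_to_doc route the fraction `p` to DOC instead of SOC (the
#'   literal single-death bookkeeping of the event-loop description; default
#'   `FALSE`, numerically identical at the default `p = 0.5`).
#' @return the updated `microsite_state`.
#' @export
apply_death <- function(site, params, route_p_to_doc = FALSE) {
  m <- nrow(site$cells)
  if (m < 1) stop("apply_death on an empty site")
  j <- sample.int(m, 1)
  mass <- params$omega_M + site$cells$S[j]
  keep <- (1 - params$l) * mass
  if (route_p_to_doc) {
    site$d <- site$d + params$p * keep
    site$c <- site$c + (1 - params$p) * keep
  } else {
    site$c <- site$c + params$p * keep
    site$d <- site$d + (1 - params$p) * keep
  }
  site$cells <- site$cells[-j, , drop = FALSE]
  rownames(site$cells) <- NULL
  site
}

#' Simulate the hybrid model in a single microsite
#'
#' Runs the hybrid stochastic-deterministic event loop (compiled core) for
#' one isolated microsite: deterministic c/d/z flows and storage accrual,
#' threshold divisions, and stochastic deaths. By default the site is
#' initialised at the deterministic equilibrium for `phi0` with cell
#' reserves drawn uniformly on `[0, omega_M)`.
#'
#' @param params a [soil_params()] object.
#' @param phi0 founding (monomorphic) trait value.
#' @param T_max simulation horizon (h).
#' @param with_mutation logical; if `FALSE`, `p_mut` is forced to 0.
#' @param init optional [microsite_state()] to start from.
#' @param record_every trajectory sampling interval (h).
#' @param ... further arguments passed to [simulate_lattice()].
#' @return a `decomp_sim` object (see [simulate_lattice()]).
#' @export
simulate_site <- function(params, phi0 = params$phi, T_max = params$T_max,
                          with_mutation = FALSE, init = NULL,
                          record_every = T_max / 200, ...) {
  params$L <- 1
  params$sigma_diff <- 0
  if (is.null(init)) {
    lat <- make_fixture("steady-monomorphic", params, phi = phi0)
  } else {
    stopifnot(inherits(init, "microsite_state"))
    lat <- lattice_state(params, L = 1)
    lat$c[1] <- init$c; lat$d[1] <- init$d; lat$z[1] <- init$z
    lat$cells[[1]] <- init$cells
  }
  if (!with_mutation) params$p_mut <- 0
  simulate_lattice(params, init = lat, T_max = T_max,
                   record_every = record_every, ...)
}
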