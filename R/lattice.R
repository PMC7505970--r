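# Lattice-scale coupling: DOC diffusion, newborn dispersal,
# micro-disturbances, the master event loop, and the compiled-simulator
# front end.

#' Construct an empty lattice state
#'
#' @param params a [soil_params()] object (supplies the default `L`).
#' @param L lattice side length.
#' @param t simulation clock (h).
#' @return an object of class `lattice_state`: matrices `c`, `d`, `z`
#'   (L x L, mg) and a list `cells` of per-site cell data.frames, in
#'   row-major site order.
#' @export
lattice_state <- function(params, L = params$L, t = 0) {
  L <- as.integer(L)
  if (L < 1) stop("L must be >= 1")
  z <- matrix(0, L, L)
  structure(list(t = t, L = L, c = z, d = z, z = z,
                 cells = replicate(L * L, empty_cells(), simplify = FALSE)),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d x %d microsites at t = %g h; %d cells, total DOC %.3e mg\n",
              x$L, x$L, x$t, sum(vapply(x$cells, nrow, 0L)), sum(x$d)))
  invisible(x)
}

# site index helpers (1-based, R matrix linear order)
.site_index <- function(row, col, L) (col - 1L) * L + row

.neighbours <- function(s, L) {
  row <- (s - 1L) %/% L + 1L
  col <- (s - 1L) %% L + 1L
  out <- integer(0)
  if (row > 1) out <- c(out, s - L)
  if (row < L) out <- c(out, s + L)
  if (col > 1) out <- c(out, s - 1L)
  if (col < L) out <- c(out, s + 1L)
  out
}

#' Diffuse DOC across the lattice
#'
#' One explicit Euler step of the DOC diffusion equation on the microsite
#' grid: each site's DOC is updated by
#' `f * (sum of neighbour DOC - n_neigh * DOC)` with
#' `f = sigma_diff * tau / (V k)^(2/3)`, the denominator being the squared
#' inter-site distance. Boundaries are reflecting (Neumann): missing
#' neighbours contribute nothing and the stencil uses only existing
#' neighbours, so total DOC is conserved exactly.
#'
#' @param lattice a [lattice_state()].
#' @param tau diffusion time step (h), `> 0`.
#' @param params a [soil_params()] object.
#' @return the lattice with updated `d`.
#' @export
diffuse_doc <- function(lattice, tau, params) {
  if (tau <= 0) stop("tau must be > 0")
  f <- params$sigma_diff * tau / (params$V * params$k)^(2 / 3)
  if (4 * f >= 1)
    stop(sprintf(paste0("diffusion update factor 4f = %.3g >= 1: the explicit ",
                        "scheme is unstable; reduce tau_diff below %.3g h"),
                 4 * f, (params$V * params$k)^(2 / 3) / (4 * params$sigma_diff)))
  d <- lattice$d
  L <- lattice$L
  if (L > 1 && f > 0) {
    up    <- rbind(d[1, , drop = FALSE] * 0, d[-L, , drop = FALSE])
    down  <- rbind(d[-1, , drop = FALSE], d[L, , drop = FALSE] * 0)
    left  <- cbind(d[, 1, drop = FALSE] * 0, d[, -L, drop = FALSE])
    right <- cbind(d[, -1, drop = FALSE], d[, L, drop = FALSE] * 0)
    nn <- matrix(4, L, L)
    nn[1, ] <- nn[1, ] - 1; nn[L, ] <- nn[L, ] - 1
    nn[, 1] <- nn[, 1] - 1; nn[, L] <- nn[, L] - 1
    lattice$d <- d + f * (up + down + left + right - nn * d)
  }
  lattice
}

#' Place a newborn cell on the lattice
#'
#' With probability `1 - p_disp` the newborn stays in its natal microsite.
#' Otherwise it attempts to disperse to one of the (up to four) adjacent
#' sites: if at least one is empty it moves to a uniformly chosen empty one;
#' if all are occupied, with probability `p_open` a uniformly chosen
#' neighbour is struck by a micro-disturbance (its whole population dies and
#' is recycled locally) and the newborn colonises it; otherwise dispersal
#' fails and the newborn stays at home.
#'
#' @param lattice a [lattice_state()].
#' @param origin_site linear site index of the mother cell's microsite.
#' @param newborn one-row data.frame (`phi`, `S`, `strain`).
#' @param params a [soil_params()] object.
#' @return list with `lattice`, `placed_at` (site index), `dispersed` and
#'   `disturbed` (logicals).
#' @export
place_newborn <- function(lattice, origin_site, newborn, params) {
  L <- lattice$L
  if (origin_site < 1 || origin_site > L * L) stop("origin site does not exist")
  dest <- origin_site
  dispersed <- FALSE
  disturbed <- FALSE
  ngh <- .neighbours(origin_site, L)
  if (length(ngh) && stats::runif(1) >= 1 - params$p_disp) {
    occ <- vapply(lattice$cells[ngh], nrow, 0L)
    empty <- ngh[occ == 0L]
    if (length(empty)) {
      dest <- empty[sample.int(length(empty), 1)]
      dispersed <- TRUE
    } else if (stats::runif(1) >= 1 - params$p_open) {
      dest <- ngh[sample.int(length(ngh), 1)]
      lattice <- micro_disturbance(lattice, dest, params)
      dispersed <- TRUE
      disturbed <- TRUE
    }
  }
  lattice$cells[[dest]] <- rbind(lattice$cells[[dest]], newborn)
  rownames(lattice$cells[[dest]]) <- NULL
  list(lattice = lattice, placed_at = dest, dispersed = dispersed,
       disturbed = disturbed)
}

#' Kill and recycle a microsite's whole population
#'
#' All `M` cells of the target site die simultaneously; after leaching of a
#' fraction `l`, a fraction `p` of the released carbon (structural mass plus
#' stored reserves) is added to the site's SOC and the rest to its DOC —
#' recycling is local.
#'
#' @param lattice a [lattice_state()].
#' @param target_site linear site index.
#' @param params a [soil_params()] object.
#' @return the updated lattice.
#' @export
micro_disturbance <- function(lattice, target_site, params) {
  L <- lattice$L
  if (target_site < 1 || target_site > L * L) stop("target site does not exist")
  cells <- lattice$cells[[target_site]]
  if (nrow(cells)) {
    mass <- params$omega_M * nrow(cells) + sum(cells$S)
    keep <- (1 - params$l) * mass
    lattice$c[target_site] <- lattice$c[target_site] + params$p * keep
    lattice$d[target_site] <- lattice$d[target_site] + (1 - params$p) * keep
    lattice$cells[[target_site]] <- empty_cells()
  }
  lattice
}

#' One iteration of the master event loop (reference implementation)
#'
#' Draws the global death waiting time `T` (rate `d_M * M_total`), advances
#' every site's deterministic flows by `dt = min(T, tau)` where `tau` is the
#' (stability-capped) diffusion step, applies threshold divisions and
#' newborn placement in uniformly random order, applies one DOC diffusion
#' update over the elapsed time, and, if the death clock fired, removes one
#' uniformly chosen cell of the whole lattice. This plain-R path is the
#' reference against which the compiled simulator is checked; use
#' [simulate_lattice()] for production runs.
#'
#' @param lattice a [lattice_state()].
#' @param params a [soil_params()] object.
#' @param zero_reset,route_p_to_doc,fixed_tau variant switches matching
#'   [apply_divisions()], [apply_death()] and the diffusion cadence
#'   (`fixed_tau` applies the diffusion update with the full step `tau`
#'   even when a death shortens the interval).
#' @return the advanced lattice; attribute `info` carries the interval's
#'   ledger and event counts.
#' @export
step_lattice <- function(lattice, params, zero_reset = FALSE,
                         route_p_to_doc = FALSE, fixed_tau = FALSE) {
  L <- lattice$L
  n_sites <- L * L
  tau <- effective_tau(params)
  M_site <- vapply(lattice$cells, nrow, 0L)
  M_tot <- sum(M_site)
  T_death <- draw_death_time(M_tot, params)
  dt <- min(T_death, tau)
  ledger <- c(input = 0, leach = 0, respiration = 0, discard = 0)
  counts <- c(births = 0, deaths = 0, disturbances = 0, dispersals = 0)

  # flows + storage increments, cell numbers frozen
  newborns <- list()
  next_strain <- max(c(0L, unlist(lapply(lattice$cells, `[[`, "strain")))) + 1L
  for (s in seq_len(n_sites)) {
    site <- microsite_state(lattice$c[s], lattice$d[s], lattice$z[s],
                            lattice$cells[[s]])
    fl <- integrate_flows(site, dt, params)
    ledger <- ledger + fl$ledger
    dv <- apply_divisions(fl$site, fl$Delta, params, zero_reset = zero_reset,
                          next_strain = next_strain)
    next_strain <- dv$next_strain
    lattice$c[s] <- dv$site$c; lattice$d[s] <- dv$site$d
    lattice$z[s] <- dv$site$z; lattice$cells[[s]] <- dv$site$cells
    if (nrow(dv$newborns))
      newborns[[length(newborns) + 1L]] <-
        cbind(dv$newborns, origin = rep(s, nrow(dv$newborns)))
  }

  # newborn placement in uniformly random order
  if (length(newborns)) {
    nb <- do.call(rbind, newborns)
    ord <- if (nrow(nb) > 1) sample.int(nrow(nb)) else 1L
    for (i in ord) {
      pl <- place_newborn(lattice, nb$origin[i],
                          nb[i, c("phi", "S", "strain"), drop = FALSE], params)
      lattice <- pl$lattice
      counts["births"] <- counts["births"] + 1
      counts["dispersals"] <- counts["dispersals"] + pl$dispersed
      counts["disturbances"] <- counts["disturbances"] + pl$disturbed
    }
  }

  # diffusion over the elapsed interval (or the full tau under fixed_tau)
  if (params$sigma_diff > 0 && L > 1)
    lattice <- diffuse_doc(lattice, if (fixed_tau) tau else dt, params)

  # death event
  if (is.finite(T_death) && T_death <= tau) {
    M_site <- vapply(lattice$cells, nrow, 0L)
    s <- sample.int(n_sites, 1, prob = M_site)
    site <- microsite_state(lattice$c[s], lattice$d[s], lattice$z[s],
                            lattice$cells[[s]])
    site <- apply_death(site, params, route_p_to_doc = route_p_to_doc)
    lattice$c[s] <- site$c; lattice$d[s] <- site$d; lattice$z[s] <- site$z
    lattice$cells[[s]] <- site$cells
    counts["deaths"] <- 1
  }

  lattice$t <- lattice$t + dt
  attr(lattice, "info") <- list(dt = dt, ledger = ledger, counts = counts)
  lattice
}

# lattice_state -> compiled-core arguments. Sites are indexed linearly in R
# matrix order; the compiled core uses the same linear index (the 4-neighbour
# adjacency is identical under either row- or column-major labelling).
.lattice_to_core <- function(lattice) {
  list(c = as.numeric(lattice$c), d = as.numeric(lattice$d),
       z = as.numeric(lattice$z),
       cells = lapply(lattice$cells, function(df)
         list(S = as.numeric(df$S), phi = as.numeric(df$phi),
              strain = as.integer(df$strain))))
}

.core_to_lattice <- function(fin, L, t) {
  lat <- lattice_state(list(L = L), L = L, t = t)
  lat$c <- matrix(fin$c, L, L)
  lat$d <- matrix(fin$d, L, L)
  lat$z <- matrix(fin$z, L, L)
  lat$cells <- lapply(fin$cells, function(cl)
    data.frame(phi = cl$phi, S = cl$S, strain = cl$strain))
  lat
}

#' Simulate the hybrid model on the lattice
#'
#' Runs the compiled hybrid event loop from an initial lattice state to
#' `T_max` (or extinction). Reproducible under `set.seed()`.
#'
#' @param params a [soil_params()] object; `params$L` must match `init`.
#' @param init a [lattice_state()]; typically from [make_fixture()] or
#'   [initialize_contest()].
#' @param T_max simulation horizon (h).
#' @param record_every trajectory sampling interval (h).
#' @param n_track number of low-numbered strain ids whose cell counts are
#'   recorded through time (columns `strain_1`, ... of the trajectory).
#' @param stop_strain if a positive tracked strain id, stop early once that
#'   strain is extinct.
#' @param stop_on_extinction stop once the whole population is extinct.
#' @param zero_reset,route_p_to_doc,fixed_tau variant switches, see
#'   [step_lattice()].
#' @return an object of class `decomp_sim`: list with `trajectory`
#'   (data.frame: time, pool totals, cell count, trait summaries, cumulative
#'   carbon ledger, tracked strain counts), `final` ([lattice_state()]),
#'   `counters`, `ledger`, `registry` (strains founded by mutation),
#'   `tau_eff` and stop flags.
#' @export
simulate_lattice <- function(params, init, T_max = params$T_max,
                             record_every = T_max / 200, n_track = 4L,
                             stop_strain = -1L, stop_on_extinction = TRUE,
                             zero_reset = FALSE, route_p_to_doc = FALSE,
                             fixed_tau = FALSE) {
  stopifnot(inherits(init, "lattice_state"))
  if (init$L != params$L)
    stop("params$L does not match the initial lattice")
  core <- .lattice_to_core(init)
  next_id <- max(c(0L, unlist(lapply(init$cells, `[[`, "strain")))) + 1L
  res <- .sim_hybrid_cpp(unclass(params), core$c, core$d, core$z, core$cells,
                         init$t, init$t + T_max, record_every,
                         as.integer(n_track), as.integer(next_id),
                         fixed_tau, zero_reset, route_p_to_doc,
                         as.integer(stop_strain), stop_on_extinction)
  traj <- as.data.frame(res$trajectory)
  sc <- res$strain_counts
  for (i in seq_along(sc)) traj[[paste0("strain_", i)]] <- sc[[i]]
  structure(list(trajectory = traj,
                 final = .core_to_lattice(res$final, init$L, res$t_end),
                 final_strain_counts = res$final_strain_counts,
                 M_final = res$M_final,
                 counters = res$counters, ledger = res$ledger,
                 registry = as.data.frame(res$registry),
                 tau_eff = res$tau_eff,
                 stopped_strain_extinct = res$stopped_strain_extinct,
                 stopped_all_extinct = res$stopped_all_extinct,
                 params = params),
            class = "decomp_sim")
}

#' @export
print.decomp_sim <- function(x, ...) {
  tr <- x$trajectory
  n <- nrow(tr)
  cat(sprintf("<decomp_sim> %d x %d lattice, t = %g .. %g h (%d records)\n",
              x$params$L, x$params$L, tr$time[1], tr$time[n], n))
  cat(sprintf("  cells: %d -> %d; births %d, deaths %d, disturbances %d, mutations %d\n",
              tr$M[1], tr$M[n], x$counters$births, x$counters$deaths,
              x$counters$disturbances, x$counters$mutations))
  invisible(x)
}

#' Total carbon on the lattice (pools + cells) for budget checks
#'
#' @param sim_row one row of a `decomp_sim` trajectory.
#' @return total carbon mass in mg: `c + d + z` plus structural and stored
#'   cell carbon.
#' @param omega_M cell structural mass (mg).
#' @export
total_carbon <- function(sim_row, omega_M) {
  sim_row$c + sim_row$d + sim_row$z + sim_row$M * omega_M + sim_row$reserve
}
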