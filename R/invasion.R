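# Adaptive-dynamics experiment layer: resident-mutant contests on the
# lattice, the invasion-fitness proxy, ESS bracketing across soil
# diffusivities, and ecosystem-function read-outs.

# the five central microsites (plus shape) used to introduce mutants
.intro_sites <- function(L, n_intro = 5) {
  ctr <- ceiling(L / 2)
  sites <- .site_index(ctr, ctr, L)
  if (n_intro > 1 && L >= 3) {
    sites <- c(sites,
               .site_index(ctr - 1, ctr, L), .site_index(ctr + 1, ctr, L),
               .site_index(ctr, ctr - 1, L), .site_index(ctr, ctr + 1, L))
    sites <- sites[seq_len(min(n_intro, length(sites)))]
  }
  sites
}

#' Initial lattice for a resident-mutant contest
#'
#' Every microsite is initialised at the resident's deterministic
#' equilibrium (pools and cell number), with cell reserves drawn uniformly
#' on `[0, omega_M)`. Mutant cells are then introduced in the central
#' microsites at 5% of the local resident abundance (rounded up, so at least
#' one cell), each mutant replacing one resident so total biomass is
#' unchanged. Residents carry strain id 1, mutants strain id 2.
#'
#' @param params a [soil_params()] object.
#' @param phi_res,phi_mut resident and mutant allocation fractions.
#' @param n_intro number of introduction microsites (1 or 5; default 5, a
#'   plus shape at the lattice centre).
#' @param mutant_frequency introduction frequency per introduction site.
#' @return a [lattice_state()].
#' @export
initialize_contest <- function(params, phi_res, phi_mut, n_intro = 5,
                               mutant_frequency = 0.05) {
  lat <- make_fixture("steady-monomorphic", params, phi = phi_res)
  for (s in .intro_sites(params$L, n_intro)) {
    cells <- lat$cells[[s]]
    m <- nrow(cells)
    if (m == 0) stop("resident equilibrium has no cells to replace")
    n_mut <- min(m, ceiling(mutant_frequency * m))
    idx <- seq_len(n_mut)
    cells$phi[idx] <- phi_mut
    cells$strain[idx] <- 2L
    lat$cells[[s]] <- cells
  }
  lat
}

#' Run replicated resident-mutant contests
#'
#' Simulates `n_replicates` independent invasion assays of a rare mutant
#' introduced into the resident-shaped ecosystem ([initialize_contest()]),
#' each to `T_max`, without mutation. The mutant survival probability is the
#' fraction of replicates with a non-extinct mutant population at `T_max`;
#' the long-term growth rate is the average of
#' `(1 / T_max) log(final mutant population / initial mutant population)`
#' over the surviving replicates; and the invasion-fitness proxy is
#' `survival_fraction * mean_growth_rate * T_max`.
#'
#' @param params a [soil_params()] object (`p_mut` is forced to 0).
#' @param phi_res,phi_mut resident and mutant allocation fractions.
#' @param n_replicates number of independent replicates.
#' @param T_max contest horizon (h).
#' @param seed master seed; per-replicate seeds are derived from it so
#'   contests are reproducible.
#' @param n_intro number of introduction microsites.
#' @return an object of class `invasion_result`.
#' @export
run_contest <- function(params, phi_res, phi_mut, n_replicates = 20,
                        T_max = params$T_max, seed = 1, n_intro = 5) {
  params$p_mut <- 0
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  final <- numeric(n_replicates)
  initial <- numeric(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(rep_seeds[i])
    lat <- initialize_contest(params, phi_res, phi_mut, n_intro = n_intro)
    initial[i] <- sum(vapply(lat$cells, function(df) sum(df$strain == 2L), 0))
    sim <- simulate_lattice(params, lat, T_max = T_max,
                            record_every = T_max, n_track = 2L,
                            stop_strain = 2L, stop_on_extinction = TRUE)
    final[i] <- sim$final_strain_counts[2]
  }
  surviving <- final > 0
  survival <- mean(surviving)
  growth <- if (any(surviving))
    mean(log(final[surviving] / initial[surviving]) / T_max) else 0
  structure(list(phi_res = phi_res, phi_mut = phi_mut,
                 n_replicates = n_replicates,
                 survival_fraction = survival,
                 mean_growth_rate = growth,
                 fitness_proxy = survival * growth * T_max,
                 final_counts = final, initial_counts = initial,
                 T_max = T_max, seed = seed, rep_seeds = rep_seeds),
            class = "invasion_result")
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("<invasion_result> resident phi = %g, mutant phi = %g (%s)\n",
              x$phi_res, x$phi_mut,
              if (x$phi_mut < x$phi_res) "cheater" else
                if (x$phi_mut > x$phi_res) "cooperator" else "neutral"))
  cat(sprintf("  %d replicates to T = %g h: survival %.2f, growth %.3e /h, fitness proxy %.3f\n",
              x$n_replicates, x$T_max, x$survival_fraction,
              x$mean_growth_rate, x$fitness_proxy))
  invisible(x)
}

#' Bracket the allocation ESS from pairwise contests
#'
#' For each trait value on the grid, runs a cheater contest (mutant
#' `phi - delta_phi`) and a cooperator contest (mutant `phi + delta_phi`)
#' against a resident at `phi`. The evolutionarily stable strategy is
#' bracketed between the largest grid value at which the cooperator mutant
#' has positive invasion fitness (lower bound; 0 if none) and the smallest
#' grid value at which the cheater mutant has positive fitness (upper bound;
#' the grid maximum if none). Directional selection beyond the grid is
#' reported in `direction`.
#'
#' @param params a [soil_params()] object.
#' @param sigma_diff DOC diffusion coefficient for the scan.
#' @param phi_grid ordered trait values.
#' @param delta_phi resident-mutant trait offset.
#' @param n_replicates replicates per contest.
#' @param T_max contest horizon (h).
#' @param seed master seed.
#' @param n_intro number of introduction microsites.
#' @return an object of class `ess_estimate`: the fitness `table`
#'   (sigma_diff, phi_res, phi_mut, role, survival_fraction,
#'   mean_growth_rate, fitness_proxy), the `lower`/`upper` bracket, the
#'   midpoint `estimate` and `direction` (`"down"`, `"up"`, `"interior"` or
#'   `"non-directional"`).
#' @export
ess_scan <- function(params, sigma_diff = params$sigma_diff,
                     phi_grid = seq(0.05, 0.25, by = 0.05),
                     delta_phi = 0.05, n_replicates = 20,
                     T_max = params$T_max, seed = 1, n_intro = 5) {
  stopifnot(!is.unsorted(phi_grid))
  params$sigma_diff <- sigma_diff
  set.seed(seed)
  contest_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                     2 * length(phi_grid)),
                          nrow = 2)
  rows <- list()
  for (g in seq_along(phi_grid)) {
    phi <- phi_grid[g]
    for (role in c("cheater", "cooperator")) {
      phi_mut <- if (role == "cheater") phi - delta_phi else phi + delta_phi
      if (phi_mut < 0 || phi_mut > 1) next
      r <- run_contest(params, phi_res = phi, phi_mut = phi_mut,
                       n_replicates = n_replicates, T_max = T_max,
                       seed = contest_seeds[match(role, c("cheater", "cooperator")), g],
                       n_intro = n_intro)
      rows[[length(rows) + 1L]] <- data.frame(
        sigma_diff = sigma_diff, phi_res = phi, phi_mut = phi_mut,
        role = role, survival_fraction = r$survival_fraction,
        mean_growth_rate = r$mean_growth_rate,
        fitness_proxy = r$fitness_proxy)
    }
  }
  tab <- do.call(rbind, rows)
  coop_pos <- tab$phi_res[tab$role == "cooperator" & tab$fitness_proxy > 0]
  cheat_pos <- tab$phi_res[tab$role == "cheater" & tab$fitness_proxy > 0]
  lower <- if (length(coop_pos)) max(coop_pos) else 0
  upper <- if (length(cheat_pos)) min(cheat_pos) else max(phi_grid)
  direction <- if (lower > upper) "non-directional"
    else if (lower == 0 && upper == min(phi_grid)) "down"
    else if (lower == max(phi_grid) && upper == max(phi_grid)) "up"
    else "interior"
  if (lower > upper) {
    tmp <- lower; lower <- upper; upper <- tmp
  }
  structure(list(sigma_diff = sigma_diff, phi_grid = phi_grid,
                 delta_phi = delta_phi, table = tab,
                 lower = lower, upper = upper,
                 estimate = (lower + upper) / 2, direction = direction,
                 n_replicates = n_replicates, T_max = T_max, seed = seed),
            class = "ess_estimate")
}

#' @export
print.ess_estimate <- function(x, ...) {
  cat(sprintf("<ess_estimate> sigma_diff = %g: ESS in [%.3g, %.3g] (midpoint %.3g, %s selection)\n",
              x$sigma_diff, x$lower, x$upper, x$estimate, x$direction))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Lattice-scale ecosystem function of a monomorphic population
#'
#' Runs the spatial model with a fixed (non-evolving) allocation fraction
#' and measures, over `[burn_in, T_max]`, the decomposition rate — the
#' time-average of `theta` times the total lattice enzyme mass — and the
#' SOC mass per microsite averaged across the lattice and over time.
#'
#' @param params a [soil_params()] object (`p_mut` forced to 0).
#' @param phi_fixed the fixed allocation fraction.
#' @param sigma_diff DOC diffusion coefficient.
#' @param T_max horizon (h).
#' @param burn_in discarded initial transient (h).
#' @param seed seed.
#' @param n_replicates independent replicates (averaged).
#' @return an object of class `ecosystem_function`: `decomposition_rate`
#'   (mg/h), `mean_SOC_per_microsite` (mg), per-replicate values, and
#'   `extinct` (replicates that died before `burn_in`, reported, excluded
#'   from the averages).
#' @export
ecosystem_function <- function(params, phi_fixed = params$phi,
                               sigma_diff = params$sigma_diff,
                               T_max = params$T_max, burn_in = 2e5,
                               seed = 1, n_replicates = 1) {
  if (burn_in >= T_max) stop("burn_in must be smaller than T_max")
  params$p_mut <- 0
  params$sigma_diff <- sigma_diff
  params$phi <- phi_fixed
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  dec <- soc <- rep(NA_real_, n_replicates)
  extinct <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(rep_seeds[i])
    lat <- make_fixture("steady-monomorphic", params, phi = phi_fixed)
    sim <- simulate_lattice(params, lat, T_max = T_max,
                            record_every = T_max / 400, n_track = 1L)
    tr <- sim$trajectory
    win <- tr$time >= burn_in
    if (sim$stopped_all_extinct && sim$final$t < burn_in) {
      extinct[i] <- TRUE
      warning(sprintf("replicate %d extinct at t = %.3g h, before burn-in", i,
                      sim$final$t))
      next
    }
    dec[i] <- params$theta * mean(tr$z[win])
    soc[i] <- mean(tr$c[win]) / params$L^2
  }
  structure(list(phi = phi_fixed, sigma_diff = sigma_diff,
                 decomposition_rate = mean(dec, na.rm = TRUE),
                 mean_SOC_per_microsite = mean(soc, na.rm = TRUE),
                 per_replicate = data.frame(decomposition_rate = dec,
                                            mean_SOC_per_microsite = soc,
                                            extinct = extinct),
                 T_max = T_max, burn_in = burn_in, seed = seed),
            class = "ecosystem_function")
}

#' @export
print.ecosystem_function <- function(x, ...) {
  cat(sprintf("<ecosystem_function> phi = %g, sigma_diff = %g\n",
              x$phi, x$sigma_diff))
  cat(sprintf("  decomposition rate: %.4e mg/h (theta x lattice enzyme mass)\n",
              x$decomposition_rate))
  cat(sprintf("  mean SOC per microsite: %.4e mg\n", x$mean_SOC_per_microsite))
  invisible(x)
}
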