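test_that("death waiting times are exponential with rate d_M M", {
  p <- soil_params()
  expect_identical(draw_death_time(0, p), Inf)
  expect_error(draw_death_time(-1, p), ">= 0")
  set.seed(11)
  draws <- replicate(1e4, draw_death_time(10, p))
  expect_equal(mean(draws), 1 / (p$d_M * 10), tolerance = 0.05) # 500 h
  set.seed(99); a <- draw_death_time(5, p)
  set.seed(99); b <- draw_death_time(5, p)
  expect_identical(a, b)
})

test_that("flows decouple without cells and enzymes", {
  p <- soil_params()
  site <- microsite_state(c = 1e-8, d = 2e-12, z = 0)
  out <- integrate_flows(site, dt = 10, p)
  # closed-form linear solutions for c and d
  c_exact <- p$I_C / p$l_C + (1e-8 - p$I_C / p$l_C) * exp(-p$l_C * 10)
  d_exact <- p$I_D / p$l_D + (2e-12 - p$I_D / p$l_D) * exp(-p$l_D * 10)
  expect_equal(out$site$c, c_exact, tolerance = 1e-6)
  expect_equal(out$site$d, d_exact, tolerance = 1e-6)
  expect_equal(out$site$z, 0)
  expect_length(out$Delta, 0)
  expect_error(integrate_flows(site, dt = 0, p), "dt")
})

test_that("full allocation to enzymes leaves no storage increment", {
  p <- soil_params()
  site <- toy_site(n = 2, phi = 1, d = 1e-11, z = 0)
  out <- integrate_flows(site, dt = 5, p)
  expect_equal(out$Delta, c(0, 0))
  expect_gt(out$site$z, 0)          # allocation went to enzyme production
  expect_gt(out$A, 0)               # uptake happened regardless
})

test_that("flows at the deterministic equilibrium barely drift", {
  # pick the system size at which the equilibrium holds exactly 6 cells
  # (equilibrium biomass scales linearly with k), so the integer cell count
  # of the hybrid state matches the deterministic fixed point exactly
  p0 <- soil_params()
  p <- rescale_params(p0, 10 * 6 / steady_state(p0, 0.5)$cells)
  eq <- steady_state(p, 0.5)
  expect_equal(eq$cells, 6, tolerance = 1e-9)
  site <- microsite_state(eq$state[["c"]], eq$state[["d"]], eq$state[["z"]],
                          data.frame(phi = rep(0.5, 6), S = rep(0, 6),
                                     strain = rep(1L, 6)))
  # the event-free flow omits death recycling (it arrives through discrete
  # death events), so at the deterministic fixed point the pools drift down
  # by exactly that flux; adding it back recovers stationarity
  dt <- 0.05
  out <- integrate_flows(site, dt, p)
  m <- eq$state[["m"]]
  c_fix <- out$site$c + (1 - p$l) * p$p * p$d_M * m * dt
  d_fix <- out$site$d + (1 - p$l) * (1 - p$p) * p$d_M * m * dt
  expect_lt(rel_diff(c_fix, site$c), 1e-9)
  expect_lt(rel_diff(d_fix, site$d), 1e-9)
  expect_lt(rel_diff(out$site$z, site$z), 1e-9)
})

test_that("divisions follow the excess-splitting rule", {
  p <- soil_params(p_mut = 0)
  w <- p$omega_M
  site <- toy_site(n = 1, phi = 0.5, S = 0.6 * w)
  out <- apply_divisions(site, Delta = 0.5 * w, p)
  expect_equal(nrow(out$newborns), 1)
  expect_equal(out$site$cells$S, 0.05 * w)      # (0.6 + 0.5 - 1)/2
  expect_equal(out$newborns$S, 0.05 * w)
  expect_equal(out$newborns$phi, 0.5)
  expect_equal(out$newborns$strain, 1L)
  # below threshold: no division, reserve accumulates
  out2 <- apply_divisions(site, Delta = 0.3 * w, p)
  expect_equal(nrow(out2$newborns), 0)
  expect_equal(out2$site$cells$S, 0.9 * w)
  # zero-reset variant
  out3 <- apply_divisions(site, Delta = 0.5 * w, p, zero_reset = TRUE)
  expect_equal(out3$site$cells$S, 0)
  expect_equal(out3$newborns$S, 0)
})

test_that("death recycles structural plus stored carbon, split by p", {
  p <- soil_params(l = 0, p = 0.5)
  set.seed(1)
  site <- toy_site(n = 3, S = 0, c = 0, d = 0)
  site2 <- apply_death(site, p)
  expect_equal(nrow(site2$cells), 2)
  expect_equal(site2$c, 0.5 * p$omega_M)   # 5e-10 mg
  expect_equal(site2$d, 0.5 * p$omega_M)
  # stored reserve is recycled along with the structural mass
  site$cells$S <- rep(0.4 * p$omega_M, 3)
  site3 <- apply_death(site, p)
  expect_equal(site3$c + site3$d, 1.4 * p$omega_M)
  # full leaching: nothing comes back
  pl <- soil_params(l = 1)
  site4 <- apply_death(toy_site(n = 1, c = 0, d = 0), pl)
  expect_equal(site4$c, 0)
  expect_equal(site4$d, 0)
  expect_equal(nrow(site4$cells), 0)
  expect_error(apply_death(site4, pl), "empty")
})

test_that("single-site runs persist without mutation and never shrink without death", {
  p <- soil_params()
  set.seed(21)
  sim <- simulate_site(p, phi0 = 0.5, T_max = 5e4)
  tr <- sim$trajectory
  expect_gt(min(tr$M), 0)                 # no extinction on this horizon
  expect_equal(tr$mean_phi, rep(0.5, nrow(tr)))  # no mutation: trait frozen
  # d_M = 0: cell count is non-decreasing
  p0 <- soil_params()
  set.seed(22)
  lat <- make_fixture("steady-monomorphic", p0, phi = 0.5)
  p0$d_M <- 0
  p0$L <- 1; p0$sigma_diff <- 0
  lat1 <- lattice_state(p0, L = 1)
  lat1$c[1] <- lat$c[1]; lat1$d[1] <- lat$d[1]; lat1$z[1] <- lat$z[1]
  lat1$cells[[1]] <- lat$cells[[1]]
  sim0 <- simulate_lattice(p0, lat1, T_max = 2e4)
  expect_true(all(diff(sim0$trajectory$M) >= 0))
  expect_equal(sim0$counters$deaths, 0)
})

test_that("fixed seeds reproduce single-site trajectories bit for bit", {
  p <- soil_params()
  set.seed(5); a <- simulate_site(p, 0.5, T_max = 1e4, with_mutation = TRUE)
  set.seed(5); b <- simulate_site(p, 0.5, T_max = 1e4, with_mutation = TRUE)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$counters, b$counters)
  set.seed(6); c_ <- simulate_site(p, 0.5, T_max = 1e4, with_mutation = TRUE)
  expect_false(identical(a$trajectory, c_$trajectory))
})

test_that("hybrid event loop closes the carbon budget to integrator tolerance", {
  p <- soil_params()
  set.seed(31)
  sim <- simulate_site(p, 0.5, T_max = 5e4)
  tr <- sim$trajectory
  n <- nrow(tr)
  dC <- total_carbon(tr[n, ], p$omega_M) - total_carbon(tr[1, ], p$omega_M)
  budget <- tr$cum_input[n] - tr$cum_leach[n] - tr$cum_resp[n] +
    sim$ledger$discard
  expect_lt(rel_diff(dC, budget), 1e-8)
  # and with leaching of dead carbon switched on
  p2 <- soil_params(l = 0.3)
  set.seed(32)
  sim2 <- simulate_site(p2, 0.5, T_max = 2e4)
  tr2 <- sim2$trajectory
  n2 <- nrow(tr2)
  dC2 <- total_carbon(tr2[n2, ], p2$omega_M) - total_carbon(tr2[1, ], p2$omega_M)
  budget2 <- tr2$cum_input[n2] - tr2$cum_leach[n2] - tr2$cum_resp[n2] +
    sim2$ledger$discard
  expect_lt(rel_diff(dC2, budget2), 1e-8)
})

test_that("with mutation the allocation trait erodes toward extinction", {
  # selection in a well-mixed site is always against enzyme production, so
  # the mean trait declines (drift allowing) over an evolutionary run
  p <- soil_params(p_mut = 0.1)
  drops <- 0
  set.seed(41)
  n_rep <- 4
  for (i in seq_len(n_rep)) {
    sim <- simulate_site(p, phi0 = 0.5, T_max = 4e5, with_mutation = TRUE)
    tr <- sim$trajectory
    last <- tail(tr$mean_phi[!is.na(tr$mean_phi)], 1)
    if (last < 0.5 || sim$stopped_all_extinct) drops <- drops + 1
  }
  expect_gte(drops, 3)   # most replicates decline (or die trying)
})
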