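test_that("the diffusion stencil spreads a spike exactly as written", {
  p <- fast_params(L = 5)
  d0 <- 3e-9
  lat <- make_fixture("doc-spike", p, doc_total = d0, spike_site = 13) # (3,3)
  tau <- 0.05
  f <- p$sigma_diff * tau / (p$V * p$k)^(2 / 3)
  out <- diffuse_doc(lat, tau, p)
  expect_equal(out$d[3, 3], d0 - 4 * f * d0)
  expect_equal(out$d[2, 3], f * d0)
  expect_equal(out$d[4, 3], f * d0)
  expect_equal(out$d[3, 2], f * d0)
  expect_equal(out$d[3, 4], f * d0)
  expect_equal(sum(out$d != 0), 5)
})

test_that("uniform DOC is a fixed point and stability is guarded", {
  p <- fast_params(L = 4)
  lat <- lattice_state(p)
  lat$d[] <- 7e-12
  out <- diffuse_doc(lat, 0.05, p)
  expect_equal(out$d, lat$d)
  expect_error(diffuse_doc(lat, 1e4, p), "unstable|reduce tau")
})

test_that("diffusion conserves total DOC on random lattices", {
  p <- fast_params(L = 6)
  set.seed(3)
  worst <- 0
  for (i in 1:200) {
    lat <- lattice_state(p)
    lat$d[] <- stats::runif(36) * 10^stats::runif(36, -14, -9)
    out <- diffuse_doc(lat, 0.05, p)
    worst <- max(worst, rel_diff(sum(out$d), sum(lat$d)))
  }
  expect_lt(worst, 1e-12)
})

test_that("newborn placement follows the dispersal decision tree", {
  p <- fast_params(L = 3, p_disp = 0)
  lat <- make_fixture("steady-monomorphic", p, phi = 0.5)
  nb <- data.frame(phi = 0.5, S = 0, strain = 1L)
  set.seed(8)
  for (i in 1:50) {
    out <- place_newborn(lat, 5, nb, p)
    expect_equal(out$placed_at, 5)       # p_disp = 0: always stays
    expect_false(out$dispersed)
  }
  # all neighbours occupied and p_open = 0: dispersal always fails
  p2 <- fast_params(L = 3, p_disp = 1, p_open = 0)
  set.seed(9)
  for (i in 1:50) {
    out <- place_newborn(lat, 5, nb, p2)
    expect_equal(out$placed_at, 5)
    expect_false(out$disturbed)
  }
  # an empty neighbour attracts dispersers at rate p_disp
  p3 <- fast_params(L = 3, p_disp = 0.3)
  lat3 <- lat
  lat3$cells[[2]] <- empty_cells()
  set.seed(10)
  n <- 2000
  moved <- 0
  for (i in 1:n) {
    out <- place_newborn(lat3, 5, nb, p3)
    if (out$placed_at == 2) moved <- moved + 1
    expect_true(out$placed_at %in% c(2, 5))  # only empty neighbour eligible
  }
  expect_lt(abs(moved / n - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("micro-disturbance kills, recycles locally, and is a no-op when empty", {
  p <- fast_params(L = 3, l = 0, p = 0.5)
  lat <- lattice_state(p)
  lat$cells[[4]] <- data.frame(phi = rep(0.4, 7), S = rep(0, 7),
                               strain = rep(1L, 7))
  out <- micro_disturbance(lat, 4, p)
  expect_equal(nrow(out$cells[[4]]), 0)
  expect_equal(out$c[4], 3.5e-9)   # (1-l) p omega_M M
  expect_equal(out$d[4], 3.5e-9)
  expect_equal(sum(out$c[-4]), 0)  # recycling is local
  # l = 1: cells removed, nothing recycled
  p1 <- fast_params(L = 3, l = 1)
  out1 <- micro_disturbance(lat, 4, p1)
  expect_equal(nrow(out1$cells[[4]]), 0)
  expect_equal(out1$c[4], 0)
  # empty target is a no-op
  out2 <- micro_disturbance(lat, 5, p)
  expect_equal(out2$c, lat$c)
  expect_error(micro_disturbance(lat, 99, p), "exist")
})

test_that("an empty lattice advances by the diffusion step only", {
  p <- fast_params(L = 3)
  lat <- make_fixture("doc-spike", p, doc_total = 1e-10, spike_site = 5)
  set.seed(2)
  out <- step_lattice(lat, p)
  expect_equal(out$t, attr(out, "info")$dt)  # clock advanced by tau
  expect_equal(sum(vapply(out$cells, nrow, 0L)), 0L)
  expect_lt(out$d[5], 1e-10)            # spike spread
  dC <- sum(out$d) + sum(out$c) - (sum(lat$d) + sum(lat$c))
  budget <- attr(out, "info")$ledger[["input"]] -
    attr(out, "info")$ledger[["leach"]]
  expect_lt(rel_diff(dC, budget), 1e-6)
})

test_that("the reference R loop and the compiled loop agree without stochastic events", {
  p <- fast_params(L = 4)
  set.seed(5)
  lat <- make_fixture("steady-monomorphic", p, phi = 0.5)
  lat$d[1] <- lat$d[1] * 50            # perturbation so diffusion acts
  p$d_M <- 0; p$p_mut <- 0             # no jumps: fully deterministic
  latR <- lat
  for (i in 1:15) latR <- step_lattice(latR, p)
  sim <- simulate_lattice(p, lat, T_max = latR$t, record_every = latR$t)
  latC <- sim$final
  expect_equal(latC$t, latR$t, tolerance = 1e-12)
  expect_lt(max(rel_diff(latR$c, latC$c)), 1e-10)
  expect_lt(max(rel_diff(latR$d, latC$d)), 1e-10)
  expect_lt(max(rel_diff(latR$z, latC$z)), 1e-10)
  sR <- unlist(lapply(latR$cells, function(x) sort(x$S)))
  sC <- unlist(lapply(latC$cells, function(x) sort(x$S)))
  expect_equal(sR, sC, tolerance = 1e-10)
})

test_that("lattice runs close the carbon budget through dispersal and disturbance", {
  p <- fast_params(L = 5)
  set.seed(13)
  lat <- make_fixture("steady-monomorphic", p, phi = 0.3)
  sim <- simulate_lattice(p, lat, T_max = 3e4)
  tr <- sim$trajectory
  n <- nrow(tr)
  dC <- total_carbon(tr[n, ], p$omega_M) - total_carbon(tr[1, ], p$omega_M)
  budget <- tr$cum_input[n] - tr$cum_leach[n] - tr$cum_resp[n] +
    sim$ledger$discard
  expect_lt(rel_diff(dC, budget), 1e-8)
  expect_gt(sim$counters$dispersals, 0)  # spatial events actually exercised
})

test_that("lattice trajectories are bit-reproducible under a fixed seed", {
  p <- fast_params(L = 4)
  set.seed(77)
  lat <- make_fixture("steady-monomorphic", p, phi = 0.5)
  set.seed(78); a <- simulate_lattice(p, lat, T_max = 5e3)
  set.seed(78); b <- simulate_lattice(p, lat, T_max = 5e3)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final, b$final)
})

test_that("decoupled sites behave like independent single-site runs", {
  # with no diffusion and no dispersal, per-site dynamics on a lattice are
  # statistically the same as isolated single-site runs
  p <- fast_params(L = 3, sigma_diff = 0, p_disp = 0)
  set.seed(50)
  lat <- make_fixture("steady-monomorphic", p, phi = 0.5)
  sim <- simulate_lattice(p, lat, T_max = 4e4)
  mean_lattice <- mean(sim$trajectory$M) / 9
  p1 <- soil_params(sigma_diff = 0, p_disp = 0)
  singles <- numeric(9)
  for (i in 1:9) {
    set.seed(50 + i)
    s <- simulate_site(p1, 0.5, T_max = 4e4)
    singles[i] <- mean(s$trajectory$M)
  }
  se <- sd(singles) / sqrt(9) + 0.25
  expect_lt(abs(mean_lattice - mean(singles)), 4 * se)
})

test_that("no DOC piles up at corners in a neutral monomorphic run", {
  p <- fast_params(L = 4)
  set.seed(60)
  lat <- make_fixture("steady-monomorphic", p, phi = 0.5)
  sim <- simulate_lattice(p, lat, T_max = 3e4, record_every = 3e4)
  fin <- sim$final
  corners <- c(fin$d[1, 1], fin$d[1, 4], fin$d[4, 1], fin$d[4, 4])
  centre <- c(fin$d[2, 2], fin$d[2, 3], fin$d[3, 2], fin$d[3, 3])
  # same order of magnitude: corner mean within a factor 3 of centre mean
  expect_lt(abs(log(mean(corners) / mean(centre))), log(3))
})
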