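test_that("parameter and initial-condition validation rejects bad input", {
  expect_error(rate_params(-0.02, 10, 2, 0.2, 10), "finite and >= 0")
  expect_error(rate_params(0.02, Inf, 2, 0.2, 10), "finite and >= 0")
  expect_error(rate_params(0.02, 10, 2, 0.2, 1), "integer >= 2")
  expect_error(rate_params(0.02, 10, 2, 0.2, 10.5), "integer >= 2")
  expect_error(initial_conditions(-0.4, ratio = 100), "> 0")
  expect_error(initial_conditions(0.4), "one of")
  expect_error(initial_conditions(0.4, ratio = 100, I0 = 0.01), "inconsistent")
  ic <- initial_conditions(0.4, I0 = 0.004)
  expect_equal(ic$ratio, 100)
})

test_that("network assembly: automatic truncation and validation", {
  net <- build_network(two_stage_params(), std_ic())
  expect_equal(net$Nmax, 400L)
  expect_error(build_network(two_stage_params(), std_ic(), Nmax = 1.5),
               "integer >= 2")
  expect_warning(build_network(two_stage_params(), std_ic(), Nmax = 150),
                 "too short")
  # s beyond the ladder is the documented single-stage limit, not an error
  expect_silent(single_stage_network())
})

test_that("initial-state derivative has only the initiation flux active", {
  net <- build_network(two_stage_params(), std_ic())
  y0 <- helixkin:::initial_state_vector(net)
  d <- network_rhs(y0, net)
  flux <- 0.02 * 0.4 * 0.004
  expect_equal(unname(d["M"]), -flux)
  expect_equal(unname(d["P0"]), -flux)
  expect_equal(unname(d["P1"]), flux)
  expect_equal(sum(abs(d[setdiff(names(d), c("M", "P0", "P1"))])), 0)
})

test_that("zero monomer shuts off all bimolecular fluxes", {
  net <- build_network(two_stage_params(), std_ic(ratio = 20))
  y <- random_state_vector(net, seed = 3)
  y[1] <- 0
  d <- network_rhs(y, net)
  st <- chain_state(y, net)
  # only desorption feeds the monomer pool
  expect_equal(unname(d["M"]), 2 * sum(st$C))
  # coil chains are frozen: dP_i = 0 for 0 < i < s (no k1 flux without M)
  expect_equal(unname(d["P0"]), 0)
  expect_equal(unname(d[paste0("P", 1:9)]), rep(0, 9))
})

test_that("rate equations conserve chains and monomer units analytically", {
  net <- build_network(two_stage_params(), std_ic(ratio = 25))
  for (seed in 1:5) {
    y <- random_state_vector(net, seed)
    d <- network_rhs(y, net)
    st_names <- names(d)
    dP <- d[grep("^P", st_names)]
    dC <- d[grep("^C", st_names)]
    dp_P <- as.numeric(sub("P", "", names(dP)))
    dp_C <- as.numeric(sub("C", "", names(dC)))
    # total chain count is invariant
    expect_lt(abs(sum(dP) + sum(dC)), 1e-16 * net$ic$I0 + 1e-12)
    # monomer-unit balance: M + sum(i P_i) + sum((i+1) C_i) is invariant
    dmass <- d[["M"]] + sum(dp_P * dP) + sum((dp_C + 1) * dC)
    expect_lt(abs(dmass), 1e-12)
  }
})

test_that("unreachable helix stage reduces the scheme to pure chain growth", {
  ic <- std_ic(ratio = 25)
  net_deg <- build_network(rate_params(0.02, 10, 2, 0.2, s = 500), ic, Nmax = 100)
  net_ref <- build_network(rate_params(0.02, 0, 0, 0, s = 500), ic, Nmax = 100)
  for (seed in 1:3) {
    y <- random_state_vector(net_deg, seed)
    expect_equal(network_rhs(y, net_deg), network_rhs(y, net_ref))
  }
})

test_that("compiled right-hand side matches the R reference implementation", {
  net <- build_network(two_stage_params(), std_ic(M0 = 0.2, ratio = 20),
                       Nmax = 320)
  times <- c(0, 50, 200, 800, 2000)
  traj <- simulate_kinetics(net, times = times)
  y0 <- helixkin:::initial_state_vector(net)
  ref <- deSolve::ode(
    y = y0, times = times,
    func = function(t, y, parms) list(unname(network_rhs(y, net))),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-14
  )
  for (i in seq_along(times)) {
    expect_equal(unname(traj$y[i, ]), unname(ref[i, -1]), tolerance = 1e-6)
  }
})

test_that("conservation residuals: exactness at t0 and linear response", {
  net <- build_network(two_stage_params(), std_ic())
  y0 <- helixkin:::initial_state_vector(net)
  st0 <- chain_state(y0, net)
  expect_equal(unname(conservation_residuals(st0)), c(0, 0))
  delta <- 1e-5
  y1 <- y0
  y1["P5"] <- y1["P5"] + delta
  r <- conservation_residuals(chain_state(y1, net))
  expect_equal(unname(r["chain"]), delta / net$ic$I0)
  expect_equal(unname(r["mass"]), 5 * delta / net$ic$M0)
})

test_that("stalled second stage: kon = 0 freezes conversion at the transition", {
  p <- rate_params(0.02, kon = 0, koff = 0, kr = 0.2, s = 10)
  net <- build_network(p, std_ic(ratio = 100))
  traj <- simulate_kinetics(net, t_end = 5e5, n_out = 80)
  x <- conversion(traj, "free-monomer")$conversion
  # every chain can incorporate at most s units before stalling
  expect_lt(max(x), 10 * net$ic$I0 / net$ic$M0 + 1e-6)
  expect_gt(max(x), 0.5 * 10 * net$ic$I0 / net$ic$M0)
})
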