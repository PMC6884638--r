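test_that("initial state has an empty polymer distribution", {
  net <- build_network(two_stage_params(), std_ic())
  st <- chain_state(helixkin:::initial_state_vector(net), net)
  cld <- chain_length_distribution(st)
  expect_equal(nrow(cld), 0)
  expect_equal(attr(cld, "residual_initiator"), 0.004)
  expect_error(mw_moments(cld), "empty")
})

test_that("single-stage terminal distribution is Poisson", {
  net <- single_stage_network()
  traj <- simulate_kinetics(net, t_end = 6e4, n_out = 60)
  st <- terminal_state(traj)
  nu <- (0.4 - st$M) / 0.004      # consumed monomer per chain
  cld <- chain_length_distribution(st, drop_empty = FALSE)
  tvd <- 0.5 * (sum(abs(cld$conc / 0.004 - dpois(cld$dp, nu))) +
                  ppois(max(cld$dp), nu, lower.tail = FALSE))
  expect_lt(tvd, 1e-3)
  # first-order dispersity law of living chain growth
  m <- mw_moments(cld, residue_mass = 1, end_mass = 0)
  expect_equal(m$dispersity, 1 + 1 / m$DPn, tolerance = 1e-3)
})

test_that("moment identities: monodisperse and Poisson references", {
  mono <- structure(data.frame(dp = 100, conc = 0.004),
                    s = 10, I0 = 0.004,
                    class = c("chain_length_distribution", "data.frame"))
  expect_equal(mw_moments(mono)$dispersity, 1)
  expect_equal(mw_moments(mono)$Mn, 100 * 219.24 + 101.19)

  pois <- poisson_reference(100, I0 = 0.004)
  m <- mw_moments(pois, residue_mass = 1, end_mass = 0)
  expect_equal(m$DPw / m$DPn, 1 + 1 / 100, tolerance = 1e-4)
  # with the initiator residue counted (DP + 1 basis) the textbook form holds
  m1 <- mw_moments(pois, residue_mass = 1, end_mass = 1)
  expect_equal(m1$dispersity, 1 + 100 / 101^2, tolerance = 1e-4)
  # Poisson mode: at integer nu the mass ties at {nu - 1, nu}
  expect_true(pois$dp[which.max(pois$conc)] %in% c(99, 100))
  expect_true(all(poisson_reference(0, I0 = 0.004)$conc == 0))
  expect_equal(attr(poisson_reference(0, I0 = 0.004), "residual_initiator"),
               0.004)
})

test_that("design molecular weights reproduce the feed-ratio arithmetic", {
  expect_identical(design_mw(c(50, 100, 150)), c(11.1, 22.0, 33.0))
  expect_identical(design_mw(0), 0.1)
})

test_that("mass closure: the distribution accounts for every converted monomer", {
  net <- build_network(two_stage_params(), std_ic())
  traj <- simulate_kinetics(net, n_out = 60)
  for (i in c(20, 40, 60)) {
    st <- get_state(traj, i)
    cld <- chain_length_distribution(st)
    incorporated <- 0.4 - st$M - sum(st$C)   # bound monomer is not chain mass
    if (incorporated > 1e-6) {
      expect_equal(sum(cld$dp * cld$conc), incorporated,
                   tolerance = 1e-6)
    }
  }
})

test_that("two-stage MWD: asymmetric, short-chain tail varies with [M]0", {
  skew <- function(cld) {
    w <- cld$conc / sum(cld$conc)
    m1 <- sum(cld$dp * w)
    sum((cld$dp - m1)^3 * w) / (sum((cld$dp - m1)^2 * w))^1.5
  }
  clds <- lapply(c(0.2, 0.4), function(M0) {
    ic <- std_ic(M0 = M0)
    net <- build_network(two_stage_params(), ic, Nmax = 2000)
    traj <- simulate_kinetics(net, t_end = 3 * time_to_conversion(net, 0.99),
                              n_out = 50)
    chain_length_distribution(terminal_state(traj))
  })
  m <- lapply(clds, mw_moments)
  # dispersity exceeds 1 (strictly) and weight-average dominates
  for (mm in m) {
    expect_gt(mm$dispersity, 1)
    expect_gte(mm$DPw, mm$DPn)
  }
  # left-skewed versus the right-skewed Poisson of equal mean
  pois <- poisson_reference(m[[2]]$DPn, I0 = 0.004)
  expect_lt(skew(clds[[2]]), 0)
  expect_gt(skew(pois), 0)
  # nonzero short-chain mass fraction, decreasing with [M]0
  scf <- vapply(m, `[[`, numeric(1), "short_chain_mass_fraction")
  expect_true(all(scf > 0.001))
  expect_gt(scf[1], scf[2] * 1.2)
  # the distributions themselves depend on [M]0
  nmax <- max(clds[[1]]$dp, clds[[2]]$dp)
  pad <- function(cld) {
    v <- numeric(nmax); v[cld$dp] <- cld$conc / sum(cld$conc); v
  }
  tvd <- 0.5 * sum(abs(pad(clds[[1]]) - pad(clds[[2]])))
  expect_gt(tvd, 0.01)
})

test_that("GPC-like trace is normalized and peaks at the distribution mode", {
  pois <- poisson_reference(100, I0 = 0.004)
  tr <- gpc_trace(pois, broadening_sigma = 0.02)
  area <- sum(diff(tr$log10_M) * (head(tr$signal, -1) + tail(tr$signal, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-9)
  peak <- tr$log10_M[which.max(tr$signal)]
  expect_equal(peak, log10(100 * 219.24 + 101.19), tolerance = 0.02)

  mono <- structure(data.frame(dp = 100, conc = 0.004),
                    s = 10, I0 = 0.004,
                    class = c("chain_length_distribution", "data.frame"))
  tr0 <- gpc_trace(mono, broadening_sigma = 0)
  expect_equal(sum(tr0$signal > 0), 1)
})
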