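# canonical two-stage parameter set used throughout the tests
# (illustration constants of the helix-catalyzed model)
two_stage_params <- function() {
  rate_params(k1 = 0.02, kon = 10, koff = 2, kr = 0.2, s = 10)
}

std_ic <- function(M0 = 0.4, ratio = 100) initial_conditions(M0, ratio = ratio)

# degenerate single-stage network: s beyond the ladder, pure coil growth
single_stage_network <- function(M0 = 0.4, ratio = 100, k1 = 0.02) {
  build_network(rate_params(k1, 10, 2, 0.2, s = 2000),
                std_ic(M0, ratio), Nmax = ceiling(4 * ratio))
}

# random nonnegative state consistent with a network's layout (not conserving)
random_state_vector <- function(network, seed = 1) {
  n <- helixkin:::state_dim(network)
  set.seed(seed)
  y <- runif(n) * network$ic$I0
  y[1] <- runif(1) * network$ic$M0
  y
}
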