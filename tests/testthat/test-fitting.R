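test_that("dataset construction validates its invariants", {
  ic <- std_ic()
  expect_error(kinetic_dataset(c(10, 5), c(0.1, 0.2), ic), "increasing")
  expect_error(kinetic_dataset(c(10, 20), c(0.1, 1.5), ic), "outside")
  ds <- kinetic_dataset(c(10, 20), c(-0.01, 1.01), ic)   # raw overshoot kept
  expect_s3_class(ds, "kinetic_dataset")
})

test_that("fit specification enforces the parameter partition", {
  expect_error(fit_spec(shared = c("kr", "k1"), individual = c("k1", "K")),
               "disjoint")
  expect_error(fit_spec(shared = "s", individual = c("k1", "K"),
                        fixed = list(koff = 2)), "exactly one")
  expect_error(fit_spec(fixed = list()), "koff")
  expect_error(fit_spec(shared = c("kr", "s"), s_grid = c(1, 2)), "integers >= 2")
})

test_that("objective: zero at truth on noiseless data, larger off-truth", {
  truth <- two_stage_params()
  ds <- generate_dataset(truth, std_ic(), noise = noise_model(sigma_add = 0))[[1]]
  at_truth <- sse_objective(list(k1 = 0.02, K = 5, kr = 0.2, s = 10), ds)
  expect_lt(at_truth, 1e-8)
  off <- sse_objective(list(k1 = 0.04, K = 5, kr = 0.2, s = 10), ds)
  expect_gt(off, at_truth)
  # nine-dataset panel at truth: SSE concentrates around n * sigma^2
  panel <- generate_panel(truth, noise = noise_model(sigma_add = 0.01, seed = 2))
  n_pts <- sum(vapply(panel, function(d) length(d$times), integer(1)))
  sse <- sse_objective(list(k1 = 0.02, K = 5, kr = 0.2, s = 10), panel)
  expect_gt(sse, 0.5 * n_pts * 1e-4)
  expect_lt(sse, 2.0 * n_pts * 1e-4)
})

test_that("one-parameter fit on noiseless data is essentially exact", {
  truth <- two_stage_params()
  ds <- generate_dataset(truth, std_ic(), noise = noise_model(sigma_add = 0))[[1]]
  spec <- fit_spec(shared = "k1", individual = character(0),
                   fixed = list(K = 5, kr = 0.2, koff = 2, s = 10),
                   n_starts = 2)
  fit <- suppressWarnings(global_fit(list(ds), spec))
  k1_hat <- subset(fit$estimates, parameter == "k1")$estimate
  expect_lt(abs(k1_hat / 0.02 - 1), 1e-3)
  expect_lt(max(abs(fit$residuals[[1]])), 1e-4)
})

test_that("nine-dataset recovery around the generating parameters", {
  truth <- two_stage_params()
  panel <- generate_panel(truth, noise = noise_model(sigma_add = 0.01, seed = 1))
  fit <- suppressWarnings(
    global_fit(panel, fit_spec(s_grid = 8:12, n_starts = 4, seed = 1))
  )
  expect_equal(fit$s, 10L)
  k1s <- subset(fit$estimates, parameter == "k1")$estimate
  Ks <- subset(fit$estimates, parameter == "K")$estimate
  krv <- subset(fit$estimates, parameter == "kr")$estimate
  expect_lt(max(abs(k1s / 0.02 - 1)), 0.10)
  expect_lt(max(abs(Ks / 5 - 1)), 0.25)
  expect_lt(abs(krv / 0.2 - 1), 0.25)
  # objective self-consistency: optimum is no worse than the truth
  sse_truth <- sse_objective(list(k1 = 0.02, K = 5, kr = 0.2, s = 10), panel,
                             rtol = 1e-6)
  expect_lte(fit$sse, sse_truth + 1e-8)
})

test_that("kon/koff are degenerate at fixed K in the fast-equilibrium regime", {
  ic <- std_ic()
  times <- seq(100, 4000, by = 100)
  xs <- lapply(c(1, 10), function(f) {
    p <- rate_params(0.02, kon = 100 * f, koff = 20 * f, kr = 0.2, s = 10)
    conversion(simulate_kinetics(build_network(p, ic), times = times,
                                 model = "lumped"))$conversion
  })
  expect_lt(max(abs(xs[[1]] - xs[[2]])), 0.005)
})

test_that("binding free energy conversion and its inversion", {
  expect_equal(binding_free_energy(1, 298), 0)
  expect_equal(binding_free_energy(5, 298), -0.953, tolerance = 1e-3)
  expect_equal(binding_free_energy(57.6, 298), -2.4, tolerance = 0.01)
  # inverting -2.4 kcal/mol at 298 K recovers K ~ 57.6 1/M
  expect_equal(exp(2.4 / (1.98720e-3 * 298)), 57.6, tolerance = 1e-3)
  expect_error(binding_free_energy(0), "> 0")
})

test_that("predictions close the loop: overlay, DPn round trip, Mn vs ratio", {
  truth <- two_stage_params()
  panel3 <- generate_panel(truth, M0_list = 0.4, ratio_list = c(50, 100, 150),
                           noise = noise_model(sigma_add = 0.01, seed = 4))
  spec <- fit_spec(s_grid = 9:11, n_starts = 2, seed = 4)
  fit <- suppressWarnings(global_fit(panel3, spec))
  preds <- lapply(seq_along(panel3), function(d) predict_from_fit(fit, d))
  Mn <- vapply(preds, function(p) p$mw$Mn, numeric(1))
  expect_true(all(diff(Mn) > 0))
  # round trip: predicted terminal DPn near the generating-model DPn
  net <- build_network(truth, panel3[[2]]$ic)
  DPn_gen <- mw_moments(chain_length_distribution(
    simulate_kinetics(net, t_end = max(panel3[[2]]$times))))$DPn
  expect_lt(abs(preds[[2]]$mw$DPn / DPn_gen - 1), 0.05)
  expect_error(predict_from_fit(fit, 99), "no fitted parameters")

  # noiseless self-fit overlays its own data
  ds0 <- generate_dataset(truth, std_ic(), noise = noise_model(sigma_add = 0))[[1]]
  spec0 <- fit_spec(shared = "k1", individual = character(0),
                    fixed = list(K = 5, kr = 0.2, koff = 2, s = 10),
                    n_starts = 2)
  fit0 <- suppressWarnings(global_fit(list(ds0), spec0))
  pr <- predict_from_fit(fit0, 1)
  expect_lt(max(abs(pr$at_times$conversion - ds0$conversion)), 1e-4)
})

test_that("bootstrap: degenerate width on noiseless data, flags non-identifiability", {
  truth <- two_stage_params()
  ds0 <- generate_dataset(truth, std_ic(), noise = noise_model(sigma_add = 0))[[1]]
  spec0 <- fit_spec(shared = "k1", individual = character(0),
                    fixed = list(K = 5, kr = 0.2, koff = 2, s = 10),
                    n_starts = 2)
  fit0 <- suppressWarnings(global_fit(list(ds0), spec0))
  ci0 <- suppressWarnings(bootstrap_ci(fit0, n_boot = 30, seed = 1))
  expect_lt(ci0$upper / ci0$lower - 1, 1e-3)
  expect_false(ci0$non_identifiable)

  # first-stage-only data cannot pin the binding constant
  full <- generate_dataset(truth, std_ic(),
                           noise = noise_model(sigma_add = 0.005, seed = 6))[[1]]
  keep <- full$conversion <= 0.12
  early <- kinetic_dataset(full$times[keep], full$conversion[keep], full$ic)
  spec1 <- fit_spec(shared = c("k1", "K"), individual = character(0),
                    fixed = list(kr = 0.2, koff = 2, s = 10), n_starts = 2)
  fit1 <- suppressWarnings(global_fit(list(early), spec1))
  ci1 <- suppressWarnings(bootstrap_ci(fit1, n_boot = 40, seed = 2))
  expect_true(ci1$non_identifiable[ci1$parameter == "K"])
  expect_false(ci1$non_identifiable[ci1$parameter == "k1"])
})
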