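test_that("SSR: zero at truth, one per 1-sd deviation, order-invariant", {
  s <- toy1_setup()
  truth <- random_flux_state(s$net, seed = 11)
  mp <- make_problem(s, truth, noise_sd = 0, seed = 1)
  th <- truth_theta(mp$problem, truth)
  expect_lt(ssr_objective(th, mp$problem), 1e-10)

  # shift one flux measurement by exactly 1 sd
  p2 <- mp$problem
  p2$measurements$flux_measurements$value <-
    p2$measurements$flux_measurements$value + p2$measurements$flux_measurements$sd
  expect_equal(ssr_objective(th, p2), 1, tolerance = 1e-6)

  # reordering measurements leaves the SSR unchanged
  p3 <- mp$problem
  p3$measurements$mid_measurements <- rev(p3$measurements$mid_measurements)
  th_r <- truth_theta(p3, truth)
  expect_equal(ssr_objective(th_r, p3), ssr_objective(th, mp$problem),
               tolerance = 1e-12)
})

test_that("noiseless toy1 fits recover the generating fluxes", {
  s <- toy1_setup()
  truth <- random_flux_state(s$net, seed = 11)
  mp <- make_problem(s, truth, noise_sd = 0, seed = 1)
  fit <- fit_fluxes(mp$problem, fit_options(n_starts = 10, seed = 3))
  expect_lt(fit$ssr, 1e-6)
  expect_lt(max(abs(fit$best_flux$net - truth$net)), 0.1)
  # 6 closure-aware datapoints; the exchange of the isomerization joins two
  # identically labeled pools, so only the branch flux is effective
  expect_equal(fit$dof, 5)
  # identical seed, identical result
  fit2 <- fit_fluxes(mp$problem, fit_options(n_starts = 10, seed = 3))
  expect_identical(fit, fit2)
})

test_that("excluded fragments are dropped before fitting", {
  s <- toy1_setup()
  truth <- random_flux_state(s$net, seed = 11)
  exp <- generate_experiment(s$net, truth, s$recipe, s$fragments,
                             noise_sd = 0, seed = 1, flux_meas = s$flux_meas)
  mids <- lapply(exp$measurements$mid_measurements, function(m)
    list(fragment = m$fragment, mid = m$mid, sd = m$sd))
  ms <- measurement_set(mids, exp$flux_meas, excluded_fragments = "C_full")
  expect_length(ms$mid_measurements, 2)
  p <- flux_problem(s$net, s$recipe, ms, c(v1 = 100))
  expect_equal(p$n_data, 3 + 1)  # two fragments (2+1 channels) + one rate
})

test_that("knockouts redirect the fitted branch flux", {
  s <- toy1_setup()
  net_ko <- modify_network(s$net, knockout = "v2")
  # with v2 off, conservation forces all branch flux through v3
  fl_ko <- flux_state(net_ko, c(v1 = 100, v2 = 0, v3 = 100, v4 = 0,
                                v5 = 100, v6 = 0), c(v4 = 1))
  exp <- generate_experiment(net_ko, fl_ko,
                             s$recipe, s$fragments, noise_sd = 0, seed = 1,
                             flux_meas = s$flux_meas)
  p <- flux_problem(net_ko, s$recipe, exp$measurements, c(v1 = 100))
  fit <- fit_fluxes(p, fit_options(n_starts = 4, seed = 2))
  expect_equal(fit$best_flux$net[["v2"]], 0, tolerance = 1e-5)
  expect_equal(fit$best_flux$net[["v3"]], 100, tolerance = 1e-5)
})

test_that("adding a datapoint never decreases the optimal SSR", {
  s <- toy1_setup()
  truth <- random_flux_state(s$net, seed = 13)
  exp <- generate_experiment(s$net, truth, s$recipe, s$fragments,
                             noise_sd = 0.004, seed = 5, flux_meas = s$flux_meas)
  mids <- exp$measurements$mid_measurements
  opts <- fit_options(n_starts = 6, seed = 4)
  ssrs <- vapply(seq_along(mids), function(k) {
    ms <- measurement_set(mids[seq_len(k)], exp$flux_meas)
    fit_fluxes(flux_problem(s$net, s$recipe, ms, c(v1 = 100)), opts)$ssr
  }, numeric(1))
  expect_true(all(diff(ssrs) >= -1e-6))
})

test_that("chi2 test: critical values bracket the mean, extremes fail", {
  for (dof in c(1, 2, 5, 10, 50, 100)) {
    ct <- chi2_test(dof, dof, alpha = 0.05)
    expect_true(ct$pass, info = paste("dof", dof))
    expect_lt(ct$lower_critical, dof)
    expect_gt(ct$upper_critical, dof)
  }
  expect_false(chi2_test(1000, 10)$pass)
  expect_false(chi2_test(0.001, 10)$pass)
  expect_true(chi2_test(0.001, 10, two_sided = FALSE)$pass)
  expect_error(chi2_test(5, 0), "dof")
})

test_that("Monte-Carlo CIs: zero noise gives zero width, seeds reproduce", {
  s <- toy1_setup()
  truth <- random_flux_state(s$net, seed = 11)
  exp <- generate_experiment(s$net, truth, s$recipe, s$fragments,
                             noise_sd = 0, seed = 1, flux_meas = s$flux_meas)
  # zero-sd measurement set: intervals must collapse onto the estimate
  mids0 <- lapply(exp$measurements$mid_measurements, function(m) {
    m$sd <- rep(0, length(m$sd)); m
  })
  fm0 <- exp$flux_meas; fm0$sd <- 1e-12
  ms0 <- measurement_set(mids0, fm0)
  p0 <- flux_problem(s$net, s$recipe, ms0, c(v1 = 100))
  fit0 <- fit_fluxes(p0, fit_options(n_starts = 4, seed = 2))
  ci0 <- monte_carlo_ci(p0, fit0, n_iterations = 20, seed = 7)
  expect_lt(max(ci0$intervals$upper - ci0$intervals$lower), 1e-6)

  mp <- make_problem(s, truth, noise_sd = 0.004, seed = 3)
  fit <- fit_fluxes(mp$problem, fit_options(n_starts = 4, seed = 2))
  ci1 <- monte_carlo_ci(mp$problem, fit, n_iterations = 30, seed = 7)
  ci2 <- monte_carlo_ci(mp$problem, fit, n_iterations = 30, seed = 7)
  expect_identical(ci1, ci2)
  # 95 % level uses the 2.5 % / 97.5 % percentiles
  d <- ci1$draws[, "v2"]
  expect_equal(ci1$intervals$lower[ci1$intervals$reaction_id == "v2"],
               unname(quantile(d, 0.025)))
  expect_equal(ci1$intervals$upper[ci1$intervals$reaction_id == "v2"],
               unname(quantile(d, 0.975)))
})

test_that("degenerate problems are reported", {
  lines <- c("# MET S 1 external substrate", "# MET A 1 balanced",
             "# MET Ox 1 external",
             "u: S (a) -> A (a) @ uptake", "e: A (a) -> Ox (a) @ excretion")
  f <- withr::local_tempfile(lines = lines)
  net <- read_network(f)
  rec <- list(S = tracer_recipe("S", data.frame(positions = "1", fraction = 1,
                                                purity = 1), 1))
  fl <- flux_state(net, c(u = 100, e = 100))
  exp <- generate_experiment(net, fl, rec,
                             list(fragment_spec("A1", "A", 1)),
                             noise_sd = 0, seed = 1)
  p <- flux_problem(net, rec, exp$measurements, c(u = 100))
  expect_equal(p$n_par, 0)
  expect_warning(fit <- fit_fluxes(p), "degenerate")
  expect_equal(unname(fit$best_flux$net), c(100, 100))
})
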