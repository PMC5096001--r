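# shared fixtures: packaged templates with their default study conditions

toy1_setup <- function() {
  net <- load_template("toy1")
  list(net = net,
       recipe = default_tracers("toy1"),
       fragments = default_fragments("toy1"),
       flux_meas = default_flux_measurements("toy1"))
}

cc_setup <- function() {
  net <- load_template("central_carbon")
  list(net = net,
       recipe = default_tracers("central_carbon"),
       fragments = default_fragments("central_carbon"),
       flux_meas = default_flux_measurements("central_carbon"))
}

tca_setup <- function() {
  net <- load_template("tca_micro")
  list(net = net,
       recipe = default_tracers("tca_micro"),
       fragments = default_fragments("tca_micro"),
       flux_meas = default_flux_measurements("tca_micro"))
}

# synthetic experiment + assembled problem in one call
make_problem <- function(setup, truth, noise_sd = 0, seed = 1,
                         fixed = NULL) {
  if (is.null(fixed)) {
    kinds <- vapply(setup$net$reactions, `[[`, character(1), "kind")
    fixed <- stats::setNames(100, names(setup$net$reactions)[kinds == "uptake"][1])
  }
  exp <- generate_experiment(setup$net, truth, setup$recipe, setup$fragments,
                             noise_sd = noise_sd, seed = seed,
                             flux_meas = setup$flux_meas)
  list(exp = exp,
       problem = flux_problem(setup$net, setup$recipe, exp$measurements, fixed))
}

# true parameter vector (variable free fluxes + log10 exchanges) of a problem
truth_theta <- function(problem, truth) {
  c(truth$net[problem$basis$free_ids[problem$variable]],
    log10(pmax(truth$exchange[problem$rev_active], 1e-4)))
}

# zero-natural-abundance isotope table for exact-label tests
table0 <- function() isotope_table(list(C = c(1, 0), H = c(1, 0), N = c(1, 0),
                                        O = c(1, 0, 0), Si = c(1, 0, 0),
                                        S = c(1, 0, 0)))
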