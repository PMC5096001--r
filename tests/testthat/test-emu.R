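test_that("decomposition of toy1 matches the hand-enumerated closure", {
  net <- load_template("toy1")
  frs <- default_fragments("toy1")
  sys <- emu_decompose(net, lapply(frs, function(f)
    list(met = f$metabolite_id, atoms = f$backbone_atoms)))
  # backward closure by hand: D{12},C{12} <- B{12} (v2) and B{23} (v3);
  # D{2},C{2} <- B{2},B{3}; B EMUs <- matching S EMUs
  expect_setequal(names(sys$emus),
                  c("D|1,2", "C|1,2", "B|1,2", "B|2,3", "S|1,2", "S|2,3",
                    "D|2", "C|2", "B|2", "B|3", "S|2", "S|3"))
  # no convolution nodes in a cleavage-only network
  expect_true(all(vapply(unlist(sys$producers, recursive = FALSE),
                         function(p) length(p$parts) == 1L, logical(1))))
  expect_error(emu_decompose(net, list(list(met = "D", atoms = 1:5))),
               "exceed")
})

test_that("condensations create convolution nodes", {
  lines <- c("# MET X 2 external substrate", "# MET Y 1 external substrate",
             "# MET A 2 balanced", "# MET E 1 balanced",
             "# MET P 3 balanced", "# MET Px 3 external",
             "u1: X (ab) -> A (ab) @ uptake", "u2: Y (c) -> E (c) @ uptake",
             "cnd: A (ab) + E (c) -> P (abc)",
             "e: P (abc) -> Px (abc) @ excretion")
  f <- withr::local_tempfile(lines = lines)
  net <- read_network(f)
  sys <- emu_decompose(net, list(list(met = "P", atoms = 1:3)))
  pr <- sys$producers[["P|1,2,3"]]
  expect_length(pr, 1)
  expect_setequal(pr[[1]]$parts, c("A|1,2", "E|1"))
})

test_that("simulated MIDs pass through chains and mix by flux", {
  # two producers at 60:40 with opposite labels mix to [0.6, 0.4]
  lines <- c("# MET X 1 external substrate", "# MET Y 1 external substrate",
             "# MET Bm 1 balanced", "# MET Ox 1 external",
             "u1: X (a) -> Bm (a) @ uptake", "u2: Y (a) -> Bm (a) @ uptake",
             "e: Bm (a) -> Ox (a) @ excretion")
  f <- withr::local_tempfile(lines = lines)
  net <- read_network(f)
  t0 <- table0()
  recs <- list(X = tracer_recipe("X", data.frame(positions = "", fraction = 1,
                                                 purity = 0), 1),
               Y = tracer_recipe("Y", data.frame(positions = "1", fraction = 1,
                                                 purity = 1), 1))
  sys <- emu_decompose(net, list(list(met = "Bm", atoms = 1)))
  fl <- flux_state(net, c(u1 = 60, u2 = 40, e = 100))
  st <- simulate_mids(sys, fl, substrate_labeling(sys, recs, t0))
  expect_equal(st[["Bm|1"]], c(0.6, 0.4), tolerance = 1e-12)
})

test_that("EMU and brute-force isotopomer simulations agree on toy1", {
  s <- toy1_setup()
  sys <- emu_decompose(s$net, lapply(s$fragments, function(f)
    list(met = f$metabolite_id, atoms = f$backbone_atoms)))
  for (seed in 1:5) {
    fl <- random_flux_state(s$net, seed = seed)
    st <- simulate_mids(sys, fl, substrate_labeling(sys, s$recipe))
    bf <- brute_force_mids(s$net, fl, s$recipe)
    for (fr in s$fragments) {
      m <- isotopomer_marginal(bf[[fr$metabolite_id]], fr$backbone_atoms)
      expect_lt(max(abs(m - st[[paste0(fr$metabolite_id, "|",
                                       paste(fr$backbone_atoms, collapse = ","))]])),
                1e-9)
    }
  }
})

test_that("flux-scale invariance: MIDs unchanged when all fluxes scale", {
  s <- tca_setup()
  sys <- emu_decompose(s$net, lapply(s$fragments, function(f)
    list(met = f$metabolite_id, atoms = f$backbone_atoms)))
  sub <- substrate_labeling(sys, s$recipe)
  fl <- random_flux_state(s$net, seed = 3)
  st1 <- simulate_mids(sys, fl, sub)
  fl2 <- fl; fl2$net <- fl$net * 7.3; fl2$exchange <- fl$exchange * 7.3
  st2 <- simulate_mids(sys, fl2, sub)
  for (k in names(st1)) expect_equal(st1[[k]], st2[[k]], tolerance = 1e-12)
})

test_that("large exchange flux equilibrates the two connected pools", {
  s <- toy1_setup()
  sys <- emu_decompose(s$net, lapply(s$fragments, function(f)
    list(met = f$metabolite_id, atoms = f$backbone_atoms)))
  sub <- substrate_labeling(sys, s$recipe)
  fl <- random_flux_state(s$net, seed = 9)
  mids <- lapply(c(1e6, 1e7), function(ex) {
    fl$exchange[["v4"]] <- ex
    st <- simulate_mids(sys, fl, sub)
    st[["D|1,2"]]
  })
  expect_lt(max(abs(mids[[1]] - mids[[2]])), 1e-6)
})

test_that("unlabeled substrate at natural abundance gives natural MIDs", {
  for (setup in list(toy1_setup(), tca_setup())) {
    tab <- isotope_table()
    unlab <- lapply(setup$recipe, function(r)
      tracer_recipe(r$substrate, data.frame(positions = "", fraction = 1,
                                            purity = 0), r$n_carbons))
    sys <- emu_decompose(setup$net, lapply(setup$fragments, function(f)
      list(met = f$metabolite_id, atoms = f$backbone_atoms)))
    fl <- random_flux_state(setup$net, seed = 2)
    st <- simulate_mids(sys, fl, substrate_labeling(sys, unlab, tab))
    for (fr in setup$fragments) {
      key <- paste0(fr$metabolite_id, "|", paste(fr$backbone_atoms, collapse = ","))
      expect_lt(max(abs(st[[key]] - natural_mid(length(fr$backbone_atoms), tab))),
                1e-9)
    }
  }
})

test_that("brute force handles trivial networks and enforces capacity", {
  lines <- c("# MET S 1 external substrate", "# MET A 1 balanced",
             "# MET Ox 1 external",
             "u: S (a) -> A (a) @ uptake", "e: A (a) -> Ox (a) @ excretion")
  f <- withr::local_tempfile(lines = lines)
  net <- read_network(f)
  rec <- tracer_recipe("S", data.frame(positions = "1", fraction = 1,
                                       purity = 1), 1)
  fl <- flux_state(net, c(u = 100, e = 100))
  bf <- brute_force_mids(net, fl, rec, table0())
  expect_equal(bf$A, c(0, 1))
  # unlabeled tracer at zero natural abundance: all mass on the light state
  rec0 <- tracer_recipe("S", data.frame(positions = "", fraction = 1,
                                        purity = 0), 1)
  expect_equal(brute_force_mids(net, fl, rec0, table0())$A, c(1, 0))

  big <- c("# MET S 13 external substrate", "# MET A 13 balanced",
           "# MET Ox 13 external",
           "u: S (abcdefghijklm) -> A (abcdefghijklm) @ uptake",
           "e: A (abcdefghijklm) -> Ox (abcdefghijklm) @ excretion")
  f2 <- withr::local_tempfile(lines = big)
  net2 <- read_network(f2)
  rec2 <- tracer_recipe("S", data.frame(positions = "1", fraction = 1,
                                        purity = 1), 13)
  expect_error(brute_force_mids(net2, flux_state(net2, c(u = 1, e = 1)), rec2),
               "state space")
})

test_that("measured_fragment_mids looks up exact EMUs deterministically", {
  s <- toy1_setup()
  sys <- emu_decompose(s$net, lapply(s$fragments, function(f)
    list(met = f$metabolite_id, atoms = f$backbone_atoms)))
  fl <- random_flux_state(s$net, seed = 4)
  st <- simulate_mids(sys, fl, substrate_labeling(sys, s$recipe))
  out <- measured_fragment_mids(st, s$fragments)
  # full-coverage fragment equals the metabolite's own MID
  expect_equal(out$D_full, st[["D|1,2"]])
  # duplicate-atom fragments agree
  twin <- fragment_spec("D_full2", "D", 1:2)
  expect_equal(measured_fragment_mids(st, list(twin))$D_full2, out$D_full)
  bad <- fragment_spec("missing", "B", 1:3)
  expect_error(measured_fragment_mids(st, list(bad)), "not part")
})

test_that("EMU graphs export as DOT", {
  s <- toy1_setup()
  sys <- emu_decompose(s$net, list(list(met = "D", atoms = 1:2)))
  dot <- emu_dot(sys)
  expect_match(dot, "^digraph emu \\{")
  expect_match(dot, "D\\|1,2")
  expect_equal(sum(strsplit(dot, "")[[1]] == "{"),
               sum(strsplit(dot, "")[[1]] == "}"))
})
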