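
#' Sample a random steady-state flux state
#'
#' Uniform rejection sampling of the free net fluxes inside their bounds
#' (intersected with twice the uptake scale), with exchange fluxes of active
#' reversible reactions drawn log-uniformly. The result satisfies the
#' steady-state constraint exactly and all flux bounds.
#'
#' @param net an `mfa_network`.
#' @param seed integer seed; identical seeds give identical states.
#' @param fixed named fixed fluxes; defaults to pinning the first uptake
#'   reaction at 100.
#' @param exchange_range range of the log-uniform exchange draw.
#' @param max_tries rejection-sampling cap.
#' @return a feasible [flux_state()].
#' @export
random_flux_state <- function(net, seed, fixed = NULL,
                              exchange_range = c(0.1, 50),
                              max_tries = 1e5) {
  if (is.null(fixed)) {
    kinds <- vapply(net$reactions, `[[`, character(1), "kind")
    upt <- names(net$reactions)[kinds == "uptake"]
    if (!length(upt)) stop("network has no uptake reaction to pin")
    fixed <- stats::setNames(100, upt[1])
  }
  basis <- free_flux_basis(net, fixed)
  ids <- reaction_ids(net)
  lb <- vapply(net$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(net$reactions, `[[`, numeric(1), "ub")
  scale <- sum(abs(unlist(fixed)))
  fi <- match(basis$free_ids, ids)
  lo <- pmax(lb[fi], -2 * scale); hi <- pmin(ub[fi], 2 * scale)
  set.seed(as.integer(seed))
  for (i in seq_len(max_tries)) {
    fv <- stats::runif(length(fi), lo, hi)
    fl <- basis$embed(fv)
    v <- fl$net
    if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9)) {
      rev_ids <- basis$reversible_ids
      active <- rev_ids[!(lb[match(rev_ids, ids)] == 0 & ub[match(rev_ids, ids)] == 0)]
      if (length(active)) {
        u <- stats::runif(length(active), log10(exchange_range[1]),
                          log10(exchange_range[2]))
        fl$exchange[active] <- 10^u
      }
      return(fl)
    }
  }
  stop("no feasible flux sample found in ", max_tries, " draws")
}

#' Generate a synthetic labeling experiment with known ground truth
#'
#' Simulates the fragment MIDs at a known flux state, forward-applies each
#' fragment's correction matrix to produce raw GC-MS-style intensities, and
#' perturbs the corrected MIDs with truncated Gaussian noise (clip at zero,
#' renormalize). Measured extracellular fluxes receive Gaussian noise of
#' their own sd. All randomness derives from `seed`; regenerating with the
#' same seed is bit-identical.
#'
#' @param net an `mfa_network`.
#' @param flux the true [flux_state()].
#' @param recipe a [tracer_recipe()] or named list of recipes.
#' @param fragments list of [fragment_spec()].
#' @param noise_sd sd of the MID perturbation (mol fraction); 0.004 is a
#'   typical GC-MS MID precision. 0 gives noiseless data.
#' @param seed integer seed.
#' @param flux_meas data.frame `reaction_id`, `sd` of rates to report as
#'   measured.
#' @param assay_sd sd written to the measurement table (reported assay
#'   precision; defaults to 0.004 even for noiseless data so weights stay
#'   well-defined).
#' @param raw_scale total intensity scale of the raw channels.
#' @param table an [isotope_table()].
#' @return object of class `synthetic_experiment`.
#' @export
generate_experiment <- function(net, flux, recipe, fragments,
                                noise_sd = 0.004, seed = 1L,
                                flux_meas = NULL, assay_sd = 0.004,
                                raw_scale = 1e6, table = isotope_table()) {
  stopifnot(noise_sd >= 0)
  targets <- lapply(fragments, function(fr)
    list(met = fr$metabolite_id, atoms = fr$backbone_atoms))
  sys <- emu_decompose(net, targets)
  state <- simulate_mids(sys, flux, substrate_labeling(sys, recipe, table))
  clean <- measured_fragment_mids(state, fragments)

  raw <- list()
  for (fr in fragments) {
    nb <- length(fr$backbone_atoms)
    C <- correction_matrix(fr, table, n_rows = nb + 4L)
    raw[[fr$fragment_id]] <- as.vector(C %*% clean[[fr$fragment_id]]) * raw_scale
  }

  set.seed(as.integer(seed))
  noisy <- list()
  for (fr in fragments) {
    x <- clean[[fr$fragment_id]]
    if (noise_sd > 0) x <- pmax(x + stats::rnorm(length(x), 0, noise_sd), 0)
    noisy[[fr$fragment_id]] <- x / sum(x)
  }
  fm <- NULL
  if (!is.null(flux_meas) && nrow(flux_meas)) {
    val <- flux$net[flux_meas$reaction_id]
    if (noise_sd > 0) val <- val + stats::rnorm(length(val), 0, flux_meas$sd)
    fm <- data.frame(reaction_id = flux_meas$reaction_id,
                     value = as.numeric(val), sd = flux_meas$sd)
  }
  mids <- lapply(seq_along(fragments), function(i)
    list(fragment = fragments[[i]],
         mid = noisy[[fragments[[i]]$fragment_id]],
         sd = rep(assay_sd, length(noisy[[fragments[[i]]$fragment_id]]))))
  structure(list(net = net, truth = flux, recipe = recipe,
                 fragments = fragments, clean_mids = clean,
                 raw = raw, measurements = measurement_set(mids, fm),
                 flux_meas = fm, noise_sd = noise_sd, assay_sd = assay_sd,
                 seed = as.integer(seed)),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment> ", length(x$fragments), " fragments, noise_sd = ",
      x$noise_sd, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' Writes the same file formats the command-line interface consumes: the
#' network model, the tracer recipe, the measurement table (raw and corrected
#' kinds) and a ground-truth JSON (fluxes, seed, settings).
#'
#' @param exp a [generate_experiment()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             tracers = file.path(dir, "tracers.csv"),
             measurements = file.path(dir, "measurements.csv"),
             truth = file.path(dir, "truth.json"))
  write_network(exp$net, paths["network"])
  write_tracers(exp$recipe, paths["tracers"])
  write_measurements(exp, paths["measurements"])
  truth <- list(net = as.list(exp$truth$net),
                exchange = as.list(exp$truth$exchange),
                seed = exp$seed, noise_sd = exp$noise_sd,
                assay_sd = exp$assay_sd)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
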