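
#' Measurement set for flux fitting
#'
#' @param mid_measurements list of `list(fragment = fragment_spec, mid =
#'   numeric, sd = numeric)`; `sd` recycles to the MID length.
#' @param flux_measurements data.frame with columns `reaction_id`, `value`,
#'   `sd` (measured extracellular rates entering the objective).
#' @param excluded_fragments fragment ids dropped before fitting (e.g. ions
#'   with poor signal-to-noise).
#' @return object of class `measurement_set`.
#' @export
measurement_set <- function(mid_measurements = list(),
                            flux_measurements = NULL,
                            excluded_fragments = character(0)) {
  keep <- list()
  for (m in mid_measurements) {
    if (m$fragment$fragment_id %in% excluded_fragments) next
    m$mid <- check_mid(m$mid)
    m$sd <- rep(m$sd, length.out = length(m$mid))
    if (any(m$sd < 0)) stop("measurement sd must be non-negative")
    keep[[length(keep) + 1L]] <- m
  }
  if (is.null(flux_measurements))
    flux_measurements <- data.frame(reaction_id = character(0),
                                    value = numeric(0), sd = numeric(0))
  if (any(flux_measurements$sd <= 0) && nrow(flux_measurements))
    stop("flux measurement sd must be positive")
  structure(list(mid_measurements = keep,
                 flux_measurements = flux_measurements,
                 excluded_fragments = excluded_fragments),
            class = "measurement_set")
}

#' Fitting options
#'
#' @param n_starts number of random multi-start initial guesses.
#' @param max_iterations per-start iteration cap of the local optimizer.
#' @param tolerance relative convergence tolerance.
#' @param seed integer seed governing all randomness of the fit.
#' @param sd_floor smallest usable measurement sd (guards weights against
#'   zero-sd datapoints).
#' @return object of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10L, max_iterations = 500L,
                        tolerance = 1e-9, seed = 1L, sd_floor = 1e-6) {
  stopifnot(n_starts >= 1, max_iterations >= 1, tolerance > 0)
  structure(list(n_starts = as.integer(n_starts),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed),
                 sd_floor = sd_floor),
            class = "fit_options")
}

#' Assemble a flux-fitting problem
#'
#' Bundles the network, the free-flux parameterization, the EMU system for the
#' measured fragments, the substrate labeling and the measurements into one
#' object consumed by [ssr_objective()], [fit_fluxes()], [monte_carlo_ci()]
#' and [po_ratio_scan()].
#'
#' Parameters of the fit are the free net fluxes whose bounds leave room to
#' move (a free reaction with `lb == ub` is pinned) plus one log10-scaled
#' exchange flux per active reversible reaction. Datapoints count each
#' retained fragment as its backbone size (the MID closes to 1, so one entry
#' is redundant) plus one per measured flux; the `dof` element is the nominal
#' datapoints-minus-parameters count, while fitted results report degrees of
#' freedom with the effective (Jacobian-rank) parameter count, which
#' discounts parameters the data cannot see.
#'
#' @param net an `mfa_network`.
#' @param recipe a [tracer_recipe()] or named list of recipes.
#' @param measurements a [measurement_set()].
#' @param fixed named numeric vector of fixed fluxes (e.g. uptake = 100).
#' @param table an [isotope_table()].
#' @param extra_rows extra linear equality constraints on net fluxes (see
#'   [free_flux_basis()]).
#' @return object of class `flux_problem`.
#' @export
flux_problem <- function(net, recipe, measurements, fixed,
                         table = isotope_table(), extra_rows = NULL) {
  stopifnot(inherits(measurements, "measurement_set"))
  basis <- free_flux_basis(net, fixed, extra_rows)
  frags <- lapply(measurements$mid_measurements, `[[`, "fragment")
  targets <- lapply(frags, function(fr)
    list(met = fr$metabolite_id, atoms = fr$backbone_atoms))
  sys <- emu_decompose(net, targets)
  sub_mids <- substrate_labeling(sys, recipe, table)

  ids <- reaction_ids(net)
  lb <- vapply(net$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(net$reactions, `[[`, numeric(1), "ub")
  free_idx <- match(basis$free_ids, ids)
  variable <- lb[free_idx] < ub[free_idx]
  rev_ids <- basis$reversible_ids
  rev_active <- rev_ids[!(lb[match(rev_ids, ids)] == 0 & ub[match(rev_ids, ids)] == 0)]

  n_par <- sum(variable) + length(rev_active)
  n_data <- sum(vapply(measurements$mid_measurements,
                       function(m) length(m$mid) - 1L, integer(1))) +
    nrow(measurements$flux_measurements)

  structure(list(
    net = net, basis = basis, sys = sys, sub_mids = sub_mids,
    measurements = measurements, recipe = recipe, table = table,
    fixed = fixed, extra_rows = extra_rows,
    free_lb = lb[free_idx], free_ub = ub[free_idx],
    dep_lb = lb[match(basis$dep_ids, ids)],
    dep_ub = ub[match(basis$dep_ids, ids)],
    variable = variable, rev_active = rev_active,
    exch_log_lb = -4, exch_log_ub = 3,
    n_par = n_par, n_data = n_data, dof = n_data - n_par,
    scale = if (length(fixed)) sum(abs(unlist(fixed))) else 100
  ), class = "flux_problem")
}

#' @export
print.flux_problem <- function(x, ...) {
  cat("<flux_problem> ", x$n_par, " parameters (",
      sum(x$variable), " net + ", length(x$rev_active), " exchange), ",
      x$n_data, " datapoints, nominal dof = ", x$dof, "\n", sep = "")
  invisible(x)
}

# theta layout: variable free fluxes, then log10 exchange of active
# reversible reactions
theta_to_flux <- function(theta, problem) {
  fv <- numeric(length(problem$basis$free_ids))
  fv[!problem$variable] <- problem$free_lb[!problem$variable]
  fv[problem$variable] <- theta[seq_len(sum(problem$variable))]
  ex <- NULL
  if (length(problem$rev_active)) {
    u <- theta[sum(problem$variable) + seq_along(problem$rev_active)]
    ex <- stats::setNames(10^u, problem$rev_active)
  }
  problem$basis$embed(fv, ex)
}

theta_bounds <- function(problem) {
  list(lower = c(problem$free_lb[problem$variable],
                 rep(problem$exch_log_lb, length(problem$rev_active))),
       upper = c(problem$free_ub[problem$variable],
                 rep(problem$exch_log_ub, length(problem$rev_active))))
}

# weighted residual vector at a flux state (no penalty terms)
problem_residuals <- function(problem, flux, sd_floor = 1e-6) {
  state <- simulate_mids(problem$sys, flux, problem$sub_mids)
  res <- numeric(0)
  for (m in problem$measurements$mid_measurements) {
    key <- emu_key(m$fragment$metabolite_id, m$fragment$backbone_atoms)
    sim <- state[[key]]
    r <- (sim - m$mid) / pmax(m$sd, sd_floor)
    names(r) <- paste0(m$fragment$fragment_id, ".m", seq_along(r) - 1L)
    res <- c(res, r)
  }
  fm <- problem$measurements$flux_measurements
  if (nrow(fm)) {
    r <- (flux$net[fm$reaction_id] - fm$value) / pmax(fm$sd, sd_floor)
    names(r) <- paste0("flux.", fm$reaction_id)
    res <- c(res, r)
  }
  res
}

#' Weighted sum-of-squared-residuals objective
#'
#' SSR over all retained MID entries and measured fluxes, each residual
#' divided by its measurement standard deviation. Dependent-flux bound
#' violations add a smooth quadratic penalty so the optimizer stays inside
#' the feasible polytope; simulation failures return a large penalty value
#' instead of aborting the optimization.
#'
#' @param theta parameter vector (variable free fluxes, then log10 exchange
#'   fluxes).
#' @param problem a [flux_problem()].
#' @param penalize add bound penalties (TRUE during optimization).
#' @return non-negative scalar.
#' @export
ssr_objective <- function(theta, problem, penalize = TRUE) {
  out <- tryCatch({
    flux <- theta_to_flux(theta, problem)
    pen <- 0
    if (penalize) {
      v <- flux$net[problem$basis$dep_ids]
      viol <- pmax(problem$dep_lb - v, 0) + pmax(v - problem$dep_ub, 0)
      pen <- 1e4 * sum(viol^2)
    }
    res <- problem_residuals(problem, flux, problem$sd_floor %||% 1e-6)
    sum(res^2) + pen
  }, error = function(e) NA_real_)
  if (!is.finite(out)) 1e10 else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

theta_feasible <- function(theta, problem, tol = 1e-7) {
  tryCatch({
    fl <- theta_to_flux(theta, problem)
    v <- fl$net[problem$basis$dep_ids]
    all(v >= problem$dep_lb - tol) && all(v <= problem$dep_ub + tol)
  }, error = function(e) FALSE)
}

# deterministic phase-1 point: minimize dependent-bound violation over the
# variable free fluxes from the box midpoint
phase1_point <- function(problem) {
  bb <- theta_bounds(problem)
  nv <- sum(problem$variable)
  lo <- pmax(bb$lower[seq_len(nv)], -2 * problem$scale)
  hi <- pmin(bb$upper[seq_len(nv)], 2 * problem$scale)
  viol <- function(th) {
    fl <- theta_to_flux(c(th, numeric(length(problem$rev_active))), problem)
    v <- fl$net[problem$basis$dep_ids]
    sum(pmax(problem$dep_lb - v, 0)^2 + pmax(v - problem$dep_ub, 0)^2)
  }
  if (nv == 0L) return(numeric(0))
  fit <- stats::nlminb((lo + hi) / 2, viol, lower = lo, upper = hi,
                       control = list(iter.max = 500L))
  if (fit$objective > 1e-8)
    stop("no feasible flux state within bounds (phase-1 violation ",
         signif(fit$objective, 3), ")")
  fit$par
}

# rejection-sample a feasible start inside the free-flux bounding box; the
# box contracts toward the phase-1 feasible point when acceptance is poor
sample_start <- function(problem, center, max_tries = 20000L) {
  bb <- theta_bounds(problem)
  nv <- sum(problem$variable)
  lo <- pmax(bb$lower[seq_len(nv)], -2 * problem$scale)
  hi <- pmin(bb$upper[seq_len(nv)], 2 * problem$scale)
  for (try in seq_len(max_tries)) {
    th_net <- stats::runif(nv, lo, hi)
    th_ex <- stats::runif(length(problem$rev_active), -3, 3)
    th <- c(th_net, th_ex)
    if (theta_feasible(th, problem)) return(th)
    if (try %% 1000L == 0L && nv > 0L) {
      lo <- center + 0.7 * (lo - center)
      hi <- center + 0.7 * (hi - center)
    }
  }
  # the feasible set can be measure-zero in the box (e.g. a knockout pinning
  # a dependent flux): project random draws onto it instead
  viol <- function(thn) {
    fl <- theta_to_flux(c(thn, numeric(length(problem$rev_active))), problem)
    v <- fl$net[problem$basis$dep_ids]
    sum(pmax(problem$dep_lb - v, 0)^2 + pmax(v - problem$dep_ub, 0)^2)
  }
  for (try in 1:5) {
    thn <- stats::runif(nv, lo, hi)
    pr <- stats::nlminb(thn, viol, lower = lo, upper = hi,
                        control = list(iter.max = 200L))
    th <- c(pr$par, stats::runif(length(problem$rev_active), -3, 3))
    if (theta_feasible(th, problem)) return(th)
  }
  NULL
}

#' Fit fluxes by multi-start weighted nonlinear least squares
#'
#' Runs `n_starts` local bound-constrained minimizations of
#' [ssr_objective()] from seeded random feasible starts and keeps the best
#' converged solution (ties broken by lowest start index). Deterministic
#' given `options$seed`.
#'
#' @param problem a [flux_problem()].
#' @param options a [fit_options()].
#' @param start optional explicit start (`theta` vector); replaces the first
#'   random start.
#' @return object of class `fit_result` with elements `best_flux`, `ssr`,
#'   `residuals`, `simulated_mids`, `per_start`, `dof`, `theta`.
#' @export
fit_fluxes <- function(problem, options = fit_options(), start = NULL) {
  bb <- theta_bounds(problem)
  if (problem$n_par == 0L) {
    warning("degenerate fit: no free parameters; evaluating the unique flux state")
    th <- numeric(0)
    return(finish_fit(problem, th, data.frame(
      start = 1L, ssr = ssr_objective(th, problem), convergence = 0L,
      message = "evaluate-only"), options))
  }
  center <- phase1_point(problem)
  set.seed(options$seed)
  starts <- vector("list", options$n_starts)
  for (i in seq_len(options$n_starts)) {
    s <- sample_start(problem, center)
    if (is.null(s)) stop("could not sample a feasible start within bounds")
    starts[[i]] <- s
  }
  if (!is.null(start)) starts[[1L]] <- start

  per <- vector("list", options$n_starts)
  best <- NULL
  for (i in seq_len(options$n_starts)) {
    fit <- stats::nlminb(starts[[i]], ssr_objective, problem = problem,
                         lower = bb$lower, upper = bb$upper,
                         control = list(iter.max = options$max_iterations,
                                        eval.max = 4L * options$max_iterations,
                                        rel.tol = options$tolerance))
    per[[i]] <- data.frame(start = i, ssr = fit$objective,
                           convergence = fit$convergence,
                           message = fit$message, stringsAsFactors = FALSE)
    if (is.finite(fit$objective) &&
        (is.null(best) || fit$objective < best$objective - 1e-9))
      best <- list(objective = fit$objective, par = fit$par, start = i)
  }
  if (is.null(best)) stop("no start converged to a finite objective")
  finish_fit(problem, best$par, do.call(rbind, per), options)
}

# effective number of fitted parameters: rank of the weighted residual
# Jacobian at the solution. A parameter the data cannot see (e.g. the
# exchange flux of a reversible step joining identically labeled pools)
# contributes a zero column and must not consume a degree of freedom.
effective_rank <- function(problem, theta, h = 1e-5) {
  if (!length(theta)) return(0L)
  r0 <- problem_residuals(problem, theta_to_flux(theta, problem),
                          problem$sd_floor %||% 1e-6)
  J <- vapply(seq_along(theta), function(j) {
    th <- theta; th[j] <- th[j] + h
    r1 <- tryCatch(problem_residuals(problem, theta_to_flux(th, problem),
                                     problem$sd_floor %||% 1e-6),
                   error = function(e) r0)
    (r1 - r0) / h
  }, numeric(length(r0)))
  s <- svd(J, nu = 0, nv = 0)$d
  sum(s > max(s[1], 1e-12) * 1e-6)
}

finish_fit <- function(problem, theta, per_start, options) {
  flux <- theta_to_flux(theta, problem)
  res <- problem_residuals(problem, flux, options$sd_floor)
  state <- simulate_mids(problem$sys, flux, problem$sub_mids)
  sims <- measured_fragment_mids(
    state, lapply(problem$measurements$mid_measurements, `[[`, "fragment"))
  dof <- problem$n_data - effective_rank(problem, theta)
  structure(list(best_flux = flux, ssr = sum(res^2), residuals = res,
                 simulated_mids = sims, per_start = per_start,
                 dof = dof, n_par_nominal = problem$n_par,
                 theta = theta, options = options),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> SSR =", format(x$ssr, digits = 6),
      "on", x$dof, "degrees of freedom\n")
  print(round(x$best_flux$net, 3))
  invisible(x)
}

#' Chi-squared goodness-of-fit test
#'
#' Two-sided by default: the fit is statistically acceptable when the SSR
#' falls between the lower and upper alpha/2 quantiles of the chi-squared
#' distribution with `dof` degrees of freedom (the upper tail flags lack of
#' fit, the lower tail overestimated measurement variances).
#'
#' @param ssr fitted sum of squared weighted residuals.
#' @param dof degrees of freedom (>= 1).
#' @param alpha significance level.
#' @param two_sided use the two-sided acceptance region (FALSE = upper only).
#' @return list with `pass`, `lower_critical`, `upper_critical`.
#' @export
chi2_test <- function(ssr, dof, alpha = 0.05, two_sided = TRUE) {
  if (dof < 1) stop("over-parameterized model: dof must be >= 1")
  lo <- if (two_sided) stats::qchisq(alpha / 2, dof) else 0
  hi <- stats::qchisq(1 - alpha / (if (two_sided) 2 else 1), dof)
  list(pass = ssr >= lo && ssr <= hi, lower_critical = lo, upper_critical = hi)
}

#' Monte-Carlo bootstrap confidence intervals for fluxes
#'
#' Perturbs every measured datapoint with independent Gaussian noise of its
#' own standard deviation (MIDs are clipped at zero and renormalized), refits
#' from the base solution, and reports empirical percentile intervals of the
#' refitted net fluxes.
#'
#' @param problem a [flux_problem()].
#' @param base_fit a converged [fit_fluxes()] result.
#' @param n_iterations number of Monte-Carlo refits (>= 2).
#' @param level confidence level (0.95 = bounds at the 2.5 % and 97.5 %
#'   percentiles).
#' @param seed integer seed.
#' @param max_iterations optimizer iteration cap per refit.
#' @return object of class `ci_result`: data.frame with per-reaction point
#'   estimate and interval, plus the refit flux draws.
#' @export
monte_carlo_ci <- function(problem, base_fit, n_iterations = 100L,
                           level = 0.95, seed = 1L, max_iterations = 200L) {
  stopifnot(n_iterations >= 2, level > 0, level < 1)
  bb <- theta_bounds(problem)
  meas <- problem$measurements
  set.seed(seed)
  # pre-draw all noise so refit internals cannot shift the stream
  noise_mid <- lapply(seq_len(n_iterations), function(i)
    lapply(meas$mid_measurements, function(m) stats::rnorm(length(m$mid), 0, m$sd)))
  noise_flux <- lapply(seq_len(n_iterations), function(i)
    if (nrow(meas$flux_measurements))
      stats::rnorm(nrow(meas$flux_measurements), 0, meas$flux_measurements$sd)
    else numeric(0))

  draws <- matrix(NA_real_, n_iterations, length(base_fit$best_flux$net),
                  dimnames = list(NULL, names(base_fit$best_flux$net)))
  failed <- 0L
  for (it in seq_len(n_iterations)) {
    pm <- meas
    for (j in seq_along(pm$mid_measurements)) {
      x <- pm$mid_measurements[[j]]$mid + noise_mid[[it]][[j]]
      x <- pmax(x, 0)
      pm$mid_measurements[[j]]$mid <- x / sum(x)
    }
    if (nrow(pm$flux_measurements))
      pm$flux_measurements$value <- pm$flux_measurements$value + noise_flux[[it]]
    pp <- problem
    pp$measurements <- pm
    fit <- tryCatch(
      stats::nlminb(base_fit$theta, ssr_objective, problem = pp,
                    lower = bb$lower, upper = bb$upper,
                    control = list(iter.max = max_iterations,
                                   eval.max = 4L * max_iterations,
                                   rel.tol = 1e-8)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) { failed <- failed + 1L; next }
    draws[it, ] <- theta_to_flux(fit$par, pp)$net
  }
  if (failed > 0.2 * n_iterations)
    stop("more than 20 % of Monte-Carlo refits failed; intervals unreliable")

  a <- (1 - level) / 2
  ok <- stats::complete.cases(draws)
  q <- apply(draws[ok, , drop = FALSE], 2, stats::quantile, probs = c(a, 1 - a))
  tab <- data.frame(reaction_id = colnames(draws),
                    estimate = as.numeric(base_fit$best_flux$net),
                    lower = q[1, ], upper = q[2, ],
                    level = level, row.names = NULL)
  structure(list(intervals = tab, draws = draws[ok, , drop = FALSE],
                 n_iterations = n_iterations, n_failed = failed, seed = seed),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat("<ci_result>", nrow(x$draws), "successful Monte-Carlo refits\n")
  print(transform(x$intervals, estimate = round(estimate, 3),
                  lower = round(lower, 3), upper = round(upper, 3)))
  invisible(x)
}
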